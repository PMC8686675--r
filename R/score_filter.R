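# Feature rescaling, aggregate score, edge filtering against the
# top-XCorr edge, and the aggregate-weight grid search.

FEATURES5 <- c("tailor", "wP", "wF", "wR", "wE")

#' Fit the per-feature quantile rescaler
#'
#' Records, for each of the five evidence features, the 1st and 99th
#' empirical quantiles (linear interpolation between order statistics)
#' over all edges, targets and decoys alike.  The transform maps the two
#' quantiles to 0 and 1 without clamping; a degenerate feature (equal
#' quantiles) maps every value to 0.5.
#'
#' @param edges Edge data frame carrying the five feature columns.
#' @param probs Quantile probabilities (default `c(0.01, 0.99)`).
#' @return A list of class `"feature_scaler"` mapping feature name to
#'   `c(q_lo, q_hi)`.
#' @export
fit_scaler <- function(edges, probs = c(0.01, 0.99)) {
  if (nrow(edges) < 2L) {
    warning("fewer than 2 edges; identity scaler")
    sc <- lapply(FEATURES5, function(f) c(0, 1))
  } else {
    sc <- lapply(FEATURES5, function(f)
      unname(stats::quantile(edges[[f]], probs = probs, type = 7,
                             names = FALSE)))
  }
  names(sc) <- FEATURES5
  structure(sc, class = "feature_scaler")
}

#' Apply a fitted scaler to edge features
#'
#' @param edges Edge data frame.
#' @param scaler A `"feature_scaler"`.
#' @return The edges with rescaled feature columns `tailor_s`, `wP_s`,
#'   `wF_s`, `wR_s`, `wE_s`.
#' @export
apply_scaler <- function(edges, scaler) {
  for (f in FEATURES5) {
    q <- scaler[[f]]
    edges[[paste0(f, "_s")]] <- if (q[2] > q[1]) {
      (edges[[f]] - q[1]) / (q[2] - q[1])
    } else {
      rep(0.5, nrow(edges))
    }
  }
  edges
}

#' Aggregate edge score
#'
#' Weighted sum of the rescaled features with unit weight on the
#' calibrated XCorr: `w = tailor_s + aP * wP_s + aF * wF_s + aR * wR_s +
#' aE * wE_s`.
#'
#' @param edges Edge data frame with rescaled feature columns (see
#'   [apply_scaler()]).
#' @param alphas Named weights `c(P=, F=, R=, E=)`.
#' @return The edges with an `aggregate` column.
#' @export
aggregate_score <- function(edges, alphas) {
  need <- paste0(FEATURES5, "_s")
  if (!all(need %in% names(edges)))
    stop("rescaled features missing; call apply_scaler() first")
  edges$aggregate <- edges$tailor_s +
    alphas[["P"]] * edges$wP_s + alphas[["F"]] * edges$wF_s +
    alphas[["R"]] * edges$wR_s + alphas[["E"]] * edges$wE_s
  edges
}

#' Filter edges against the top-XCorr edge of each spectrum-charge group
#'
#' Within every (spectrum, charge) group the edge with maximal raw XCorr
#' defines a reference aggregate score; edges with a strictly smaller
#' aggregate score are discarded.  The reference edge itself always
#' survives, so no non-empty group is emptied.
#'
#' @param edges Edge data frame with `aggregate`, `xcorr` and `group`
#'   columns (groups are spectrum-charge units from [build_graph()]).
#' @return The surviving edges.
#' @export
filter_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  keep <- logical(nrow(edges))
  for (idx in split(seq_len(nrow(edges)), edges$group)) {
    ref <- idx[which.max(edges$xcorr[idx])]
    keep[idx] <- edges$aggregate[idx] >= edges$aggregate[ref]
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid search over the aggregate-score weights
#'
#' Maximizes a user-supplied objective (typically the number of accepted
#' peptides at 1% FDR) over a grid of candidate values per weight, either
#' exhaustively or by coordinate ascent.  Ties are broken toward the
#' lexicographically smallest weight vector, so a constant objective
#' returns all-zero weights.
#'
#' @param objective Function taking a named weight vector `c(P=, F=, R=,
#'   E=)` and returning a scalar to maximize.
#' @param grid Candidate values (default the shipped 10-value grid).
#' @param strategy `"coordinate"` (default; cycles through the four
#'   weights until no change) or `"full"` (all `length(grid)^4`
#'   combinations).
#' @param start Starting point for coordinate ascent (default all zero).
#' @return The best named weight vector found.
#' @export
grid_search_alphas <- function(objective,
                               grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.8,
                                        1.6, 3.2, 6.4, 12.8),
                               strategy = c("coordinate", "full"),
                               start = c(P = 0, F = 0, R = 0, E = 0)) {
  strategy <- match.arg(strategy)
  grid <- sort(grid)
  nm <- c("P", "F", "R", "E")
  if (strategy == "full") {
    best <- NULL; best_val <- -Inf
    for (aP in grid) for (aF in grid) for (aR in grid) for (aE in grid) {
      a <- c(P = aP, F = aF, R = aR, E = aE)
      v <- objective(a)
      if (v > best_val) { best_val <- v; best <- a }
    }
    return(best)
  }
  a <- start[nm]
  repeat {
    changed <- FALSE
    for (k in nm) {
      vals <- vapply(grid, function(g) {
        trial <- a; trial[k] <- g
        objective(trial)
      }, numeric(1))
      g_best <- grid[which.max(vals)]   # ties -> smallest grid value
      if (g_best != a[k]) { a[k] <- g_best; changed <- TRUE }
    }
    if (!changed) break
  }
  a
}
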