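# Primary search: SEQUEST-style fast XCorr scoring of every in-window
# precursor against every MS2 spectrum, top-k retention per spectrum and
# charge, Tailor score calibration and rank-gap features.

# Discretization of an m/z value onto the XCorr grid.
mz_bin <- function(mz, bin_width, bin_offset) {
  as.integer(floor(mz / bin_width + 1 - bin_offset))
}

#' Preprocess a centroided MS2 spectrum for XCorr scoring
#'
#' Square-root intensity transform, discretization onto a fixed-width m/z
#' grid (maximum intensity per bin), normalization of 10 equal m/z regions
#' to a common maximum of 50, and the fast-XCorr background subtraction:
#' each bin minus the mean of the bins at offsets +/-1..+/-75.
#'
#' @param spectrum A [dia_spectrum()] (MS level 2).
#' @param bin_width,bin_offset Grid parameters (defaults 1.0005079 Th,
#'   0.4).
#' @return A list of class `"binned_spectrum"` with the background-
#'   subtracted intensity vector `values` (index = bin number) and the
#'   grid parameters.  An empty spectrum yields an all-zero vector.
#' @export
preprocess_for_xcorr <- function(spectrum, bin_width = 1.0005079,
                                 bin_offset = 0.4) {
  if (length(spectrum$mz) == 0L) {
    return(structure(list(values = numeric(0), bin_width = bin_width,
                          bin_offset = bin_offset, n_regions = 10L,
                          norm_cap = 50),
                     class = "binned_spectrum"))
  }
  bins <- mz_bin(spectrum$mz, bin_width, bin_offset)
  ok <- bins >= 1L
  bins <- bins[ok]
  if (length(bins) == 0L) {
    return(structure(list(values = numeric(0), bin_width = bin_width,
                          bin_offset = bin_offset, n_regions = 10L,
                          norm_cap = 50),
                     class = "binned_spectrum"))
  }
  nb <- max(bins)
  x <- numeric(nb)
  sq <- sqrt(spectrum$intensity[ok])
  # max sqrt-intensity per bin
  agg <- tapply(sq, bins, max)
  x[as.integer(names(agg))] <- agg
  # 10 equal regions, each normalized to a maximum of 50
  region_len <- ceiling(nb / 10)
  for (r in seq_len(10)) {
    lo <- (r - 1L) * region_len + 1L
    hi <- min(r * region_len, nb)
    if (lo > hi) break
    m <- max(x[lo:hi])
    if (m > 0) x[lo:hi] <- x[lo:hi] * (50 / m)
  }
  # background subtraction: x[i] - mean over offsets +/-1..+/-75
  pad <- 75L
  xp <- c(numeric(pad), x, numeric(pad))
  cs <- c(0, cumsum(xp))                      # cs[j+1] = sum(xp[1..j])
  i <- seq_len(nb) + pad
  win_sum <- cs[i + pad + 1L] - cs[i - pad]   # sum over offsets -75..+75
  y <- x - (win_sum - x) / (2 * pad)
  structure(list(values = y, bin_width = bin_width, bin_offset = bin_offset,
                 n_regions = 10L, norm_cap = 50),
            class = "binned_spectrum")
}

#' XCorr score of a fragment set against a preprocessed spectrum
#'
#' Dot product of the unit-intensity theoretical fragment bins with the
#' background-subtracted observed vector, scaled by 0.005 (the SEQUEST
#' convention).  Each occupied theoretical bin counts once.
#'
#' @param binned A `"binned_spectrum"` from [preprocess_for_xcorr()].
#' @param fragment_mz Numeric vector of theoretical fragment m/z values.
#' @return Numeric score.
#' @export
xcorr_score <- function(binned, fragment_mz) {
  if (length(binned$values) == 0L || length(fragment_mz) == 0L) return(0)
  bins <- unique(mz_bin(fragment_mz, binned$bin_width, binned$bin_offset))
  bins <- bins[bins >= 1L & bins <= length(binned$values)]
  0.005 * sum(binned$values[bins])
}

#' Build the bipartite spectrum-to-precursor graph
#'
#' Every precursor whose theoretical m/z lies inside an MS2 spectrum's
#' isolation window (closed interval) is scored against that spectrum with
#' XCorr; per spectrum and charge state, the `top_k` highest-scoring edges
#' are retained.  The candidate count N and the full sorted candidate
#' score list per (spectrum, charge) are recorded before truncation for
#' Tailor calibration.  Ties in the top-k are broken by higher XCorr, then
#' lexicographically smaller peptide, then target before decoy.
#'
#' @param run A [dia_run()].
#' @param db A `"precursor_db"`.
#' @param config A [dia_config()]; `top_k`, `charges` and the bin
#'   parameters are used here.
#' @return A list of class `"bipartite_graph"`: `edges` (data frame with
#'   `spectrum_idx`, `prec_idx`, `charge`, `xcorr`, `rank`), `cand`
#'   (per spectrum-charge candidate count `n` and sorted score list) and
#'   the `run`/`db` references.
#' @export
build_graph <- function(run, db, config = dia_config()) {
  prec <- db$precursors
  charges <- intersect(config$charges, sort(unique(prec$charge)))
  # per-precursor theoretical bins, computed once
  bw <- config$bin_width; bo <- config$bin_offset
  frag_bins <- vector("list", nrow(prec))
  ms2 <- which(vapply(run$spectra, function(s) s$ms_level, integer(1)) == 2L)
  ord <- order(prec$mz)
  prec_mz_sorted <- prec$mz[ord]
  edges <- list(); cand <- list(); ci <- 0L
  for (si in ms2) {
    s <- run$spectra[[si]]
    binned <- preprocess_for_xcorr(s, bw, bo)
    if (length(binned$values) == 0L) next
    in_win <- ord[seq_range(prec_mz_sorted, s$window[1], s$window[2])]
    if (length(in_win) == 0L) next
    for (ch in charges) {
      cand_idx <- in_win[prec$charge[in_win] == ch]
      n <- length(cand_idx)
      if (n == 0L) next
      # fill missing fragment-bin caches
      need <- cand_idx[vapply(frag_bins[cand_idx], is.null, logical(1))]
      for (p in need) {
        fb <- unique(mz_bin(precursor_fragments(db, p), bw, bo))
        frag_bins[[p]] <- fb[fb >= 1L]
      }
      L <- length(binned$values)
      scores <- vapply(cand_idx, function(p) {
        b <- frag_bins[[p]]
        b <- b[b <= L]
        if (length(b)) 0.005 * sum(binned$values[b]) else 0
      }, numeric(1))
      pep <- db$peptides$sequence[prec$peptide_idx[cand_idx]]
      o <- order(-scores, pep, prec$is_decoy[cand_idx])
      keep <- o[seq_len(min(config$top_k, n))]
      ci <- ci + 1L
      cand[[ci]] <- list(spectrum_idx = si, charge = ch, n = n,
                         sorted_scores = sort(scores, decreasing = TRUE))
      edges[[ci]] <- data.frame(
        spectrum_idx = si, prec_idx = cand_idx[keep], charge = ch,
        xcorr = scores[keep], rank = seq_along(keep), group = ci)
    }
  }
  if (length(edges) == 0L) {
    warning("no precursor falls in any isolation window; empty graph")
    edges_df <- data.frame(spectrum_idx = integer(0), prec_idx = integer(0),
                           charge = integer(0), xcorr = numeric(0),
                           rank = integer(0), group = integer(0))
  } else {
    edges_df <- do.call(rbind, edges)
  }
  structure(list(edges = edges_df, cand = cand, run = run, db = db,
                 config = config),
            class = "bipartite_graph")
}

# Indices i with lo <= v[i] <= hi for sorted v (closed interval).
seq_range <- function(v, lo, hi) {
  a <- findInterval(lo, v, left.open = TRUE)    # count of v < lo
  b <- findInterval(hi, v)                      # count of v <= hi
  if (b <= a) integer(0) else (a + 1L):b
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("Bipartite spectrum-precursor graph: %d edges over %d spectra\n",
              nrow(x$edges), length(unique(x$edges$spectrum_idx))))
  invisible(x)
}

#' Tailor calibration of XCorr scores
#'
#' Divides each retained edge's XCorr by the spectrum- and charge-specific
#' score at sorted position `[N/100]` (1-based in decreasing order, `[.]`
#' = round half away from zero, floored at position 1), where N counts all
#' candidates scored for that spectrum and charge before top-k truncation.
#' This maps the score distribution's upper tail to a common scale (the
#' divisor approximates the 99th percentile score).
#'
#' @param graph A `"bipartite_graph"`.
#' @return The graph with a `tailor` column added to `edges`; edges whose
#'   divisor is non-positive get `tailor = 0` and are flagged in the
#'   `tailor_degenerate` column.
#' @export
tailor_calibrate <- function(graph) {
  edges <- graph$edges
  edges$tailor <- NA_real_
  edges$tailor_degenerate <- FALSE
  idx_by_group <- split(seq_len(nrow(edges)), edges$group)
  for (g in names(idx_by_group)) {
    cc <- graph$cand[[as.integer(g)]]
    idx <- idx_by_group[[g]]
    pos <- max(1L, as.integer(round_half_away(cc$n / 100)))
    div <- cc$sorted_scores[pos]
    if (!is.finite(div) || div <= 0) {
      edges$tailor[idx] <- 0
      edges$tailor_degenerate[idx] <- TRUE
    } else {
      edges$tailor[idx] <- edges$xcorr[idx] / div
    }
  }
  graph$edges <- edges
  graph
}

#' Rank-gap features per spectrum and charge
#'
#' For the retained edge at rank i with score s_i among its spectrum-charge
#' group: `delta_cn = (s_i - s_(i+1)) / max(s_i, 1)` (0 for the last
#' retained edge) and `delta_lcn = (s_i - s_last) / max(s_i, 1)`.
#'
#' @param graph A `"bipartite_graph"` (edges carry `rank` from
#'   [build_graph()]).
#' @return The graph with `delta_cn` and `delta_lcn` columns.
#' @export
rank_gap_features <- function(graph) {
  edges <- graph$edges
  edges$delta_cn <- 0
  edges$delta_lcn <- 0
  if (nrow(edges)) {
    for (idx in split(seq_len(nrow(edges)), edges$group)) {
      idx <- idx[order(edges$rank[idx])]
      s <- edges$xcorr[idx]
      m <- length(s)
      denom <- pmax(s, 1)
      if (m > 1L) {
        edges$delta_cn[idx] <- c((s[-m] - s[-1L]) / denom[-m], 0)
        edges$delta_lcn[idx] <- (s - s[m]) / denom
      }
    }
  }
  graph$edges <- edges
  graph
}
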