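# Semi-supervised reranking with pair-constrained cross-validation,
# precursor-level target-decoy competition, q-value estimation and the
# pseudo-target (entrapment) evaluation harness.

# q-values from scores and decoy labels: FDR(tau) = min(1, D/max(1,T))
# over the strictly-above-threshold sets, monotonized from the bottom.
qvalues_from_scores <- function(score, is_decoy) {
  n <- length(score)
  if (n == 0L) return(numeric(0))
  o <- order(score, decreasing = TRUE)
  s <- score[o]; d <- is_decoy[o]
  grp_last <- which(c(s[-1L] != s[-n], TRUE))   # last index of each tie group
  cum_d <- cumsum(d)[grp_last]
  cum_t <- cumsum(!d)[grp_last]
  fdr <- pmin(1, cum_d / pmax(1, cum_t))
  q_grp <- rev(cummin(rev(fdr)))
  grp_of <- rep(seq_along(grp_last), times = diff(c(0L, grp_last)))
  q <- numeric(n)
  q[o] <- q_grp[grp_of]
  q
}

# L2-regularized squared-hinge linear SVM, solved in the primal by an
# active-set Newton iteration (exact for fixed active set; d is tiny).
# Returns list(w, b).
svm_l2_fit <- function(X, y, cost, max_iter = 60L) {
  d <- ncol(X)
  Xa <- cbind(X, 1)
  pen <- c(rep(1, d), 0)                   # bias unpenalized
  wb <- numeric(d + 1L)
  active_prev <- NULL
  for (it in seq_len(max_iter)) {
    f <- drop(Xa %*% wb)
    active <- y * f < 1
    if (!any(active)) break
    if (!is.null(active_prev) && identical(active, active_prev)) break
    A <- Xa[active, , drop = FALSE]
    ya <- y[active]
    H <- diag(pen, d + 1L) + 2 * cost * crossprod(A)
    rhs <- 2 * cost * crossprod(A, ya)
    wb_new <- tryCatch(drop(solve(H, rhs)), error = function(e) wb)
    if (max(abs(wb_new - wb)) < 1e-10) { wb <- wb_new; break }
    wb <- wb_new
    active_prev <- active
  }
  list(w = wb[seq_len(d)], b = wb[d + 1L])
}

svm_decision <- function(model, X) drop(X %*% model$w + model$b)

# One semi-supervised training run on a standardized feature matrix.
# Returns the final model, or NULL if no positives can be found.
iterate_svm <- function(X, is_target, init_score, cost, iterations,
                        train_q) {
  score <- init_score
  model <- NULL
  for (it in seq_len(iterations)) {
    q <- qvalues_from_scores(score, !is_target)
    pos <- is_target & q <= train_q
    if (!any(pos)) break
    idx <- which(pos | !is_target)
    y <- ifelse(is_target[idx], 1, -1)
    model <- svm_l2_fit(X[idx, , drop = FALSE], y, cost)
    score <- svm_decision(model, X)
  }
  model
}

#' Semi-supervised reranking of edges
#'
#' Re-scores edges with the Percolator protocol: target/decoy pairs are
#' hashed into 3 cross-validation folds (all edges of a pair stay
#' together), and for each fold a linear max-margin classifier is trained
#' on the other two folds by iterative positive-set refinement (positives
#' = target edges at internal q <= 0.01 under the current score, negatives
#' = all decoy edges).  The starting score is the single feature that
#' yields the most targets at the internal threshold; the regularization
#' cost is chosen by nested validation between the two training folds.
#' Held-out edges are scored by their fold's model and per-fold scores are
#' rank-normalized to [0, 1] before merging.  A fold in which no positives
#' can be identified falls back to ranking by the calibrated XCorr.
#'
#' @param edges Edge data frame with `is_decoy`, `pair_id` and the feature
#'   columns (`charge`, `delta_cn`, `delta_lcn`, `tailor`, `wP`, `wF`,
#'   `wR`, `wE`).
#' @param config A [dia_config()]; `feature_mask` controls which auxiliary
#'   features enter the classifier.
#' @param seed Integer seed for the fold assignment.
#' @return The edges with a `rerank_score` column in [0, 1]; the attribute
#'   `"fallback_folds"` lists folds that used the XCorr fallback.
#' @export
rerank <- function(edges, config = dia_config(), seed = 1L) {
  n <- nrow(edges)
  if (n == 0L) { edges$rerank_score <- numeric(0); return(edges) }
  aux <- intersect(c("P", "F", "R", "E"), config$feature_mask)
  feat_cols <- c("charge", "delta_cn", "delta_lcn", "tailor",
                 if (length(aux)) paste0("w", aux))
  X <- as.matrix(edges[, feat_cols, drop = FALSE])
  # label-blind standardization
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sd_, "/")

  pairs <- sort(unique(edges$pair_id))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold_of_pair <- stats::setNames(
    sample(rep_len(seq_len(config$rerank_folds), length(pairs))),
    pairs)
  fold <- fold_of_pair[as.character(edges$pair_id)]

  is_target <- !edges$is_decoy
  score_out <- numeric(n)
  fallback_folds <- integer(0)
  for (f in seq_len(config$rerank_folds)) {
    test <- fold == f
    train <- !test
    Xtr <- X[train, , drop = FALSE]
    ttr <- is_target[train]
    # initial direction: best single feature, either sign
    best <- list(count = -1L, score = NULL)
    for (j in seq_len(ncol(Xtr))) for (sgn in c(1, -1)) {
      sc <- sgn * Xtr[, j]
      cnt <- sum(ttr & qvalues_from_scores(sc, !ttr) <= config$rerank_train_q)
      if (cnt > best$count) best <- list(count = cnt, score = sc)
    }
    if (best$count <= 0L) {
      score_out[test] <- edges$tailor[test]
      fallback_folds <- c(fallback_folds, f)
      next
    }
    # nested cost selection between the two training folds
    train_folds <- setdiff(seq_len(config$rerank_folds), f)
    cost <- config$rerank_costs[1]
    if (length(config$rerank_costs) > 1L && length(train_folds) >= 2L) {
      fa <- fold == train_folds[1]; fb <- fold == train_folds[2]
      besta <- list(count = -1L, score = NULL)
      Xa <- X[fa, , drop = FALSE]; ta <- is_target[fa]
      for (j in seq_len(ncol(Xa))) for (sgn in c(1, -1)) {
        sc <- sgn * Xa[, j]
        cnt <- sum(ta & qvalues_from_scores(sc, !ta) <= config$rerank_train_q)
        if (cnt > besta$count) besta <- list(count = cnt, score = sc)
      }
      if (besta$count > 0L) {
        val <- vapply(config$rerank_costs, function(cc) {
          m <- iterate_svm(Xa, ta, besta$score, cc,
                           min(3L, config$rerank_iterations),
                           config$rerank_train_q)
          if (is.null(m)) return(-1)
          sb <- svm_decision(m, X[fb, , drop = FALSE])
          sum(is_target[fb] &
                qvalues_from_scores(sb, edges$is_decoy[fb]) <=
                config$rerank_train_q)
        }, numeric(1))
        cost <- config$rerank_costs[which.max(val)]
      }
    }
    model <- iterate_svm(Xtr, ttr, best$score, cost,
                         config$rerank_iterations, config$rerank_train_q)
    if (is.null(model)) {
      score_out[test] <- edges$tailor[test]
      fallback_folds <- c(fallback_folds, f)
    } else {
      score_out[test] <- svm_decision(model, X[test, , drop = FALSE])
    }
  }
  # per-fold rank normalization for comparability across folds
  for (f in seq_len(config$rerank_folds)) {
    idx <- which(fold == f)
    if (length(idx)) {
      score_out[idx] <- (rank(score_out[idx], ties.method = "average") -
                           0.5) / length(idx)
    }
  }
  edges$rerank_score <- score_out
  attr(edges, "fallback_folds") <- fallback_folds
  attr(edges, "fold") <- unname(fold)
  edges
}

#' Precursor-level target-decoy competition
#'
#' Among all edges of a target/decoy pair (the target peptide and its
#' paired decoy, across all charge states and spectra), only the
#' highest-scoring edge is retained; its label decides whether the pair
#' contributes a target or a decoy observation.  Score ties are broken
#' toward the decoy (conservative).
#'
#' @param edges Edge data frame with `pair_id`, `is_decoy` and a score
#'   column.
#' @param score_col Name of the score column (default `"rerank_score"`).
#' @return Data frame with one row per pair: the winning edge's columns,
#'   sorted by decreasing score.
#' @export
precursor_tdc <- function(edges, score_col = "rerank_score") {
  if (nrow(edges) == 0L) return(edges)
  sc <- edges[[score_col]]
  win <- vapply(split(seq_len(nrow(edges)), edges$pair_id), function(idx) {
    s <- sc[idx]
    m <- s == max(s)
    cand <- idx[m]
    dec <- cand[edges$is_decoy[cand]]
    if (length(dec)) dec[1L] else cand[1L]
  }, integer(1))
  out <- edges[win, , drop = FALSE]
  out <- out[order(-out[[score_col]], out$is_decoy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach q-values to competition winners
#'
#' The FDR at a score threshold tau is `min(1, #decoys above tau /
#' max(1, #targets above tau))` (strictly above); a record's q-value is
#' the minimum FDR over all thresholds at which it is accepted.
#'
#' @param peptides Data frame with `is_decoy` and a score column.
#' @param score_col Score column name (default `"rerank_score"`).
#' @return The input, sorted by decreasing score, with a `q_value` column.
#' @export
compute_qvalues <- function(peptides, score_col = "rerank_score") {
  if (nrow(peptides) == 0L) { peptides$q_value <- numeric(0); return(peptides) }
  peptides$q_value <- qvalues_from_scores(peptides[[score_col]],
                                          peptides$is_decoy)
  peptides <- peptides[order(-peptides[[score_col]], peptides$is_decoy), ,
                       drop = FALSE]
  rownames(peptides) <- NULL
  peptides
}

#' Pseudo-target (entrapment) FDR calibration
#'
#' Doubles the target database with disguised decoys ("pseudo-targets"),
#' runs the full detection pipeline on the doubled database (the pipeline
#' generates its own internal decoys), and re-estimates FDR from the
#' hidden pseudo labels with the same competition formula.  The returned
#' table pairs each reported peptide's nominal q-value with the
#' pseudo-target q-value for calibration analysis.
#'
#' @param targets Data frame of target peptides (`sequence`, `mods`,
#'   `mass`, `n_missed`).
#' @param seed Integer seed for pseudo-decoy generation (kept disjoint
#'   from the pipeline's internal decoy seed by the caller).
#' @param pipeline Function taking a peptide data frame (all labeled
#'   targets) and returning the ranked result table of [detect_peptides()]
#'   (only target-labeled records are used).
#' @return Data frame with `sequence`, `mods`, `score`, `nominal_q`,
#'   `pseudo_q` and `is_pseudo`, sorted by decreasing score.
#' @export
pseudo_target_evaluate <- function(targets, seed, pipeline) {
  doubled <- generate_decoys(targets, seed = seed)
  pseudo <- doubled[doubled$is_decoy, , drop = FALSE]
  # a pseudo-target colliding with a real target is indistinguishable;
  # drop such pairs from the evaluation
  pseudo <- pseudo[!pseudo$sequence %in% targets$sequence, , drop = FALSE]
  key <- function(s, m) paste(s, m, sep = "/")
  pseudo_keys <- key(pseudo$sequence, pseudo$mods)
  input <- rbind(
    targets[, c("sequence", "mods", "mass", "n_missed")],
    pseudo[, c("sequence", "mods", "mass", "n_missed")])
  rownames(input) <- NULL
  res <- pipeline(input)
  res <- res[!res$is_decoy, , drop = FALSE]
  is_pseudo <- key(res$sequence, res$mods) %in% pseudo_keys
  out <- data.frame(sequence = res$sequence, mods = res$mods,
                    score = res$score, nominal_q = res$q_value,
                    pseudo_q = qvalues_from_scores(res$score, is_pseudo),
                    is_pseudo = is_pseudo,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
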