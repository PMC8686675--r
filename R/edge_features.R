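# Auxiliary evidence features for candidate matches: precursor isotope
# intensity rank, binomial fragment-matching P-value, retention-time
# agreement and precursor/fragment coelution.

#' Precursor isotope intensity-rank score
#'
#' For the monoisotopic m/z and the M+1 and M+2 isotopes (spacing
#' `isotope_spacing / charge`), the maximum MS1 intensity within tolerance
#' is found and converted to its rank among all peak intensities of the
#' survey scan (rank 1 = most intense; ties share the worst rank via the
#' `>=` count).  A query with no matching peak takes intensity 0 and hence
#' the worst possible rank, so undetectable precursors receive a finite
#' penalty rather than a zero score.  The score is the negative sum of the
#' three log-ranks; it is always <= 0 and equals 0 only when all three
#' queries hit the most intense peak.
#'
#' @param ms1 A [dia_spectrum()] with MS level 1.
#' @param mz Precursor m/z.
#' @param charge Precursor charge.
#' @param tol_ppm Match tolerance in ppm.
#' @param isotope_spacing Isotope spacing in Da (default 13C-12C).
#' @return Numeric score (<= 0); 0 for an empty survey scan.
#' @export
precursor_rank_score <- function(ms1, mz, charge, tol_ppm = 10,
                                 isotope_spacing = C13_SPACING) {
  n <- length(ms1$mz)
  if (n == 0L) return(0)
  q <- mz + c(0, 1, 2) * isotope_spacing / charge
  iv <- ppm_interval(q, tol_ppm)
  I <- max_intensity_in_ranges(ms1$mz, ms1$intensity, iv$lo, iv$hi)
  ranks <- vapply(I, function(x) sum(ms1$intensity >= x), numeric(1))
  -sum(log(ranks))
}

#' Segment-wise peak picking
#'
#' Splits the spectrum's m/z range into `n_segments` equal-length segments
#' (half-open, the last closed) and keeps the `peaks_per_segment` most
#' intense peaks of each, preserving m/z order.
#'
#' @param spectrum A [dia_spectrum()].
#' @param n_segments,peaks_per_segment Defaults 10 and 10 (at most 100
#'   peaks).
#' @return List with sorted `mz` and matching `intensity`.
#' @export
pick_peaks <- function(spectrum, n_segments = 10L, peaks_per_segment = 10L) {
  n <- length(spectrum$mz)
  if (n == 0L) return(list(mz = numeric(0), intensity = numeric(0)))
  lo <- spectrum$mz[1]; hi <- spectrum$mz[n]
  if (hi == lo) {
    seg <- rep(1L, n)
  } else {
    seg <- pmin(n_segments,
                1L + floor((spectrum$mz - lo) / (hi - lo) * n_segments))
  }
  keep <- unlist(lapply(split(seq_len(n), seg), function(idx) {
    if (length(idx) <= peaks_per_segment) return(idx)
    idx[order(spectrum$intensity[idx], decreasing = TRUE)][
      seq_len(peaks_per_segment)]
  }), use.names = FALSE)
  keep <- sort(keep)
  list(mz = spectrum$mz[keep], intensity = spectrum$intensity[keep])
}

#' Chance probability of matching one peak
#'
#' The fraction of the (padded) observed m/z range covered by the union of
#' the +/- tau intervals around the picked peaks.  Overlapping intervals
#' are merged (set-union measure) and the result is capped at 1.
#'
#' @param picked_mz Sorted m/z values of the picked peaks.
#' @param tol Tolerance; ppm or Th per `tol_type`.
#' @param tol_type `"ppm"` or `"th"`.
#' @return Probability in (0, 1]; returns 1 for fewer than 2 peaks.
#' @export
chance_match_prob <- function(picked_mz, tol, tol_type = c("ppm", "th")) {
  tol_type <- match.arg(tol_type)
  m <- length(picked_mz)
  if (m < 2L) return(1)
  tau <- if (tol_type == "ppm") tol * 1e-6 * picked_mz else rep(tol, m)
  lo <- picked_mz - tau
  hi <- picked_mz + tau
  # union length of sorted intervals
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in 2:m) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total <- total + (cur_hi - cur_lo)
  rng <- (picked_mz[m] + tau[m]) - (picked_mz[1] - tau[1])
  min(1, total / rng)
}

#' Binomial fragment-matching P-value score
#'
#' Number of theoretical fragments landing within tolerance of a picked
#' peak, converted to the upper-tail probability of the binomial
#' distribution with per-trial success probability [chance_match_prob()],
#' and returned as its negative natural logarithm (computed in log space
#' for numerical stability).  Uninformative cases (no fragments, fewer
#' than two picked peaks, or chance probability 1) score 0.
#'
#' @param spectrum A [dia_spectrum()] (MS level 2, raw peaks; peak picking
#'   is applied internally).
#' @param fragment_mz Theoretical fragment m/z values.
#' @param tol,tol_type Match tolerance (ppm or Th).
#' @param n_segments,peaks_per_segment Peak-picking parameters.
#' @return Numeric score >= 0.
#' @export
fragment_pvalue_score <- function(spectrum, fragment_mz, tol = 10,
                                  tol_type = c("ppm", "th"),
                                  n_segments = 10L,
                                  peaks_per_segment = 10L) {
  tol_type <- match.arg(tol_type)
  picked <- pick_peaks(spectrum, n_segments, peaks_per_segment)
  n_v <- length(fragment_mz)
  if (n_v == 0L || length(picked$mz) < 2L) return(0)
  p_u <- chance_match_prob(picked$mz, tol, tol_type)
  if (p_u >= 1) return(0)
  n_uv <- count_fragment_matches(picked$mz, fragment_mz, tol, tol_type)
  binomial_tail_score(n_uv, n_v, p_u)
}

# -log P(X >= n_uv) for X ~ Binom(n_v, p_u), in log space for stability.
binomial_tail_score <- function(n_uv, n_v, p_u) {
  if (n_uv <= 0L || n_v <= 0L || p_u >= 1) return(0)
  -stats::pbinom(n_uv - 1L, n_v, p_u, lower.tail = FALSE, log.p = TRUE)
}

# Number of fragments falling inside a +/- tau interval of a picked peak.
count_fragment_matches <- function(picked_mz, fragment_mz, tol, tol_type) {
  if (tol_type == "ppm") {
    t <- tol * 1e-6
    # f in [z - t z, z + t z]  <=>  z in [f/(1+t), f/(1-t)]
    hit <- any_peak_in_ranges(picked_mz, fragment_mz / (1 + t),
                              fragment_mz / (1 - t))
  } else {
    hit <- any_peak_in_ranges(picked_mz, fragment_mz - tol,
                              fragment_mz + tol)
  }
  sum(hit)
}

#' Retention-time agreement score
#'
#' Both the observed scan cycle and the predicted retention time are
#' converted to normalized ranks within their respective populations
#' (fraction of values <= the query), and the score is the negative
#' absolute difference of the two ranks, in [-1, 0].  Peptides without a
#' retention-time prediction receive the fallback value.
#'
#' @param t_u Observed retention proxy (scan cycle) of the spectrum.
#' @param t_v Predicted retention time of the precursor, or `NA`.
#' @param observed_rts Sorted numeric vector of the observed retention
#'   proxies of all MS2 spectra in the run.
#' @param predicted_rts Sorted numeric vector of predicted retention times
#'   over all precursors with predictions.
#' @param fallback Value when `t_v` is `NA` (default -0.5).
#' @return Numeric score in [-1, 0].
#' @export
rt_diff_score <- function(t_u, t_v, observed_rts, predicted_rts,
                          fallback = -0.5) {
  if (is.na(t_v) || length(predicted_rts) == 0L) return(fallback)
  nu <- findInterval(t_u, observed_rts) / length(observed_rts)
  nv <- findInterval(t_v, predicted_rts) / length(predicted_rts)
  -abs(nu - nv)
}

#' Precursor/fragment coelution score
#'
#' Extracts the precursor's elution profile from the MS1 scans of the
#' `delta_t` cycles around the match and each fragment's profile from the
#' same-window MS2 scans of those cycles (per-scan value = maximum
#' intensity within tolerance; cycles outside the run contribute 0).  The
#' score is the mean of the 3 largest inner products between the
#' L2-normalized precursor profile and the L2-normalized fragment profiles
#' (mean of all if fewer than 3 fragments); zero-norm profiles contribute
#' a dot product of 0.  The score lies in [0, 1].
#'
#' @param run A [dia_run()].
#' @param spectrum_idx Index of the matched MS2 spectrum in `run$spectra`.
#' @param prec_mz Precursor m/z.
#' @param fragment_mz Theoretical fragment m/z values.
#' @param delta_t Half-width of the profile in cycles (default 2).
#' @param tol_ppm Match tolerance in ppm.
#' @return Numeric score in [0, 1].
#' @export
coelution_score <- function(run, spectrum_idx, prec_mz, fragment_mz,
                            delta_t = 2L, tol_ppm = 10) {
  s <- run$spectra[[spectrum_idx]]
  w <- which(run$windows$low == s$window[1] & run$windows$high == s$window[2])
  cycles <- (s$cycle_index - delta_t):(s$cycle_index + delta_t)
  nf <- length(fragment_mz)
  if (nf == 0L) return(0)
  prec_prof <- numeric(length(cycles))
  frag_prof <- matrix(0, nrow = nf, ncol = length(cycles))
  piv <- ppm_interval(prec_mz, tol_ppm)
  fiv <- ppm_interval(fragment_mz, tol_ppm)
  for (j in seq_along(cycles)) {
    r <- cycles[j] + 1L               # cycle_index is 0-based
    if (r < 1L || r > run$n_cycles) next
    i1 <- run$ms1_index[r]
    if (!is.na(i1)) {
      m1 <- run$spectra[[i1]]
      prec_prof[j] <- max_intensity_in_ranges(m1$mz, m1$intensity,
                                              piv$lo, piv$hi)
    }
    i2 <- run$ms2_index[r, w]
    if (!is.na(i2)) {
      m2 <- run$spectra[[i2]]
      frag_prof[, j] <- max_intensity_in_ranges(m2$mz, m2$intensity,
                                                fiv$lo, fiv$hi)
    }
  }
  pn <- sqrt(sum(prec_prof^2))
  if (pn == 0) return(0)
  p <- prec_prof / pn
  dots <- apply(frag_prof, 1L, function(f) {
    fn <- sqrt(sum(f^2))
    if (fn == 0) 0 else sum(p * f) / fn
  })
  top <- sort(dots, decreasing = TRUE)[seq_len(min(3L, nf))]
  mean(top)
}

#' Attach all auxiliary features to a graph's edges
#'
#' Computes the precursor intensity-rank, fragment-matching P-value,
#' retention-time and coelution scores for every retained edge, reusing
#' per-spectrum peak picking and the run-wide retention-time context.
#'
#' @param graph A `"bipartite_graph"` after [tailor_calibrate()] and
#'   [rank_gap_features()].
#' @return The graph with `wP`, `wF`, `wR`, `wE` columns on `edges`.
#' @export
add_edge_features <- function(graph) {
  edges <- graph$edges
  run <- graph$run
  db <- graph$db
  cfg <- graph$config
  n <- nrow(edges)
  edges$wP <- numeric(n); edges$wF <- numeric(n)
  edges$wR <- numeric(n); edges$wE <- numeric(n)
  if (n == 0L) { graph$edges <- edges; return(graph) }

  # retention-time context (pooled over all MS2 spectra / all precursors)
  lvl <- vapply(run$spectra, function(s) s$ms_level, integer(1))
  obs_rts <- sort(vapply(run$spectra[lvl == 2L],
                         function(s) as.numeric(s$cycle_index), numeric(1)))
  prec_rt <- db$peptides$rt[db$precursors$peptide_idx]
  pred_rts <- sort(prec_rt[!is.na(prec_rt)])

  # per-spectrum cached peak picking and chance-match probability
  sp_used <- unique(edges$spectrum_idx)
  picked_cache <- new.env(parent = emptyenv())
  for (si in sp_used) {
    picked <- pick_peaks(run$spectra[[si]], cfg$n_segments,
                         cfg$peaks_per_segment)
    p_u <- chance_match_prob(picked$mz, cfg$fragment_tol_ppm, "ppm")
    assign(as.character(si), list(picked = picked, p_u = p_u),
           envir = picked_cache)
  }

  frag_cache <- vector("list", nrow(db$precursors))
  for (e in seq_len(n)) {
    si <- edges$spectrum_idx[e]
    s <- run$spectra[[si]]
    pi <- edges$prec_idx[e]
    mzv <- db$precursors$mz[pi]
    ch <- db$precursors$charge[pi]
    if (is.null(frag_cache[[pi]]))
      frag_cache[[pi]] <- precursor_fragments(db, pi)
    frags <- frag_cache[[pi]]

    # precursor rank in the cycle's survey scan
    r <- s$cycle_index + 1L
    if (r >= 1L && r <= length(run$ms1_index)) {
      ms1 <- run$spectra[[run$ms1_index[r]]]
      edges$wP[e] <- precursor_rank_score(ms1, mzv, ch,
                                          cfg$precursor_tol_ppm,
                                          cfg$isotope_spacing)
    }

    # fragment-matching P-value from the cached picked peaks
    pc <- get(as.character(si), envir = picked_cache)
    n_v <- length(frags)
    if (n_v > 0L && length(pc$picked$mz) >= 2L && pc$p_u < 1) {
      n_uv <- count_fragment_matches(pc$picked$mz, frags,
                                     cfg$fragment_tol_ppm, "ppm")
      edges$wF[e] <- binomial_tail_score(n_uv, n_v, pc$p_u)
    }

    # retention-time agreement
    t_v <- prec_rt[pi]
    edges$wR[e] <- rt_diff_score(s$cycle_index, t_v, obs_rts, pred_rts,
                                 cfg$rt_fallback)

    # precursor/fragment coelution
    edges$wE[e] <- coelution_score(run, si, mzv, frags, cfg$delta_t,
                                   cfg$fragment_tol_ppm)
  }
  graph$edges <- edges
  graph
}
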