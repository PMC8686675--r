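# Independent oracles used by both the unit tests and the acceptance
# checks.

# Re-derivation of the XCorr preprocessing up to (but not including)
# background subtraction: sqrt intensities, max per bin, 10 regions
# normalized to 50.
binned_vector <- function(mz, intensity, bin_width = 1.0005079,
                          bin_offset = 0.4) {
  bins <- floor(mz / bin_width + 1 - bin_offset)
  nb <- max(bins)
  x <- numeric(nb)
  for (i in seq_along(bins)) {
    x[bins[i]] <- max(x[bins[i]], sqrt(intensity[i]))
  }
  region_len <- ceiling(nb / 10)
  for (r in 1:10) {
    lo <- (r - 1) * region_len + 1
    hi <- min(r * region_len, nb)
    if (lo > hi) break
    m <- max(x[lo:hi])
    if (m > 0) x[lo:hi] <- x[lo:hi] * (50 / m)
  }
  x
}

# Direct cross-correlation oracle: corr(0) - mean over tau = +/-1..+/-75
# of corr(tau), times the 0.005 SEQUEST scale.
xcorr_oracle <- function(x, frag_bins) {
  t <- numeric(length(x) + 200)
  t[unique(frag_bins)] <- 1
  corr <- function(tau) {
    idx <- seq_along(x) + tau
    ok <- idx >= 1 & idx <= length(x)
    sum(t[seq_along(x)][ok] * x[idx[ok]])
  }
  taus <- setdiff(-75:75, 0)
  0.005 * (corr(0) - mean(vapply(taus, corr, numeric(1))))
}

# Brute-force q-value oracle: FDR at every threshold, suffix minimum.
qvalue_oracle <- function(score, is_decoy) {
  vapply(seq_along(score), function(i) {
    taus <- c(min(score) - 1, sort(unique(score)))
    taus <- taus[taus < score[i]]
    fdrs <- vapply(taus, function(tau) {
      d <- sum(is_decoy & score > tau)
      t <- sum(!is_decoy & score > tau)
      min(1, d / max(1, t))
    }, numeric(1))
    min(fdrs)
  }, numeric(1))
}

# TRUE where a detected sequence shares evidence with a planted peptide:
# identical, or one is a subsequence of the other (missed-cleavage or
# modification relatives share most fragment ions).
overlaps_truth <- function(sequences, truth_sequences) {
  vapply(sequences, function(s) {
    any(grepl(s, truth_sequences, fixed = TRUE)) ||
      any(vapply(truth_sequences, grepl, logical(1), x = s, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
}
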