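# Small numeric helpers shared across modules.

# Round half away from zero (R's round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Maximum intensity among peaks with lo < mz <= hi, vectorized over query
# ranges.  `mz` must be sorted increasingly.  Returns 0 where no peak falls
# in the range.  Ranges in ppm-based queries are narrow, so the common case
# is zero or one peak; wider hits fall back to a short loop.
max_intensity_in_ranges <- function(mz, intensity, lo, hi) {
  n <- length(lo)
  if (length(mz) == 0L || n == 0L) return(numeric(n))
  i_lo <- findInterval(lo, mz)           # peaks <= lo
  i_hi <- findInterval(hi, mz)           # peaks <= hi
  out <- numeric(n)
  one <- i_hi - i_lo == 1L
  out[one] <- intensity[i_hi[one]]
  multi <- which(i_hi - i_lo > 1L)
  for (j in multi) {
    out[j] <- max(intensity[(i_lo[j] + 1L):i_hi[j]])
  }
  out
}

# TRUE where some peak lies within the query range (lo, hi]; mz sorted.
any_peak_in_ranges <- function(mz, lo, hi) {
  if (length(mz) == 0L) return(rep(FALSE, length(lo)))
  findInterval(hi, mz) > findInterval(lo, mz)
}

# Symmetric ppm match interval: x matches q iff |x - q| <= tol_ppm * 1e-6 *
# max(x, q), i.e. x in [q (1 - t), q / (1 - t)].  Symmetry of the relation
# makes the cycle-neighbor noise filter idempotent.
ppm_interval_sym <- function(q, tol_ppm) {
  t <- tol_ppm * 1e-6
  list(lo = q * (1 - t), hi = q / (1 - t))
}

# One-sided ppm interval [q(1-t), q(1+t)] used for feature extraction.
ppm_interval <- function(q, tol_ppm) {
  t <- tol_ppm * 1e-6
  list(lo = q * (1 - t), hi = q * (1 + t))
}
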