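# Physical constants and residue tables used throughout the package.

#' Monoisotopic masses of the 20 standard amino-acid residues (Da)
#'
#' Residue masses (peptide-bond residues, i.e. the amino acid minus water).
#' Static modifications such as carbamidomethyl cysteine are applied on top
#' of these values; see [dia_config()].
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @keywords internal
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.0105646

# 13C - 12C spacing used for the M+1 / M+2 isotope queries.  Switchable to
# 1.0 via dia_config(isotope_spacing = 1) for a literal unit-spacing model.
C13_SPACING <- 1.00335483

# Residue retention coefficients (Krokhin-style hydrophobicity scale, C18,
# arbitrary monotone units).  Only the induced ordering of peptides matters
# for the retention-time feature, which works on normalized ranks.
RT_COEF <- c(
  W = 11.0, F = 10.5, L = 9.6, I = 8.4, M = 5.8, V = 5.0, Y = 4.0,
  A = 0.8, T = 0.4, P = 0.2, E = 0.0, D = -0.5, C = -0.8, S = -0.8,
  Q = -0.9, G = -0.9, N = -1.2, R = -1.3, H = -1.3, K = -2.1
)

# Mass deltas of the modifications the default retention-time predictor
# understands (oxidized methionine elutes earlier than methionine).
OXIDATION_MASS <- 15.99491
CARBAMIDOMETHYL_MASS <- 57.02146
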