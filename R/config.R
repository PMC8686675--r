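#' Configuration for a DIA peptide-detection run
#'
#' Collects every tunable parameter of the pipeline with the shipped
#' defaults.  Defaults reflect a wide-window Orbitrap-style acquisition;
#' for TripleTOF-style data raise the tolerances to 30 ppm and consider
#' enabling `noise_reduction`.
#'
#' @param top_k Number of candidate matches retained per MS2 spectrum and
#'   charge state after the primary XCorr search (default 5).
#' @param charges Precursor charge states considered (default `1:5`).
#' @param enzyme Digestion rule; only `"trypsin"` is built in (cleave
#'   C-terminal to K/R).
#' @param cleave_before_proline Logical; if `FALSE`, K/R followed by P is
#'   not cleaved.  Default `TRUE` (cleave regardless of proline).
#' @param missed_cleavages Maximum missed cleavages per peptide (default 2).
#' @param peptide_length Length bounds, inclusive (default `c(7, 50)`).
#' @param peptide_mass Monoisotopic mass bounds in Da (default
#'   `c(200, 6000)`).
#' @param static_mods Named numeric vector of fixed residue mass deltas in
#'   Da (default carbamidomethyl cysteine, +57.02146).
#' @param variable_mods Named numeric vector of variable residue mass
#'   deltas (default oxidized methionine, +15.99491).
#' @param max_variable_mods Cap on variable modifications per peptide
#'   (default 3).
#' @param bin_width,bin_offset XCorr discretization (default 1.0005079 Th
#'   at offset 0.4; use 0.02 Th for high-resolution fragment spectra).
#' @param precursor_tol_ppm Tolerance for matching precursor m/z in MS1
#'   scans (ppm, default 10).
#' @param fragment_tol_ppm Tolerance for matching fragment m/z in MS2
#'   scans (ppm, default 10).
#' @param noise_reduction Logical; drop MS2 peaks absent from the
#'   same-window scans of both neighboring cycles (default `FALSE`).
#' @param noise_tol_ppm Tolerance for the noise-reduction match; defaults
#'   to `fragment_tol_ppm`.
#' @param isotope_spacing Spacing of the M+1/M+2 isotope queries in Da
#'   (default 1.00335483, the 13C-12C mass difference; set to 1 for unit
#'   spacing).
#' @param n_segments,peaks_per_segment Peak picking for the fragment
#'   matching P-value: the m/z range is split into `n_segments` equal
#'   segments and the `peaks_per_segment` most intense peaks of each are
#'   kept (defaults 10 and 10, i.e. at most 100 peaks).
#' @param delta_t Half-width of elution profiles in scan cycles for the
#'   coelution score (default 2, giving profiles of length 5).
#' @param scale_quantiles Probabilities of the two quantiles mapped to 0
#'   and 1 when features are rescaled (default `c(0.01, 0.99)`).
#' @param alphas Named numeric vector of aggregate-score weights
#'   `c(P=, F=, R=, E=)` for the four auxiliary features (the calibrated
#'   XCorr always has unit weight).
#' @param alpha_grid Candidate values per weight for [grid_search_alphas()].
#' @param feature_mask Character vector naming the auxiliary features that
#'   are active; any of `"P"`, `"F"`, `"R"`, `"E"`.  Masked features get a
#'   zero aggregate weight and are excluded from the reranker, supporting
#'   ablation experiments.
#' @param rt_fallback Retention-time feature value for peptides the
#'   predictor cannot handle (default -0.5).
#' @param rerank_iterations Iterations of the semi-supervised reranker
#'   (default 10).
#' @param rerank_train_q Internal q-value threshold defining positive
#'   training examples (default 0.01).
#' @param rerank_folds Cross-validation folds (default 3).
#' @param rerank_costs Candidate regularization costs for the linear
#'   max-margin classifier (default `c(0.1, 1, 10)`).
#'
#' @return A list of class `"dia_config"`.
#' @examples
#' cfg <- dia_config(fragment_tol_ppm = 30, noise_reduction = TRUE)
#' cfg$top_k
#' @export
dia_config <- function(top_k = 5L,
                       charges = 1:5,
                       enzyme = "trypsin",
                       cleave_before_proline = TRUE,
                       missed_cleavages = 2L,
                       peptide_length = c(7L, 50L),
                       peptide_mass = c(200, 6000),
                       static_mods = c(C = CARBAMIDOMETHYL_MASS),
                       variable_mods = c(M = OXIDATION_MASS),
                       max_variable_mods = 3L,
                       bin_width = 1.0005079,
                       bin_offset = 0.4,
                       precursor_tol_ppm = 10,
                       fragment_tol_ppm = 10,
                       noise_reduction = FALSE,
                       noise_tol_ppm = NULL,
                       isotope_spacing = C13_SPACING,
                       n_segments = 10L,
                       peaks_per_segment = 10L,
                       delta_t = 2L,
                       scale_quantiles = c(0.01, 0.99),
                       alphas = c(P = 0.8, F = 0.1, R = 0.8, E = 0.8),
                       alpha_grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.8,
                                      1.6, 3.2, 6.4, 12.8),
                       feature_mask = c("P", "F", "R", "E"),
                       rt_fallback = -0.5,
                       rerank_iterations = 10L,
                       rerank_train_q = 0.01,
                       rerank_folds = 3L,
                       rerank_costs = c(0.1, 1, 10)) {
  stopifnot(top_k >= 1, all(charges %in% 1:5),
            missed_cleavages >= 0, length(peptide_length) == 2,
            length(scale_quantiles) == 2,
            all(names(alphas) %in% c("P", "F", "R", "E")),
            all(alphas >= 0),
            all(feature_mask %in% c("P", "F", "R", "E")))
  if (is.null(noise_tol_ppm)) noise_tol_ppm <- fragment_tol_ppm
  cfg <- list(
    top_k = as.integer(top_k), charges = as.integer(charges),
    enzyme = enzyme, cleave_before_proline = cleave_before_proline,
    missed_cleavages = as.integer(missed_cleavages),
    peptide_length = as.integer(peptide_length),
    peptide_mass = as.numeric(peptide_mass),
    static_mods = static_mods, variable_mods = variable_mods,
    max_variable_mods = as.integer(max_variable_mods),
    bin_width = bin_width, bin_offset = bin_offset,
    precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol_ppm = fragment_tol_ppm,
    noise_reduction = noise_reduction, noise_tol_ppm = noise_tol_ppm,
    isotope_spacing = isotope_spacing,
    n_segments = as.integer(n_segments),
    peaks_per_segment = as.integer(peaks_per_segment),
    delta_t = as.integer(delta_t),
    scale_quantiles = scale_quantiles,
    alphas = alphas[c("P", "F", "R", "E")],
    alpha_grid = alpha_grid,
    feature_mask = feature_mask,
    rt_fallback = rt_fallback,
    rerank_iterations = as.integer(rerank_iterations),
    rerank_train_q = rerank_train_q,
    rerank_folds = as.integer(rerank_folds),
    rerank_costs = rerank_costs
  )
  class(cfg) <- "dia_config"
  cfg
}

#' @export
print.dia_config <- function(x, ...) {
  cat("DIA detection configuration\n")
  cat(sprintf("  top_k: %d, charges: %s\n", x$top_k,
              paste(x$charges, collapse = ",")))
  cat(sprintf("  tolerances: precursor %g ppm, fragment %g ppm\n",
              x$precursor_tol_ppm, x$fragment_tol_ppm))
  cat(sprintf("  XCorr bins: %g Th (offset %g)\n", x$bin_width, x$bin_offset))
  cat(sprintf("  alphas: %s\n",
              paste(sprintf("%s=%g", names(x$alphas), x$alphas),
                    collapse = ", ")))
  invisible(x)
}
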