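#' Detect peptides in a DIA run
#'
#' End-to-end pipeline: (optional) cycle-neighbor noise reduction, precursor
#' database construction, bipartite graph search with XCorr and top-k
#' retention, Tailor calibration and rank-gap features, auxiliary evidence
#' features, quantile rescaling, aggregate-score filtering, semi-supervised
#' reranking, precursor-level target-decoy competition and q-value
#' estimation.
#'
#' @param run A [dia_run()].
#' @param fasta FASTA path or named character vector of proteins (ignored
#'   when `peptides` or `db` is given).
#' @param peptides Optional prepared target peptide table (`sequence`,
#'   `mods`, `mass`, `n_missed`), bypassing digestion.
#' @param db Optional prebuilt `"precursor_db"`.
#' @param config A [dia_config()].
#' @param seed Integer seed controlling decoy generation and the reranker
#'   fold assignment.
#' @param rt_predictor Retention-time predictor (default hydrophobicity
#'   sum).
#' @return A list of class `"dia_detection"`: `results` (one row per
#'   target/decoy pair: sequence, modifications, charge, m/z, scan, the
#'   eight features, aggregate and final scores, `q_value`, `is_decoy`),
#'   `edges` (surviving edges with features), `scaler`, `db` and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_run(simulate_fasta(sim_config(n_proteins = 4, seed = 7)),
#'                     sim_config(n_proteins = 4, seed = 7))
#' det <- detect_peptides(sim$run, peptides = sim$peptides, seed = 7)
#' head(subset(det$results, !is_decoy & q_value <= 0.01))
#' }
#' @export
detect_peptides <- function(run, fasta = NULL, peptides = NULL, db = NULL,
                            config = dia_config(), seed = 1L,
                            rt_predictor = rt_predictor_hydrophobicity()) {
  stopifnot(inherits(run, "dia_run"))
  if (config$noise_reduction) {
    run <- denoise_run(run, config$noise_tol_ppm)
  }
  if (is.null(db)) {
    db <- build_precursor_db(fasta = fasta, peptides = peptides,
                             config = config, seed = seed,
                             rt_predictor = rt_predictor)
  }
  graph <- build_graph(run, db, config)
  graph <- tailor_calibrate(graph)
  graph <- rank_gap_features(graph)
  graph <- add_edge_features(graph)
  edges <- graph$edges
  if (nrow(edges) == 0L) {
    return(structure(list(results = empty_results(), edges = edges,
                          scaler = NULL, db = db, config = config),
                     class = "dia_detection"))
  }
  scaler <- fit_scaler(edges, config$scale_quantiles)
  edges <- apply_scaler(edges, scaler)
  alphas <- config$alphas
  alphas[setdiff(c("P", "F", "R", "E"), config$feature_mask)] <- 0
  edges <- aggregate_score(edges, alphas)
  edges <- filter_edges(edges)
  edges$is_decoy <- db$precursors$is_decoy[edges$prec_idx]
  edges$pair_id <- db$precursors$pair_id[edges$prec_idx]
  edges <- rerank(edges, config, seed = seed)
  winners <- precursor_tdc(edges)
  winners <- compute_qvalues(winners)
  results <- format_results(winners, run, db)
  structure(list(results = results, edges = edges, scaler = scaler,
                 db = db, config = config),
            class = "dia_detection")
}

empty_results <- function() {
  data.frame(sequence = character(0), modifications = character(0),
             mods = character(0), charge = integer(0), mz = numeric(0),
             scan = character(0), xcorr = numeric(0), tailor = numeric(0),
             delta_cn = numeric(0), delta_lcn = numeric(0),
             wP = numeric(0), wF = numeric(0), wR = numeric(0),
             wE = numeric(0), aggregate = numeric(0), score = numeric(0),
             q_value = numeric(0), is_decoy = logical(0),
             pair_id = integer(0), stringsAsFactors = FALSE)
}

format_results <- function(winners, run, db) {
  if (nrow(winners) == 0L) return(empty_results())
  pidx <- db$precursors$peptide_idx[winners$prec_idx]
  data.frame(
    sequence = db$peptides$sequence[pidx],
    modifications = mapply(format_modified_sequence,
                           db$peptides$sequence[pidx],
                           db$peptides$mods[pidx], USE.NAMES = FALSE),
    mods = db$peptides$mods[pidx],
    charge = winners$charge,
    mz = db$precursors$mz[winners$prec_idx],
    scan = vapply(winners$spectrum_idx,
                  function(i) run$spectra[[i]]$scan_id, character(1)),
    xcorr = winners$xcorr, tailor = winners$tailor,
    delta_cn = winners$delta_cn, delta_lcn = winners$delta_lcn,
    wP = winners$wP, wF = winners$wF, wR = winners$wR, wE = winners$wE,
    aggregate = winners$aggregate, score = winners$rerank_score,
    q_value = winners$q_value, is_decoy = winners$is_decoy,
    pair_id = winners$pair_id,
    stringsAsFactors = FALSE)
}

#' @export
print.dia_detection <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "DIA detection: %d pairs competed; %d targets at q <= 0.01\n",
    nrow(r), sum(!r$is_decoy & r$q_value <= 0.01)))
  invisible(x)
}
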