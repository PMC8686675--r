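#' Construct a single centroided spectrum
#'
#' @param mz,intensity Numeric peak vectors; peaks are sorted by m/z on
#'   construction.  Intensities must be non-negative and m/z positive.
#' @param ms_level 1 (survey scan) or 2 (fragment scan).
#' @param scan_id Opaque scan identifier.
#' @param window Numeric length-2 isolation window `c(low, high)` in m/z;
#'   required for MS2, must be `NULL` for MS1.  The window is a closed
#'   interval: a precursor exactly on a boundary belongs to both adjacent
#'   windows.
#' @return A list of class `"dia_spectrum"`.
#' @export
dia_spectrum <- function(mz, intensity, ms_level, scan_id = NA_character_,
                         window = NULL) {
  stopifnot(length(mz) == length(intensity), ms_level %in% c(1L, 2L))
  if (length(mz)) {
    stopifnot(all(mz > 0), all(intensity >= 0))
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  if (ms_level == 2L) {
    stopifnot(!is.null(window), length(window) == 2, window[1] <= window[2])
  } else if (!is.null(window)) {
    stop("MS1 spectra carry no isolation window")
  }
  structure(list(scan_id = scan_id, ms_level = as.integer(ms_level),
                 cycle_index = NA_integer_,
                 window = if (is.null(window)) NULL else as.numeric(window),
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "dia_spectrum")
}

#' Assemble spectra into a DIA run with cycle structure
#'
#' Cycle indices are assigned by counting MS1 scans in acquisition order:
#' MS2 scans between MS1 scan i and MS1 scan i+1 get cycle index i (0-based),
#' associating each MS2 scan with the most recent preceding survey scan.
#'
#' @param spectra List of [dia_spectrum()] objects in acquisition order.
#' @return A list of class `"dia_run"` with elements `spectra`, `windows`
#'   (data frame of the distinct isolation windows, ordered by lower
#'   bound), `n_cycles`, `ms1_index` (spectrum index of each cycle's MS1
#'   scan) and `ms2_index` (cycles x windows matrix of spectrum indices,
#'   `NA` where a window was not acquired in a cycle).
#' @export
dia_run <- function(spectra) {
  levels <- vapply(spectra, function(s) s$ms_level, integer(1))
  n_cycles <- sum(levels == 1L)
  cyc <- cumsum(levels == 1L) - 1L   # 0-based; -1 for MS2 before first MS1
  if (any(cyc < 0L & levels == 2L)) {
    warning("MS2 scan(s) before the first MS1 scan assigned to cycle 0")
    cyc[cyc < 0L] <- 0L
  }
  spectra <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]; s$cycle_index <- cyc[i]; s
  })
  is_ms2 <- levels == 2L
  wins <- unique(do.call(rbind, lapply(spectra[is_ms2], function(s)
    data.frame(low = s$window[1], high = s$window[2]))))
  if (is.null(wins)) wins <- data.frame(low = numeric(0), high = numeric(0))
  wins <- wins[order(wins$low, wins$high), , drop = FALSE]
  rownames(wins) <- NULL
  ms1_index <- which(levels == 1L)
  ms2_index <- matrix(NA_integer_, nrow = n_cycles, ncol = nrow(wins))
  for (i in which(is_ms2)) {
    s <- spectra[[i]]
    w <- which(wins$low == s$window[1] & wins$high == s$window[2])
    r <- s$cycle_index + 1L
    if (r >= 1L && r <= n_cycles) {
      if (!is.na(ms2_index[r, w]))
        warning(sprintf("window [%g,%g] appears twice in cycle %d",
                        s$window[1], s$window[2], s$cycle_index))
      ms2_index[r, w] <- i
    }
  }
  structure(list(spectra = spectra, windows = wins,
                 n_cycles = n_cycles, ms1_index = ms1_index,
                 ms2_index = ms2_index),
            class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  cat(sprintf("DIA run: %d spectra, %d cycles, %d isolation windows\n",
              length(x$spectra), x$n_cycles, nrow(x$windows)))
  invisible(x)
}

#' Read a centroided DIA run from an mzML file
#'
#' @param path Path to a centroided mzML file with interleaved MS1 and MS2
#'   scans.
#' @param window_spec Optional explicit isolation windows: a two-column
#'   matrix or data frame (`low`, `high` in m/z).  Required when the MS2
#'   scans carry no isolation-window metadata; windows are then assigned
#'   round-robin, in order, to the MS2 scans of each cycle.
#' @return A [dia_run()].
#' @export
read_dia_run <- function(path, window_spec = NULL) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) return(dia_run(list()))
  if ("centroided" %in% names(hdr) &&
      any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra found; centroid the data first ",
         "(e.g. msconvert peakPicking)")
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  if (!is.null(window_spec)) {
    window_spec <- as.data.frame(window_spec)
    names(window_spec)[1:2] <- c("low", "high")
  }
  have_iso <- all(c("isolationWindowTargetMZ", "isolationWindowLowerOffset",
                    "isolationWindowUpperOffset") %in% names(hdr))
  ms2_in_cycle <- 0L
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    lvl <- hdr$msLevel[i]
    m <- pk[[i]]
    win <- NULL
    if (lvl == 1L) {
      ms2_in_cycle <- 0L
    } else {
      ms2_in_cycle <- ms2_in_cycle + 1L
      tgt <- if (have_iso) hdr$isolationWindowTargetMZ[i] else NA_real_
      if (have_iso && !is.na(tgt)) {
        win <- c(tgt - hdr$isolationWindowLowerOffset[i],
                 tgt + hdr$isolationWindowUpperOffset[i])
      } else if (!is.null(window_spec)) {
        w <- (ms2_in_cycle - 1L) %% nrow(window_spec) + 1L
        win <- c(window_spec$low[w], window_spec$high[w])
      } else {
        stop("MS2 scan ", i, " has no isolation-window metadata; ",
             "supply window_spec")
      }
    }
    spectra[[i]] <- dia_spectrum(m[, 1], m[, 2], lvl,
                                 scan_id = as.character(hdr$acquisitionNum[i]),
                                 window = win)
  }
  dia_run(spectra)
}

#' Remove single-cycle MS2 peaks (noise reduction)
#'
#' A peak in an MS2 scan is retained only if the MS2 scan of the same
#' isolation window in the preceding or succeeding cycle contains a peak
#' within the given ppm tolerance; peaks seen in a single cycle are treated
#' as noise.  First and last cycles are checked against their single
#' neighbor.  MS1 scans are never modified, and runs with fewer than two
#' cycles are returned unchanged.  The matching relation is symmetric in
#' the two peaks, which makes the operation idempotent.
#'
#' @param run A [dia_run()].
#' @param tolerance_ppm Match tolerance in ppm.
#' @return A [dia_run()] with filtered MS2 peak lists.
#' @export
denoise_run <- function(run, tolerance_ppm) {
  stopifnot(inherits(run, "dia_run"), tolerance_ppm > 0)
  if (run$n_cycles < 2L) return(run)
  spectra <- run$spectra
  for (r in seq_len(run$n_cycles)) {
    for (w in seq_len(ncol(run$ms2_index))) {
      i <- run$ms2_index[r, w]
      if (is.na(i)) next
      s <- run$spectra[[i]]
      if (length(s$mz) == 0L) next
      iv <- ppm_interval_sym(s$mz, tolerance_ppm)
      keep <- rep(FALSE, length(s$mz))
      for (rn in c(r - 1L, r + 1L)) {
        if (rn < 1L || rn > run$n_cycles) next
        j <- run$ms2_index[rn, w]
        if (is.na(j)) next
        keep <- keep | any_peak_in_ranges(run$spectra[[j]]$mz, iv$lo, iv$hi)
      }
      s$mz <- s$mz[keep]; s$intensity <- s$intensity[keep]
      spectra[[i]] <- s
    }
  }
  out <- run
  out$spectra <- spectra
  out
}

#' Write detection results
#'
#' @param peptides Data frame of scored peptides as returned by
#'   [detect_peptides()] (columns include `sequence`, `modifications`,
#'   `charge`, `mz`, `scan`, the edge features, `score`, `q_value`,
#'   `is_decoy`).
#' @param path Output file path.
#' @param format `"tsv"` (one row per precursor, all feature columns) or
#'   `"pepxml"` (one `spectrum_query` per retained match).
#' @return Invisibly, `path`.
#' @export
write_results <- function(peptides, path, format = c("tsv", "pepxml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    write_pepxml(peptides, path)
  }
  invisible(path)
}

#' Read back a TSV result file
#'
#' @param path Path written by [write_results()] with `format = "tsv"`.
#' @return Data frame.
#' @export
read_results <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  cls <- rep(NA, length(hdr))
  cls[hdr %in% c("sequence", "modifications", "mods", "scan")] <- "character"
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = cls)
}

write_pepxml <- function(peptides, path) {
  doc <- xml2::xml_new_root(
    "msms_pipeline_analysis",
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    summary_xml = basename(path),
    xmlns = "http://regis-web.systemsbiology.net/pepXML")
  runsum <- xml2::xml_add_child(doc, "msms_run_summary",
                                base_name = basename(path),
                                raw_data_type = "raw", raw_data = ".mzML")
  xml2::xml_add_child(runsum, "search_summary",
                      base_name = basename(path),
                      search_engine = "diadetect",
                      precursor_mass_type = "monoisotopic",
                      fragment_mass_type = "monoisotopic",
                      search_id = "1")
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    sq <- xml2::xml_add_child(
      runsum, "spectrum_query",
      spectrum = as.character(p$scan),
      start_scan = as.character(p$scan), end_scan = as.character(p$scan),
      precursor_neutral_mass =
        sprintf("%.6f", (p$mz - PROTON_MASS) * p$charge),
      assumed_charge = as.character(p$charge), index = as.character(i))
    sr <- xml2::xml_add_child(sq, "search_result")
    sh <- xml2::xml_add_child(
      sr, "search_hit", hit_rank = "1", peptide = p$sequence,
      protein = if (isTRUE(p$is_decoy)) "decoy" else "target",
      num_tot_proteins = "1", calc_neutral_pep_mass =
        sprintf("%.6f", (p$mz - PROTON_MASS) * p$charge),
      massdiff = "0")
    xml2::xml_add_child(sh, "search_score", name = "score",
                        value = sprintf("%.6f", p$score))
    xml2::xml_add_child(sh, "search_score", name = "q_value",
                        value = sprintf("%.6g", p$q_value))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a DIA run to mzML
#'
#' Serializes an in-memory run (for example one produced by
#' [simulate_run()]) as a centroided mzML file with isolation-window
#' metadata, readable by [read_dia_run()] and other DIA tools.
#'
#' @param run A [dia_run()].
#' @param path Output mzML path.
#' @param cycle_seconds Nominal duration of one scan cycle, used to invent
#'   retention-time stamps (default 2 s).
#' @param include_isolation_windows If `FALSE`, omit the isolation-window
#'   metadata from the MS2 scans (emulating acquisitions whose window
#'   scheme is supplied externally via `window_spec`).
#' @return Invisibly, `path`.
#' @export
write_run_mzml <- function(run, path, cycle_seconds = 2,
                           include_isolation_windows = TRUE) {
  n <- length(run$spectra)
  pk <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  lvl <- vapply(run$spectra, function(s) s$ms_level, integer(1))
  win <- t(vapply(run$spectra, function(s)
    if (is.null(s$window)) c(NA_real_, NA_real_) else s$window, numeric(2)))
  cyc <- vapply(run$spectra, function(s) s$cycle_index, integer(1))
  npk <- vapply(pk, nrow, integer(1))
  tic <- vapply(pk, function(m) if (nrow(m)) sum(m[, 2]) else 0, numeric(1))
  bpi <- vapply(pk, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1))
  bpm <- vapply(pk, function(m)
    if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1))
  ctr <- (win[, 1] + win[, 2]) / 2
  if (!include_isolation_windows) ctr <- rep(NA_real_, n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = lvl, polarity = 1L, peaksCount = npk,
    totIonCurrent = tic,
    retentionTime = cyc * cycle_seconds +
      stats::ave(seq_len(n), cyc, FUN = seq_along) * 1e-3,
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = ifelse(lvl == 2L, 25, 0), ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(lvl == 2L & !is.na(ctr), ctr, 0),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ctr,
    isolationWindowLowerOffset = ctr - win[, 1],
    isolationWindowUpperOffset = win[, 2] - ctr,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}
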