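# Synthetic DIA runs with known ground truth: wide isolation windows,
# co-fragmented peptides, isotope envelopes, Gaussian elution profiles and
# background noise, for end-to-end validation without real data.

# Background amino-acid frequencies (vertebrate-like), with K and R
# enriched so tryptic digestion yields realistic peptide lengths.
AA_FREQ <- c(
  A = 0.074, R = 0.070, N = 0.044, D = 0.059, C = 0.025, E = 0.058,
  Q = 0.037, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.090,
  M = 0.028, F = 0.040, P = 0.050, S = 0.071, T = 0.062, W = 0.013,
  Y = 0.033, V = 0.068
)

#' Configuration of a simulated DIA acquisition
#'
#' Defaults emulate a wide-window acquisition at desk scale: 24 fixed
#' windows of 25 m/z covering 400-1000 m/z, 40 scan cycles, a database of
#' roughly two thousand peptides of which about 15% are present,
#' log-normal peptide abundances and Gaussian chromatographic peaks.  Apex cycles follow the
#' default hydrophobicity retention predictor plus Gaussian noise with a
#' standard deviation of 3% of the gradient, so the retention-time
#' feature is informative but not decisive.
#'
#' @param n_proteins,protein_length Simulated database size.
#' @param window_low,n_windows,window_width Isolation-window scheme (m/z).
#' @param n_cycles Number of scan cycles (one MS1 + one MS2 per window).
#' @param peak_width_cycles Chromatographic Gaussian sigma, in cycles.
#' @param present_fraction Fraction of database peptides truly present.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param noise_peaks_ms1,noise_peaks_ms2 Uniform-m/z noise peaks per scan.
#' @param noise_meanlog,noise_sdlog Log-normal noise peak intensities.
#' @param mz_jitter_ppm Gaussian m/z jitter (standard deviation, ppm).
#' @param ms1_suppressed_fraction Fraction of present peptides that emit
#'   no MS1 signal (undetectable precursor).
#' @param rt_noise_frac Apex-cycle noise sigma as a fraction of the
#'   gradient length.
#' @param present_charges Charge states sampled for present peptides.
#' @param seed Integer seed; every simulation output is reproducible
#'   under it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 14L, protein_length = 300L,
                       window_low = 400, n_windows = 24L,
                       window_width = 25,
                       n_cycles = 40L, peak_width_cycles = 2,
                       present_fraction = 0.15,
                       abundance_meanlog = log(1e5),
                       abundance_sdlog = 1,
                       noise_peaks_ms1 = 100L, noise_peaks_ms2 = 50L,
                       noise_meanlog = log(1e3), noise_sdlog = 1,
                       mz_jitter_ppm = 3,
                       ms1_suppressed_fraction = 0,
                       rt_noise_frac = 0.03,
                       present_charges = c(2L, 3L),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins >= 0, cfg$window_width > 0, cfg$n_cycles >= 0,
            cfg$present_fraction >= 0, cfg$present_fraction <= 1,
            cfg$ms1_suppressed_fraction >= 0,
            cfg$ms1_suppressed_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a protein FASTA database
#'
#' Proteins are i.i.d. residue strings drawn from realistic amino-acid
#' frequencies (lysine/arginine enriched for tryptic sites).  Output is
#' deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A single string of FASTA-formatted text (possibly empty).
#' @export
simulate_fasta <- function(config = sim_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(config$seed))
  if (config$n_proteins == 0L) return("")
  recs <- vapply(seq_len(config$n_proteins), function(i) {
    sq <- paste(sample(names(AA_FREQ), config$protein_length,
                       replace = TRUE, prob = AA_FREQ), collapse = "")
    paste0(">sim_protein_", i, "\n", sq)
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

# Accept FASTA text or a path; returns a digestible input for digest_fasta.
fasta_to_proteins <- function(fasta) {
  if (length(fasta) == 1L && grepl("^>", fasta)) {
    lines <- strsplit(fasta, "\n")[[1]]
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                   collapse = "")
    names(seqs) <- sub("^>", "", lines[hdr])
    seqs
  } else {
    fasta
  }
}

# Poisson-like isotope envelope ratios (M, M+1, M+2) as a function of
# peptide mass: an averagine-style approximation; only the relative ranks
# of the three isotope intensities matter downstream.
isotope_ratios <- function(mass) {
  lambda <- mass / 1800
  r <- c(1, lambda, lambda^2 / 2)
  r / max(r)
}

#' Simulate a DIA run with known ground truth
#'
#' Digests the given database, marks a random subset of peptides as
#' present, assigns each an apex cycle (via the default retention
#' predictor plus noise), a log-normal abundance and a charge state, and
#' emits per cycle one MS1 scan (isotope envelopes M/M+1/M+2 scaled by the
#' Gaussian elution factor; suppressed peptides emit nothing) plus one MS2
#' scan per isolation window (b/y fragments of the co-isolated present
#' peptides with random per-fragment efficiencies, scaled by elution).
#' All signal m/z values are jittered; every scan receives uniform-m/z
#' log-normal noise peaks.
#'
#' @param fasta FASTA text (from [simulate_fasta()]), a FASTA path, or a
#'   named character vector of proteins.
#' @param config A [sim_config()].
#' @param digestion A [dia_config()] providing the digestion settings
#'   (defaults match the search defaults).
#' @return List with `run` (a [dia_run()]), `truth` (data frame of
#'   present precursors: `sequence`, `mods`, `charge`, `mz`, `apex_cycle`,
#'   `abundance`, `ms1_suppressed`) and `peptides` (the digested target
#'   peptide table, the search database).
#' @export
simulate_run <- function(fasta, config = sim_config(),
                         digestion = dia_config()) {
  proteins <- fasta_to_proteins(fasta)
  peptides <- if (length(proteins) == 0L || identical(proteins, "")) {
    data.frame(sequence = character(0), mods = character(0),
               mass = numeric(0), n_missed = integer(0))
  } else {
    digest_fasta(proteins, digestion)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(config$seed) + 1L)

  win_low <- config$window_low + (seq_len(config$n_windows) - 1L) *
    config$window_width
  windows <- data.frame(low = win_low, high = win_low + config$window_width)
  mz_min <- min(windows$low); mz_max <- max(windows$high)

  n_present <- round(config$present_fraction * nrow(peptides))
  present <- peptides[sample(nrow(peptides), n_present), , drop = FALSE]
  truth <- NULL
  if (n_present > 0L) {
    charge <- sample(config$present_charges, n_present, replace = TRUE)
    mz <- (present$mass + charge * PROTON_MASS) / charge
    # re-draw the charge where the precursor falls outside the acquired
    # range; drop peptides no charge state can place in a window
    for (i in which(mz < mz_min | mz > mz_max)) {
      for (ch in sample(config$present_charges)) {
        m <- (present$mass[i] + ch * PROTON_MASS) / ch
        if (m >= mz_min && m <= mz_max) {
          charge[i] <- ch; mz[i] <- m; break
        }
      }
    }
    ok <- mz >= mz_min & mz <= mz_max
    present <- present[ok, , drop = FALSE]
    charge <- charge[ok]; mz <- mz[ok]
    n_present <- nrow(present)
    rt <- predict_rt(rt_predictor_hydrophobicity(), present)
    rt[is.na(rt)] <- stats::median(rt, na.rm = TRUE)
    apex <- if (n_present > 0L) {
      r <- (rank(rt, ties.method = "first") - 0.5) / n_present
      a <- (0.1 + 0.8 * r) * config$n_cycles +
        stats::rnorm(n_present, 0, config$rt_noise_frac * config$n_cycles)
      pmin(pmax(a, 0), config$n_cycles - 1)
    } else numeric(0)
    truth <- data.frame(
      sequence = present$sequence, mods = present$mods,
      charge = charge, mz = mz, apex_cycle = apex,
      abundance = stats::rlnorm(n_present, config$abundance_meanlog,
                                config$abundance_sdlog),
      ms1_suppressed = stats::runif(n_present) <
        config$ms1_suppressed_fraction,
      stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(sequence = character(0), mods = character(0),
                        charge = integer(0), mz = numeric(0),
                        apex_cycle = numeric(0), abundance = numeric(0),
                        ms1_suppressed = logical(0))
  }

  frag_list <- lapply(seq_len(nrow(truth)), function(i)
    theoretical_fragments(truth$sequence[i], truth$mods[i],
                          charge = truth$charge[i],
                          static_mods = digestion$static_mods))
  eff_list <- lapply(frag_list, function(f) stats::runif(length(f), 0.2, 1))
  iso <- lapply(seq_len(nrow(truth)), function(i) {
    r <- isotope_ratios((truth$mz[i] - PROTON_MASS) * truth$charge[i])
    r / r[1]
  })
  jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0,
                                             config$mz_jitter_ppm * 1e-6))
  sigma <- config$peak_width_cycles
  spectra <- list(); si <- 0L
  for (cyc in seq_len(config$n_cycles) - 1L) {
    g <- if (nrow(truth)) {
      exp(-(cyc - truth$apex_cycle)^2 / (2 * sigma^2))
    } else numeric(0)
    live <- which(g > 0.01)
    # MS1 survey scan
    mz1 <- numeric(0); in1 <- numeric(0)
    for (i in live) {
      if (truth$ms1_suppressed[i]) next
      q <- truth$mz[i] + c(0, 1, 2) * C13_SPACING / truth$charge[i]
      mz1 <- c(mz1, jit(q))
      in1 <- c(in1, truth$abundance[i] * g[i] * iso[[i]])
    }
    if (config$noise_peaks_ms1 > 0L) {
      mz1 <- c(mz1, stats::runif(config$noise_peaks_ms1, mz_min, mz_max))
      in1 <- c(in1, stats::rlnorm(config$noise_peaks_ms1,
                                  config$noise_meanlog, config$noise_sdlog))
    }
    si <- si + 1L
    spectra[[si]] <- dia_spectrum(mz1, in1, 1L,
                                  scan_id = sprintf("c%d_ms1", cyc))
    # one MS2 scan per isolation window
    for (w in seq_len(nrow(windows))) {
      inw <- live[truth$mz[live] >= windows$low[w] &
                    truth$mz[live] <= windows$high[w]]
      mz2 <- numeric(0); in2 <- numeric(0)
      for (i in inw) {
        mz2 <- c(mz2, jit(frag_list[[i]]))
        in2 <- c(in2, truth$abundance[i] * g[i] * 0.5 * eff_list[[i]])
      }
      if (config$noise_peaks_ms2 > 0L) {
        mz2 <- c(mz2, stats::runif(config$noise_peaks_ms2, 100, 1800))
        in2 <- c(in2, stats::rlnorm(config$noise_peaks_ms2,
                                    config$noise_meanlog,
                                    config$noise_sdlog))
      }
      si <- si + 1L
      spectra[[si]] <- dia_spectrum(mz2, in2, 2L,
                                    scan_id = sprintf("c%d_w%d", cyc, w),
                                    window = c(windows$low[w],
                                               windows$high[w]))
    }
  }
  list(run = dia_run(spectra), truth = truth, peptides = peptides)
}
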