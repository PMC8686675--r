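# Shared fixture builders: minimal runs and precursor databases built in
# code so every test input is fully controlled.

# A minimal precursor database from explicit precursor m/z values, all at
# one charge state, with trivial fragment lists.  Lets graph-level tests
# control candidate sets exactly.
toy_db <- function(mz, charge = 2L, is_decoy = rep(FALSE, length(mz)),
                   fragments = NULL) {
  n <- length(mz)
  peps <- data.frame(
    sequence = vapply(seq_len(n), function(i)
      paste(LETTERS[(i %% 20) + 1][1], paste0("PEPT", i), sep = ""),
      character(1)),
    mods = "", mass = mz * charge - charge * diadetect:::PROTON_MASS,
    n_missed = 0L, is_decoy = is_decoy, pair_id = seq_len(n),
    rt = seq_len(n), rt_ok = TRUE, stringsAsFactors = FALSE)
  if (is.null(fragments)) {
    fragments <- lapply(mz, function(m) sort(c(m / 2, m / 3 + 50)))
  }
  structure(list(peptides = peps,
                 precursors = data.frame(peptide_idx = seq_len(n),
                                         charge = as.integer(charge),
                                         mz = mz, is_decoy = is_decoy,
                                         pair_id = seq_len(n)),
                 fragments1 = fragments, config = dia_config()),
            class = "precursor_db")
}

# A run of `n_cycles` cycles over the given windows; `ms2_peaks` is a
# function(cycle0, window_index) returning list(mz=, intensity=), and
# `ms1_peaks` a function(cycle0) likewise.
toy_run <- function(n_cycles, windows,
                    ms2_peaks = function(cyc, w) list(mz = numeric(0),
                                                      intensity = numeric(0)),
                    ms1_peaks = function(cyc) list(mz = numeric(0),
                                                   intensity = numeric(0))) {
  spectra <- list()
  k <- 0L
  for (cyc in seq_len(n_cycles) - 1L) {
    p1 <- ms1_peaks(cyc)
    k <- k + 1L
    spectra[[k]] <- dia_spectrum(p1$mz, p1$intensity, 1L,
                                 scan_id = sprintf("c%d_ms1", cyc))
    for (w in seq_len(nrow(windows))) {
      p2 <- ms2_peaks(cyc, w)
      k <- k + 1L
      spectra[[k]] <- dia_spectrum(p2$mz, p2$intensity, 2L,
                                   scan_id = sprintf("c%d_w%d", cyc, w),
                                   window = c(windows$low[w],
                                              windows$high[w]))
    }
  }
  dia_run(spectra)
}

one_window <- data.frame(low = 100, high = 2000)

# Random tryptic-looking peptide sequences.
random_peptides <- function(n, len_range = c(7, 20)) {
  aa <- setdiff(names(diadetect:::AA_MONO_MASS), c("K", "R"))
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}
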