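# Precursor database construction: in silico digestion, variable
# modifications, decoy pairing, charge enumeration, theoretical fragment
# ions and retention-time prediction.

mod_positions <- function(mods) {
  if (is.na(mods) || mods == "") return(integer(0))
  as.integer(vapply(strsplit(mods, ",")[[1]],
                    function(x) strsplit(x, ":")[[1]][1], character(1)))
}

mod_deltas <- function(mods) {
  if (is.na(mods) || mods == "") return(numeric(0))
  as.numeric(vapply(strsplit(mods, ",")[[1]],
                    function(x) strsplit(x, ":")[[1]][2], character(1)))
}

make_mod_string <- function(pos, delta) {
  if (length(pos) == 0L) return("")
  o <- order(pos)
  paste(sprintf("%d:%.5f", pos[o], delta[o]), collapse = ",")
}

#' Format a peptide with inline modification deltas
#'
#' @param sequence Amino-acid string.
#' @param mods Internal modification string (`"pos:delta"` pairs).
#' @return A string such as `"PEPTM[+15.9949]IDEK"`.
#' @export
format_modified_sequence <- function(sequence, mods) {
  pos <- mod_positions(mods)
  if (length(pos) == 0L) return(sequence)
  delta <- mod_deltas(mods)
  aa <- strsplit(sequence, "")[[1]]
  aa[pos] <- sprintf("%s[+%.4f]", aa[pos], delta)
  paste(aa, collapse = "")
}

# Monoisotopic peptide mass: residues + water + static mods + variable mods.
peptide_mass <- function(sequence, mods = "",
                         static_mods = c(C = CARBAMIDOMETHYL_MASS)) {
  aa <- strsplit(sequence, "")[[1]]
  m <- sum(AA_MONO_MASS[aa]) + WATER_MASS
  if (length(static_mods))
    m <- m + sum(static_mods[aa], na.rm = TRUE)
  m + sum(mod_deltas(mods))
}

#' Digest a FASTA protein database into candidate peptides
#'
#' Fully enzymatic digestion (trypsin: cleave C-terminal to K/R) with
#' missed cleavages, static modifications applied implicitly to every
#' matching residue, and variable modifications enumerated up to the
#' configured cap.  Peptides are deduplicated across proteins.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   protein sequences.
#' @param config A [dia_config()].
#' @return Data frame with columns `sequence`, `mods` (internal
#'   `"pos:delta"` string, `""` when unmodified), `mass` (monoisotopic Da)
#'   and `n_missed`.
#' @export
digest_fasta <- function(fasta, config = dia_config()) {
  if (length(fasta) == 1L && file.exists(fasta)) {
    seqs <- tryCatch(
      as.character(Biostrings::readAAStringSet(fasta)),
      error = function(e) stop("malformed FASTA input '", fasta, "': ",
                               conditionMessage(e)))
  } else {
    seqs <- fasta
  }
  bad <- grepl("[^A-Z]", seqs) |
    vapply(seqs, function(s)
      any(!strsplit(s, "")[[1]] %in% names(AA_MONO_MASS)), logical(1))
  if (any(bad)) {
    nm <- names(seqs)[bad][1]
    stop("malformed FASTA record ",
         if (is.null(nm) || is.na(nm)) which(bad)[1] else sQuote(nm),
         ": non-standard residues")
  }
  pep <- unique(unlist(lapply(seqs, digest_protein, config = config)))
  if (length(pep) == 0L) {
    return(data.frame(sequence = character(0), mods = character(0),
                      mass = numeric(0), n_missed = integer(0)))
  }
  out <- do.call(rbind, lapply(pep, enumerate_mod_variants, config = config))
  lens <- nchar(out$sequence)
  keep <- lens >= config$peptide_length[1] & lens <= config$peptide_length[2] &
    out$mass >= config$peptide_mass[1] & out$mass <= config$peptide_mass[2]
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(paste(out$sequence, out$mods)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All enzymatic peptides of one protein, tagged "seq|n_missed".
digest_protein <- function(protein, config) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  if (!config$cleave_before_proline) {
    cut_after <- cut_after[cut_after == n | aa[cut_after + 1L] != "P"]
  }
  bounds <- unique(c(0L, cut_after, n))   # segment boundaries
  nb <- length(bounds)
  peps <- character(0)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + config$missed_cleavages)) {
      peps <- c(peps,
                paste0(substr(protein, bounds[i] + 1L, bounds[j]),
                       "|", j - i - 1L))
    }
  }
  peps
}

# Expand one "seq|missed" tag into its variable-modification variants.
enumerate_mod_variants <- function(tagged, config) {
  parts <- strsplit(tagged, "|", fixed = TRUE)[[1]]
  sequence <- parts[1]
  n_missed <- as.integer(parts[2])
  aa <- strsplit(sequence, "")[[1]]
  sites <- which(aa %in% names(config$variable_mods))
  combos <- list(integer(0))
  if (length(sites)) {
    for (k in seq_len(min(length(sites), config$max_variable_mods))) {
      cmb <- utils::combn(seq_along(sites), k, simplify = FALSE)
      combos <- c(combos, lapply(cmb, function(j) sites[j]))
    }
  }
  base_mass <- peptide_mass(sequence, "", config$static_mods)
  rows <- lapply(combos, function(pos) {
    delta <- unname(config$variable_mods[aa[pos]])
    data.frame(sequence = sequence,
               mods = make_mod_string(pos, delta),
               mass = base_mass + sum(delta),
               n_missed = n_missed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate shuffled decoy peptides paired with their targets
#'
#' Each target peptide receives one decoy built by shuffling its internal
#' residues while keeping the first and last residues fixed (preserving
#' mass, composition and the enzymatic C-terminus).  Modifications travel
#' with their residues through the shuffle.  If a shuffle collides with any
#' target sequence it is retried up to `max_retries` times and then falls
#' back to reversing the internal residues.  Targets too short to have
#' internal residues yield self-identical decoys, flagged in the output.
#'
#' @param peptides Data frame from [digest_fasta()].
#' @param seed Integer seed; decoys are reproducible given the seed.
#' @param max_retries Shuffle retries on collision (default 10).
#' @return Data frame of `2 * nrow(peptides)` rows with the columns of the
#'   input plus `is_decoy`, `pair_id` (shared by a target and its decoy)
#'   and `self_identical`.
#' @export
generate_decoys <- function(peptides, seed, max_retries = 10L) {
  stopifnot(is.data.frame(peptides))
  n <- nrow(peptides)
  targets <- peptides
  targets$is_decoy <- FALSE
  targets$pair_id <- seq_len(n)
  target_seqs <- unique(peptides$sequence)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  dec <- vector("list", n)
  for (i in seq_len(n)) {
    sq <- peptides$sequence[i]
    pos <- mod_positions(peptides$mods[i])
    delta <- mod_deltas(peptides$mods[i])
    len <- nchar(sq)
    aa <- strsplit(sq, "")[[1]]
    if (len <= 3L) {
      dseq <- sq; dpos <- pos
    } else {
      internal <- 2L:(len - 1L)
      dseq <- NULL
      for (try in seq_len(max_retries)) {
        perm <- sample(internal)
        cand <- paste(c(aa[1L], aa[perm], aa[len]), collapse = "")
        if (!cand %in% target_seqs) {
          dseq <- cand
          new_index <- c(1L, perm, len)   # new position p holds old residue
          break
        }
      }
      if (is.null(dseq)) {
        perm <- rev(internal)
        dseq <- paste(c(aa[1L], aa[perm], aa[len]), collapse = "")
        new_index <- c(1L, perm, len)
      }
      # old position -> new position for the modification map
      dpos <- if (length(pos)) match(pos, new_index) else integer(0)
    }
    dec[[i]] <- data.frame(
      sequence = dseq, mods = make_mod_string(dpos, delta),
      mass = peptides$mass[i], n_missed = peptides$n_missed[i],
      is_decoy = TRUE, pair_id = i,
      self_identical = dseq == sq,
      stringsAsFactors = FALSE)
  }
  decoys <- do.call(rbind, dec)
  targets$self_identical <- decoys$self_identical
  out <- rbind(targets, decoys)
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Enumerate charged precursors from peptides
#'
#' @param peptides Data frame with at least `sequence`, `mods`, `mass`
#'   (plus `is_decoy`/`pair_id` if present).
#' @param charges Integer charge states (default 1 through 5).
#' @return Data frame with one row per (peptide, charge): `peptide_idx`
#'   (row in `peptides`), `charge` and theoretical `mz`.
#' @export
enumerate_precursors <- function(peptides, charges = 1:5) {
  n <- nrow(peptides)
  idx <- rep(seq_len(n), each = length(charges))
  ch <- rep(as.integer(charges), times = n)
  out <- data.frame(peptide_idx = idx, charge = ch,
                    mz = (peptides$mass[idx] + ch * PROTON_MASS) / ch)
  if (!is.null(peptides$is_decoy)) out$is_decoy <- peptides$is_decoy[idx]
  if (!is.null(peptides$pair_id)) out$pair_id <- peptides$pair_id[idx]
  out
}

#' Theoretical b- and y-ion m/z values
#'
#' Singly charged b- and y-ions at every cleavage position; doubly charged
#' ions are added when the precursor charge is 3 or higher.  Variable
#' modification deltas are included for the residues each ion covers, and
#' static modifications are always applied.
#'
#' @param sequence Peptide string.
#' @param mods Internal modification string.
#' @param charge Precursor charge state.
#' @param static_mods Named static modification deltas.
#' @return Sorted numeric vector of fragment m/z values.
#' @export
theoretical_fragments <- function(sequence, mods = "", charge = 2L,
                                  static_mods = c(C = CARBAMIDOMETHYL_MASS)) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(numeric(0))
  res <- AA_MONO_MASS[aa]
  if (length(static_mods)) {
    extra <- static_mods[aa]
    extra[is.na(extra)] <- 0
    res <- res + extra
  }
  pos <- mod_positions(mods)
  if (length(pos)) res[pos] <- res[pos] + mod_deltas(mods)
  fwd <- cumsum(res)                      # prefix residue masses
  b1 <- fwd[seq_len(n - 1L)] + PROTON_MASS
  y1 <- (fwd[n] - fwd[seq_len(n - 1L)]) + WATER_MASS + PROTON_MASS
  frags <- c(b1, y1)
  if (charge >= 3L) frags <- c(frags, (frags + PROTON_MASS) / 2)
  sort(unname(frags))
}

#' Hydrophobicity-sum retention-time predictor
#'
#' The default predictor: predicted retention time is the sum of residue
#' retention coefficients (Krokhin-style C18 scale), with a reduced
#' coefficient for oxidized methionine.  Peptides carrying any other
#' variable modification are reported as unpredictable, so the
#' retention-time feature falls back to its default value downstream.
#'
#' @return An object of class `"rt_predictor"` with elements `predict(seq,
#'   mods)` and `predictable(seq, mods)`, both vectorized.
#' @export
rt_predictor_hydrophobicity <- function() {
  pr <- function(sequence, mods = rep("", length(sequence))) {
    mapply(function(sq, md) {
      aa <- strsplit(sq, "")[[1]]
      v <- sum(RT_COEF[aa])
      pos <- mod_positions(md)
      if (length(pos)) {
        # oxidized Met elutes earlier
        nox <- sum(abs(mod_deltas(md) - OXIDATION_MASS) < 1e-3)
        v <- v - 3.8 * nox
      }
      unname(v)
    }, sequence, mods, USE.NAMES = FALSE)
  }
  ok <- function(sequence, mods = rep("", length(sequence))) {
    mapply(function(sq, md) {
      if (!all(strsplit(sq, "")[[1]] %in% names(RT_COEF))) return(FALSE)
      d <- mod_deltas(md)
      all(abs(d - OXIDATION_MASS) < 1e-3)
    }, sequence, mods, USE.NAMES = FALSE)
  }
  structure(list(predict = pr, predictable = ok,
                 label = "hydrophobicity-sum"),
            class = "rt_predictor")
}

#' File-backed retention-time predictor
#'
#' Reads a two-column TSV (modified peptide string as produced by
#' [format_modified_sequence()], predicted retention time) or accepts an
#' equivalent data frame.  Peptides absent from the table are flagged
#' unpredictable rather than raising an error.
#'
#' @param table Path to a TSV file without header, or a data frame whose
#'   first two columns are peptide and retention time.
#' @return An `"rt_predictor"`.
#' @export
rt_predictor_table <- function(table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, header = FALSE,
                               stringsAsFactors = FALSE)
  }
  rt <- stats::setNames(as.numeric(table[[2]]), as.character(table[[1]]))
  key <- function(sequence, mods)
    mapply(format_modified_sequence, sequence, mods, USE.NAMES = FALSE)
  pr <- function(sequence, mods = rep("", length(sequence)))
    unname(rt[key(sequence, mods)])
  ok <- function(sequence, mods = rep("", length(sequence)))
    key(sequence, mods) %in% names(rt)
  structure(list(predict = pr, predictable = ok, label = "table"),
            class = "rt_predictor")
}

#' Predict retention times for a peptide table
#'
#' @param predictor An `"rt_predictor"`.
#' @param peptides Data frame with `sequence` and `mods` columns.
#' @return Numeric vector of predicted retention times, `NA` where the
#'   predictor cannot handle the peptide.
#' @export
predict_rt <- function(predictor, peptides) {
  stopifnot(inherits(predictor, "rt_predictor"))
  ok <- predictor$predictable(peptides$sequence, peptides$mods)
  out <- rep(NA_real_, nrow(peptides))
  if (any(ok)) {
    out[ok] <- predictor$predict(peptides$sequence[ok], peptides$mods[ok])
  }
  out
}

#' Build the full precursor database for a search
#'
#' Digests the FASTA (or takes a prepared peptide table), generates paired
#' decoys, enumerates charge states, precomputes singly charged fragment
#' m/z vectors per peptide and predicts retention times.
#'
#' @param fasta FASTA path or named character vector of proteins; ignored
#'   when `peptides` is given.
#' @param peptides Optional data frame of target peptides (columns
#'   `sequence`, `mods`, `mass`, `n_missed`) to use instead of digesting.
#' @param config A [dia_config()].
#' @param seed Integer seed for decoy generation.
#' @param rt_predictor An `"rt_predictor"` (default hydrophobicity sum).
#' @return A list of class `"precursor_db"` with `peptides` (targets and
#'   decoys, with `rt` and `rt_ok`), `precursors` and `fragments1` (list of
#'   singly charged fragment m/z vectors, one per peptide row).
#' @export
build_precursor_db <- function(fasta = NULL, peptides = NULL,
                               config = dia_config(), seed = 1L,
                               rt_predictor = rt_predictor_hydrophobicity()) {
  if (is.null(peptides)) {
    stopifnot(!is.null(fasta))
    peptides <- digest_fasta(fasta, config)
  }
  peps <- generate_decoys(peptides, seed = seed)
  peps$rt <- predict_rt(rt_predictor, peps)
  peps$rt_ok <- !is.na(peps$rt)
  prec <- enumerate_precursors(peps, config$charges)
  frag1 <- lapply(seq_len(nrow(peps)), function(i)
    theoretical_fragments(peps$sequence[i], peps$mods[i], charge = 1L,
                          static_mods = config$static_mods))
  structure(list(peptides = peps, precursors = prec, fragments1 = frag1,
                 config = config),
            class = "precursor_db")
}

#' @export
print.precursor_db <- function(x, ...) {
  cat(sprintf(
    "Precursor database: %d peptides (%d targets), %d precursors\n",
    nrow(x$peptides), sum(!x$peptides$is_decoy), nrow(x$precursors)))
  invisible(x)
}

# Fragment m/z vector for one precursor row of a db.
precursor_fragments <- function(db, prec_row) {
  f1 <- db$fragments1[[db$precursors$peptide_idx[prec_row]]]
  if (db$precursors$charge[prec_row] >= 3L) {
    sort(c(f1, (f1 + PROTON_MASS) / 2))
  } else {
    f1
  }
}
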