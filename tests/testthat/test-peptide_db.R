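unbounded <- dia_config(peptide_length = c(1L, 1000L),
                        peptide_mass = c(0, 1e7),
                        variable_mods = numeric(0))

test_that("tryptic digestion enumerates missed-cleavage peptides", {
  got <- digest_fasta(c(p1 = "MKRAK"), unbounded)
  expect_setequal(got$sequence, c("MK", "R", "AK", "MKR", "RAK", "MKRAK"))
  expect_equal(got$n_missed[got$sequence == "MKRAK"], 2L)
  # zero missed cleavages partition the protein
  cfg0 <- dia_config(peptide_length = c(1L, 1000L), peptide_mass = c(0, 1e7),
                     variable_mods = numeric(0), missed_cleavages = 0L)
  prot <- "MKAAARDDDKEEEK"
  parts <- digest_fasta(c(p = prot), cfg0)
  expect_equal(paste(parts$sequence, collapse = ""), prot)
})

test_that("proline rule and malformed records are handled", {
  cfgp <- dia_config(peptide_length = c(1L, 1000L), peptide_mass = c(0, 1e7),
                     variable_mods = numeric(0),
                     cleave_before_proline = FALSE)
  got <- digest_fasta(c(p = "AKPSK"), cfgp)
  expect_false("AK" %in% got$sequence)   # K-P bond preserved
  expect_true("AKPSK" %in% got$sequence)
  expect_error(digest_fasta(c(bad = "PEPT1DEK"), unbounded), "bad")
})

test_that("variable modifications enumerate subsets up to the cap", {
  cfg <- dia_config(peptide_length = c(1L, 1000L), peptide_mass = c(0, 1e7))
  got <- digest_fasta(c(p = "MM"), cfg)
  expect_equal(nrow(got), 4L)            # none, M1ox, M2ox, both
  expect_setequal(got$mods,
                  c("", "1:15.99491", "2:15.99491",
                    "1:15.99491,2:15.99491"))
  # masses differ by exactly one/two oxidations
  base <- got$mass[got$mods == ""]
  expect_equal(sort(got$mass - base), c(0, 15.99491, 15.99491, 2 * 15.99491),
               tolerance = 1e-6)
  # cap: MMMM with <=3 mods -> 1 + 4 + 6 + 4 = 15 variants
  got4 <- digest_fasta(c(p = "MMMM"), cfg)
  expect_equal(nrow(got4), 15L)
})

test_that("monoisotopic masses are additive", {
  got <- digest_fasta(c(p = "PEPTIDEK"), unbounded)
  aa <- strsplit("PEPTIDEK", "")[[1]]
  expect_equal(got$mass, sum(diadetect:::AA_MONO_MASS[aa]) + 18.010565,
               tolerance = 1e-5)
  # static carbamidomethyl always applied on C
  cfgC <- dia_config(peptide_length = c(1L, 1000L), peptide_mass = c(0, 1e7),
                     variable_mods = numeric(0))
  gotC <- digest_fasta(c(p = "ACDK"), cfgC)
  expect_equal(gotC$mass,
               sum(diadetect:::AA_MONO_MASS[c("A", "C", "D", "K")]) +
                 18.0105646 + 57.02146, tolerance = 1e-5)
})

test_that("decoy generation is seeded, mass-preserving and paired", {
  set.seed(99)
  peps <- data.frame(sequence = random_peptides(200), mods = "",
                     mass = 0, n_missed = 0L, stringsAsFactors = FALSE)
  peps$mass <- vapply(peps$sequence, function(s)
    diadetect:::peptide_mass(s), numeric(1))
  a <- generate_decoys(peps, seed = 5)
  b <- generate_decoys(peps, seed = 5)
  expect_identical(a, b)                         # determinism
  dec <- a[a$is_decoy, ]
  tar <- a[!a$is_decoy, ]
  expect_equal(nrow(dec), nrow(tar))             # bijection via pair_id
  expect_setequal(dec$pair_id, tar$pair_id)
  # shuffling preserves composition, hence the mass multiset
  expect_equal(sort(dec$mass), sort(tar$mass), tolerance = 1e-9)
  # terminal residues fixed
  first <- function(x) substr(x, 1, 1)
  last <- function(x) substr(x, nchar(x), nchar(x))
  o <- order(dec$pair_id)
  expect_equal(first(dec$sequence[o]), first(tar$sequence[order(tar$pair_id)]))
  expect_equal(last(dec$sequence[o]), last(tar$sequence[order(tar$pair_id)]))
})

test_that("degenerate short targets yield flagged self-identical decoys", {
  peps <- data.frame(sequence = "AK", mods = "",
                     mass = diadetect:::peptide_mass("AK"), n_missed = 0L,
                     stringsAsFactors = FALSE)
  out <- generate_decoys(peps, seed = 1)
  expect_equal(out$sequence[out$is_decoy], "AK")
  expect_true(all(out$self_identical))
})

test_that("modifications travel with their residue through the shuffle", {
  peps <- data.frame(sequence = "AMCDEFGK", mods = "2:15.99491",
                     mass = diadetect:::peptide_mass("AMCDEFGK",
                                                     "2:15.99491"),
                     n_missed = 0L, stringsAsFactors = FALSE)
  out <- generate_decoys(peps, seed = 3)
  dec <- out[out$is_decoy, ]
  pos <- diadetect:::mod_positions(dec$mods)
  expect_length(pos, 1L)
  expect_equal(substr(dec$sequence, pos, pos), "M")
})

test_that("precursor enumeration crosses peptides with charges", {
  peps <- data.frame(sequence = rep("PEPTIDEK", 10),
                     mods = "", mass = seq(800, 1700, by = 100),
                     n_missed = 0L, stringsAsFactors = FALSE)
  prec <- enumerate_precursors(peps, 1:5)
  expect_equal(nrow(prec), 50L)
  prec23 <- enumerate_precursors(peps, c(2L, 3L))
  expect_equal(nrow(prec23), 20L)
  # hand arithmetic: mass 999.0 at charge 2
  one <- enumerate_precursors(data.frame(sequence = "X", mods = "",
                                         mass = 999.0), 2L)
  expect_equal(one$mz, (999.0 + 2 * 1.007276466) / 2, tolerance = 1e-9)
  expect_equal(one$mz, 500.50728, tolerance = 1e-4)
})

test_that("theoretical fragments follow the b/y ion series", {
  f <- theoretical_fragments("AG", charge = 1L)
  expect_equal(sort(f), c(72.0444, 76.0393), tolerance = 1e-4)
  # length-n peptide at charge 2: exactly 2(n-1) fragments
  f8 <- theoretical_fragments("PEPTIDEK", charge = 2L)
  expect_length(f8, 2 * 7)
  # charge >= 3 adds doubly charged ions
  f83 <- theoretical_fragments("PEPTIDEK", charge = 3L)
  expect_length(f83, 4 * 7)
  expect_true(all(f8 %in% f83))
  # an internal shuffle preserves b_(n-1) and y_1 (same covered residues)
  AA <- diadetect:::AA_MONO_MASS
  p <- 1.007276466; w <- 18.0105646
  by_ends <- function(sq) {
    aa <- strsplit(sq, "")[[1]]; n <- length(aa)
    c(b = sum(AA[aa[1:(n - 1)]]) + p, y = AA[[aa[n]]] + w + p)
  }
  ft <- theoretical_fragments("ANDGK", charge = 1L, static_mods = NULL)
  fd <- theoretical_fragments("AGDNK", charge = 1L, static_mods = NULL)
  near <- function(v, set) all(vapply(v, function(x)
    min(abs(set - x)) < 1e-9, logical(1)))
  expect_true(near(by_ends("ANDGK"), ft))
  expect_true(near(by_ends("AGDNK"), fd))
  expect_equal(unname(by_ends("ANDGK")), unname(by_ends("AGDNK")),
               tolerance = 1e-9)
})

test_that("fragments include modification deltas at covered positions", {
  f0 <- theoretical_fragments("AMGK", charge = 1L)
  f1 <- theoretical_fragments("AMGK", mods = "2:15.99491", charge = 1L)
  # b1 (A only) unchanged; the 3 ions covering position 2 (b2, b3, y3)
  # shift by exactly one oxidation each
  expect_lt(abs(min(f1) - min(f0)), 1e-9)
  expect_equal(sum(f1) - sum(f0), 3 * 15.99491, tolerance = 1e-6)
})

test_that("retention-time predictors order, look up and flag peptides", {
  hp <- rt_predictor_hydrophobicity()
  peps <- data.frame(sequence = c("KKKK", "LLLL"), mods = c("", ""),
                     stringsAsFactors = FALSE)
  rt <- predict_rt(hp, peps)
  expect_lt(rt[1], rt[2])
  # oxidation supported, other modifications flagged unpredictable
  peps2 <- data.frame(sequence = c("AMGK", "AMGK"),
                      mods = c("2:15.99491", "2:79.96633"),
                      stringsAsFactors = FALSE)
  rt2 <- predict_rt(hp, peps2)
  expect_false(is.na(rt2[1]))
  expect_true(is.na(rt2[2]))
  # file-backed predictor
  tab <- data.frame(pep = "PEPTIDEK", rt = 42.0)
  fb <- rt_predictor_table(tab)
  got <- predict_rt(fb, data.frame(sequence = c("PEPTIDEK", "OTHERK"),
                                   mods = c("", ""),
                                   stringsAsFactors = FALSE))
  expect_equal(got, c(42.0, NA_real_))
})

test_that("stored precursor m/z matches recomputation from sequence", {
  cfg <- dia_config()
  db <- build_precursor_db(
    peptides = digest_fasta(c(p = "MKRAAACDEFGHIKLLLMNPQRSTVWYK"), cfg),
    config = cfg, seed = 2)
  pr <- db$precursors
  m <- vapply(seq_len(nrow(pr)), function(i) {
    j <- pr$peptide_idx[i]
    diadetect:::peptide_mass(db$peptides$sequence[j], db$peptides$mods[j],
                             cfg$static_mods)
  }, numeric(1))
  expect_equal(pr$mz, (m + pr$charge * diadetect:::PROTON_MASS) / pr$charge,
               tolerance = 1e-6)
})
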