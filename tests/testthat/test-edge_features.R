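test_that("precursor rank score counts intensity ranks with >=", {
  # peaks: 400 (100), mono 500 (80), M+1 (60), 450 (40), M+2 (20)
  sp <- 1.00335483
  ms1 <- dia_spectrum(c(400, 450, 500, 500 + sp / 2, 500 + 2 * sp / 2),
                      c(100, 40, 80, 60, 20), 1L)
  w <- precursor_rank_score(ms1, 500, charge = 2L, tol_ppm = 10,
                            isotope_spacing = sp)
  expect_equal(w, -log(2 * 3 * 5), tolerance = 1e-6)   # -ln 30
})

test_that("unmatched isotope queries take the worst rank", {
  ms1 <- dia_spectrum(c(300, 310, 320, 330, 340),
                      c(10, 20, 30, 40, 50), 1L)
  w <- precursor_rank_score(ms1, 800, charge = 2L, tol_ppm = 10)
  expect_equal(w, -3 * log(5), tolerance = 1e-6)
  # empty survey scan is flagged as the degenerate zero
  expect_identical(precursor_rank_score(dia_spectrum(numeric(0),
                                                     numeric(0), 1L),
                                        800, 2L), 0)
})

test_that("rank score is zero only when all queries hit the top peak", {
  # huge tolerance: all three isotope queries match the single most
  # intense peak -> rank 1 each
  ms1 <- dia_spectrum(c(500, 520), c(100, 5), 1L)
  w <- precursor_rank_score(ms1, 500, charge = 2L, tol_ppm = 5000)
  expect_identical(w, 0)
  # and the score is never positive
  set.seed(3)
  for (i in 1:20) {
    ms1r <- dia_spectrum(sort(runif(10, 300, 900)), runif(10, 1, 100), 1L)
    expect_lte(precursor_rank_score(ms1r, runif(1, 300, 900), 2L, 10), 0)
  }
})

test_that("segment peak picking keeps the 10 most intense per segment", {
  set.seed(5)
  mz <- sort(runif(300, 100, 1100))
  s <- dia_spectrum(mz, runif(300, 1, 1000), 2L, window = c(400, 425))
  p <- pick_peaks(s)
  expect_lte(length(p$mz), 100L)
  expect_true(all(p$mz %in% s$mz))
  # per segment at most 10
  seg <- pmin(10, 1 + floor((p$mz - min(mz)) / (max(mz) - min(mz)) * 10))
  expect_lte(max(table(seg)), 10L)
})

test_that("chance-match probability is the padded interval-union fraction", {
  # picked peaks at 100 and 200, tau = 0.5 Th: union 2.0, range 101
  expect_equal(chance_match_prob(c(100, 200), 0.5, "th"), 2 / 101,
               tolerance = 1e-12)
  # overlapping intervals are merged and the value is capped at 1
  # fully overlapping intervals cover the whole padded range
  expect_equal(chance_match_prob(c(100, 100.4), 0.5, "th"), 1,
               tolerance = 1e-12)
  expect_lte(chance_match_prob(seq(100, 101, by = 0.1), 0.5, "th"), 1)
})

test_that("chance-match probability agrees with Monte-Carlo sampling", {
  set.seed(17)
  for (rep in 1:3) {
    picked <- sort(runif(30, 300, 900))
    tau <- 0.3
    p <- chance_match_prob(picked, tau, "th")
    lo <- picked[1] - tau; hi <- picked[30] + tau
    q <- runif(20000, lo, hi)
    phat <- mean(vapply(q, function(x) any(abs(picked - x) <= tau),
                        logical(1)))
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(phat - p), 3 * se + 1e-6)
  }
})

test_that("fragment P-value matches binomial tail enumeration", {
  # N_v = 3, N_uv = 2, p = 0.1: tail = 3(0.1)^2(0.9) + (0.1)^3 = 0.028
  expect_equal(diadetect:::binomial_tail_score(2L, 3L, 0.1), -log(0.028),
               tolerance = 1e-9)
  # boundary cases are uninformative zeros
  expect_identical(diadetect:::binomial_tail_score(0L, 3L, 0.1), 0)
  expect_identical(diadetect:::binomial_tail_score(2L, 0L, 0.1), 0)
  expect_identical(diadetect:::binomial_tail_score(2L, 3L, 1), 0)
  # log-space tail equals term enumeration over a grid
  for (n_v in c(1L, 5L, 17L, 30L)) {
    for (p in c(0.01, 0.2, 0.5, 0.9)) {
      for (n_uv in unique(c(1L, n_v %/% 2 + 1L, n_v))) {
        terms <- vapply(n_uv:n_v, function(j)
          choose(n_v, j) * p^j * (1 - p)^(n_v - j), numeric(1))
        expect_equal(diadetect:::binomial_tail_score(n_uv, n_v, p),
                     -log(sum(terms)), tolerance = 1e-9)
      }
    }
  }
})

test_that("full fragment P-value pipeline scores a constructed spectrum", {
  # two picked peaks at 100 and 200 with tau chosen so p_u = 0.1; three
  # fragments of which two match
  tau <- 10 / 3.8                       # 4*tau / (100 + 2*tau) = 0.1
  s <- dia_spectrum(c(100, 200), c(5, 5), 2L, window = c(400, 425))
  w <- fragment_pvalue_score(s, c(100 + tau / 2, 150, 200 - tau / 2),
                             tol = tau, tol_type = "th")
  expect_equal(w, -log(0.028), tolerance = 1e-6)
  # no fragment in range -> 0; empty fragment set -> 0
  expect_identical(fragment_pvalue_score(s, c(500, 600), tol = tau,
                                         tol_type = "th"), 0)
  expect_identical(fragment_pvalue_score(s, numeric(0), tol = tau,
                                         tol_type = "th"), 0)
  # fewer than 2 picked peaks -> uninformative
  s1 <- dia_spectrum(100, 5, 2L, window = c(400, 425))
  expect_identical(fragment_pvalue_score(s1, c(100), tol = tau,
                                         tol_type = "th"), 0)
})

test_that("fragment P-value is non-decreasing in the match count", {
  vals <- vapply(0:10, function(k)
    diadetect:::binomial_tail_score(k, 10L, 0.15), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("retention-time score compares normalized ranks", {
  # observed {10,20,30,40}, t_u = 20 -> 0.5; predicted {5..9}, t_v = 9 -> 1
  expect_equal(rt_diff_score(20, 9, c(10, 20, 30, 40), 5:9), -0.5,
               tolerance = 1e-12)
  # both at their maxima -> 0
  expect_equal(rt_diff_score(40, 9, c(10, 20, 30, 40), 5:9), 0)
  # unpredictable peptide -> fallback regardless of scan
  expect_equal(rt_diff_score(20, NA, c(10, 20, 30, 40), 5:9), -0.5)
  expect_equal(rt_diff_score(20, NA, c(10, 20, 30, 40), 5:9,
                             fallback = -0.25), -0.25)
  # bounded in [-1, 0]
  set.seed(2)
  for (i in 1:50) {
    v <- rt_diff_score(runif(1, 0, 50), runif(1, -10, 10),
                       sort(runif(9, 0, 50)), sort(runif(7, -10, 10)))
    expect_gte(v, -1); expect_lte(v, 0)
  }
})

# Run with one window whose MS2 scans carry chosen fragment profiles and
# whose MS1 scans carry a chosen precursor profile.
profile_run <- function(prec_profile, frag_profiles, prec_mz = 450,
                        frag_mz = c(210, 320, 430)) {
  wins <- data.frame(low = 440, high = 460)
  toy_run(length(prec_profile), wins,
          ms1_peaks = function(cyc) {
            v <- prec_profile[cyc + 1]
            if (v > 0) list(mz = prec_mz, intensity = v)
            else list(mz = numeric(0), intensity = numeric(0))
          },
          ms2_peaks = function(cyc, w) {
            fm <- frag_mz[seq_along(frag_profiles)]
            int <- vapply(frag_profiles, function(p) p[cyc + 1], numeric(1))
            keep <- int > 0
            list(mz = fm[keep], intensity = int[keep])
          })
}

test_that("coelution score matches hand-computed normalized dot products", {
  # precursor [0,1,1,0,0]; fragments: identical to precursor (dot 1),
  # [1,1,0,0,0] (dot 0.5), [sqrt(11.5),1,0,0,0] (dot exactly 0.2)
  run <- profile_run(c(0, 1, 1, 0, 0),
                     list(c(0, 1, 1, 0, 0),
                          c(1, 1, 0, 0, 0),
                          c(sqrt(11.5), 1, 0, 0, 0)))
  si <- run$ms2_index[3, 1]             # center cycle (index 2, 0-based)
  w <- coelution_score(run, si, 450, c(210, 320, 430), delta_t = 2L,
                       tol_ppm = 10)
  expect_equal(w, (1 + 0.5 + 0.2) / 3, tolerance = 1e-6)
})

test_that("coelution self-similarity and orthogonality cases", {
  run1 <- profile_run(c(1, 2, 3, 2, 1),
                      list(c(1, 2, 3, 2, 1), c(2, 4, 6, 4, 2),
                           c(0.5, 1, 1.5, 1, 0.5)))
  si <- run1$ms2_index[3, 1]
  expect_equal(coelution_score(run1, si, 450, c(210, 320, 430), 2L, 10), 1,
               tolerance = 1e-9)
  run2 <- profile_run(c(1, 0, 0, 0, 0), list(c(0, 1, 0, 0, 0)))
  si2 <- run2$ms2_index[3, 1]
  expect_equal(coelution_score(run2, si2, 450, c(210), 2L, 10), 0)
  # zero-norm precursor profile contributes 0
  run3 <- profile_run(c(0, 0, 0, 0, 0), list(c(1, 1, 1, 1, 1)))
  expect_equal(coelution_score(run3, run3$ms2_index[3, 1], 450, 210, 2L, 10),
               0)
})

test_that("coelution stays within [0, 1] and averages all if < 3 fragments", {
  run <- profile_run(c(1, 2, 3, 2, 1),
                     list(c(1, 2, 3, 2, 1), c(3, 2, 1, 0, 0)))
  si <- run$ms2_index[3, 1]
  w <- coelution_score(run, si, 450, c(210, 320), 2L, 10)
  p <- c(1, 2, 3, 2, 1); f <- c(3, 2, 1, 0, 0)
  d2 <- sum(p * f) / sqrt(sum(p^2) * sum(f^2))
  expect_equal(w, (1 + d2) / 2, tolerance = 1e-9)
  expect_gte(w, 0); expect_lte(w, 1)
})
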