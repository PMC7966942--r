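test_that("octave binning follows half-open power-of-2 classes", {
  h <- octave_histogram(c(1, 1, 2, 3, 4))
  expect_equal(h$octave, 0:2)
  expect_equal(h$n_species, c(2, 2, 1))
  expect_equal(attr(h, "S"), 5)
  expect_equal(attr(h, "N"), 11)
  # exact power of two lands in its own octave
  h2 <- octave_histogram(1024)
  expect_equal(h2$octave, 0:10)
  expect_equal(h2$n_species, c(rep(0, 10), 1))
  expect_error(octave_histogram(c(1, 0)), "positive")
})

test_that("octave binning matches a brute-force log2 tally and conserves S", {
  ab <- withr::with_seed(9, sample.int(5000, 1000, replace = TRUE))
  h <- octave_histogram(ab)
  oracle <- table(factor(floor(log2(ab)), levels = 0:max(h$octave)))
  expect_equal(h$n_species, as.vector(oracle))
  expect_equal(sum(h$n_species), length(ab))
  # ranges are disjoint and cover [1, max]
  expect_equal(h$lower[-1], h$upper[-nrow(h)])
  expect_true(max(ab) < h$upper[nrow(h)] && max(ab) >= h$lower[nrow(h)])
})

test_that("chi-squared GOF matches hand formulas and brute force", {
  perfect <- gof_chisq(c(5, 10, 20), c(5, 10, 20), 0)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)
  hand <- gof_chisq(c(10, 20), c(15, 15), 0)
  expect_equal(hand$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(hand$dof, 1)
  expect_equal(hand$p_value, pchisq(10 / 3, 1, lower.tail = FALSE))
  # brute force, no pooling triggered
  o <- withr::with_seed(2, rpois(8, 20))
  e <- withr::with_seed(3, runif(8, 10, 30))
  g <- gof_chisq(o, e, 2)
  expect_equal(g$chi2, sum((o - e)^2 / e), tolerance = 1e-12)
  expect_equal(g$dof, 8 - 1 - 2)
  # identical reordering leaves chi2 unchanged (no pooling)
  perm <- withr::with_seed(4, sample(8))
  expect_equal(gof_chisq(o[perm], e[perm], 2)$chi2, g$chi2, tolerance = 1e-12)
})

test_that("GOF pooling merges low-expectation tail bins", {
  o <- c(1, 4, 30, 40, 3, 0)
  e <- c(0.2, 3, 28, 41, 2.5, 0.3)
  g <- gof_chisq(o, e, 0, min_expected = 1)
  expect_true(all(g$expected >= 1))
  expect_equal(sum(g$observed), sum(o))
  expect_equal(sum(g$expected), sum(e))
  g5 <- gof_chisq(o, e, 0, min_expected = 5)
  expect_true(all(g5$expected >= 5))
  expect_lt(length(g5$expected), length(g$expected))
  # pooling floor: never below 2 bins, even when the threshold is unmet
  floor2 <- gof_chisq(c(1, 1), c(0.1, 0.2), 0, min_expected = 5)
  expect_equal(length(floor2$expected), 2)
  expect_error(gof_chisq(1:3, c(1, -1, 2), 0), "positive")
})

test_that("Fisher's alpha solves S = alpha log(1 + N/alpha) and round-trips", {
  # forward map: alpha = 10, N = 1000 -> S; solving back recovers alpha
  S_fwd <- 10 * log(1 + 1000 / 10)
  a <- rareassembly:::fisher_alpha(S_fwd, 1000)
  expect_equal(a, 10, tolerance = 1e-6)
  expect_equal(a * log(1 + 1000 / a), S_fwd, tolerance = 1e-8)
  expect_error(rareassembly:::fisher_alpha(10, 10), "S >= 2 and N > S")
})

test_that("log-series fit recovers alpha independently of binning and handles S ~ N", {
  ab <- withr::with_seed(10, rareassembly:::rlogseries(300, 2000 / 2020))
  h <- octave_histogram(ab)
  f <- fit_logseries(h)
  # alpha depends only on (S, N), not the octaves
  expect_equal(f$alpha * log(1 + f$N / f$alpha), f$S, tolerance = 1e-8)
  expect_equal(f$x, f$N / (f$N + f$alpha))
  # expected octave counts are partial sums of alpha x^n / n
  n <- seq_len(3)
  expect_equal(f$expected[1], f$alpha * f$x, tolerance = 1e-10)
  expect_equal(f$expected[2], sum(f$alpha * f$x^(2:3) / (2:3)), tolerance = 1e-10)
  # nearly all singletons: alpha large, expected bin 0 ~ S
  h99 <- octave_histogram(c(rep(1, 98), 2))
  f99 <- fit_logseries(h99)
  expect_gt(f99$alpha, 1000)
  expect_equal(f99$expected[1], attr(h99, "S"), tolerance = 0.15 * attr(h99, "S"))
})

test_that("log-normal fit recovers exact Preston parameters and the symmetry center", {
  k <- 0:10
  S0 <- 50; a <- 0.4; R0 <- 5
  counts <- round(S0 * exp(-a^2 * (k - R0)^2), 8)
  # synthesize a histogram object carrying these octave counts
  h <- octave_histogram(rep(2^k, times = pmax(round(counts), 1)))
  h$n_species <- counts
  f <- fit_lognormal(h)
  expect_equal(f$S0, S0, tolerance = 1e-4)
  expect_equal(f$a, a, tolerance = 1e-4)
  expect_equal(f$R0, R0, tolerance = 1e-4)
  expect_lt(f$chi2, 1e-6)
  # symmetric histogram -> R0 at the center of symmetry
  sym <- c(2, 10, 30, 10, 2)
  hs <- octave_histogram(rep(2^(0:4), times = sym))
  fs <- fit_lognormal(hs)
  expect_equal(fs$R0, 2, tolerance = 1e-6)
  expect_error(fit_lognormal(octave_histogram(c(1, 2))), "3 nonempty")
})

test_that("log-normal least squares agrees with an independent Levenberg-Marquardt fit", {
  skip_if_not_installed("minpack.lm")
  counts <- withr::with_seed(6, rpois(9, 40 * exp(-0.35^2 * (0:8 - 4)^2)) + 1)
  h <- octave_histogram(rep(2^(0:8), times = counts))
  f <- fit_lognormal(h)
  dat <- data.frame(k = 0:8, y = counts)
  lm_fit <- minpack.lm::nlsLM(
    y ~ S0 * exp(-a^2 * (k - R0)^2), data = dat,
    start = list(S0 = max(counts), a = 0.3, R0 = 4)
  )
  cf <- coef(lm_fit)
  expect_equal(f$S0, unname(cf["S0"]), tolerance = 1e-3)
  expect_equal(abs(f$a), abs(unname(cf["a"])), tolerance = 1e-3)
  expect_equal(f$R0, unname(cf["R0"]), tolerance = 1e-3)
})

test_that("noisy Preston curves are recovered with bounded parameter error", {
  errs <- vapply(1:20, function(s) withr::with_seed(s, {
    k <- 0:10
    counts <- rpois(11, 50 * exp(-0.4^2 * (k - 5)^2))
    if (sum(counts > 0) < 3) return(NA_real_)
    h <- octave_histogram(2^k)  # one species per octave fixes the 11 bins
    h$n_species <- counts
    abs(fit_lognormal(h)$S0 - 50) / 50
  }), numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("the grid scan emits one row per cohort, model and combination", {
  tbl <- simulate_neutral(n_taxa = 250, Nm = 300, depth = 2000,
                          n_samples = 12, seed = 14)
  g <- threshold_grid(c(0.005, 0.01, 0.02), c(3L, 4L))
  scan <- sad_grid_scan(tbl, g)
  expect_equal(nrow(scan), nrow(g) * 2 * 2)
  expect_setequal(unique(scan$cohort), c("transient_rare", "common"))
  # exactly one preferred model per (combination, cohort) with any fit
  pref <- scan |>
    dplyr::group_by(abund_threshold, occ_threshold, cohort) |>
    dplyr::summarise(n_pref = sum(preferred), any_fit = any(!is.na(chi2)),
                     .groups = "drop")
  expect_true(all(pref$n_pref[pref$any_fit] == 1))
  expect_true(all(pref$n_pref[!pref$any_fit] == 0))
})

test_that("a 1x1 grid scan equals a single classify-and-fit run", {
  tbl <- simulate_neutral(n_taxa = 250, Nm = 300, depth = 2000,
                          n_samples = 12, seed = 15)
  scan <- sad_grid_scan(tbl, threshold_grid(0.01, 4L))
  s <- summarize_taxa(tbl)
  part <- classify_taxa(s, cohort_thresholds(0.01, 4, 8))
  ab <- s$total_count[as.character(part$cohort) == "transient_rare"]
  direct <- fit_logseries(octave_histogram(ab[ab > 0]))
  got <- scan$chi2[scan$cohort == "transient_rare" & scan$model == "logseries"]
  expect_equal(got, direct$chi2)
})

test_that("empty cohorts yield NA fit rows, not errors", {
  # a table where nothing is rare at a tiny threshold
  tbl <- tibble::tibble(taxon_id = c("a", "b"),
                        s1 = c(500L, 500L), s2 = c(500L, 500L),
                        s3 = c(500L, 500L))
  scan <- sad_grid_scan(tbl, threshold_grid(0.0005, 2L))
  tr <- scan[scan$cohort == "transient_rare", ]
  expect_equal(nrow(tr), 2)
  expect_true(all(is.na(tr$chi2)))
  expect_true(all(!tr$preferred))
})
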