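test_that("the neutral prediction equals beta-tail quadrature and is monotone", {
  p <- 0.001; Nm <- 3000; d <- 1 / 2988
  quad <- integrate(function(q) dbeta(q, Nm * p, Nm * (1 - p)),
                    lower = d, upper = 1, rel.tol = 1e-12)$value
  expect_equal(ncm_predict(p, Nm, d = d), quad, tolerance = 1e-8)
  # nondecreasing everywhere, strictly increasing before saturation
  grid <- seq(1e-5, 0.05, length.out = 200)
  preds <- ncm_predict(grid, Nm = 300, d = d)
  expect_true(all(diff(preds) >= 0))
  low <- grid <= 0.005
  expect_true(all(diff(preds[low]) > 0))
  expect_true(all(preds >= 0 & preds <= 1))
  # dominant taxon limit
  expect_equal(ncm_predict(1 - 1e-9, Nm = 1e5, d = d), 1, tolerance = 1e-6)
  # beta median symmetry: p = 0.5 with d = 0.5 gives exactly 1/2
  expect_equal(ncm_predict(0.5, Nm = 40, d = 0.5), 0.5, tolerance = 1e-12)
  expect_error(ncm_predict(0, 10, d = 0.1), "strictly")
  expect_error(ncm_predict(0.5, -1, d = 0.1), "positive")
})

test_that("the neutral prediction approaches the no-drift binomial limit", {
  N <- 2988; d <- 1 / N
  # away from the detection transition zone both models saturate together
  p <- c(1e-8, 0.005, 0.05, 0.5, 0.99)
  binom <- 1 - pbinom(ceiling(N * d) - 1, N, p)
  expect_true(all(abs(ncm_predict(p, Nm = 1e7, d = d) - binom) < 1e-3))
})

test_that("fitting model-generated frequencies recovers Nm exactly", {
  p <- exp(seq(log(1e-4), log(0.05), length.out = 200))
  d <- 1 - 2^(-1 / 3000)
  obs <- ncm_predict(p, Nm = 300, d = d)
  s <- tibble::tibble(taxon_id = as.character(seq_along(p)), total_count = 1,
                      mean_rel_abund = p, occurrence = round(obs * 12),
                      occurrence_freq = obs)
  attr(s, "n_samples") <- 12
  fit <- fit_ncm(s, N = 3000)
  expect_equal(fit$Nm, 300, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
  # duplicating every record leaves the fitted Nm unchanged
  s2 <- dplyr::bind_rows(s, dplyr::mutate(s, taxon_id = paste0(taxon_id, "b")))
  attr(s2, "n_samples") <- 12
  expect_equal(fit_ncm(s2, N = 3000)$Nm, fit$Nm, tolerance = 1e-6)
})

test_that("the fit agrees with an independent Levenberg-Marquardt optimizer", {
  skip_if_not_installed("minpack.lm")
  tbl <- simulate_neutral(n_taxa = 400, Nm = 300, depth = 3000,
                          n_samples = 12, seed = 61)
  s <- summarize_taxa(tbl)
  fit <- fit_ncm(s, N = 3000)
  ok <- s$mean_rel_abund > 0 & s$mean_rel_abund < 1
  dat <- data.frame(p = s$mean_rel_abund[ok], f = s$occurrence_freq[ok])
  d <- fit$d
  lm_fit <- minpack.lm::nlsLM(
    f ~ pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE),
    data = dat, start = list(Nm = 100), lower = 1e-2, upper = 1e7
  )
  expect_equal(fit$Nm, unname(coef(lm_fit)["Nm"]), tolerance = 1e-4)
})

test_that("a flat observed-frequency profile is flagged uninformative", {
  p <- seq(0.001, 0.01, length.out = 20)
  s <- tibble::tibble(taxon_id = as.character(1:20), total_count = 1,
                      mean_rel_abund = p, occurrence = 6,
                      occurrence_freq = 0.5)
  attr(s, "n_samples") <- 12
  fit <- fit_ncm(s, N = 3000)
  expect_true(fit$uninformative)
  expect_lte(fit$r_squared, 0)
})

test_that("Wilson intervals match the closed formula, symmetry and boundaries", {
  # boundary exactness
  expect_equal(wilson_interval(0, 12)$lower, 0)
  expect_equal(wilson_interval(1, 12)$upper, 1)
  # symmetry about one half
  w <- wilson_interval(0.5, 12, alpha = 0.05)
  expect_equal(w$upper - 0.5, 0.5 - w$lower, tolerance = 1e-12)
  # direct formula evaluation on a (p, n) grid
  z <- qnorm(0.975)
  for (n in c(5, 12, 100)) {
    p_hat <- seq(0, 1, by = 0.125)
    w <- wilson_interval(p_hat, n)
    center <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    expect_equal(w$lower, pmax(0, center - half), tolerance = 1e-12)
    expect_equal(w$upper, pmin(1, center + half), tolerance = 1e-12)
  }
  expect_error(wilson_interval(1.2, 10), "0, 1")
})

test_that("envelope width shrinks as the sample count grows", {
  tbl <- simulate_neutral(n_taxa = 300, Nm = 300, depth = 2000,
                          n_samples = 12, seed = 62)
  fit <- fit_ncm(summarize_taxa(tbl), N = 2000)
  widths <- vapply(c(6, 12, 24, 96), function(n) {
    e <- ncm_envelope(fit, n_samples = n)
    mean(e$upper - e$lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(ncm_envelope(fit, n_samples = 0), "at least 1")
})

test_that("envelope positions use closed intervals and brute-force tallies agree", {
  tbl <- simulate_neutral(n_taxa = 300, Nm = 300, depth = 2000,
                          n_samples = 12, seed = 63)
  s <- summarize_taxa(tbl)
  fit <- fit_ncm(s, N = 2000)
  tx <- fit$taxa
  # closed-interval convention
  expect_true(all(tx$position[tx$obs_freq >= tx$lower & tx$obs_freq <= tx$upper] == "within"))
  expect_true(all(tx$obs_freq[tx$position == "above"] > tx$upper[tx$position == "above"]))
  expect_true(all(tx$obs_freq[tx$position == "below"] < tx$lower[tx$position == "below"]))
  pe <- partition_by_envelope(fit)
  oracle <- table(tx$position)
  expect_equal(pe$n[match(names(oracle), pe$position)], as.vector(oracle))
  expect_equal(sum(pe$fraction), 1, tolerance = 1e-12)
  # per-cohort breakdown fractions sum to 1 within cohorts
  part <- classify_taxa(s)
  pec <- partition_by_envelope(fit, part)
  sums <- pec |>
    dplyr::group_by(cohort) |>
    dplyr::summarise(f = sum(fraction), r = sum(rel_abund), .groups = "drop")
  expect_true(all(abs(sums$f - 1) < 1e-9))
  expect_true(all(abs(sums$r - 1) < 1e-9))
})

test_that("a perfectly fitting dataset is 100% within the envelope", {
  p <- exp(seq(log(1e-3), log(0.03), length.out = 50))
  d <- 1 - 2^(-1 / 3000)
  obs <- ncm_predict(p, Nm = 300, d = d)
  s <- tibble::tibble(taxon_id = as.character(1:50), total_count = 1,
                      mean_rel_abund = p, occurrence = round(obs * 12),
                      occurrence_freq = obs)
  attr(s, "n_samples") <- 12
  fit <- fit_ncm(s, N = 3000)
  expect_true(all(fit$taxa$position == "within"))
  nc <- neutrality_curve(fit, n_bins = 5)
  expect_true(all(nc$bins$neutrality_fraction == 1))
})

test_that("neutrality curves bin on log abundance and report cohort fractions", {
  tbl <- simulate_neutral(n_taxa = 400, Nm = 300, depth = 3000,
                          n_samples = 12, seed = 64)
  s <- summarize_taxa(tbl)
  fit <- fit_ncm(s, N = 3000)
  part <- classify_taxa(s)
  nc <- neutrality_curve(fit, part, n_bins = 8)
  expect_true(all(nc$bins$neutrality_fraction >= 0 & nc$bins$neutrality_fraction <= 1))
  expect_true(all(nc$bins$n >= 1))  # empty bins absent, not zero
  expect_equal(sum(nc$bins$n), nrow(fit$taxa))
  expect_true(all(c("fraction_within", "rel_abund_within") %in% names(nc$cohorts)))
})

test_that("the binomial model matches its closed form and has no free parameter", {
  N <- 2988; d <- 1 / N
  p <- c(0.001, 0.01, 0.2)
  s <- tibble::tibble(taxon_id = as.character(1:13), total_count = 1,
                      mean_rel_abund = c(p, seq(0.0001, 0.001, length.out = 10)),
                      occurrence = 6, occurrence_freq = 0.5)
  fit <- fit_binomial_model(s, N = N, d = d)
  expect_equal(fit$taxa$pred_freq[1:3], 1 - (1 - p)^N, tolerance = 1e-12)
  # degenerate probabilities map to the endpoints
  expect_equal(1 - pbinom(0, N, 0), 0)
  expect_equal(1 - pbinom(0, N, 1), 1)
})
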