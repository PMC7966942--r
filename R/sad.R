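# Species-abundance-distribution analysis on Preston octaves.

#' Preston octave histogram of species abundances
#'
#' Bins species (taxa) by power-of-2 abundance classes: octave k holds the
#' species whose pooled abundance falls in `[2^k, 2^(k+1))` (half-open, no
#' boundary splitting). Interior empty octaves are kept so the bins cover
#' `[1, max abundance]`; trailing empty octaves are omitted.
#'
#' @param abundances Positive integer read counts, one per species.
#' @return A tibble of class `"octave_histogram"` with columns `octave`,
#'   `lower`, `upper` (abundance range, upper exclusive) and `n_species`;
#'   total species `S` and total individuals `N` are attached as
#'   attributes.
#' @export
octave_histogram <- function(abundances) {
  if (length(abundances) == 0) rlang::abort("`abundances` is empty.")
  if (any(abundances < 1 | abundances != floor(abundances))) {
    rlang::abort("All abundances must be positive integers.")
  }
  k <- floor(log2(abundances))
  max_k <- max(k)
  counts <- tabulate(k + 1, nbins = max_k + 1)
  out <- tibble::tibble(
    octave = 0:max_k,
    lower = 2^(0:max_k),
    upper = 2^(1:(max_k + 1)),
    n_species = counts
  )
  attr(out, "S") <- length(abundances)
  attr(out, "N") <- sum(abundances)
  class(out) <- c("octave_histogram", class(out))
  out
}

#' Chi-squared goodness of fit with tail pooling
#'
#' Pools adjacent low-expectation bins (starting from the tails, where SAD
#' expectations decay) until every pooled expectation reaches
#' `min_expected`, then computes `chi2 = sum((O - E)^2 / E)` with
#' `dof = pooled bins - 1 - n_fitted_params` (floored at 1) and the
#' upper-tail chi-squared p-value.
#'
#' @param observed,expected Equal-length vectors of observed counts and
#'   positive expected counts.
#' @param n_fitted_params Number of parameters estimated from the data.
#' @param min_expected Pooling threshold on expected counts: 1 by default
#'   (permissive), settable to the textbook 5. Pooling never reduces the
#'   histogram below 2 bins, so a 2-bin result may keep expectations
#'   below the threshold.
#' @return A list with `chi2`, `dof`, `p_value`, and the pooled
#'   `observed`/`expected` vectors.
#' @export
gof_chisq <- function(observed, expected, n_fitted_params = 0, min_expected = 1) {
  if (length(observed) != length(expected)) {
    rlang::abort("`observed` and `expected` must have equal length.")
  }
  if (any(expected <= 0)) rlang::abort("All expected counts must be positive.")
  obs <- as.numeric(observed)
  exp <- as.numeric(expected)
  # merge the minimum-expectation bin into its smaller neighbour until all
  # expectations clear the threshold
  while (min(exp) < min_expected && length(exp) > 2) {
    i <- which.min(exp)
    j <- if (i == 1) 2
    else if (i == length(exp)) i - 1
    else if (exp[i - 1] <= exp[i + 1]) i - 1
    else i + 1
    lo <- min(i, j); hi <- max(i, j)
    obs[lo] <- obs[lo] + obs[hi]
    exp[lo] <- exp[lo] + exp[hi]
    obs <- obs[-hi]
    exp <- exp[-hi]
  }
  if (length(exp) < 2) {
    rlang::abort("Pooling collapsed the histogram below 2 usable bins.")
  }
  chi2 <- sum((obs - exp)^2 / exp)
  dof <- max(1L, length(exp) - 1L - as.integer(n_fitted_params))
  list(
    chi2 = chi2,
    dof = dof,
    p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
    observed = obs,
    expected = exp
  )
}

# Fisher's alpha from (S, N): the unique root of S = alpha * log(1 + N/alpha).
fisher_alpha <- function(S, N) {
  if (S < 2 || N <= S) rlang::abort("Log-series fit needs S >= 2 and N > S.")
  f <- function(log_a) {
    a <- exp(log_a)
    a * log1p(N / a) - S
  }
  lo <- log(1e-8)
  hi <- log(1e12)
  if (f(hi) < 0) rlang::abort("No Fisher alpha root in bracket (S too close to N).")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  exp(root$root)
}

# Expected log-series species counts per octave of `hist`:
# E_k = sum over n in [2^k, 2^(k+1)) of alpha * x^n / n.
logseries_octave_expected <- function(hist, alpha, x) {
  n_max <- max(hist$upper) - 1
  n <- seq_len(n_max)
  term <- alpha * x^n / n
  cum <- cumsum(term)
  vapply(seq_len(nrow(hist)), function(i) {
    hi <- min(hist$upper[i] - 1, n_max)
    lo <- hist$lower[i]
    cum[hi] - if (lo > 1) cum[lo - 1] else 0
  }, numeric(1))
}

#' Fit a log-series species abundance distribution
#'
#' Estimates Fisher's alpha from the species and individual totals (S, N)
#' by solving `S = alpha * log(1 + N / alpha)` (bracketed root finding),
#' sets the series parameter `x = N / (N + alpha)`, derives the expected
#' species count per octave by direct summation of `alpha * x^n / n`, and
#' scores the fit against the observed octave counts with [gof_chisq()]
#' (one fitted parameter). This is the classic (S, N)-based log-series
#' fit; the octave expectations are derived afterwards rather than
#' least-squares-fitted to the histogram.
#'
#' @param hist An [octave_histogram()].
#' @param min_expected Pooling threshold passed to [gof_chisq()].
#' @return An object of class `c("logseries_fit", "sad_fit")`: a list with
#'   `alpha`, `x`, `S`, `N`, `expected` (per octave), `chi2`, `dof`,
#'   `p_value`.
#' @export
fit_logseries <- function(hist, min_expected = 1) {
  stopifnot(inherits(hist, "octave_histogram"))
  S <- attr(hist, "S")
  N <- attr(hist, "N")
  alpha <- fisher_alpha(S, N)
  x <- N / (N + alpha)
  expected <- logseries_octave_expected(hist, alpha, x)
  gof <- gof_chisq(hist$n_species, expected, n_fitted_params = 1,
                   min_expected = min_expected)
  structure(
    list(
      model = "logseries", alpha = alpha, x = x, S = S, N = N,
      octave = hist$octave, observed = hist$n_species, expected = expected,
      chi2 = gof$chi2, dof = gof$dof, p_value = gof$p_value
    ),
    class = c("logseries_fit", "sad_fit")
  )
}

#' Fit a log-normal (Preston) species abundance curve
#'
#' Least-squares fit of the Preston Gaussian
#' `E_k = S0 * exp(-a^2 (k - R0)^2)` to the octave species counts, started
#' from moment estimates (`R0` the count-weighted mean octave, `a` from
#' the weighted octave spread, `S0` the modal count) and refined by
#' Nelder-Mead with restarts. The veil line is not modelled. Goodness of
#' fit via [gof_chisq()] with 3 fitted parameters.
#'
#' @param hist An [octave_histogram()] with at least 3 nonempty octaves.
#' @param min_expected Pooling threshold passed to [gof_chisq()].
#' @return An object of class `c("lognormal_fit", "sad_fit")`: a list with
#'   `S0`, `a`, `R0`, `expected`, `chi2`, `dof`, `p_value`, `converged`.
#' @export
fit_lognormal <- function(hist, min_expected = 1) {
  stopifnot(inherits(hist, "octave_histogram"))
  k <- hist$octave
  y <- hist$n_species
  if (sum(y > 0) < 3) rlang::abort("Log-normal fit needs >= 3 nonempty octaves.")
  w <- y / sum(y)
  R0_start <- sum(w * k)
  spread <- sqrt(max(sum(w * (k - R0_start)^2), 0.25))
  start <- c(S0 = max(y), a = 1 / (spread * sqrt(2)), R0 = R0_start)
  sse <- function(par) {
    if (par[1] <= 0 || par[2] <= 0) return(Inf)
    sum((y - par[1] * exp(-par[2]^2 * (k - par[3])^2))^2)
  }
  best <- NULL
  for (fac in c(1, 0.5, 2)) {
    st <- start * c(fac, fac, 1)
    opt <- stats::optim(st, sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    # polish with BFGS from the simplex optimum
    opt2 <- tryCatch(
      stats::optim(opt$par, sse, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) opt
    )
    cand <- if (opt2$value <= opt$value) opt2 else opt
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (!is.finite(best$value)) rlang::abort("Log-normal fit failed to converge.")
  par <- best$par
  expected <- par[1] * exp(-par[2]^2 * (k - par[3])^2)
  gof <- gof_chisq(y, pmax(expected, 1e-12), n_fitted_params = 3,
                   min_expected = min_expected)
  structure(
    list(
      model = "lognormal",
      S0 = unname(par[1]), a = unname(par[2]), R0 = unname(par[3]),
      octave = k, observed = y, expected = unname(expected),
      chi2 = gof$chi2, dof = gof$dof, p_value = gof$p_value,
      converged = best$convergence == 0
    ),
    class = c("lognormal_fit", "sad_fit")
  )
}

#' @export
print.sad_fit <- function(x, ...) {
  if (x$model == "logseries") {
    cat(sprintf("Log-series SAD fit: alpha = %.4g, x = %.6f (S = %.0f, N = %.0f)\n",
                x$alpha, x$x, x$S, x$N))
  } else {
    cat(sprintf("Log-normal SAD fit: S0 = %.4g, a = %.4g, R0 = %.4g\n",
                x$S0, x$a, x$R0))
  }
  cat(sprintf("  chi2 = %.4g on %d dof, p = %.3g\n", x$chi2, x$dof, x$p_value))
  invisible(x)
}

# Fit both SAD models to one cohort's pooled abundances (detected taxa
# only -- all-zero rows can survive rarefaction); NULL components where a
# model is not fittable.
fit_both_sads <- function(abundances, min_expected = 1) {
  abundances <- abundances[abundances > 0]
  hist <- tryCatch(octave_histogram(abundances), error = function(e) NULL)
  if (is.null(hist)) return(list(logseries = NULL, lognormal = NULL))
  list(
    logseries = tryCatch(fit_logseries(hist, min_expected), error = function(e) NULL),
    lognormal = tryCatch(fit_lognormal(hist, min_expected), error = function(e) NULL)
  )
}

#' Sensitivity scan of SAD model preference over a threshold grid
#'
#' For every (abundance, occurrence) threshold combination, re-classifies
#' the taxa, builds the pooled-abundance octave histogram of each analysed
#' cohort (transient-rare and common), fits both SAD models, and records
#' which model attains the lower chi-squared. Combinations yielding an
#' empty or unfittable cohort produce `NA` fit columns, not errors.
#'
#' @param table OTU tibble.
#' @param grid A [threshold_grid()] tibble.
#' @param persistent_min_occ Persistent-rare bound used during
#'   classification (default 8; raised to the occurrence threshold when
#'   the grid exceeds it, keeping thresholds valid).
#' @param min_expected Pooling threshold for [gof_chisq()].
#' @return A long tibble with one row per (combination, cohort, model):
#'   `abund_threshold`, `occ_threshold`, `cohort`, `n_taxa`, `model`,
#'   `chi2`, `dof`, `p_value`, `preferred` (TRUE for the lower-chi2 model
#'   of that cohort/combination).
#' @export
sad_grid_scan <- function(table, grid = threshold_grid(),
                          persistent_min_occ = 8, min_expected = 1) {
  validate_otu(table)
  summaries <- summarize_taxa(table)
  purrr::pmap_dfr(grid, function(abund_threshold, occ_threshold) {
    thr <- cohort_thresholds(
      rare_max_rel_abund = abund_threshold,
      transient_max_occ = occ_threshold,
      persistent_min_occ = max(persistent_min_occ, occ_threshold)
    )
    part <- classify_taxa(summaries, thr)
    purrr::map_dfr(c("transient_rare", "common"), function(ch) {
      taxa <- part$taxon_id[part$cohort == ch]
      ab <- summaries$total_count[summaries$taxon_id %in% taxa]
      fits <- if (length(ab) > 0) fit_both_sads(ab, min_expected)
              else list(logseries = NULL, lognormal = NULL)
      chi <- c(
        logseries = if (is.null(fits$logseries)) NA_real_ else fits$logseries$chi2,
        lognormal = if (is.null(fits$lognormal)) NA_real_ else fits$lognormal$chi2
      )
      pref <- if (all(is.na(chi))) c(FALSE, FALSE) else chi == min(chi, na.rm = TRUE)
      purrr::map_dfr(c("logseries", "lognormal"), function(mod) {
        f <- fits[[mod]]
        tibble::tibble(
          abund_threshold = abund_threshold,
          occ_threshold = occ_threshold,
          cohort = ch,
          n_taxa = length(ab),
          model = mod,
          chi2 = if (is.null(f)) NA_real_ else f$chi2,
          dof = if (is.null(f)) NA_integer_ else f$dof,
          p_value = if (is.null(f)) NA_real_ else f$p_value,
          preferred = isTRUE(unname(pref[mod]))
        )
      })
    })
  })
}
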