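# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ncm_tidiers
#' @title Tidy and glance at a Sloan neutral-model fit
#' @description `tidy()` returns the per-taxon table (abundance, observed
#'   and predicted frequency, envelope, position); `glance()` a one-row
#'   model summary.
#' @param x An `"ncm_fit"`.
#' @param ... Unused.
#' @method tidy ncm_fit
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @rdname ncm_tidiers
#' @method glance ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(
    Nm = x$Nm, m = x$m, N = x$N, d = x$d,
    r_squared = x$r_squared,
    n_taxa = nrow(x$taxa), n_excluded = x$n_excluded,
    n_samples = x$n_samples, envelope_alpha = x$alpha,
    converged = x$converged
  )
}

#' @rdname sad_tidiers
#' @title Tidy and glance at species-abundance-distribution fits
#' @description `tidy()` returns observed and expected species counts per
#'   octave; `glance()` the parameters and goodness of fit.
#' @param x A `"logseries_fit"` or `"lognormal_fit"`.
#' @param ... Unused.
#' @method tidy sad_fit
#' @export
tidy.sad_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, octave = x$octave,
    observed = x$observed, expected = x$expected
  )
}

#' @rdname sad_tidiers
#' @method glance sad_fit
#' @export
glance.sad_fit <- function(x, ...) {
  base <- tibble::tibble(model = x$model, chi2 = x$chi2, dof = x$dof,
                         p_value = x$p_value)
  if (x$model == "logseries") {
    # pull the fields out first: tibble() evaluates sequentially, and the
    # column named `x` would shadow the fit object itself
    vals <- list(alpha = x$alpha, x = x$x, S = x$S, N = x$N)
    dplyr::bind_cols(base, tibble::as_tibble(vals))
  } else {
    dplyr::bind_cols(base, tibble::tibble(S0 = x$S0, a = x$a, R0 = x$R0,
                                          converged = x$converged))
  }
}

#' @rdname binomial_tidiers
#' @title Tidy and glance at the binomial occurrence model
#' @param x A `"binomial_fit"`.
#' @param ... Unused.
#' @method tidy binomial_fit
#' @export
tidy.binomial_fit <- function(x, ...) x$taxa

#' @rdname binomial_tidiers
#' @method glance binomial_fit
#' @export
glance.binomial_fit <- function(x, ...) {
  tibble::tibble(N = x$N, d = x$d, r_squared = x$r_squared,
                 n_taxa = nrow(x$taxa))
}

#' @rdname perm_tidiers
#' @title Tidy and glance at permutation-test results
#' @param x A `"perm_test"`.
#' @param ... Unused.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    permutations = x$permutations, exact = x$exact
  )
}

#' @rdname perm_tidiers
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) glance(x)

#' @rdname timedecay_tidiers
#' @title Tidy and glance at a time-decay fit
#' @description `tidy()` returns the per-pair lag/similarity table;
#'   `glance()` the slope, intercept and permutation p-value.
#' @param x A `"time_decay_fit"`.
#' @param ... Unused.
#' @method tidy time_decay_fit
#' @export
tidy.time_decay_fit <- function(x, ...) x$pairs

#' @rdname timedecay_tidiers
#' @method glance time_decay_fit
#' @export
glance.time_decay_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, p_value = x$p_value,
    n_pairs = x$n_pairs, n_dropped = x$n_dropped,
    permutations = x$permutations
  )
}

#' @rdname betanull_tidiers
#' @title Tidy and glance at a beta-null deviation result
#' @description `tidy()` returns the per-sample mean deviations;
#'   `glance()` per-cohort means and the cohort-comparison p-value.
#' @param x A `"null_deviation"`.
#' @param ... Unused.
#' @method tidy null_deviation
#' @export
tidy.null_deviation <- function(x, ...) x$samples

#' @rdname betanull_tidiers
#' @method glance null_deviation
#' @export
glance.null_deviation <- function(x, ...) {
  wide <- x$samples |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(mean_deviation = mean(.data$mean_deviation), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "mean_deviation",
                       names_prefix = "mean_deviation_")
  p <- if (!is.null(x$comparison)) {
    x$comparison$p_value[x$comparison$test == "mann_whitney"]
  } else NA_real_
  dplyr::bind_cols(wide, tibble::tibble(comparison_p_value = p,
                                        iterations = x$iterations))
}
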