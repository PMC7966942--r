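# Sloan neutral community model: occurrence frequency as a function of
# metacommunity mean relative abundance.
#
# Under neutral assembly with dispersal limitation, a taxon with
# metacommunity relative abundance p has local relative abundance
# Beta(Nm*p, Nm*(1-p)), where Nm is the product of local community size
# and immigration rate. Its chance of being detected (exceeding the
# detection limit d) in a sample is therefore 1 - pbeta(d, Nm*p, Nm*(1-p)).

#' Predicted occurrence frequency under the Sloan neutral model
#'
#' @param p Metacommunity mean relative abundance(s), strictly in (0, 1).
#' @param Nm Product of community size and immigration rate (> 0).
#' @param N Reads per sample (used only for the default detection limit).
#' @param d Detection limit as a relative abundance. Defaults to
#'   `1 - 2^(-1/N)` (approximately `ln(2)/N`), the abundance at which a
#'   depth-`N` sample detects a taxon with probability one half -- the
#'   hard threshold matched to real count-based detection; set `d = 1/N`
#'   for the one-read convention.
#' @return Predicted detection frequency in \[0, 1\], increasing in `p`.
#' @export
ncm_predict <- function(p, Nm, N = NULL, d = if (!is.null(N)) 1 - 2^(-1 / N) else NULL) {
  if (is.null(d)) rlang::abort("Provide `d`, or `N` to use the default detection limit.")
  if (Nm <= 0) rlang::abort("`Nm` must be positive.")
  if (d <= 0 || d >= 1) rlang::abort("`d` must lie strictly between 0 and 1.")
  if (any(p <= 0 | p >= 1)) {
    rlang::abort("`p` must lie strictly in (0, 1); the beta is degenerate at 0 and 1.")
  }
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

# Sum of squared residuals of observed frequencies against the model at a
# given Nm.
ncm_sse <- function(log_nm, p, obs, d) {
  pred <- stats::pbeta(d, exp(log_nm) * p, exp(log_nm) * (1 - p), lower.tail = FALSE)
  sum((obs - pred)^2)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the single free parameter Nm by nonlinear least squares of
#' the observed occurrence frequencies on [ncm_predict()], searching
#' log(Nm) over \[1e-2, 1e7\] (deterministic coarse log-grid followed by
#' golden-section refinement, so the fit needs no starting value and is
#' reproducible). The fit quality is the generalized R-squared
#' `1 - SS_err / SS_total` with `SS_total` taken about the mean observed
#' frequency. Taxa with mean relative abundance 0 or 1 are excluded from
#' fitting and counted in `n_excluded`. The 95% Wilson score envelope
#' around the predictions and the above/within/below position of every
#' fitted taxon are computed immediately (see [ncm_envelope()]).
#'
#' @param summaries Per-taxon summaries from [summarize_taxa()].
#' @param N Reads per sample (the rarefaction depth). For tables with
#'   unequal depths pass the mean depth.
#' @param d Detection limit (default `1 - 2^(-1/N)`, the depth-matched
#'   threshold; see [ncm_predict()]).
#' @param alpha Significance level of the confidence envelope (default
#'   0.05).
#' @param n_samples Trial count for the Wilson envelope; defaults to the
#'   summaries' sample count (the occurrence denominator).
#' @return An object of class `"ncm_fit"`: a list with `Nm`, `m`
#'   (`Nm / N`), `N`, `d`, `r_squared`, `converged`, `n_samples`,
#'   `alpha`, `n_excluded`, and `taxa`, a tibble with per-taxon `taxon_id`,
#'   `p`, `obs_freq`, `pred_freq`, `lower`, `upper`, `position`.
#' @seealso [fit_binomial_model()] for the dispersal-unlimited comparison
#'   model, [partition_by_envelope()], [neutrality_curve()].
#' @export
fit_ncm <- function(summaries, N, d = 1 - 2^(-1 / N), alpha = 0.05,
                    n_samples = attr(summaries, "n_samples")) {
  if (is.null(n_samples)) {
    rlang::abort("`n_samples` not available; pass it explicitly or use summarize_taxa() output.")
  }
  ok <- summaries$mean_rel_abund > 0 & summaries$mean_rel_abund < 1
  n_excluded <- sum(!ok)
  dat <- summaries[ok, ]
  if (nrow(dat) < 10) rlang::abort("Need at least 10 taxa with 0 < p < 1 to fit.")
  p <- dat$mean_rel_abund
  obs <- dat$occurrence_freq
  # deterministic global search on log(Nm), then golden-section refinement
  lg <- seq(log(1e-2), log(1e7), length.out = 80)
  sse <- vapply(lg, ncm_sse, numeric(1), p = p, obs = obs, d = d)
  i <- which.min(sse)
  bracket <- c(lg[max(1, i - 1)], lg[min(length(lg), i + 1)])
  opt <- stats::optimize(ncm_sse, bracket, p = p, obs = obs, d = d, tol = 1e-10)
  Nm <- exp(opt$minimum)
  pred <- ncm_predict(p, Nm, d = d)
  ss_err <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_err / ss_tot else -Inf
  env <- wilson_interval(pred, n_samples, alpha)
  fit <- structure(
    list(
      Nm = Nm, m = Nm / N, N = N, d = d,
      r_squared = r2,
      converged = is.finite(Nm) && opt$objective <= min(sse),
      uninformative = ss_tot <= 0,
      n_samples = n_samples, alpha = alpha, n_excluded = n_excluded,
      taxa = tibble::tibble(
        taxon_id = dat$taxon_id,
        p = p,
        obs_freq = obs,
        pred_freq = pred,
        lower = env$lower,
        upper = env$upper,
        position = dplyr::case_when(
          obs > env$upper ~ "above",
          obs < env$lower ~ "below",
          .default = "within"
        )
      )
    ),
    class = "ncm_fit"
  )
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan neutral community model fit\n  Nm = %.4g (m = %.4g), N = %.0f, d = %.3g\n  generalized R2 = %.4f; %d taxa fitted (%d excluded at p in {0,1})\n",
    x$Nm, x$m, x$N, x$d, x$r_squared, nrow(x$taxa), x$n_excluded
  ))
  tab <- table(x$taxa$position)
  cat(sprintf(
    "  envelope (%d%%): %s\n", round(100 * (1 - x$alpha)),
    paste(names(tab), tab, sep = " = ", collapse = ", ")
  ))
  invisible(x)
}

#' Wilson confidence envelope around neutral-model predictions
#'
#' Recomputes the per-taxon confidence envelope of an [fit_ncm()] object
#' at a chosen significance level or trial count: the Wilson score
#' interval for a binomial proportion with point value the predicted
#' frequency and trial count the number of samples (the denominator of
#' the occurrence frequency).
#'
#' @param fit An `"ncm_fit"`.
#' @param alpha Significance level.
#' @param n_samples Trial count.
#' @return Tibble with `taxon_id`, `lower`, `upper`.
#' @export
ncm_envelope <- function(fit, alpha = fit$alpha, n_samples = fit$n_samples) {
  stopifnot(inherits(fit, "ncm_fit"))
  if (n_samples < 1) rlang::abort("`n_samples` must be at least 1.")
  env <- wilson_interval(fit$taxa$pred_freq, n_samples, alpha)
  tibble::tibble(taxon_id = fit$taxa$taxon_id, lower = env$lower, upper = env$upper)
}

#' Partition taxa by their position relative to the envelope
#'
#' Taxa whose observed frequency lies inside the closed
#' \[lower, upper\] envelope are "within" (boundary counts as within);
#' the rest are "above" or "below". Counts and summed mean relative
#' abundance are reported per position, optionally per cohort.
#'
#' @param fit An `"ncm_fit"`.
#' @param partition Optional cohort partition from [classify_taxa()]; when
#'   given, tallies are additionally broken down by cohort.
#' @return A tibble with columns (`cohort`,) `position`, `n`, `fraction`
#'   (of that (cohort's) fitted taxa), and `rel_abund` (summed mean
#'   relative abundance of the taxa at that position divided by the
#'   (cohort's) total, i.e. an abundance-weighted fraction).
#' @export
partition_by_envelope <- function(fit, partition = NULL) {
  stopifnot(inherits(fit, "ncm_fit"))
  taxa <- fit$taxa
  if (!is.null(partition)) {
    taxa <- dplyr::inner_join(taxa, partition, by = "taxon_id")
    grp <- c("cohort", "position")
  } else {
    grp <- "position"
  }
  taxa |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = dplyr::n(), p_mass = sum(.data$p), .groups = "drop_last") |>
    dplyr::mutate(
      fraction = .data$n / sum(.data$n),
      rel_abund = .data$p_mass / sum(.data$p_mass)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"p_mass")
}

#' Neutrality fraction as a function of abundance
#'
#' Bins the fitted taxa into log-spaced mean-relative-abundance bins and
#' reports the fraction inside the confidence envelope per bin (the
#' "neutrality fraction"), plus per-cohort neutrality fractions weighted
#' two ways (by OTU count and by relative abundance).
#'
#' @param fit An `"ncm_fit"`.
#' @param partition Optional cohort partition for the per-cohort table.
#' @param n_bins Number of log-spaced abundance bins (>= 2).
#' @return A list of class `"neutrality_curve"` with `bins` (tibble:
#'   `bin`, `p_lo`, `p_hi`, `n`, `neutrality_fraction`; empty bins are
#'   absent, not zero) and `cohorts` (tibble from
#'   [partition_by_envelope()] filtered to position "within", or `NULL`
#'   without a partition).
#' @export
neutrality_curve <- function(fit, partition = NULL, n_bins = 10) {
  stopifnot(inherits(fit, "ncm_fit"), n_bins >= 2)
  p <- fit$taxa$p
  brk <- exp(seq(log(min(p)), log(max(p)), length.out = n_bins + 1))
  brk[1] <- brk[1] * (1 - 1e-10)
  brk[n_bins + 1] <- brk[n_bins + 1] * (1 + 1e-10)
  bin <- cut(p, brk, labels = FALSE)
  bins <- tibble::tibble(bin = bin, within = fit$taxa$position == "within", p = p) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      p_lo = min(.data$p), p_hi = max(.data$p),
      n = dplyr::n(),
      neutrality_fraction = mean(.data$within),
      .groups = "drop"
    )
  cohorts <- if (!is.null(partition)) {
    partition_by_envelope(fit, partition) |>
      dplyr::filter(.data$position == "within") |>
      dplyr::select("cohort", n_within = "n", fraction_within = "fraction",
                    rel_abund_within = "rel_abund")
  }
  structure(list(bins = bins, cohorts = cohorts), class = "neutrality_curve")
}

#' Fit the binomial (no-drift) occurrence model
#'
#' The dispersal-unlimited comparison model: if local communities were
#' random samples of the metacommunity with no drift, a taxon with
#' relative abundance p would be detected with probability
#' `1 - pbinom(ceiling(N*d) - 1, N, p)` (with `d = 1/N` this is
#' `1 - (1 - p)^N`). The model has no free parameter; its generalized
#' R-squared is computed exactly as in [fit_ncm()] so the two are
#' directly comparable.
#'
#' @inheritParams fit_ncm
#' @return An object of class `"binomial_fit"`: list with `N`, `d`,
#'   `r_squared` and per-taxon `taxa` tibble (`taxon_id`, `p`,
#'   `obs_freq`, `pred_freq`).
#' @export
fit_binomial_model <- function(summaries, N, d = 1 - 2^(-1 / N)) {
  ok <- summaries$mean_rel_abund > 0 & summaries$mean_rel_abund < 1
  dat <- summaries[ok, ]
  if (nrow(dat) < 10) rlang::abort("Need at least 10 taxa with 0 < p < 1 to fit.")
  p <- dat$mean_rel_abund
  obs <- dat$occurrence_freq
  pred <- stats::pbinom(ceiling(N * d) - 1, size = N, prob = p, lower.tail = FALSE)
  ss_err <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  structure(
    list(
      N = N, d = d,
      r_squared = if (ss_tot > 0) 1 - ss_err / ss_tot else -Inf,
      taxa = tibble::tibble(taxon_id = dat$taxon_id, p = p,
                            obs_freq = obs, pred_freq = pred)
    ),
    class = "binomial_fit"
  )
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial (no-drift) occurrence model: N = %.0f, d = %.3g, generalized R2 = %.4f\n",
    x$N, x$d, x$r_squared
  ))
  invisible(x)
}
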