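# Time-decay of community similarity: log-log regression of pairwise
# similarity on time lag.

#' Fit the time-decay relationship
#'
#' Computes, for every pair of dated samples, the Bray-Curtis similarity
#' `1 - d` and the time lag in days, then fits
#' `log10(similarity) ~ log10(lag)` by ordinary least squares. The slope
#' w summarizes how fast the community diverges over time. Because the
#' pairwise points are not independent, significance comes from a
#' Mantel-style permutation: the date assignment is shuffled, the slope
#' refit, and `p = (|slope_perm| >= |slope| exceedances + 1) /
#' (permutations + 1)`. Pairs with zero similarity or zero lag are
#' dropped with a warning (log undefined).
#'
#' @param table OTU tibble.
#' @param dates Metadata tibble (`sample_id`, `date`) covering every
#'   sample; at least 4 distinct dates.
#' @param permutations Number of date permutations (default 999).
#' @param seed Optional integer seed.
#' @param relative Compute Bray-Curtis on per-sample relative abundances
#'   (default `TRUE`).
#' @return An object of class `"time_decay_fit"`: `slope`, `intercept`,
#'   `p_value`, `n_pairs` (used in the fit), `n_dropped`, and `pairs`
#'   (tibble: `sample_a`, `sample_b`, `lag_days`, `similarity`, `used`).
#' @export
time_decay <- function(table, dates, permutations = 999, seed = NULL,
                       relative = TRUE) {
  validate_otu(table)
  ids <- sample_ids(table)
  if (is.null(dates) || !all(ids %in% dates$sample_id)) {
    rlang::abort("`dates` must provide a date for every sample.")
  }
  date_vec <- dates$date[match(ids, dates$sample_id)]
  if (length(unique(date_vec)) < 4) rlang::abort("Need at least 4 distinct dates.")
  sim <- 1 - as.matrix(bray_curtis(table, relative = relative))
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  slope_of <- function(dv) {
    lag <- abs(as.numeric(dv[idx[, 2]] - dv[idx[, 1]]))
    s <- sim[idx]
    use <- lag > 0 & s > 0
    if (sum(use) < 3) return(NULL)
    fit <- stats::lm(log10(s[use]) ~ log10(lag[use]))
    list(coef = stats::coef(fit), use = use, lag = lag)
  }
  obs <- slope_of(date_vec)
  if (is.null(obs)) rlang::abort("Fewer than 3 usable pairs (nonzero lag and similarity).")
  lag <- obs$lag
  use <- obs$use
  if (any(!use)) {
    rlang::warn(paste0("Dropping ", sum(!use),
                       " pair(s) with zero lag or zero similarity from the log-log fit."))
  }
  slope <- unname(obs$coef[2])
  intercept <- unname(obs$coef[1])
  p <- NA_real_
  if (permutations > 0) {
    exceed <- with_seed_or_current(seed, {
      sum(vapply(seq_len(permutations), function(i) {
        r <- slope_of(sample(date_vec))
        !is.null(r) && abs(unname(r$coef[2])) >= abs(slope) - 1e-12
      }, logical(1)))
    })
    p <- (exceed + 1) / (permutations + 1)
  }
  structure(
    list(
      slope = slope, intercept = intercept, p_value = p,
      n_pairs = sum(use), n_dropped = sum(!use),
      permutations = permutations, seed = seed,
      pairs = tibble::tibble(
        sample_a = ids[idx[, 1]],
        sample_b = ids[idx[, 2]],
        lag_days = lag,
        similarity = sim[idx],
        used = use
      )
    ),
    class = "time_decay_fit"
  )
}

#' @export
print.time_decay_fit <- function(x, ...) {
  cat(sprintf(
    "Time-decay fit: log10(similarity) = %.4g %+.4g * log10(lag days)\n  %d pairs (%d dropped), permutation p = %.4g\n",
    x$intercept, x$slope, x$n_pairs, x$n_dropped, x$p_value
  ))
  invisible(x)
}
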