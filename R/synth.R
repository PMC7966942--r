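# Synthetic community generator: known assembly processes for testing
# every analysis stage without sequence data.
#
# The neutral generator is the exact generative dual of the fitted Sloan
# model: local relative abundances are Dirichlet(Nm * p), so each taxon's
# marginal is Beta(Nm*p_i, Nm*(1-p_i)), and counts are multinomial at the
# target depth. Parameter recovery by fit_ncm() is therefore a sharp test
# of the estimator, not an approximation.

# One draw from the log-series distribution P(n) = x^n / (n * L),
# L = -log(1 - x), via Kemp's exact two-uniform algorithm.
rlogseries <- function(n, x) {
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  q <- 1 - (1 - x)^u1
  k <- floor(1 + log(u2) / log(q))
  # guard numerical overflow at u2 -> 0 or q -> 1
  k[!is.finite(k) | k < 1] <- 1
  as.integer(pmin(k, .Machine$integer.max))
}

#' Simulate a log-series metacommunity
#'
#' Draws `n_taxa` species abundances from the log-series distribution
#' and normalizes them into a relative-abundance vector. The series
#' parameter x is chosen so that Fisher's alpha and the expected species
#' count match: `n_taxa = alpha * log(1 / (1 - x))`. With the default
#' alpha = 50 this produces the many-rare-taxa regime typical of
#' activated-sludge 16S surveys.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param alpha Fisher's alpha of the metacommunity (default 50).
#' @param p Optional explicit relative-abundance vector; returned
#'   normalized, bypassing the log-series draw.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_taxa`, strictly positive, summing
#'   to 1.
#' @export
simulate_metacommunity <- function(n_taxa, alpha = 50, p = NULL, seed = NULL) {
  if (!is.null(p)) {
    if (any(p <= 0)) rlang::abort("Explicit `p` must be strictly positive.")
    return(p / sum(p))
  }
  if (n_taxa < 2) rlang::abort("Need at least 2 taxa.")
  if (alpha <= 0) rlang::abort("`alpha` must be positive.")
  if (n_taxa / alpha > 500) {
    rlang::abort("n_taxa/alpha too large: the implied log-series parameter x underflows.")
  }
  x <- 1 - exp(-n_taxa / alpha)
  ab <- with_seed_or_current(seed, rlogseries(n_taxa, x))
  ab / sum(ab)
}

# shared: draw one Dirichlet-multinomial sample given metacommunity p
dm_sample <- function(p, Nm, depth) {
  if (Nm * min(p) < 1e-300) {
    rlang::abort(paste0(
      "Nm * min(p) underflows to zero; increase Nm, reduce n_taxa, ",
      "or supply a less skewed metacommunity."
    ))
  }
  local <- rdirichlet1(Nm * p)
  as.numeric(stats::rmultinom(1, size = depth, prob = local))
}

# bimonthly dates: n dates starting start, stepping 2 calendar months
bimonthly_dates <- function(n, start = as.Date("2005-05-15")) {
  seq(start, by = "2 months", length.out = n)
}

sample_names <- function(n) sprintf("s%02d", seq_len(n))
taxon_names <- function(n) sprintf("otu%04d", seq_len(n))

#' Simulate a neutrally assembled community table
#'
#' Dispersal-limited local assembly from a shared metacommunity: per
#' sample, local relative abundances are drawn from
#' `Dirichlet(Nm * p)` and counts from a multinomial of size `depth`.
#' `Nm` is the migration-dispersal parameter the Sloan model estimates;
#' small `Nm` means strong drift/dispersal limitation.
#'
#' @param n_taxa Number of taxa.
#' @param Nm Migration parameter (> 0).
#' @param depth Reads per sample.
#' @param n_samples Number of samples (default 12, the bimonthly 2-year
#'   design).
#' @param seed Optional integer seed (bit-reproducible output).
#' @param p Optional explicit metacommunity vector; otherwise drawn by
#'   [simulate_metacommunity()] with `alpha`.
#' @param alpha Fisher's alpha for the drawn metacommunity.
#' @param dated Attach bimonthly sample dates as attribute
#'   `"sample_dates"` (tibble `sample_id`, `date`).
#' @return OTU tibble (`taxon_id` + one column per sample); the
#'   metacommunity vector is attached as attribute `"metacommunity"`.
#' @export
simulate_neutral <- function(n_taxa = 500, Nm = 300, depth = 3000,
                             n_samples = 12, seed = NULL, p = NULL,
                             alpha = 50, dated = FALSE) {
  with_seed_or_current(seed, {
    pvec <- simulate_metacommunity(n_taxa, alpha = alpha, p = p)
    m <- vapply(seq_len(n_samples), function(j) dm_sample(pvec, Nm, depth),
                numeric(n_taxa))
    m <- t(m)
    dimnames(m) <- list(sample_names(n_samples), taxon_names(n_taxa))
    out <- otu_tibble(m)
    attr(out, "metacommunity") <- stats::setNames(pvec, colnames(m))
    if (dated) {
      attr(out, "sample_dates") <- tibble::tibble(
        sample_id = rownames(m), date = bimonthly_dates(n_samples)
      )
    }
    out
  })
}

#' Simulate a niche-structured community table
#'
#' The deterministic alternative to [simulate_neutral()]: each taxon has
#' an environmental optimum and the samples sit on an environmental
#' gradient, so the expected local proportion of taxon i in sample j is
#' `p_i * exp(-(e_j - u_i)^2 / (2 sigma^2))`, renormalized per sample;
#' counts are multinomial at `depth`. Small `sigma` (narrow niches) means
#' strong environmental filtering; `sigma = Inf` recovers proportional
#' sampling of the metacommunity.
#'
#' @inheritParams simulate_neutral
#' @param sigma Shared niche breadth (> 0; may be `Inf`). Default 0.5
#'   on the unit gradient: strong environmental filtering.
#' @param env Environment value per sample (default an evenly spaced
#'   gradient over \[-1, 1\]).
#' @param optima Per-taxon optima (default drawn uniformly over the
#'   range of `env`).
#' @return OTU tibble; attributes `"metacommunity"`, `"env"`, `"optima"`.
#' @export
simulate_niche <- function(n_taxa = 500, depth = 3000, n_samples = 12,
                           sigma = 0.5, seed = NULL, p = NULL, alpha = 50,
                           env = seq(-1, 1, length.out = n_samples),
                           optima = NULL, dated = FALSE) {
  if (sigma <= 0) rlang::abort("`sigma` must be positive (possibly Inf).")
  if (length(env) != n_samples) rlang::abort("`env` must have one value per sample.")
  with_seed_or_current(seed, {
    pvec <- simulate_metacommunity(n_taxa, alpha = alpha, p = p)
    if (is.null(optima)) optima <- stats::runif(n_taxa, min(env), max(env))
    m <- vapply(seq_len(n_samples), function(j) {
      w <- if (is.finite(sigma)) exp(-(env[j] - optima)^2 / (2 * sigma^2)) else rep(1, n_taxa)
      ex <- pvec * w
      as.numeric(stats::rmultinom(1, size = depth, prob = ex / sum(ex)))
    }, numeric(n_taxa))
    m <- t(m)
    dimnames(m) <- list(sample_names(n_samples), taxon_names(n_taxa))
    out <- otu_tibble(m)
    attr(out, "metacommunity") <- pvec
    attr(out, "env") <- env
    attr(out, "optima") <- optima
    if (dated) {
      attr(out, "sample_dates") <- tibble::tibble(
        sample_id = rownames(m), date = bimonthly_dates(n_samples)
      )
    }
    out
  })
}

#' Simulate a drifting time series of communities
#'
#' The metacommunity itself drifts between sampling dates: its
#' log-abundances follow an AR(1) process
#' `l_t = rho * l_(t-1) + (1 - rho) * l_0 + innovation` with Gaussian
#' innovations, so community similarity decays with time lag (the decay
#' is steeper the closer `rho` is to 1 and the larger `innovation_sd`).
#' Each dated sample is then drawn from the current metacommunity by the
#' neutral Dirichlet-multinomial scheme, so time-decay structure and
#' neutral occurrence-abundance structure coexist. Defaults emulate the
#' bimonthly 12-sample, 2-year design.
#'
#' @inheritParams simulate_neutral
#' @param rho AR(1) drift coefficient in \[0, 1).
#' @param innovation_sd Standard deviation of the log-abundance
#'   innovations (default 0.4).
#' @param start_date First sampling date.
#' @return A list with `counts` (OTU tibble) and `dates` (tibble
#'   `sample_id`, `date`, bimonthly).
#' @export
simulate_timeseries <- function(n_taxa = 500, Nm = 300, depth = 3000,
                                n_samples = 12, rho = 0.9,
                                innovation_sd = 0.4, seed = NULL,
                                p = NULL, alpha = 50,
                                start_date = as.Date("2005-05-15")) {
  if (rho < 0 || rho >= 1) rlang::abort("`rho` must lie in [0, 1).")
  with_seed_or_current(seed, {
    p0 <- simulate_metacommunity(n_taxa, alpha = alpha, p = p)
    l0 <- log(p0)
    l <- l0
    m <- matrix(0, n_samples, n_taxa,
                dimnames = list(sample_names(n_samples), taxon_names(n_taxa)))
    for (t in seq_len(n_samples)) {
      if (t > 1) {
        l <- rho * l + (1 - rho) * l0 + stats::rnorm(n_taxa, sd = innovation_sd)
      }
      pt <- exp(l - max(l))
      pt <- pt / sum(pt)
      m[t, ] <- dm_sample(pt, Nm, depth)
    }
    list(
      counts = otu_tibble(m),
      dates = tibble::tibble(
        sample_id = rownames(m),
        date = bimonthly_dates(n_samples, start_date)
      )
    )
  })
}
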