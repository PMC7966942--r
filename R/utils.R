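# Internal helpers shared across modules.

# Columns of an OTU tibble that are not count columns.
.meta_cols <- c("taxon_id", "taxonomy")

#' Names of the sample (count) columns of an OTU tibble
#'
#' @param table An OTU tibble as returned by [read_otu_table()] or the
#'   simulators: one row per taxon, a `taxon_id` column, one integer column
#'   per sample, and an optional `taxonomy` column.
#' @return Character vector of sample ids, in column order.
#' @export
sample_ids <- function(table) {
  setdiff(names(table), .meta_cols)
}

# samples x taxa numeric matrix from an OTU tibble.
otu_matrix <- function(table) {
  ids <- sample_ids(table)
  m <- t(as.matrix(table[ids]))
  colnames(m) <- table$taxon_id
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

# OTU tibble from a taxa x nothing... (samples x taxa matrix), preserving
# optional taxonomy from a template table.
otu_tibble <- function(mat, taxonomy = NULL) {
  out <- tibble::tibble(taxon_id = colnames(mat))
  counts <- tibble::as_tibble(t(mat), .name_repair = "minimal")
  names(counts) <- rownames(mat)
  out <- dplyr::bind_cols(out, counts)
  if (!is.null(taxonomy)) out$taxonomy <- taxonomy
  out
}

# Validate the basic OtuTable invariants; returns the table invisibly.
validate_otu <- function(table, call = rlang::caller_env()) {
  if (!"taxon_id" %in% names(table)) {
    rlang::abort("OTU table must have a `taxon_id` column.", call = call)
  }
  dup_t <- table$taxon_id[duplicated(table$taxon_id)]
  if (length(dup_t) > 0) {
    rlang::abort(
      paste0("Duplicate taxon id(s): ", paste(unique(dup_t), collapse = ", ")),
      call = call
    )
  }
  ids <- sample_ids(table)
  if (length(ids) == 0) {
    rlang::abort("OTU table has no sample columns.", call = call)
  }
  for (s in ids) {
    v <- table[[s]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      rlang::abort(
        paste0("Sample `", s, "` contains negative, missing or non-integer counts."),
        call = call
      )
    }
  }
  invisible(table)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# a NULL seed uses (and advances) the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Dirichlet draw: one vector of proportions with concentration `shape`.
# Degenerate all-zero gamma draws (possible when min(shape) is tiny) are
# redrawn rather than returned as NaN.
rdirichlet1 <- function(shape) {
  repeat {
    g <- stats::rgamma(length(shape), shape = shape, rate = 1)
    s <- sum(g)
    if (s > 0 && is.finite(s)) return(g / s)
  }
}

#' Wilson score interval for a binomial proportion
#'
#' The score interval inverts the normal approximation to the binomial test
#' around the point estimate `p_hat` with `n` trials; unlike the Wald
#' interval it stays inside \[0, 1\] and has exact endpoints at
#' `p_hat = 0` (lower bound 0) and `p_hat = 1` (upper bound 1).
#'
#' @param p_hat Proportion point estimate(s) in \[0, 1\].
#' @param n Number of trials (a single positive integer).
#' @param alpha Two-sided significance level (default 0.05 for a 95%
#'   interval).
#' @return A tibble with columns `lower` and `upper`, one row per element
#'   of `p_hat`.
#' @export
wilson_interval <- function(p_hat, n, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  if (any(p_hat < 0 | p_hat > 1)) {
    rlang::abort("`p_hat` must lie in [0, 1].")
  }
  z <- stats::qnorm(1 - alpha / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    lower = pmax(0, center - half),
    upper = pmin(1, center + half)
  )
}

# (exceedances + 1) / (permutations + 1) p-value rule.
perm_pvalue <- function(perm_stats, observed) {
  (sum(perm_stats >= observed - 1e-12) + 1) / (length(perm_stats) + 1)
}

# All permutations of seq_len(n) as an n! x n integer matrix (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
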