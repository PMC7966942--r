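# Abundance-based beta-null deviation: how far observed beta-diversity
# sits from what ecologically equivalent taxa would produce.

#' Draw one null community table
#'
#' For every sample, redraws exactly the observed number of reads with
#' replacement from the regional pool, with probabilities proportional to
#' the pooled (table-wide) taxon totals — the abundance-based null in
#' which taxa are ecologically equivalent and samples differ only by
#' multinomial sampling. Sample totals and the taxon identity set are
#' conserved exactly.
#'
#' @param table OTU tibble.
#' @param seed Optional integer seed; the draw is deterministic given the
#'   seed.
#' @return OTU tibble of the same shape with randomized counts.
#' @export
null_community <- function(table, seed = NULL) {
  validate_otu(table)
  m <- otu_matrix(table)
  pool <- colSums(m)
  if (sum(pool) == 0) rlang::abort("All-zero table: no reads to redistribute.")
  prob <- pool / sum(pool)
  totals <- rowSums(m)
  raw <- with_seed_or_current(seed, {
    vapply(totals, function(tt) {
      if (tt == 0) numeric(length(prob))
      else as.numeric(stats::rmultinom(1, size = tt, prob = prob))
    }, numeric(length(prob)))
  })
  null <- matrix(raw, nrow = nrow(m), ncol = ncol(m), byrow = TRUE,
                 dimnames = dimnames(m))
  otu_tibble(null,
             taxonomy = if ("taxonomy" %in% names(table)) table$taxonomy)
}

# mean Bray-Curtis pair matrix over null iterations for a counts matrix
# (samples x taxa), using the same regional-pool scheme without tibble
# overhead. Returns the n x n mean null distance matrix.
null_mean_bray <- function(m, iterations, relative) {
  prob <- colSums(m) / sum(m)
  totals <- rowSums(m)
  acc <- matrix(0, nrow(m), nrow(m))
  for (i in seq_len(iterations)) {
    draw <- vapply(totals, function(tt) {
      as.numeric(stats::rmultinom(1, size = tt, prob = prob))
    }, numeric(ncol(m)))
    draw <- t(draw)
    dm <- if (relative) draw / pmax(rowSums(draw), 1) else draw
    acc <- acc + as.matrix(vegan::vegdist(dm, method = "bray"))
  }
  acc / iterations
}

#' Abundance-based beta-null deviation of cohort assemblages
#'
#' For each analysed cohort (transient-rare and common by default), the
#' cohort sub-table's observed pairwise Bray-Curtis dissimilarities are
#' compared with their mean over `iterations` null tables drawn by
#' [null_community()] applied to that sub-table. The per-pair deviation
#' is `observed - mean(null)`; values near zero indicate assembly
#' indistinguishable from ecologically equivalent taxa (neutral), larger
#' magnitudes indicate structure the null cannot produce (niche
#' association). Deviations are aggregated per sample (mean over the
#' pairs involving the sample) and the two cohorts compared with a
#' two-sided Mann-Whitney U test on the per-sample deviations (a Welch
#' t-test is reported alongside).
#'
#' @param table OTU tibble with >= 3 samples.
#' @param partition Cohort partition from [classify_taxa()].
#' @param iterations Null iterations (default 999).
#' @param seed Optional integer seed.
#' @param cohorts Cohort labels to analyse (default transient_rare and
#'   common).
#' @param relative Compute Bray-Curtis on per-sample relative abundances
#'   within the sub-table (default `TRUE`; cohort sub-table totals are
#'   unequal). The null draws always conserve the sub-table's counts.
#' @return A list of class `"null_deviation"`: `pairs` (tibble: `cohort`,
#'   `sample_a`, `sample_b`, `observed`, `mean_null`, `deviation`),
#'   `samples` (tibble: `cohort`, `sample_id`, `mean_deviation`),
#'   `comparison` (tibble: `test`, `statistic`, `p_value`), plus
#'   `iterations` and `seed`. A cohort with fewer than 3 taxa is reported
#'   as not computable (absent from the tibbles, named in
#'   `not_computable`).
#' @export
beta_null_deviation <- function(table, partition, iterations = 999, seed = NULL,
                                cohorts = c("transient_rare", "common"),
                                relative = TRUE) {
  validate_otu(table)
  if (iterations < 1) rlang::abort("`iterations` must be at least 1.")
  ids <- sample_ids(table)
  if (length(ids) < 3) rlang::abort("Need at least 3 samples.")
  not_computable <- character(0)
  res <- with_seed_or_current(seed, {
    purrr::map(cohorts, function(ch) {
      taxa <- partition$taxon_id[partition$cohort == ch]
      sub <- table[table$taxon_id %in% taxa, c("taxon_id", ids)]
      if (nrow(sub) < 3) return(NULL)
      m <- otu_matrix(sub)
      keep <- rowSums(m) > 0
      m <- m[keep, , drop = FALSE]
      if (nrow(m) < 3) return(NULL)
      mo <- if (relative) m / rowSums(m) else m
      obs <- as.matrix(vegan::vegdist(mo, method = "bray"))
      nul <- null_mean_bray(m, iterations, relative)
      dev <- obs - nul
      pairs <- which(upper.tri(obs), arr.ind = TRUE)
      tibble::tibble(
        cohort = ch,
        sample_a = rownames(obs)[pairs[, 1]],
        sample_b = rownames(obs)[pairs[, 2]],
        observed = obs[pairs],
        mean_null = nul[pairs],
        deviation = dev[pairs]
      )
    })
  })
  not_computable <- cohorts[vapply(res, is.null, logical(1))]
  pair_tbl <- dplyr::bind_rows(res)
  if (nrow(pair_tbl) == 0) {
    pair_tbl <- tibble::tibble(
      cohort = character(), sample_a = character(), sample_b = character(),
      observed = numeric(), mean_null = numeric(), deviation = numeric()
    )
  }
  sample_tbl <- pair_tbl |>
    tidyr::pivot_longer(c("sample_a", "sample_b"), values_to = "sample_id") |>
    dplyr::group_by(.data$cohort, .data$sample_id) |>
    dplyr::summarise(mean_deviation = mean(.data$deviation), .groups = "drop")
  comparison <- NULL
  present <- setdiff(cohorts, not_computable)
  if (length(present) == 2) {
    x <- sample_tbl$mean_deviation[sample_tbl$cohort == present[1]]
    y <- sample_tbl$mean_deviation[sample_tbl$cohort == present[2]]
    w <- stats::wilcox.test(x, y, exact = FALSE)
    tt <- stats::t.test(x, y)
    comparison <- tibble::tibble(
      test = c("mann_whitney", "welch_t"),
      statistic = c(unname(w$statistic), unname(tt$statistic)),
      p_value = c(w$p.value, tt$p.value)
    )
  }
  structure(
    list(pairs = pair_tbl, samples = sample_tbl, comparison = comparison,
         iterations = iterations, seed = seed, not_computable = not_computable),
    class = "null_deviation"
  )
}

#' @export
print.null_deviation <- function(x, ...) {
  cat(sprintf("Beta-null deviation (%d iterations)\n", x$iterations))
  agg <- x$samples |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(mean = mean(.data$mean_deviation), .groups = "drop")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %s: mean per-sample deviation = %.4f\n", agg$cohort[i], agg$mean[i]))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  cohort comparison (Mann-Whitney): p = %.4g\n",
                x$comparison$p_value[x$comparison$test == "mann_whitney"]))
  }
  if (length(x$not_computable) > 0) {
    cat("  not computable (fewer than 3 taxa):", paste(x$not_computable, collapse = ", "), "\n")
  }
  invisible(x)
}
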