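#' Cohort classification thresholds
#'
#' Bundles the three thresholds that define the rarity cohorts: a taxon is
#' *rare* when its pooled reads are below `rare_max_rel_abund` of the
#' table's grand total; among rare taxa, those detected in fewer than
#' `transient_max_occ` samples are *transient-rare* and those detected in
#' more than `persistent_min_occ` samples are *persistent-rare* (both
#' bounds strict, matching the field convention "<1%", "<4 occurrences",
#' ">8 occurrences" for a 12-sample series). Rare taxa between the two
#' occurrence bounds are labelled *intermediate-rare*; non-rare taxa are
#' *common*.
#'
#' @param rare_max_rel_abund Rarity cut-off as a fraction of total reads
#'   (default 0.01, i.e. "<1% of all sequence reads").
#' @param transient_max_occ Exclusive upper occurrence bound for
#'   transient-rare taxa (default 4).
#' @param persistent_min_occ Exclusive lower occurrence bound for
#'   persistent-rare taxa (default 8).
#' @return A list of class `"cohort_thresholds"`.
#' @export
cohort_thresholds <- function(rare_max_rel_abund = 0.01,
                              transient_max_occ = 4,
                              persistent_min_occ = 8) {
  if (!(rare_max_rel_abund > 0 && rare_max_rel_abund < 1)) {
    rlang::abort("`rare_max_rel_abund` must lie strictly between 0 and 1.")
  }
  if (transient_max_occ <= 0 || transient_max_occ > persistent_min_occ) {
    rlang::abort("Need 0 < transient_max_occ <= persistent_min_occ.")
  }
  structure(
    list(
      rare_max_rel_abund = rare_max_rel_abund,
      transient_max_occ = as.integer(transient_max_occ),
      persistent_min_occ = as.integer(persistent_min_occ)
    ),
    class = "cohort_thresholds"
  )
}

#' @export
print.cohort_thresholds <- function(x, ...) {
  cat(sprintf(
    "Cohort thresholds: rare < %.4g%% of reads; transient < %d occurrences; persistent > %d occurrences\n",
    100 * x$rare_max_rel_abund, x$transient_max_occ, x$persistent_min_occ
  ))
  invisible(x)
}

# Cohort label levels, in reporting order.
cohort_levels <- c("transient_rare", "persistent_rare", "intermediate_rare", "common")

#' Classify taxa into rarity/persistence cohorts
#'
#' @param summaries Per-taxon summary tibble from [summarize_taxa()].
#' @param thresholds A [cohort_thresholds()] object.
#' @return A tibble with columns `taxon_id` and `cohort` (factor with
#'   levels transient_rare, persistent_rare, intermediate_rare, common).
#'   The thresholds used are attached as attribute `"thresholds"`, with
#'   the occurrence bounds also expressed as fractions of the sample count
#'   when the summaries carry one.
#' @export
classify_taxa <- function(summaries, thresholds = cohort_thresholds()) {
  if (nrow(summaries) == 0) rlang::abort("`summaries` is empty.")
  stopifnot(inherits(thresholds, "cohort_thresholds"))
  grand <- sum(summaries$total_count)
  rare <- summaries$total_count < thresholds$rare_max_rel_abund * grand
  occ <- summaries$occurrence
  label <- dplyr::case_when(
    !rare ~ "common",
    occ < thresholds$transient_max_occ ~ "transient_rare",
    occ > thresholds$persistent_min_occ ~ "persistent_rare",
    .default = "intermediate_rare"
  )
  out <- tibble::tibble(
    taxon_id = summaries$taxon_id,
    cohort = factor(label, levels = cohort_levels)
  )
  attr(out, "thresholds") <- thresholds
  n_samp <- attr(summaries, "n_samples")
  if (!is.null(n_samp)) {
    attr(out, "occ_fractions") <- c(
      transient_max = thresholds$transient_max_occ / n_samp,
      persistent_min = thresholds$persistent_min_occ / n_samp
    )
  }
  out
}

#' Per-cohort OTU and read tallies
#'
#' @param partition Partition tibble from [classify_taxa()].
#' @param summaries The matching per-taxon summaries.
#' @return A tibble with one row per cohort (all four cohorts always
#'   present): `cohort`, `n_otus`, `pct_otus`, `pct_reads`, percentages
#'   against table-wide totals (each column sums to 100).
#' @export
cohort_summary <- function(partition, summaries) {
  if (!setequal(partition$taxon_id, summaries$taxon_id)) {
    rlang::abort("Partition and summaries cover different taxon sets.")
  }
  joined <- dplyr::inner_join(partition, summaries, by = "taxon_id")
  grand_reads <- sum(joined$total_count)
  joined |>
    dplyr::group_by(cohort = .data$cohort) |>
    dplyr::summarise(
      n_otus = dplyr::n(),
      reads = sum(.data$total_count),
      .groups = "drop"
    ) |>
    tidyr::complete(
      cohort = factor(cohort_levels, levels = cohort_levels),
      fill = list(n_otus = 0L, reads = 0)
    ) |>
    dplyr::mutate(
      pct_otus = 100 * .data$n_otus / nrow(joined),
      pct_reads = 100 * .data$reads / grand_reads
    ) |>
    dplyr::select("cohort", "n_otus", "pct_otus", "pct_reads")
}

#' Threshold grid for cohort-definition sensitivity scans
#'
#' Enumerates the Cartesian product of rarity (relative abundance) and
#' occurrence thresholds. The default grid is the 60-combination
#' sensitivity design: 12 relative-abundance cut-offs spanning 0.05% to
#' 4.00% crossed with transient-occurrence cut-offs 2 to 6.
#'
#' @param abund_values Rarity cut-offs as fractions (default 12 values
#'   from 0.0005 to 0.04).
#' @param occ_values Transient occurrence cut-offs (default 2:6).
#' @return A tibble with columns `abund_threshold` and `occ_threshold`,
#'   ordered with `abund_threshold` varying slowest (lexicographic).
#' @export
threshold_grid <- function(abund_values = c(0.05, 0.075, 0.1, 0.2, 0.3, 0.5,
                                            0.8, 1.0, 1.5, 2.0, 3.0, 4.0) / 100,
                           occ_values = 2:6) {
  if (length(abund_values) == 0 || length(occ_values) == 0) {
    rlang::abort("Threshold value lists must be nonempty.")
  }
  if (any(abund_values <= 0 | abund_values >= 1)) {
    rlang::abort("Abundance thresholds must lie strictly between 0 and 1.")
  }
  if (any(occ_values <= 0 | occ_values != floor(occ_values))) {
    rlang::abort("Occurrence thresholds must be positive integers.")
  }
  tidyr::expand_grid(
    abund_threshold = abund_values,
    occ_threshold = as.integer(occ_values)
  )
}

#' Flag conditionally rare taxa
#'
#' Conditionally rare taxa are rare most of the time but occasionally
#' bloom. A taxon is flagged when the coefficient of bimodality of its
#' per-sample relative abundances, b = (skewness^2 + 1) / kurtosis (raw
#' moment-ratio kurtosis), exceeds `bimodality_cutoff` *and* the taxon is
#' below `rarity_rel_abund` in at least one sample and above it in at
#' least one sample. Zero-variance (including all-zero) taxa are never
#' flagged.
#'
#' @param table OTU tibble with at least 4 samples (kurtosis needs 4
#'   points).
#' @param bimodality_cutoff Flagging threshold on b (default 0.9).
#' @param rarity_rel_abund Per-sample relative-abundance rarity line that
#'   must be crossed (default 0.01).
#' @return A tibble with columns `taxon_id`, `bimodality`, `min_rel_abund`,
#'   `max_rel_abund`, `flagged`; `bimodality` is `NA` for zero-variance
#'   taxa.
#' @export
flag_conditionally_rare <- function(table, bimodality_cutoff = 0.9,
                                    rarity_rel_abund = 0.01) {
  validate_otu(table)
  m <- otu_matrix(table)
  if (nrow(m) < 4) rlang::abort("Need at least 4 samples (kurtosis undefined below).")
  props <- m / rowSums(m)
  b <- apply(props, 2, function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 == 0) return(NA_real_)
    g1 <- mean((x - mean(x))^3) / m2^1.5
    g2 <- mean((x - mean(x))^4) / m2^2
    (g1^2 + 1) / g2
  })
  lo <- apply(props, 2, min)
  hi <- apply(props, 2, max)
  tibble::tibble(
    taxon_id = colnames(m),
    bimodality = unname(b),
    min_rel_abund = unname(lo),
    max_rel_abund = unname(hi),
    flagged = !is.na(b) & b > bimodality_cutoff &
      lo < rarity_rel_abund & hi > rarity_rel_abund
  )
}
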