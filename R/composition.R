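# Taxonomic composition of cohorts and cross-cohort comparisons.

# Parse a semicolon-separated lineage string into a fixed-rank character
# vector (domain, phylum, class, order, family, genus). Missing trailing
# ranks come back as NA.
lineage_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- length(lineage_ranks)
    p
  }, character(length(lineage_ranks))))
  colnames(out) <- lineage_ranks
  out
}

#' Aggregate cohort composition at a taxonomic rank
#'
#' Summarizes each cohort's per-sample relative abundance at a chosen
#' rank. `rank = "phylum"` reproduces the conventional microbiome view
#' where Proteobacteria are split into their classes
#' (Alpha/Beta/Gamma/...); `rank = "family"` aggregates at family level.
#' Taxa whose lineage lacks the rank are grouped as
#' `"unclassified_<deepest known parent>"`.
#'
#' @param table OTU tibble with a `taxonomy` column.
#' @param partition Cohort partition from [classify_taxa()].
#' @param rank `"phylum"` (Proteobacteria split to class) or `"family"`.
#' @return A tibble with columns `cohort`, `sample_id`, `value` (the rank
#'   value) and `rel_abund` (fraction of the *whole sample's* reads), so
#'   that within each (cohort, sample) the values sum to the cohort's
#'   total relative abundance in that sample.
#' @export
aggregate_composition <- function(table, partition, rank = c("phylum", "family")) {
  rank <- match.arg(rank)
  validate_otu(table)
  if (!"taxonomy" %in% names(table)) {
    rlang::abort("`table` has no taxonomy column; composition needs lineages.")
  }
  ranks <- parse_lineage(table$taxonomy)
  value <- if (rank == "phylum") {
    ifelse(
      !is.na(ranks[, "phylum"]) & ranks[, "phylum"] == "Proteobacteria",
      ifelse(is.na(ranks[, "class"]), "unclassified_Proteobacteria", ranks[, "class"]),
      ranks[, "phylum"]
    )
  } else {
    ranks[, "family"]
  }
  # unclassified at the requested rank: name after the deepest known parent
  missing <- is.na(value)
  if (any(missing)) {
    depth <- match(if (rank == "phylum") "phylum" else "family", lineage_ranks)
    parent <- apply(ranks[missing, seq_len(depth - 1), drop = FALSE], 1, function(p) {
      known <- p[!is.na(p)]
      if (length(known) == 0) "root" else known[length(known)]
    })
    value[missing] <- paste0("unclassified_", parent)
  }
  m <- otu_matrix(table)
  props <- m / rowSums(m)
  long <- tibble::tibble(
    taxon_id = rep(colnames(props), each = nrow(props)),
    sample_id = rep(rownames(props), times = ncol(props)),
    rel_abund = as.vector(props),
    value = rep(value, each = nrow(props))
  )
  long |>
    dplyr::inner_join(partition, by = "taxon_id") |>
    dplyr::group_by(.data$cohort, .data$sample_id, .data$value) |>
    dplyr::summarise(rel_abund = sum(.data$rel_abund), .groups = "drop") |>
    dplyr::arrange(.data$cohort, .data$sample_id, .data$value)
}

#' Compare two cohort compositions rank value by rank value
#'
#' For every taxonomic rank value present in either composition, runs a
#' two-sample Welch t-test across samples on the per-sample relative
#' abundances (absent values treated as 0). P-values are reported without
#' multiple-testing correction, flagged by the `p_adjust_method` column.
#'
#' @param a,b Composition tibbles from [aggregate_composition()], each for
#'   one cohort, sharing the sample set.
#' @return A tibble with columns `value`, `mean_a`, `mean_b`, `statistic`,
#'   `p_value`, `p_adjust_method` ("none").
#' @export
compare_compositions <- function(a, b) {
  samples <- union(a$sample_id, b$sample_id)
  if (length(samples) < 2) rlang::abort("Need at least 2 samples to compare.")
  if (!setequal(a$sample_id, b$sample_id)) {
    rlang::abort("Compositions cover different sample sets.")
  }
  values <- sort(union(a$value, b$value))
  fill <- function(tab, v) {
    x <- tab$rel_abund[tab$value == v][match(samples, tab$sample_id[tab$value == v])]
    x[is.na(x)] <- 0
    x
  }
  purrr::map_dfr(values, function(v) {
    xa <- fill(a, v)
    xb <- fill(b, v)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      stat <- if (mean(xa) == mean(xb)) 0 else Inf
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      tt <- stats::t.test(xa, xb)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble::tibble(
      value = v, mean_a = mean(xa), mean_b = mean(xb),
      statistic = stat, p_value = p, p_adjust_method = "none"
    )
  })
}
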