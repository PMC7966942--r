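#' Read a classic tab-separated OTU table
#'
#' Reads the "classic" OTU table layout: tab-separated, first column taxon
#' ids, header row of sample ids, and an optional trailing `taxonomy`
#' column holding a semicolon-separated lineage (domain down to genus).
#' Counts are validated strictly: anything that is not a non-negative
#' integer is an error, never silently zeroed.
#'
#' @param path Path to the OTU table TSV.
#' @param metadata_path Optional path to a sample metadata TSV with columns
#'   `sample_id` and `date` (ISO 8601). When given, every sample column of
#'   the table must appear in the metadata and vice versa.
#' @return A tibble with one row per taxon: `taxon_id`, one integer column
#'   per sample and, when present in the file, a `taxonomy` column. When
#'   `metadata_path` is supplied the parsed metadata tibble is attached as
#'   attribute `"sample_dates"` (also retrievable with
#'   [read_sample_metadata()]).
#' @seealso [write_otu_table()], [read_sample_metadata()]
#' @export
read_otu_table <- function(path, metadata_path = NULL) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2) rlang::abort("OTU table needs a taxon id column and at least one sample column.")
  names(raw)[1] <- "taxon_id"
  has_tax <- tolower(names(raw)[ncol(raw)]) == "taxonomy"
  if (has_tax) names(raw)[ncol(raw)] <- "taxonomy"
  count_cols <- setdiff(names(raw), .meta_cols)
  dup_s <- count_cols[duplicated(count_cols)]
  if (length(dup_s) > 0) {
    rlang::abort(paste0("Duplicate sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  for (s in count_cols) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- is.na(v) | v < 0 | v != floor(v)
    if (any(bad)) {
      rlang::abort(paste0(
        "Sample `", s, "`: unparseable or non-integer count(s), e.g. `",
        raw[[s]][which(bad)[1]], "` for taxon `", raw$taxon_id[which(bad)[1]], "`."
      ))
    }
    raw[[s]] <- as.integer(v)
  }
  validate_otu(raw)
  if (!is.null(metadata_path)) {
    meta <- read_sample_metadata(metadata_path)
    if (!setequal(meta$sample_id, count_cols)) {
      rlang::abort("Metadata sample ids do not match the OTU table's sample columns.")
    }
    attr(raw, "sample_dates") <- meta
  }
  raw
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id` and `date`
#'   (ISO 8601, e.g. `2005-05-15`).
#' @return A tibble with columns `sample_id` (character) and `date`
#'   (`Date`).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("sample_id", "date") %in% names(meta))) {
    rlang::abort("Metadata must have columns `sample_id` and `date`.")
  }
  if (anyDuplicated(meta$sample_id)) rlang::abort("Duplicate sample ids in metadata.")
  d <- as.Date(meta$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    rlang::abort(paste0("Unparseable date(s) in metadata, e.g. `", meta$date[which(is.na(d))[1]], "`."))
  }
  tibble::tibble(sample_id = meta$sample_id, date = d)
}

#' Write an OTU table (and optional metadata) back to TSV
#'
#' Writes the same dialect [read_otu_table()] consumes, so a write/read
#' round trip is lossless for counts and lineages.
#'
#' @param table OTU tibble.
#' @param path Output path.
#' @param metadata Optional metadata tibble (`sample_id`, `date`); written
#'   to `metadata_path`.
#' @param metadata_path Output path for metadata (required when `metadata`
#'   is given).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, metadata = NULL, metadata_path = NULL) {
  validate_otu(table)
  cols <- c("taxon_id", sample_ids(table), intersect("taxonomy", names(table)))
  readr::write_tsv(table[cols], path, progress = FALSE)
  if (!is.null(metadata)) {
    if (is.null(metadata_path)) rlang::abort("`metadata_path` required when writing metadata.")
    out <- dplyr::mutate(metadata, date = format(.data$date, "%Y-%m-%d"))
    readr::write_tsv(out, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Rarefy every sample to a common depth
#'
#' Random subsampling without replacement (multivariate hypergeometric per
#' sample) down to `depth` reads, the standard normalization that removes
#' sampling-depth bias before richness-sensitive analyses. Samples whose
#' total is below `depth` are dropped with a warning.
#'
#' @param table OTU tibble.
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; the subsampling is deterministic given the
#'   seed.
#' @return OTU tibble with every retained sample summing exactly to
#'   `depth`. Taxa never gain reads; rows are kept even if rarefied to
#'   all-zero so taxon sets stay aligned (drop them explicitly with
#'   [remove_singletons()] or a filter if desired).
#' @export
rarefy <- function(table, depth, seed = NULL) {
  validate_otu(table)
  if (length(depth) != 1 || depth <= 0 || depth != floor(depth)) {
    rlang::abort("`depth` must be a single positive integer.")
  }
  ids <- sample_ids(table)
  totals <- vapply(ids, function(s) sum(table[[s]]), numeric(1))
  keep <- totals >= depth
  if (!any(keep)) rlang::abort("All samples are below the rarefaction depth.")
  if (any(!keep)) {
    rlang::warn(paste0(
      "Dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
      paste(ids[!keep], collapse = ", ")
    ))
  }
  out <- table[c("taxon_id", ids[keep], intersect("taxonomy", names(table)))]
  with_seed_or_current(seed, {
    for (s in ids[keep]) {
      counts <- table[[s]]
      if (sum(counts) == depth) next  # exhaustive draw: unchanged
      pool <- rep.int(seq_along(counts), counts)
      drawn <- sample(pool, depth, replace = FALSE)
      out[[s]] <- tabulate(drawn, nbins = length(counts))
    }
  })
  out
}

#' Remove singleton taxa
#'
#' Drops taxa whose total count across the whole table is exactly 1
#' (likely sequencing artifacts). The filter is on the pooled total, not
#' per-sample counts, and is idempotent.
#'
#' @param table OTU tibble.
#' @return OTU tibble without singleton taxa (possibly zero rows).
#' @export
remove_singletons <- function(table) {
  validate_otu(table)
  totals <- rowSums(table[sample_ids(table)])
  table[totals != 1, , drop = FALSE]
}

#' Per-taxon abundance and occurrence summaries
#'
#' Computes, for every taxon, the pooled read total, the mean relative
#' abundance p (mean over samples of the per-sample proportion), the
#' occurrence (number of samples where the taxon is detected) and the
#' occurrence frequency (occurrence / number of samples). These are the
#' inputs of cohort classification and of the neutral-model fit.
#'
#' @param table OTU tibble; every sample must have a positive total.
#' @return A tibble with columns `taxon_id`, `total_count`,
#'   `mean_rel_abund`, `occurrence`, `occurrence_freq`, ordered as in the
#'   input. The number of samples is attached as attribute `"n_samples"`.
#' @export
summarize_taxa <- function(table) {
  validate_otu(table)
  m <- otu_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    rlang::abort(paste0(
      "Sample(s) with zero total reads: ",
      paste(rownames(m)[totals == 0], collapse = ", ")
    ))
  }
  props <- m / totals
  out <- tibble::tibble(
    taxon_id = colnames(m),
    total_count = unname(colSums(m)),
    mean_rel_abund = unname(colMeans(props)),
    occurrence = unname(colSums(m > 0)),
    occurrence_freq = unname(colSums(m > 0)) / nrow(m)
  )
  attr(out, "n_samples") <- nrow(m)
  out
}
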