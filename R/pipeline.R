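# End-to-end orchestration: rarefy -> filter -> classify -> SAD -> NCM ->
# beta-null -> permutation tests -> time-decay -> sensitivity scan.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with its default. All
#' stochastic stages draw from streams derived from the single `seed`, so
#' a fixed config reproduces byte-identical outputs.
#'
#' @param rarefaction_depth Reads per sample after rarefaction; `NULL`
#'   rarefies to the minimum sample total.
#' @param thresholds A [cohort_thresholds()] object.
#' @param grid A [threshold_grid()] for the sensitivity scan; `NULL`
#'   skips the scan.
#' @param detection_limit NCM detection limit d; `NULL` means `1/N`.
#' @param envelope_alpha Significance level of the NCM envelope.
#' @param null_iterations Beta-null iterations.
#' @param permutations Permutations for PERMANOVA/PERMDISP/time-decay.
#' @param seed Master integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(rarefaction_depth = NULL,
                            thresholds = cohort_thresholds(),
                            grid = threshold_grid(),
                            detection_limit = NULL,
                            envelope_alpha = 0.05,
                            null_iterations = 999,
                            permutations = 999,
                            seed = 1L) {
  stopifnot(inherits(thresholds, "cohort_thresholds"))
  structure(
    list(
      rarefaction_depth = rarefaction_depth,
      thresholds = thresholds,
      grid = grid,
      detection_limit = detection_limit,
      envelope_alpha = envelope_alpha,
      null_iterations = null_iterations,
      permutations = permutations,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full community-assembly analysis pipeline
#'
#' Sequences every stage on one OTU table: rarefaction, singleton
#' removal, per-taxon summaries, cohort classification, per-cohort SAD
#' fits, Sloan NCM fit with envelope partition and neutrality curve,
#' binomial comparison model, beta-null deviation, cohort PERMANOVA and
#' PERMDISP, time-decay (when dates are available; skipped with a
#' warning otherwise), and the threshold-sensitivity scan. Any stage
#' failure is rethrown with the stage name.
#'
#' @param table OTU tibble (raw counts).
#' @param dates Optional metadata tibble (`sample_id`, `date`).
#' @param config A [pipeline_config()].
#' @return A named list of class `"rare_pipeline"` with elements
#'   `rarefied`, `summaries`, `partition`, `cohort_summary`, `sad_fits`,
#'   `ncm`, `envelope_partition`, `neutrality`, `binomial`, `betanull`,
#'   `permtest`, `timedecay` (`NULL` when skipped), `grid_scan` (`NULL`
#'   when skipped), and `manifest` (seeds, thresholds, decisions).
#' @export
run_pipeline <- function(table, dates = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)),
                   parent = e)
    })
  }
  seeds <- config$seed + c(rarefy = 101L, betanull = 202L, perm = 303L, decay = 404L)

  depth <- config$rarefaction_depth %||%
    min(vapply(sample_ids(table), function(s) sum(table[[s]]), numeric(1)))
  rarefied <- stage("rarefy", rarefy(table, depth, seed = seeds[["rarefy"]]))
  filtered <- stage("remove_singletons", remove_singletons(rarefied))
  summaries <- stage("summarize_taxa", summarize_taxa(filtered))
  partition <- stage("classify_taxa", classify_taxa(summaries, config$thresholds))
  cs <- stage("cohort_summary", cohort_summary(partition, summaries))

  sad_fits <- stage("sad", {
    purrr::map(stats::setNames(c("transient_rare", "common"),
                               c("transient_rare", "common")), function(ch) {
      ab <- summaries$total_count[partition$cohort == ch]
      if (length(ab) > 0) fit_both_sads(ab) else list(logseries = NULL, lognormal = NULL)
    })
  })

  d <- config$detection_limit %||% (1 - 2^(-1 / depth))
  ncm <- stage("ncm", fit_ncm(summaries, N = depth, d = d,
                              alpha = config$envelope_alpha))
  env_part <- stage("partition_by_envelope", partition_by_envelope(ncm, partition))
  neutrality <- stage("neutrality_curve", neutrality_curve(ncm, partition))
  binom <- stage("binomial_model", fit_binomial_model(summaries, N = depth, d = d))

  betanull <- stage("beta_null_deviation", beta_null_deviation(
    filtered, partition,
    iterations = config$null_iterations, seed = seeds[["betanull"]]
  ))
  permtest <- stage("permtest", compare_cohort_assemblages(
    filtered, partition,
    permutations = config$permutations, seed = seeds[["perm"]]
  ))

  timedecay <- NULL
  if (!is.null(dates)) {
    timedecay <- stage("time_decay", time_decay(
      filtered, dates,
      permutations = config$permutations, seed = seeds[["decay"]]
    ))
  } else {
    rlang::warn("No sample dates supplied: time-decay stage skipped.")
  }

  grid_scan <- if (!is.null(config$grid)) {
    stage("sad_grid_scan", sad_grid_scan(filtered, config$grid))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rareassembly")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    rarefaction_depth = depth,
    thresholds = unclass(config$thresholds),
    detection_limit = d,
    envelope_alpha = config$envelope_alpha,
    null_iterations = config$null_iterations,
    permutations = config$permutations,
    decisions = list(
      distance = "Bray-Curtis (no phylogeny; replaces weighted UniFrac)",
      rarefaction = "multivariate hypergeometric without replacement",
      mean_rel_abund = "mean of per-sample proportions",
      envelope = "Wilson score interval, trial count = number of samples",
      singleton_rule = "pooled table-wide total equal to 1"
    ),
    timedecay_skipped = is.null(dates)
  )

  structure(
    list(
      rarefied = rarefied, summaries = summaries, partition = partition,
      cohort_summary = cs, sad_fits = sad_fits, ncm = ncm,
      envelope_partition = env_part, neutrality = neutrality,
      binomial = binom, betanull = betanull, permtest = permtest,
      timedecay = timedecay, grid_scan = grid_scan, manifest = manifest
    ),
    class = "rare_pipeline"
  )
}

#' Write pipeline results to a directory
#'
#' Emits the plot-ready TSV/JSON files of every computed stage plus a
#' `manifest.json` recording versions, seeds, thresholds and decision
#' flags. Re-running the same config writes byte-identical files.
#'
#' @param results A `"rare_pipeline"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(results, dir) {
  stopifnot(inherits(results, "rare_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(f) file.path(dir, f)
  wjson <- function(x, f) jsonlite::write_json(x, out(f), auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE, null = "null")
  write_otu_table(results$rarefied, out("rarefied_otu_table.tsv"))
  readr::write_tsv(results$summaries, out("taxon_summaries.tsv"), progress = FALSE)
  readr::write_tsv(results$partition, out("cohort_partition.tsv"), progress = FALSE)
  readr::write_tsv(results$cohort_summary, out("cohort_summary.tsv"), progress = FALSE)
  readr::write_tsv(tidy(results$ncm), out("ncm_per_taxon.tsv"), progress = FALSE)
  wjson(c(glance(results$ncm), list(binomial_r_squared = results$binomial$r_squared)),
        "ncm_fit.json")
  readr::write_tsv(results$envelope_partition, out("envelope_partition.tsv"), progress = FALSE)
  readr::write_tsv(results$neutrality$bins, out("neutrality_bins.tsv"), progress = FALSE)
  sadj <- purrr::map(results$sad_fits, function(fits) {
    purrr::map(fits, function(f) {
      if (is.null(f)) NULL else as.list(glance(f))
    })
  })
  wjson(sadj, "sad_fits.json")
  readr::write_tsv(results$betanull$samples, out("betanull_samples.tsv"), progress = FALSE)
  wjson(list(
    comparison = results$betanull$comparison,
    iterations = results$betanull$iterations,
    seed = results$betanull$seed
  ), "betanull_summary.json")
  wjson(list(
    permanova = as.list(glance(results$permtest$permanova)),
    permdisp = as.list(glance(results$permtest$permdisp))
  ), "permutation_tests.json")
  if (!is.null(results$timedecay)) {
    readr::write_tsv(results$timedecay$pairs, out("timedecay_pairs.tsv"), progress = FALSE)
    wjson(as.list(glance(results$timedecay)), "timedecay_fit.json")
  }
  if (!is.null(results$grid_scan)) {
    readr::write_tsv(results$grid_scan, out("sad_grid_scan.tsv"), progress = FALSE)
  }
  wjson(results$manifest, "manifest.json")
  invisible(dir)
}
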