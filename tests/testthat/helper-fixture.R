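# Shared fixture builders. The reference community is the frozen synthetic
# table shipped under inst/extdata; reference_community() regenerates it
# bit-for-bit from its seed, which a test asserts.

fixture_phyla <- c(
  "Proteobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes",
  "Nitrospirae", "Planctomycetes", "Chloroflexi", "Acidobacteria"
)
fixture_proteo_classes <- c(
  "Alphaproteobacteria", "Betaproteobacteria", "Gammaproteobacteria",
  "Deltaproteobacteria", "Epsilonproteobacteria"
)

# Deterministic semicolon lineages for n taxa (some truncated at phylum or
# class to exercise the unclassified_* handling).
fixture_taxonomy <- function(n, seed = 424242) {
  withr::with_seed(seed, {
    phy <- sample(fixture_phyla, n, replace = TRUE,
                  prob = c(0.35, 0.2, 0.1, 0.1, 0.05, 0.05, 0.08, 0.07))
    vapply(seq_len(n), function(i) {
      cls <- if (phy[i] == "Proteobacteria") {
        sample(fixture_proteo_classes, 1)
      } else {
        paste0(phy[i], "_class")
      }
      depth <- sample(c(2L, 3L, 5L, 6L), 1, prob = c(0.05, 0.1, 0.25, 0.6))
      lineage <- c("Bacteria", phy[i], cls,
                   paste0(substr(cls, 1, 4), "ales"),
                   paste0(substr(cls, 1, 4), "aceae"),
                   paste0("Genus_", i %% 40))
      paste(lineage[seq_len(depth)], collapse = ";")
    }, character(1))
  })
}

# The shipped 12-sample x 300-taxon neutral community with bimonthly dates.
reference_community <- function() {
  tbl <- simulate_neutral(
    n_taxa = 300, Nm = 300, depth = 3000, n_samples = 12,
    alpha = 50, seed = 20050515, dated = TRUE
  )
  dates <- attr(tbl, "sample_dates")
  tbl$taxonomy <- fixture_taxonomy(nrow(tbl))
  list(counts = tbl, dates = dates)
}

# Small deterministic toy table used across unit tests.
toy_table <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3", "t4"),
    sA = c(10L, 0L, 1L, 5L),
    sB = c(8L, 2L, 0L, 5L),
    sC = c(12L, 1L, 0L, 5L),
    taxonomy = c(
      "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales",
      "Bacteria;Bacteroidetes",
      "Bacteria;Proteobacteria",
      "Bacteria;Nitrospirae;Nitrospira_class;Nitrospirales;Nitrospiraceae;Nitrospira"
    )
  )
}

# Random valid OTU tibble for property tests.
random_table <- function(n_taxa, n_samples, max_count = 20, seed = NULL) {
  with_seed_or_current <- get("with_seed_or_current", asNamespace("rareassembly"))
  with_seed_or_current(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda = max_count / 4),
                nrow = n_samples)
    dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                        sprintf("t%03d", seq_len(n_taxa)))
    get("otu_tibble", asNamespace("rareassembly"))(m)
  })
}

# All-taxa single-cohort partition (for single-assemblage null analyses).
single_cohort_partition <- function(tbl, cohort = "transient_rare") {
  lv <- get("cohort_levels", asNamespace("rareassembly"))
  tibble::tibble(taxon_id = tbl$taxon_id, cohort = factor(cohort, levels = lv))
}

# Build a table whose usable pairs sit exactly on similarity = c * lag^w:
# sample 1 shares taxon t1k with sample k at proportion c / lag^(0.2) where
# the lags are fifth powers (32, 243, 1024 days), so lag^0.2 is integral
# and the shared proportions are exact; all other pairs share nothing and
# are dropped as zero-similarity pairs.
power_law_series <- function() {
  M <- 12000L  # c = 0.1: shared proportions c/2, c/3, c/4 -> 600, 400, 300
  counts <- rbind(
    t12 = c(600L, 600L, 0L, 0L),
    t13 = c(400L, 0L, 400L, 0L),
    t14 = c(300L, 0L, 0L, 300L),
    f1 = c(M - 1300L, 0L, 0L, 0L),
    f2 = c(0L, M - 600L, 0L, 0L),
    f3 = c(0L, 0L, M - 400L, 0L),
    f4 = c(0L, 0L, 0L, M - 300L)
  )
  colnames(counts) <- c("s1", "s2", "s3", "s4")
  tbl <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(counts)),
                          tibble::as_tibble(counts))
  dates <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    date = as.Date("2000-01-01") + c(0, 32, 243, 1024)
  )
  list(counts = tbl, dates = dates)
}

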