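test_that("read_otu_table parses the classic TSV layout with taxonomy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "OTU_ID\ts1\ts2\ttaxonomy",
    "tA\t3\t0\tBacteria;Proteobacteria;Betaproteobacteria",
    "tB\t1\t5\tBacteria;Bacteroidetes",
    "tC\t0\t2\tBacteria"
  ), path)
  tbl <- read_otu_table(path)
  expect_equal(sample_ids(tbl), c("s1", "s2"))
  expect_equal(tbl$taxon_id, c("tA", "tB", "tC"))
  expect_equal(tbl$s1, c(3L, 1L, 0L))
  expect_equal(tbl$s2, c(0L, 5L, 2L))
  expect_true(all(lengths(strsplit(tbl$taxonomy, ";")) <= 7))
})

test_that("read_otu_table rejects duplicate ids and unparseable counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1", "tA\t3", "tA\t1"), path)
  expect_error(read_otu_table(path), "tA")
  writeLines(c("id\ts1", "tA\tthree"), path)
  expect_error(read_otu_table(path), "three")
  writeLines(c("id\ts1", "tA\t-2"), path)
  expect_error(read_otu_table(path), "s1")
  writeLines(c("id\ts1", "tA\t1.5"), path)
  expect_error(read_otu_table(path), "non-integer")
})

test_that("write/read round trip is lossless for counts, lineages and dates", {
  tbl <- random_table(50, 12, seed = 71)
  tbl$taxonomy <- fixture_taxonomy(50, seed = 72)
  dates <- tibble::tibble(
    sample_id = sample_ids(tbl),
    date = as.Date("2005-05-15") + seq(0, by = 61, length.out = 12)
  )
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tbl, p1, metadata = dates, metadata_path = p2)
  back <- read_otu_table(p1, metadata_path = p2)
  expect_equal(as.data.frame(back)[names(tbl)],
               as.data.frame(dplyr::mutate(tbl, dplyr::across(-c(taxon_id, taxonomy), as.integer))))
  expect_equal(attr(back, "sample_dates"), dates)
})

test_that("read_otu_table checks metadata sample ids against the table", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "tA\t3\t1"), p1)
  writeLines(c("sample_id\tdate", "s1\t2005-05-15", "sX\t2005-07-15"), p2)
  expect_error(read_otu_table(p1, metadata_path = p2), "do not match")
})

test_that("rarefy conserves depth exactly and is deterministic under a seed", {
  tbl <- random_table(80, 12, max_count = 60, seed = 5)
  totals <- vapply(sample_ids(tbl), function(s) sum(tbl[[s]]), numeric(1))
  depth <- min(totals) - 7
  r1 <- rarefy(tbl, depth, seed = 11)
  r2 <- rarefy(tbl, depth, seed = 11)
  expect_identical(r1, r2)
  post <- vapply(sample_ids(r1), function(s) sum(r1[[s]]), numeric(1))
  expect_true(all(post == depth))
  # taxon counts never exceed pre-rarefaction counts
  for (s in sample_ids(tbl)) expect_true(all(r1[[s]] <= tbl[[s]]))
})

test_that("rarefying 12 samples to depth 2988 retains exactly 35856 reads", {
  tbl <- simulate_neutral(n_taxa = 200, Nm = 300, depth = 3100,
                          n_samples = 12, seed = 8)
  r <- rarefy(tbl, 2988, seed = 1)
  expect_identical(sum(vapply(sample_ids(r), function(s) sum(r[[s]]), numeric(1))),
                   35856)
})

test_that("rarefy at a sample's exact total is an exhaustive, unchanged draw", {
  tbl <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(5L, 3L), s2 = c(9L, 1L))
  r <- rarefy(tbl, 8, seed = 3)
  expect_equal(r$s1, c(5L, 3L))
  expect_equal(sum(r$s2), 8)
})

test_that("rarefy drops shallow samples with a warning and errors when none remain", {
  tbl <- tibble::tibble(taxon_id = "a", s1 = 10L, s2 = 3L)
  expect_warning(r <- rarefy(tbl, 5, seed = 1), "s2")
  expect_equal(sample_ids(r), "s1")
  expect_error(rarefy(tbl, 50, seed = 1), "below")
  expect_error(rarefy(tbl, 0), "positive")
})

test_that("rarefaction subsampling matches the hypergeometric mean", {
  # one sample with counts (5, 5), depth 4: retained count of taxon A has
  # hypergeometric mean 4 * 5/10 = 2 and variance 4*(1/2)*(1/2)*(6/9)
  tbl <- tibble::tibble(taxon_id = c("A", "B"), s1 = c(5L, 5L))
  n_rep <- 4000
  draws <- vapply(seq_len(n_rep), function(i) rarefy(tbl, 4, seed = i)$s1[1],
                  numeric(1))
  se <- sqrt(4 * 0.5 * 0.5 * (6 / 9)) / sqrt(n_rep)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("remove_singletons filters on pooled totals and is idempotent", {
  tbl <- tibble::tibble(
    taxon_id = c("one_read", "two_reads_one_sample", "split"),
    s1 = c(1L, 2L, 1L), s2 = c(0L, 0L, 1L)
  )
  out <- remove_singletons(tbl)
  expect_equal(out$taxon_id, c("two_reads_one_sample", "split"))
  expect_identical(remove_singletons(out), out)
  # no singletons -> identity
  expect_identical(remove_singletons(out), remove_singletons(remove_singletons(out)))
  # brute-force oracle on a random 200-taxon table
  big <- random_table(200, 6, max_count = 3, seed = 13)
  keep <- rowSums(as.matrix(big[sample_ids(big)])) != 1
  expect_equal(remove_singletons(big)$taxon_id, big$taxon_id[keep])
})

test_that("summarize_taxa matches a per-taxon brute-force loop", {
  tbl <- random_table(40, 7, seed = 21)
  tbl[[sample_ids(tbl)[1]]][1] <- tbl[[sample_ids(tbl)[1]]][1] + 1L  # break ties
  s <- summarize_taxa(tbl)
  ids <- sample_ids(tbl)
  totals <- vapply(ids, function(x) sum(tbl[[x]]), numeric(1))
  for (i in c(1, 17, 40)) {
    counts <- vapply(ids, function(x) tbl[[x]][i], numeric(1))
    expect_equal(s$total_count[i], sum(counts))
    expect_equal(s$mean_rel_abund[i], mean(counts / totals))
    expect_equal(s$occurrence[i], sum(counts > 0))
    expect_equal(s$occurrence_freq[i], sum(counts > 0) / length(ids))
  }
  expect_equal(attr(s, "n_samples"), 7)
})

test_that("taxon summaries handle full presence, absence, and zero-total samples", {
  tbl <- tibble::tibble(taxon_id = c("everywhere", "nowhere"),
                        s1 = c(4L, 0L), s2 = c(1L, 0L), s3 = c(9L, 0L))
  s <- summarize_taxa(tbl)
  expect_equal(s$occurrence, c(3, 0))
  expect_equal(s$occurrence_freq, c(1, 0))
  expect_equal(s$mean_rel_abund, c(1, 0))
  bad <- tibble::tibble(taxon_id = "a", s1 = 0L, s2 = 2L)
  expect_error(summarize_taxa(bad), "s1")
})

test_that("mean relative abundances sum to 1 on equal-depth tables", {
  tbl <- simulate_neutral(n_taxa = 120, Nm = 100, depth = 500,
                          n_samples = 6, seed = 33)
  s <- summarize_taxa(tbl)
  expect_equal(sum(s$mean_rel_abund), 1, tolerance = 1e-9)
})

test_that("the shipped fixture is regenerated bit-for-bit from its seed", {
  ref <- reference_community()
  path <- system.file("extdata", "synthetic_community.tsv", package = "rareassembly")
  mpath <- system.file("extdata", "synthetic_metadata.tsv", package = "rareassembly")
  shipped <- read_otu_table(path, metadata_path = mpath)
  regen <- dplyr::mutate(ref$counts,
                         dplyr::across(-c(taxon_id, taxonomy), as.integer))
  expect_equal(as.data.frame(shipped), as.data.frame(regen), ignore_attr = TRUE)
  expect_equal(attr(shipped, "sample_dates"), ref$dates)
})
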