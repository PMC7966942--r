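# Bray-Curtis dissimilarity, principal-coordinates embedding, and
# permutation tests of location (PERMANOVA) and dispersion (PERMDISP).

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over taxa. Computed with
#' vegan's `vegdist`.
#'
#' @param table OTU tibble; every sample must have a positive total.
#' @param relative Normalize each sample to relative abundances first
#'   (recommended when sample totals differ, e.g. cohort sub-tables).
#'   Default `FALSE`: the formula is applied to the values as given.
#' @return A `dist` object over the samples.
#' @export
bray_curtis <- function(table, relative = FALSE) {
  validate_otu(table)
  m <- otu_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    rlang::abort(paste0(
      "Zero-total sample(s): ", paste(rownames(m)[totals == 0], collapse = ", ")
    ))
  }
  if (relative) m <- m / totals
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities and eigendecomposes,
#' retaining *all* axes including those with negative eigenvalues (the
#' "imaginary" part that arises for semi-metric dissimilarities such as
#' Bray-Curtis). Coordinates are scaled by sqrt(|eigenvalue|) and ordered
#' by decreasing eigenvalue.
#'
#' @param dist A `dist` object or symmetric dissimilarity matrix.
#' @return A list of class `"pcoa_embed"`: `points` (items x real axes),
#'   `imaginary_points` (items x negative-eigenvalue axes, possibly 0
#'   columns), `eigenvalues` (all, decreasing), `ids`.
#' @export
pcoa <- function(dist) {
  m <- as.matrix(dist)
  if (!isSymmetric(unname(m), tol = 1e-8)) rlang::abort("Dissimilarity matrix must be symmetric.")
  n <- nrow(m)
  ids <- rownames(m) %||% as.character(seq_len(n))
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))  # row- then column-centering = double centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- e$values > tol
  neg <- e$values < -tol
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  ipts <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  rownames(pts) <- rownames(ipts) <- ids
  structure(
    list(points = pts, imaginary_points = ipts, eigenvalues = e$values, ids = ids),
    class = "pcoa_embed"
  )
}

# Pseudo-F from a squared-distance matrix and integer group codes.
# SS_total = sum of all pairwise d^2 / n; SS_within = sum over groups of
# within-group pairwise d^2 / group size.
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# One-way ANOVA F on distances-to-centroid z given group codes.
dispersion_stat <- function(z, groups) {
  n <- length(z)
  a <- length(unique(groups))
  grand <- mean(z)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    zi <- z[groups == g]
    ss_between <- ss_between + length(zi) * (mean(zi) - grand)^2
    ss_within <- ss_within + sum((zi - mean(zi))^2)
  }
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Distances to own-group centroid in a PCoA embedding, with the standard
# imaginary-axis correction: squared distance = real part - imaginary part
# (floored at 0 before the square root).
centroid_distances <- function(emb, groups) {
  z2 <- numeric(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(emb$points[idx, , drop = FALSE])
    dr <- sweep(emb$points[idx, , drop = FALSE], 2, cr)
    real <- rowSums(dr^2)
    imag <- 0
    if (ncol(emb$imaginary_points) > 0) {
      ci <- colMeans(emb$imaginary_points[idx, , drop = FALSE])
      di <- sweep(emb$imaginary_points[idx, , drop = FALSE], 2, ci)
      imag <- rowSums(di^2)
    }
    z2[idx] <- real - imag
  }
  sqrt(pmax(z2, 0))
}

check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n) rlang::abort("`groups` length must match the distance matrix.")
  if (nlevels(droplevels(groups)) < 2) rlang::abort("Need at least 2 groups.")
  if (any(table(groups) < 2)) rlang::abort("Every group needs at least 2 items.")
  droplevels(groups)
}

perm_test_result <- function(method, statistic, p_value, permutations, seed, exact) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         permutations = permutations, seed = seed, exact = exact),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "%s: F = %.4g, p = %.4g (%s)\n", x$method, x$statistic, x$p_value,
    if (x$exact) sprintf("exact, %d permutations", x$permutations)
    else sprintf("%d random permutations", x$permutations)
  ))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based one-factor PERMANOVA: the pseudo-F is computed from the
#' decomposition of summed squared dissimilarities into within- and
#' between-group parts, and its null distribution from random
#' relabelings of the items. The p-value follows the
#' `(exceedances + 1) / (permutations + 1)` rule. With `exact = TRUE` all
#' `n!` relabelings are enumerated (small n only) and
#' `p = mean(F_perm >= F_obs)` over the full permutation distribution.
#'
#' @param dist `dist` object or symmetric dissimilarity matrix.
#' @param groups Group labels, one per item; >= 2 groups of >= 2 items.
#' @param permutations Number of random permutations (default 999).
#' @param seed Optional integer seed for a reproducible permutation
#'   stream.
#' @param exact Enumerate all permutations instead of sampling.
#' @return A `"perm_test"` object: `statistic` (pseudo-F), `p_value`,
#'   `permutations`, `seed`, `exact`.
#' @export
permanova <- function(dist, groups, permutations = 999, seed = NULL, exact = FALSE) {
  d2 <- as.matrix(dist)^2
  groups <- check_groups(groups, nrow(d2))
  g <- as.integer(groups)
  f_obs <- permanova_stat(d2, g)
  if (exact) {
    perms <- all_permutations(length(g))
    f_perm <- apply(perms, 1, function(ix) permanova_stat(d2, g[ix]))
    p <- mean(f_perm >= f_obs - 1e-12)
    return(perm_test_result("PERMANOVA", f_obs, p, nrow(perms), seed, TRUE))
  }
  f_perm <- with_seed_or_current(seed, {
    vapply(seq_len(permutations), function(i) {
      permanova_stat(d2, sample(g))
    }, numeric(1))
  })
  perm_test_result("PERMANOVA", f_obs, perm_pvalue(f_perm, f_obs),
                   permutations, seed, FALSE)
}

#' Permutational test of multivariate dispersion (PERMDISP)
#'
#' Embeds the dissimilarities by [pcoa()] (keeping the imaginary axes),
#' computes every item's distance to its group centroid with the
#' real-minus-imaginary correction, and compares group mean dispersions
#' with a one-way F statistic whose null distribution comes from
#' permuting the group labels (the embedding stays fixed). P-value rules
#' as in [permanova()].
#'
#' @inheritParams permanova
#' @return A `"perm_test"` object with the dispersion F; the per-item
#'   centroid distances are attached as attribute `"distances"`.
#' @export
permdisp <- function(dist, groups, permutations = 999, seed = NULL, exact = FALSE) {
  m <- as.matrix(dist)
  groups <- check_groups(groups, nrow(m))
  g <- as.integer(groups)
  emb <- pcoa(m)
  f_of <- function(gg) dispersion_stat(centroid_distances(emb, gg), gg)
  f_obs <- f_of(g)
  if (exact) {
    perms <- all_permutations(length(g))
    f_perm <- apply(perms, 1, function(ix) f_of(g[ix]))
    res <- perm_test_result("PERMDISP", f_obs, mean(f_perm >= f_obs - 1e-12),
                            nrow(perms), seed, TRUE)
  } else {
    f_perm <- with_seed_or_current(seed, {
      vapply(seq_len(permutations), function(i) f_of(sample(g)), numeric(1))
    })
    res <- perm_test_result("PERMDISP", f_obs, perm_pvalue(f_perm, f_obs),
                            permutations, seed, FALSE)
  }
  attr(res, "distances") <- centroid_distances(emb, g)
  res
}

#' Compare two cohort assemblages by PERMANOVA and PERMDISP
#'
#' Stacks the two cohorts' per-sample assemblages as separate items (for
#' 12 samples and 2 cohorts: 24 items labelled by cohort), computes
#' Bray-Curtis dissimilarities on per-sample relative abundances within
#' each cohort sub-table, and runs both permutation tests. Because the
#' cohorts share no taxa, between-cohort dissimilarities saturate near 1;
#' the location test then mostly reflects that separation, while the
#' dispersion test compares the cohorts' internal temporal variability
#' (the ecologically informative contrast).
#'
#' @param table OTU tibble.
#' @param partition Cohort partition from [classify_taxa()].
#' @param cohorts The two cohort labels to compare.
#' @param permutations,seed Passed to the tests (the same seed gives both
#'   tests identical permutation streams).
#' @param relative Normalize cohort sub-tables to per-sample relative
#'   abundances first (default `TRUE`; sub-table totals are unequal).
#' @return A list with `permanova`, `permdisp` (both `"perm_test"`),
#'   `dist` (the stacked `dist`), and `groups`.
#' @export
compare_cohort_assemblages <- function(table, partition,
                                       cohorts = c("transient_rare", "common"),
                                       permutations = 999, seed = NULL,
                                       relative = TRUE) {
  validate_otu(table)
  stopifnot(length(cohorts) == 2)
  ids <- sample_ids(table)
  blocks <- purrr::map(cohorts, function(ch) {
    taxa <- partition$taxon_id[partition$cohort == ch]
    sub <- table[table$taxon_id %in% taxa, c("taxon_id", ids)]
    if (nrow(sub) < 2) rlang::abort(paste0("Cohort `", ch, "` has fewer than 2 taxa."))
    m <- otu_matrix(sub)
    keep <- rowSums(m) > 0
    if (!all(keep)) {
      rlang::warn(paste0("Cohort `", ch, "`: dropping ", sum(!keep),
                         " sample(s) with no reads in this cohort."))
      m <- m[keep, , drop = FALSE]
    }
    if (relative) m <- m / rowSums(m)
    rownames(m) <- paste(ch, rownames(m), sep = ":")
    m
  })
  all_taxa <- unique(unlist(purrr::map(blocks, colnames)))
  stacked <- do.call(rbind, purrr::map(blocks, function(m) {
    full <- matrix(0, nrow(m), length(all_taxa),
                   dimnames = list(rownames(m), all_taxa))
    full[, colnames(m)] <- m
    full
  }))
  groups <- rep(cohorts, times = vapply(blocks, nrow, integer(1)))
  d <- vegan::vegdist(stacked, method = "bray")
  list(
    permanova = permanova(d, groups, permutations, seed),
    permdisp = permdisp(d, groups, permutations, seed),
    dist = d,
    groups = groups
  )
}
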