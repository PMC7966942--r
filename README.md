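# rareassembly

Tools for asking a specific ecological question of microbial time series:
**are the rare members of a community assembled by neutral processes
(dispersal and drift) or by niche processes (environmental selection)?**

The package was built around the analysis style used for activated-sludge
bioreactor 16S surveys — a dozen samples collected over a couple of years,
rarefied to equal depth, with thousands of OTUs of which most are rare —
but every function takes a plain OTU count table and works on any
taxa-by-samples survey.

## What it computes

Given an OTU table (taxa × samples, non-negative integer counts) and
optional sample dates:

1. **Cohorts of rarity.** Taxa are split into *transient-rare* (below a
   pooled-abundance cut-off, default < 1% of all reads, and detected in
   fewer than 4 samples), *persistent-rare* (rare but detected in more
   than 8 samples), *intermediate-rare*, and *common*. Conditionally rare
   taxa (occasional bloomers) are flagged by the bimodality coefficient
   b = (skewness² + 1) / kurtosis of their abundance series.
2. **Species abundance distributions.** Preston octave histograms
   (power-of-2 abundance classes) per cohort, with a log-series fit —
   Fisher's α solving S = α·ln(1 + N/α), series parameter x = N/(N+α) —
   and a least-squares log-normal (Preston) fit
   E_k = S₀·exp(−a²(k−R₀)²), compared by chi-squared goodness of fit.
   A 60-combination threshold grid scan checks that the preferred model
   is not an artifact of the cohort definition.
3. **Sloan neutral community model.** Under neutral assembly with
   migration parameter Nm, a taxon with metacommunity relative abundance
   p has local relative abundance Beta(Nm·p, Nm·(1−p)); its predicted
   detection frequency is 1 − I_d(Nm·p, Nm·(1−p)), the regularized
   incomplete beta tail above the detection limit d. `fit_ncm()`
   estimates Nm by nonlinear least squares of observed occurrence
   frequencies on mean relative abundances, reports the generalized
   R² = 1 − SS_err/SS_total, draws 95% Wilson score envelopes around the
   predictions, and tallies taxa above/within/below the envelope (the
   *neutrality fraction*). A no-free-parameter binomial model
   (1 − (1−p)^N) is the dispersal-unlimited comparison.
4. **Beta-null deviation.** Observed pairwise Bray–Curtis dissimilarity
   minus its mean over randomized communities in which taxa are
   ecologically equivalent (fixed sample totals, regional-pool
   multinomial draws); values near zero indicate neutral assembly.
5. **Permutation tests.** One-factor PERMANOVA (location) and PERMDISP
   (dispersion, with the negative-eigenvalue PCoA correction) on
   Bray–Curtis distances, with seeded permutation streams, the
   (exceedances+1)/(permutations+1) p-value rule, and an exact
   enumeration mode for small designs.
6. **Time-decay.** Ordinary least squares of log₁₀(similarity) on
   log₁₀(time lag in days), with a Mantel-style date-permutation test.
7. **Synthetic communities.** Dirichlet-multinomial neutral tables (the
   exact generative dual of the fitted Sloan model), niche-structured
   tables on an environmental gradient, and AR(1)-drifting time series —
   so every stage above is testable against known truth.

Results are tibbles or small S3 objects with broom-style `tidy()` /
`glance()` methods and `autoplot()` ggplot methods throughout.

## Worked example

The package ships a small synthetic community (12 bimonthly samples ×
300 taxa, generated by `simulate_neutral()` with Nm = 300 and a
log-series metacommunity) under `inst/extdata/`.

```r
library(rareassembly)

otu   <- read_otu_table(system.file("extdata", "synthetic_community.tsv",
                                    package = "rareassembly"))
dates <- read_sample_metadata(system.file("extdata", "synthetic_metadata.tsv",
                                          package = "rareassembly"))

otu       <- otu |> rarefy(depth = 2988, seed = 1) |> remove_singletons()
summaries <- summarize_taxa(otu)
partition <- classify_taxa(summaries, cohort_thresholds())
cohort_summary(partition, summaries)
#> # A tibble: 4 × 4
#>   cohort            n_otus pct_otus pct_reads
#>   <fct>              <int>    <dbl>     <dbl>
#> 1 transient_rare       125    43.1       2.26
#> 2 persistent_rare       79    27.2      33.0
#> 3 intermediate_rare     60    20.7       6.64
#> 4 common                26     8.97     58.1
```

43% of the OTUs are transient-rare but they carry only 2.3% of the
reads — the classic rare-biosphere pattern. Fitting the neutral model:

```r
fit <- fit_ncm(summaries, N = 2988)
fit
#> Sloan neutral community model fit
#>   Nm = 274.6 (m = 0.09191), N = 2988, d = 0.000232
#>   generalized R2 = 0.8998; 244 taxa fitted (46 excluded at p in {0,1})
#>   envelope (95%): above = 59, below = 7, within = 178
partition_by_envelope(fit, partition)
#> 1 transient_rare    below        7   0.0886   0.271
#> 2 transient_rare    within      72   0.911    0.729
#> ...
#> 7 common            above       13   0.5      0.303
#> 8 common            within      13   0.5      0.697
```

The fitted migration parameter (Nm ≈ 275) recovers the generator's
Nm = 300 within 10%, and the transient-rare cohort sits inside the 95%
envelope far more often (91%) than the common cohort (50%) — rare taxa
look neutral, abundant taxa do not, mirroring the pattern reported for
real bioreactor communities. `autoplot(fit)` draws the standard
occurrence-vs-abundance figure with the envelope.

Beta-null deviations and the time-decay regression complete the picture:

```r
beta_null_deviation(otu, partition, iterations = 199, seed = 2)
#> Beta-null deviation (199 iterations)
#>   common: mean per-sample deviation = 0.1520
#>   transient_rare: mean per-sample deviation = 0.4132
#>   cohort comparison (Mann-Whitney): p = 3.658e-05

time_decay(otu, dates, permutations = 999, seed = 3)
#> Time-decay fit: log10(similarity) = -0.1909 +0.003321 * log10(lag days)
#>   66 pairs (0 dropped), permutation p = 0.526
```

This fixture has no temporal drift, and the time-decay slope is
correctly indistinguishable from zero. `run_pipeline()` executes all of
the above (plus the SAD fits and the sensitivity grid) in one call and
`write_pipeline_results()` writes every table, a JSON summary per fit,
and a `manifest.json` recording seeds and decision flags.

## Limitations

The neutrality fraction conflates model misfit with estimation noise
when the number of samples is small and dispersal limitation strong; the
methods vignette (`vignettes/rare-taxa-assembly.Rmd`) quantifies this
and documents every numerical choice, including the depth-matched
detection limit d = 1 − 2^(−1/N) and the Bray–Curtis substitution for
phylogenetic (UniFrac) distances, which are out of scope.
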