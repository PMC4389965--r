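# evi1kit

Tools for studying transcription-factor-mediated gene repression in myeloid
cells, built around the EVI1/MS4A3 regulatory axis. EVI1 is a zinc-finger
transcription factor whose overexpression marks a particularly aggressive
subset of acute myeloid leukaemia (AML); MS4A3 is a candidate direct target
repressed by it. `evi1kit` implements, as reusable tibble-in/tibble-out
functions, the complete computational workflow for establishing such a
regulatory relationship:

1. **Regulated-gene calling** from a tet-off induction time course.
   Two inducible clones (E10, E14) and two control lines (P2, U937T) are
   profiled with and without tetracycline. A probe set is kept when its
   average log2 intensity is ≥ 3 in every named (line, time) condition,
   and called regulated when |log2 FC| ≥ 1 (two-fold) at 24 h and 48 h in
   both clones with one consistent sign, **and** the 48 h effect in each
   clone exceeds the background effect of tetracycline withdrawal:
   |log2FC₄₈| ≥ 10^(|log2FC₄₈|/3) · max(|control log2FC₄₈|). Multiple probe
   sets per gene collapse to the most pronounced one; genes are ordered by
   descending mean 48 h fold change for heatmap display.
2. **Cohort anti-correlation** (the patient-data statistic). The splitter
   gene's log2 expression density is estimated with a Gaussian KDE; the
   cutoff sits at a density minimum (with several minima, the minimum
   closest to the low-expression mode having < 5% of the maximal density).
   The high group is then compared to 10,000 randomly sampled, equally
   sized low-expression groups: with dᵢ the per-iteration difference in
   mean response expression, the test reports M = mean(dᵢ), SD = sd(dᵢ),
   **Z = −M/SD**, and the two-sided normal p-value 2(1 − Φ(|Z|)).
   Repression shows up as M < 0, Z > 0.
3. **Promoter motif scanning** with information-weighted PWM similarity:
   ci(l) = (100/ln 4) Σ_b f(b,l) ln f(b,l) + 100 weighs each position, and
   a window scores Σ ci(l) f(b_l,l) / Σ ci(l) f_max(l) ∈ [0, 1]. Detection
   thresholds are calibrated on background sequence to allow one binding
   site per 10 kb.
4. **Term-for-term GO enrichment** with one-sided Fisher exact tests and
   Benjamini–Hochberg adjustment (significant at adjusted p < 0.1).
5. **ΔΔCт qPCR quantification** with technical-replicate averaging and
   SEM over biological replicates.

A first-class synthetic-data module (`simulate_timecourse()`,
`simulate_cohort()`, `simulate_promoters()`, `simulate_go_annotations()`,
`simulate_qpcr()`) generates every input with known planted structure, so
the whole pipeline runs and is validated without any external downloads.

## Worked example

```r
library(evi1kit)

# a cohort of 220 patients: bimodal splitter, planted 1.0 log2 repression
cohort <- simulate_cohort(cohort_design(seed = 11))
fit <- cohort_association(cohort, n_iter = 10000, seed = 11)
tidy(fit)
#> # A tibble: 1 × 9
#>   cutoff n_high n_low pct_high     M    SD     Z p_two_sided    p_2sf
#>    <dbl>  <int> <int>    <dbl> <dbl> <dbl> <dbl>       <dbl>    <dbl>
#> 1   6.77     20   200      9.1 -1.05 0.107  9.76    1.71e-22 1.70e-22
```

The KDE cutoff (6.77) falls between the planted modes at 4 and 9; 20 of
220 patients (9.1%) are high expressors; the mean resampled difference M
recovers the planted −1.0 log2 repression, and Z = −M/SD ≈ 9.8 rejects the
null decisively. `autoplot(fit)` shows the density with the cutoff;
`autoplot(fit$bootstrap)` the resampled-difference histogram.

```r
# the induction time course: 500 probe sets, 20 induced + 20 repressed
tc <- simulate_timecourse(timecourse_design(seed = 7))
calls <- regulated_genes(tc$expr, tc$meta, tc$probe_map)
head(dplyr::select(calls, gene, probe_id, direction, mean_fc_48h))
#> # A tibble: 6 × 4
#>   gene  probe_id  direction mean_fc_48h
#>   <chr> <chr>     <chr>           <dbl>
#> 1 G0218 PS0218_at up               3.89
#> 2 G0271 PS0271_at up               3.83
#> 3 G0415 PS0415_at up               3.75
#> 4 G0194 PS0194_at up               3.66
#> 5 G0323 PS0323_at up               3.36
#> 6 G0392 PS0392_at up               3.24
```

38 of the 40 planted probe sets are recovered (the misses sit at the soft
edge of the two-fold rule), none of the 460 null probe sets is called, and
`plot_regulation_heatmap(calls)` draws the fold-change heatmap in
descending 48 h order. `run_pipeline(pipeline_config(seed = 1), out_dir)`
executes all five stages end to end and writes TSV/BED/FASTA outputs plus
a JSON manifest of parameters, seeds and file hashes.

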