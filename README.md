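# seroMAD

Robust seropositivity calling and prevalence analysis for antigen-array
autoantibody profiling.

## What problem this solves

Affinity-proteomics screens (planar antigen arrays and suspension bead
arrays) measure IgG reactivity of serum samples against panels of protein
fragment antigens, reporting a raw median fluorescence intensity (MFI) per
sample × antigen. Absolute intensities are not comparable across samples:
each serum carries its own background level and scale. The analysis problem
is to decide, per sample, which antigens are truly reactive
("seropositive"), and then to compare seropositivity prevalence between
clinical groups — for example patients with ANCA-associated vasculitis (AAV)
versus healthy controls, or anti-MPO–positive MPA patients versus
anti-PR3–positive GPA patients.

`seroMAD` implements the full analysis chain for this kind of study, aimed
at researchers analysing bead-array serology cohorts:

* **Per-sample robust cutoff**: an antibody is called reactive in sample *s*
  when its intensity exceeds `median(x_s) + n · MAD(x_s)`, where `x_s` is
  the vector of that sample's intensities across all antigens on the array,
  MAD is the (unscaled) median absolute deviation, and `n` is an
  assay-specific multiplier (30 for planar arrays, 50 for a targeted bead
  array, 20 for a dense kinesin-family bead array).
* **nMAD normalization**: `nMAD_i = (x_i − median(x_s)) / MAD(x_s)`, the
  scale-free deviation score used for dot plots, heatmaps and intensity-based
  classification. Thresholding nMAD scores at `n` is exactly equivalent to
  the binary calling above.
* **Autoantibody load**: reactive antigens per sample, compared between
  groups with Mann–Whitney–Wilcoxon / Kruskal–Wallis rank tests and
  correlated with clinical covariates (age, BVAS) by Spearman rank.
* **Prevalence scans**: per-antigen 2×2 tables tested with Fisher's exact
  test (sample odds ratio, optional Benjamini–Hochberg adjustment), with a
  percentage-unit prevalence-gap filter for reporting.
* **Combination panels and ROC**: k-of-n panel positivity rules, intensity
  (summed nMAD) and binary (count of positive members) panel scores, ROC
  curves with trapezoidal/Mann–Whitney AUC, Youden and fixed-specificity
  operating points, and paired stratified-bootstrap comparison of two curves.
* **ELISA verification**: optical-density positivity against the
  mean + 3 SD cutoff in healthy controls, plus cross-platform concordance.
* **Longitudinal analysis**: matched diagnosis/remission/relapse series,
  Wilcoxon signed-rank on load and exact McNemar on per-antigen serostatus.
* **Synthetic cohorts with known truth**: a generator of bead-array-like
  cohorts (lognormal backgrounds, per-sample scales, site batches, planted
  seropositives with group-specific prevalence, matched longitudinal
  samples) so that every stage of the pipeline can be validated against a
  planted ground truth.

Data live in a `SeroExperiment`, a `SummarizedExperiment` subclass with
antigens in rows and samples in columns (assays `MFI`, `calls`, `nmad` and —
for simulated cohorts — `truth`).

## Worked example

```r
library(seroMAD)

# a targeted-screen-shaped cohort: 126 AAV + 168 HC x 151 antigens
se <- simulateCohort(studyPhaseConfig("phase2", seed = 1))
se
#> SeroExperiment: 151 antigens x 294 samples
#>   assays: MFI, truth
#>   groups: AAV=126, HC=168

se <- callReactivity(se)            # median + 50 x MAD (assay default)
se <- nmadNormalize(se)
summary(autoantibodyLoad(se))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.000   3.000   4.000   4.235   5.000  10.000

res <- comparePrevalence(se, "group", c("AAV", "HC"))
head(res[order(res$p), c("antigen_id","a","c","prevalence1","prevalence2","odds_ratio","p")], 3)
#>     antigen_id a  c prevalence1 prevalence2 odds_ratio          p
#> 98       AG098 0  9 0.000000000 0.053571429 0.06636156 0.01160299
#> 30       AG030 1 11 0.007936508 0.065476190 0.11418182 0.01523777
#> 149      AG149 6  1 0.047619048 0.005952381 8.35000000 0.04484813
```

A typical simulated sample carries a median of 4–5 reactive antigens; the
scan reports, per antigen, the positive counts in each group (`a`, `c`), the
group prevalences, the sample odds ratio and the exact two-sided p-value.
A 6/126-vs-1/168 table, as in the third row above, yields p ≈ 0.045:

```r
fisherExact2x2(6, 119, 1, 167)$p
#> [1] 0.04465351
```

Panels and ROC:

```r
panel <- AntibodyPanel(c("AG001", "AG002", "AG003"), k = 1)   # >=1 of 3
pos <- panelCall(se, panel)
roc <- rocCurve(panelScore(se, panel),
                SummarizedExperiment::colData(se)$group == "AAV")
auc(roc); operatingPoint(roc, "fixed_specificity", value = 0.9)
```

The full chain (QC → calling → normalization → scans → panels → PCA →
longitudinal) is wrapped in `runPipeline()`, and `exportReportTables()`
writes plain TSV/JSON tables (calls, nMAD scores, cutoffs, loads, prevalence
tables, ROC points, QC exclusions, resolved config) for plotting tools.

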