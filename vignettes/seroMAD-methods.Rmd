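---
title: "seroMAD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seroMAD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `seroMAD`, the
reasoning for its defaults, and what the simulation-based validation does
and does not establish.

# The calling model

## Per-sample robust cutoffs

Raw antigen-array readouts (median fluorescence intensity, MFI, in
arbitrary units) are not comparable across sera: each sample has its own
background level, driven by total IgG content, dilution accuracy and
nonspecific binding. The package therefore thresholds each sample against
its own distribution across the antigens of one array:

$$\mathrm{cutoff}_s = \mathrm{median}(x_s) + n \cdot \mathrm{MAD}(x_s),$$

where $x_s$ is sample $s$'s intensity vector across all antigens,
$\mathrm{MAD}$ is the median absolute deviation from the sample median, and
$n$ is an assay-specific multiplier. A value is called reactive when it
*strictly exceeds* the cutoff. The matching normalization is the per-value
deviation score

$$\mathrm{nMAD}_{i,s} = \frac{x_{i,s} - \mathrm{median}(x_s)}{\mathrm{MAD}(x_s)},$$

so that strict-greater calling at multiplier $n$ is algebraically identical
to thresholding nMAD scores at $n$ (an identity the test suite verifies on
random matrices). Both statistics are invariant to rescaling a sample by
any positive constant, which is exactly the property that makes per-sample
calling robust to serum-specific background. The implicit assumptions are
that (i) only a small minority of antigens are truly reactive in any one
sample, so median and MAD estimate the background, and (ii) reactive values
are far in the right tail. If a serum were broadly polyreactive (say a
third of the antigens truly bound), the background estimate would inflate
and sensitivity would drop; the median/MAD pair tolerates roughly up to
50% contamination in principle but degrades well before that.

Key choices:

* **MAD constant.** The MAD is used *unscaled* by default — no 1.4826
  normal-consistency factor — because the cutoff formula is defined
  directly in MAD units, not as a Gaussian-SD surrogate. The constant is
  available as a flag (`madConstant = TRUE`); enabling it is equivalent to
  multiplying $n$ by 1.4826.
* **Strictness.** Ties with the cutoff are negative (strict `>`). With
  continuous MFI data ties are measure-zero; with quantized exports this is
  the conservative direction.
* **MAD = 0 samples.** A constant (or majority-constant) sample has an
  undefined score. Such samples are flagged *degenerate* and excluded from
  calling by default (`NA` calls, logged); a configurable fallback
  substitutes the smallest nonzero per-sample MAD in the cohort instead.
  Exclusion is the default because an auditable gap is preferable to a
  silently imputed denominator.
* **Assay-specific multipliers.** The presets are 30 (untargeted planar
  array), 50 (targeted bead array) and 20 (kinesin-family bead array),
  exposed via `defaultNFactor()`. Where the multiplier has to be chosen
  from data, `selectNFactor()` makes the choice explicit and deterministic:
  among a candidate grid it returns the smallest multiplier under which no
  antigen's cohort-wide positivity exceeds a configured cap, with a
  per-candidate diagnostic table. This is a surrogate for an
  informally-described per-assay tuning step; the published multipliers are
  available as fixed presets, and all results in this package use them.

## QC

One sample in the motivating study design is excluded "for technical
reasons" without a stated rule. The package's stand-in is deterministic and
auditable: a sample is dropped when fewer than a configurable fraction
(default 0.9) of its antigen measurements are valid (finite, strictly
positive), and every exclusion is recorded with its observed fraction in the
object's metadata and exportable as JSON lines. The rule is idempotent.

# Group statistics

* **Prevalence comparisons** use Fisher's exact test on the per-antigen
  2×2 table (positives/negatives × group). Two-sided p-values follow the
  minimum-likelihood convention (the sum of point hypergeometric
  probabilities not exceeding the observed table's), which is the
  convention of mainstream statistical software; the test suite checks the
  implementation against full fixed-margin enumeration on every table with
  total count ≤ 24. The reported effect size is the unconditional sample
  odds ratio $(ad)/(bc)$; when a cell is zero the Haldane 0.5 correction is
  applied to all cells and flagged. Reporting additionally filters on a
  prevalence *gap* in percentage units (default 10), mirroring the
  convention of reporting antigens with "at least 10 percentage units
  higher reactivity".
* **Multiple testing** is off by default — the primary analyses report raw
  exact p-values, as the motivating analyses did — with Benjamini–Hochberg
  q-values available by flag. This is a deliberate faithfulness choice, not
  a statistical recommendation: a 118–151-antigen scan at α = 0.05 will
  produce false positives, and the BH option exists precisely so users can
  quantify that.
* **Load comparisons** use `stats::wilcox.test` (exact when group sizes
  permit and no ties are present, otherwise the normal approximation with
  tie and continuity correction) and `stats::kruskal.test` for >2 groups.
  Covariate checks (age, BVAS) use Spearman rank correlation with listwise
  deletion; missing clinical values are never imputed.
* **Batch checks** use a plain column-centred PCA (`prcomp`) of the nMAD
  matrix with samples as observations; degenerate samples' missing scores
  are mean-imputed per antigen before decomposition and the imputed
  fraction is reported alongside.

# Panels and ROC

Combination panels are k-of-n rules over named antigens. Because the
source analyses never state how member intensities were combined for the
intensity-data ROC, the package exposes three explicit scores — summed nMAD
(default), maximum nMAD, and the count of positive members (the "binary
data" score, which produces the stepwise curve a 0–3-valued score implies)
— rather than pretending to reconstruct an unstated rule.

The ROC sweep places thresholds at midpoints between adjacent unique score
values with strict-greater prediction, so tied scores contribute ½; the
trapezoidal AUC is then exactly the Mann–Whitney probability. The package
computes the curve by direct sweep and the test suite independently
verifies the AUC against a pairwise-count oracle and against `pROC`.
Curve comparison uses a paired nonparametric bootstrap over samples,
stratified by class so that no resample loses a class entirely, with a
percentile CI and a two-sided p from the position of zero in the
AUC-difference distribution; B defaults to 2000 and the whole procedure is
deterministic given a seed.

# ELISA verification and longitudinal tests

ELISA positivity uses the conventional mean + 3 SD cutoff computed from
healthy-control OD450 readings (sample SD, n − 1 denominator — the
convention for small control panels; the source does not specify), with
strict exceedance and controls never called. Cross-platform agreement
between bead-array and ELISA calls is tabulated and tested with the same
exact Fisher machinery.

The longitudinal comparisons are declared surrogates: the motivating study
reports "no difference" across disease stages without naming tests, so the
package uses the two standard nonparametric paired tests consistent with
the rest of the toolkit — Wilcoxon signed-rank on within-subject load
differences (zeros dropped; an all-zero difference vector is reported as
p = 1 with a degenerate flag) and an exact McNemar binomial test on
discordant serostatus pairs. Relapse samples are treated descriptively by
default (n = 5 in the emulated design is too few to test).

# The synthetic cohort generator

The generator exists so that calling, scanning, panel and longitudinal code
can be validated against known truth. Its model: intensity of sample $s$,
antigen $a$ is

$$x_{s,a} = \exp\!\big(\mu + \alpha_a + \sigma_s + \beta_{\mathrm{site}(s)}
 + T_{s,a} \, b_{s,a} + \varepsilon_{s,a}\big)$$

with antigen background locations $\alpha_a \sim N(0, 0.5)$ around
$\mu = \log 500$ (arbitrary MFI units), per-sample scales
$\sigma_s \sim N(0, 0.2)$, site batch effects
$\beta \sim N(0, 0.05)$, measurement noise
$\varepsilon \sim N(0, 0.3)$, planted truth
$T_{s,a} \sim \mathrm{Bernoulli}(p_{g(s),a})$ and a seropositivity boost
$b \sim N(\log 50, 0.4)$. Lognormal, multiplicative structure is the
natural choice for strictly positive, right-skewed fluorescence data, and
it is exactly the regime in which median/MAD calling is the appropriate
detector. The raw intensity scale is arbitrary — no real MFI ranges are
published — which is immaterial because every statistic downstream is
scale-invariant; only the log-scale ratios matter. A between-antigen
location spread (`antigenLogSd`) is included even though a single shared
background would be simpler, because per-sample MADs in real arrays are
dominated by antigen-to-antigen background differences; without it the
cutoffs would be unrealistically tight.

The two presets mirror the emulated study designs: `phase2` with
126 AAV + 168 HC samples × 151 antigens, and `phase3` with 126 AAV
diagnosis + 65 matched remission + 5 relapse + 121 GCA + 63 PMR + 171 HC
samples × 118 kinesin fragments. Planted prevalences put most antigens at
a low background rate (0.028–0.03) with a handful of broadly reactive
fragments (up to 0.45) and group-enriched fragments (e.g. 0.40 vs 0.10 in
AAV for the strongest phase-3 antigen, and a deliberately weak
0.048-vs-0.006 phase-2 pair matching the modest published contrast), tuned
once so that a typical sample carries about five reactive antigens — the
reported median autoantibody load. Longitudinally, a diagnosis positive
persists into remission with probability 0.9 (reflecting the reported
stability of serostatus across disease stages) and relapse reuses the
diagnosis truth.

Clinical covariates (ANCA serotype, phenotype, sex, age, treatment, BVAS,
organ flags) are drawn from plausible marginal distributions and are, by
construction, independent of the planted antibody truth; they exist so that
subgroup machinery has realistic inputs, not to encode real associations.

**Determinism.** One root seed governs a run; per-stage and per-group
substreams are derived from it by a fixed integer hash, so adding a group
to a design never perturbs the draws of the other groups (verified in the
tests). Identical configuration and seed reproduce every output
bit-for-bit.

**What passing tests do and do not show.** The generator emulates
per-sample scale variation, heavy-tailed backgrounds, sparse strong
positives, batch structure and matched timepoints. It does not emulate
antigen cross-reactivity networks, tag-binding chemistry, bead-count
sampling noise, plate-layout artefacts, or covariate–antibody
associations. Recovery of planted truth (sensitivity ≥ 0.95,
specificity ≥ 0.99 at the preset effect size) therefore validates the
*implementation* of the calling chain under the stated noise model; it is
not evidence about sensitivity or specificity on real sera, where effect
sizes and backgrounds are unknown.

# Validation choices and problem sizes

* The Fisher implementation is checked against exhaustive fixed-margin
  enumeration over all 2×2 tables with total ≤ 24, and against the four
  fully specified published tables (6/125 vs 1/168 → 0.045; 20/125 vs
  17/168 → 0.156; 21/33 vs 13/55 → 0.0003; 8/33 vs 1/55 → 0.0014, at
  printed precision).
* Type-I calibration of the prevalence scan is assessed on null cohorts
  (identical group prevalences) pooled over three seeds of the phase-2
  design; the empirical rejection rate at α = 0.05 is compared to the
  binomial 99% band around 0.05. Exact tests at low prevalence are
  discretely conservative, so rates modestly below 0.05 are expected and
  fall inside that band.
* Per-(group, antigen) prevalence recovery is evaluated on
  diagnosis/single-timepoint samples (where the configured probabilities
  apply directly); each of the ~472 pairs is compared to its binomial 99%
  interval, and since about 1% of pairs miss by chance under perfect
  calling, the test requires at least 97% inside rather than all.
* Simulation sizes throughout (phase-2/phase-3-shaped cohorts, a few
  hundred samples, ≤ 3 seeds per property) are chosen to make the binomial
  bands informative while keeping the default test run fast.
* Cohort-dependent published quantities — the exact median-load value,
  subgroup p-values such as 0.002/0.0008/0.0005, and the ROC operating
  points (89.1%/57.6% intensity, 76.4%/63.3% binary) — derive from
  access-restricted clinical data and are not reproducible from any
  simulation; the package covers them qualitatively (loads in the right
  regime, planted subgroup effects recovered, operating-point machinery
  exercised) and makes no numeric claim about them.

# Known limitations

* The n-factor selection procedure is a documented surrogate, not a
  reconstruction of the original per-assay tuning.
* Per-antigen (column-wise) cutoffs are deliberately out of scope: the
  calling model is per-sample only.
* Only IgG-style single-readout arrays are modelled; no isotype handling,
  titer estimation or standard-curve fitting.
* The exact McNemar/signed-rank longitudinal tests assume exchangeable
  pairs; informative dropout between diagnosis and remission is not
  modelled.
* Vendor-native binary exports, bead-count QC and plate layouts are not
  parsed; inputs are plain CSV/TSV matrices.
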