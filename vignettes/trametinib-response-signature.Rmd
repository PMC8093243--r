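---
title: "Predicting MEK-inhibitor response from transcriptional signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MEK-inhibitor response from transcriptional signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupsig)
```

This vignette documents the models behind `cupsig`, the parameters that
matter, the choices made where conventions diverge, and what the synthetic
benchmarks do and do not demonstrate.

## The problem

Cancers of unknown primary (CUP) often carry constitutive MAPK signaling
without a canonical *BRAF*/*RAS* mutation, so a mutation test is a poor
guide to MEK-inhibitor (trametinib) sensitivity. The alternative pursued
here is transcriptional: learn which genes mark *resistant* cell lines from
a panel with measured drug response, then ask in any new profile whether
those resistance markers sit near the top (resistant) or bottom
(sensitive) of the expression ranking.

## Expression preprocessing

Counts (3'-tag style) are normalized to counts per million:
$\mathrm{CPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$. Two filters are
available, both with strict inequalities as conventionally printed:

* panel QC: drop genes with mean CPM < 5 or duplicated-read percentage
  > 20% (the duplication criterion is skipped with a warning when the
  pipeline upstream did not report it, as external matrices rarely do);
* cohort filter: drop genes with mean CPM < 1 across all samples.

Cohort profiles are averaged across replicates (arithmetic mean), then
z-scored. Two z-scoring conventions exist and the source material for this
pipeline names neither, so both are implemented:

* `per_gene_across_samples` (default): each gene is centered/scaled over
  the cohort. Rationale: within-sample rankings of raw abundance are
  dominated by housekeeping genes; removing the per-gene baseline makes
  the ranking reflect *relative* activity, which is what a resistance
  signature should read.
* `per_sample_across_genes`: standardizes each profile; exposed as a flag.

The variance uses the sample (n − 1) denominator, so tests can be exact.
Zero-variance genes are dropped with a warning rather than emitting NaNs.
By default CPM is transformed to log2(CPM + 1) before scaling — not stated
in the original description but standard variance stabilization for
count-derived data; `log2_transform = FALSE` disables it.

## Signature construction

With a joined panel (expression + AUC for the same lines; lower AUC =
more sensitive):

1. **Correlation screen.** Per gene, the Pearson correlation between
   log2(CPM + 1) expression and AUC across lines. The log transform is a
   package choice (the original pipeline reports only "normalized
   counts"); correlations on heavy-tailed raw CPM would be driven by a few
   high-expression lines.
2. **Shortlist.** The top 1000 genes by PCC (largest first; ties broken by
   gene ID, documented so the selection is a pure function of the data).
3. **Extreme labeling.** Sensitive = AUC ≤ 5th percentile, resistant =
   AUC ≥ 95th percentile, with `stats::quantile` type 7 (linear
   interpolation). The source wording "5% quartile" is read as the 5th
   percentile — a quartile cannot be 5% — and the percentile reading
   reproduces the intended tail sizes (5 + 5 lines of 100).
4. **RFE-SVM.** On the extreme lines only, iterate: standardize each
   feature (mean 0, unit variance over these lines), fit a linear
   soft-margin SVM (`kernlab::ksvm`, `vanilladot`, C = 1), rank features
   by |w|, drop the lowest ceil(10% × current) without overshooting the
   target of 500, and refit. The elimination schedule, C, and per-round
   re-standardization are not recorded in the original description; fixed
   defaults are chosen for reproducibility and exposed as arguments. The
   returned order (final |w| descending) is metadata: the signature is
   consumed as an unordered gene set.

## Enrichment scoring and significance

For a ranked profile $r$ (statistics sorted non-increasing, ties broken by
gene ID) and a set $S$ with $k$ members present among $N$ genes, the
running sum gains $|s_i|^p / \sum_{j \in S} |s_j|^p$ at members and loses
$1/(N-k)$ elsewhere; the enrichment score ES is the signed maximum
deviation from zero (positive branch wins an exact tie), with the weight
exponent $p = 1$ by default. The engine evaluates the sum only at member
positions (O(k) after ranking); the test suite verifies exact agreement
with a literal O(N) walk and with `fgsea` on random instances.

The null is by gene-label permutation — `nperm` random same-size sets from
the profile (default 10,000; analysis drivers use 500–1000, see problem
sizes below) — because phenotype permutation is undefined for a single
profile. The p-value is the two-sided magnitude test with add-one
smoothing:

$$p = \frac{1 + \#\{|ES_{null}| \ge |ES_{obs}|\}}{nperm + 1}.$$

Design note: a one-sided count over a full-`nperm` denominator (counting
only same-sign nulls but dividing by all of them) is *not* uniformly
distributed under the null — it concentrates below ~0.5 and roughly
doubles the type-I error at nominal α. The two-sided magnitude form keeps
the floor at 1/(nperm + 1) and is calibrated, which the acceptance checks
verify empirically (type-I error within [0.03, 0.07] at α = 0.05). NES is
reported as ES divided by the mean |null ES| of the same sign, but
significance always uses the permutation p with Benjamini–Hochberg FDR
across whatever family is tested: the sets of a collection for gene-set
scoring, or the samples of a cohort for response prediction (one test per
sample against the single signature). Significance is strict:
FDR < 0.10, so FDR = 0.10 exactly is not significant.

A positive significant ES calls the sample resistant (resistance markers
highly expressed), negative sensitive, otherwise indeterminate. In
validation against an IC50 truth rule (sensitive iff IC50 < 1 µM),
indeterminate predictions count as errors in their truth class — a
conservative accounting, since the original report does not state how
non-significant lines were counted — and the headline number is the macro
average of the two per-class accuracies.

## Limiting-dilution and qPCR statistics

The single-hit model gives $P(\text{positive well} \mid \text{dose } n) =
1 - e^{-fn}$; the Poisson/complementary-log-log form is used (rather than
$1-(1-f)^n$; they agree to O(f²)) because it makes the fit an
intercept-only binomial GLM with cloglog link and offset $\log n$, with
$\hat f = e^{\text{intercept}}$ and a Wald 95% CI on the log scale. A
single dose has the closed form $\hat f = -\ln(1-\hat p)/n$, which the GLM
reproduces to 1e−6 (tested over random cases). Saturated doses are routine
and the GLM's fitted-probability warnings are muffled; genuinely
degenerate plates are handled explicitly (all-positive → error, the
frequency is unbounded; all-negative → $\hat f = 0$ with a one-sided upper
bound and a boundary flag). Two experiments are compared by a 1-df
likelihood-ratio (chi-square) test of shared vs separate frequency.
Profile-likelihood intervals and multi-group simultaneous fits are out of
scope.

Copy number: ΔΔCt = (Ct_target − Ct_norm)_sample − (Ct_target −
Ct_norm)_calibrator, ratio = 2^−ΔΔCt (1 = biallelic), allelic loss called
iff ratio < 0.7, strictly. Tumor volume is d²·D/2 (minor² × major / 2,
mm³), fold changes are ratios to the day-0 baseline per animal, and
viability is mean(treated)/mean(control) over ≥ 6 technical replicates
(fewer replicates warn rather than fail).

## The synthetic panel generator

`simulate_ccl_panel()` emulates the joint structure the signature build
assumes: a latent resistance score $r_i \sim N(0,1)$ per line shifts the
log2 expression of planted marker genes ($\beta$ per unit score, default
1.0) and the response ($AUC = \alpha + \gamma r_i + \eta$, $\gamma = 1.0$),
with N(0, 0.5) noise on both — giving marker–AUC correlations around 0.8,
a strong but not degenerate planted signal. Baselines are $\mu_g \sim
N(5, 2)$ on the log2 scale and counts are multinomial at a ~10⁶ library,
a deliberately simple log-normal/multinomial model: dispersion beyond
Poisson, batch effects, FFPE degradation, 3'-bias, and real gene–gene
correlation structure are *not* simulated, so passing benchmarks show the
pipeline's selection and calibration machinery works under its stated
assumptions — not that the signature generalizes to real cohorts. A
held-out panel shares planted markers with its training panel via the
`markers` argument (the biology is fixed; only sampling varies).
`simulate_cohort()` plants ±2 z-unit signature shifts on N(0,1) profiles;
`simulate_lda()` draws binomial wells under the single-hit model. All
generators are pure functions of (parameters, seed) and restore the
caller's RNG stream.

## Problem sizes and numerical choices

The benchmarks run at: 300 training / 100 held-out lines × 2000 genes with
100 planted markers; 1000 → 500 RFE; nperm = 199–1000 for permutation
nulls (2000 draws for type-I calibration); 1000 simulated plates for CI
coverage. These sizes keep every property measurable with comfortable
margins (e.g. hypergeometric SDs for null marker counts, binomial SEs for
coverage) at desk-scale runtimes. Ties in rankings and eliminations are
always broken by gene ID; seeds are explicit arguments everywhere;
quantiles are type 7. Degenerate inputs (constant AUC, zero-variance
genes, empty intersections, boundary plates) raise errors or flagged
results rather than silent numbers.

## Known limitations

* Plain CPM only: the original normalization names edgeR without
  specifying whether TMM scaling was applied; TMM would be a
  straightforward extension but is intentionally not silently implied.
* The validation treatment of indeterminate lines is conservative; on
  panels where most lines are mid-response, many calls are indeterminate
  and the macro accuracy under this accounting is correspondingly low —
  the informative regime is the response extremes.
* The permutation null is over gene labels; it tests whether the
  signature's placement is unusual *within a profile*, not cohort-level
  hypotheses.
* Real-data effects (batch, platform, FFPE quality) are outside the
  generator's scope; applying the pipeline to real cohorts needs the
  usual upstream QC.
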