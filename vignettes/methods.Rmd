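---
title: "Methods: from summary statistics to transcriptomic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from summary statistics to transcriptomic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrxome)
```

mrxome chains two-sample Mendelian randomization (MR) with downstream
transcriptomic scoring: trait-level MR establishes a causal exposure-outcome
link; a per-gene QTL screen classifies genes as risk (OR > 1) or protective
(OR < 1); single-sample GSEA turns those gene lists into per-patient risk
scores compared across disease-activity groups; and regulon and immune-cell
layers characterize what differs between active and inactive patients. This
vignette records the models, the tunable parameters, and the design choices
made where the method descriptions left the design open.

## Instrument selection and harmonization

Instruments are variants strongly associated with the exposure, independent
of confounders, and affecting the outcome only through the exposure.
Exposure and outcome tables are merged on variant id; when allele codings
are swapped the outcome effect is negated and its allele frequency
complemented. Strand-ambiguous (palindromic A/T, C/G) variants are dropped
when either allele frequency is missing or within [0.42, 0.58] — a
conservative, conventional window; the source method descriptions are
silent on the policy, so it is a package choice, exposed in the audit
trail.

Selection order is fixed: variants directly associated with the outcome
(`p_outcome < 5e-6`) are removed first; the exposure threshold `p < 5e-8`
with greedy LD clumping at `r^2 = 0.001` is applied; if fewer than 20
instruments survive, the fallback tier `p < 5e-6` / `r^2 = 0.01` restarts
from the post-outcome-removal candidates; weak instruments
(`F = (beta/se)^2 < 10`) are dropped; finally a user-supplied exclusion
list removes confounder proxies (a reproducible local stand-in for a live
Phenoscanner screen; the confounders of interest in the motivating setting
are mechanical stress, infections and psoriasis). The clumping threshold is
read as a squared correlation: a raw correlation of 0.001 would be
indistinguishable from independence, while `r^2 = 0.001` is the
conventional default of the standard MR toolchains. Clumping uses the LD
matrix only (no base-pair windows — positions are not part of the data
model), and breaks p-value ties by variant id so results are independent of
row order.

## Estimators and diagnostics

The fixed-effect inverse-variance-weighted (IVW) estimator is the primary:
`beta = sum(bx*by/se_y^2) / sum(bx^2/se_y^2)`, the zero-intercept weighted
least squares of outcome on exposure betas, with `se = sum(bx^2/se_y^2)^(-1/2)`.
With one instrument it reduces exactly to the Wald ratio `by/bx` with
first-order delta-method standard error `|se_y/bx|`. Effects are log-odds
throughout; odds ratios and 95% bounds `exp(beta +/- 1.96 se)` are derived
at reporting time. A multiplicative random-effects SE inflation is available
as an option but is not the default, because the fixed-effect form is the
printed estimator. P-values are two-sided normal throughout.

Diagnostics: MR-Egger (weighted regression with free intercept; the
intercept tests directional pleiotropy; coefficient variances carry a
`max(1, RSE^2)` overdispersion factor, the method's original convention);
Cochran's Q on the per-variant ratios with chi-square reference on K-1 df;
and MR-PRESSO. The MR-PRESSO global statistic is the weighted residual sum
of squares of leave-one-out-predicted outcome betas, ranked within `n_sim`
(default 1000, seed mandatory) parametric draws
`by_k* ~ N(beta_ivw(-k) * bx_k, se_y_k)`; per-variant outliers use the
same simulated per-variant residuals with Bonferroni adjustment, and the
distortion test references the estimate change after outlier removal to
random same-size removals. Because the null draws are centered on the
observed leave-one-out fits, the global test is mildly conservative (its
measured size is about 0.04 at a nominal 0.05 under the package's null
generator); this is a property of the construction, not a calibration
knob.

## Per-gene screen and classification

Each gene's cis-QTL table is an exposure against the shared outcome. The
per-gene screen uses the strict tier only (`5e-8` / `r^2 = 0.001`, no
fallback): the fallback rule is described for the trait-level analysis
only, and the stricter reading is adopted deliberately. Significance uses
the raw p-value (a stated choice of the motivating analysis, accepting
~5% false positives among null genes to limit false negatives), and
classification is a pure function of the estimate: `risk` iff `p < 0.05`
and OR > 1, `protective` iff `p < 0.05` and OR < 1, otherwise `excluded` —
genes with OR exactly 1 or without surviving instruments are excluded, not
protective. Protein-level (pQTL) verification runs the identical machinery
and flags genes with the same significant direction in both screens as
concordant.

Differential expression uses a per-gene two-group linear model with
empirical-Bayes variance moderation: the posterior variance
`(d0*s0^2 + dg*s2_g)/(d0+dg)` is a convex combination of the gene variance
and a prior fitted by moment matching on the log residual variances
(matching the mean and variance of `log s2` against the theoretical
log-chi-square moments, with a Newton inversion of the trigamma function).
This reproduces the moderated-t construction of the standard array
toolchain; exact numeric equality with any particular package is not a
contract — the shrinkage property and p-value calibration are. BH
adjustment is applied across genes.

## Single-sample GSEA and group comparison

For one sample, genes are ranked by expression from largest to smallest
(ties broken by gene id, so constant profiles score deterministically). The
score integrates the difference between the in-set ECDF — each in-set gene
weighted by its rank-normalized magnitude raised to `alpha` — and the
uniform out-of-set ECDF. `alpha` defaults to 0.25, the convention of the
toolchain the motivating analysis cites; with `alpha = 0` the score is a
pure rank statistic, invariant to monotone transforms of a sample. Scores
are not renormalized across samples: the downstream group comparison is a
two-sided Wilcoxon rank-sum (exact null when the smaller group has at most
10 samples and there are no ties, normal approximation with continuity
correction otherwise), which is invariant to any monotone rescaling.

Two-group GSEA ranks genes by the signal-to-noise statistic, computes the
classical weighted Kolmogorov-Smirnov running-sum enrichment score, and
permutes sample labels (not genes) for the null; the normalized score
divides by the mean same-signed permuted score and the p-value is the
same-signed permuted tail. Ranking metric, permutation scheme and count
(default 1000) are package choices where the source is silent.

## Regulons by mutual information

TF-target dependence is measured by plug-in mutual information on
equal-frequency bins, with the bin count growing as the cube root of the
sample size (`max(2, floor(n^(1/3)))`). The bin count trades two errors:
too few bins discretize away real dependence (at `n = 2000`, `rho = 0.8`,
ternary binning recovers only ~57% of the closed form
`-0.5*log(1-rho^2)`), while a square-root rule gives a joint table with
on the order of `n` cells and the plug-in estimator's upward bias then
dominates (the same reference point estimates ~1.8x the closed form).
Cube-root binning keeps the cell count at `n^(2/3)` and lands within a
few percent of the closed form at that reference point, while reducing to
a coarse ternary low/mid/high discretization at typical cohort sizes
(tens of samples), where it also maximizes permutation power. Ties are
broken by first occurrence, which makes every
gene's marginal bin profile identical; consequently the permutation null
of MI against a shuffled regulator is the same for every candidate target,
and one `n_perm`-draw null per TF serves all genes (and doubles as the
bootstrap presence threshold).

Inference prunes in three steps: permutation significance at `alpha = 0.01`
(gene-wise, seeded); bootstrap stability — an edge must clear the null
threshold in at least 75% of 100 sample resamples; and
data-processing-inequality pruning — in each regulator-regulator-target
triangle the weakest edge is removed when below the smaller of the other
two minus `dpi_tol` (default 0; `Inf` disables pruning). Edge signs come
from the Spearman correlation. All operations are keyed on sorted ids, so
output is independent of input order given the seed.

A known limitation, verified by simulation: at 40 samples and a planted
TF-target correlation of 0.71 (effect strength 1 against unit noise), the
per-edge power of any coarse binned-MI permutation test at `alpha = 0.01`
is about 0.66-0.72 — a correlation-based detector would be near 1 — so
recall around 0.7, not 0.8+, is what this estimator can deliver at that
effect size; precision stays at or above 0.9. The binned-MI estimator is
retained because it is the method being modeled and admits an exact hand
oracle.

Regulon activity per sample is a signed two-arm single-sample enrichment:
the ssGSEA walk score of the positive targets minus that of the negative
targets, so negating all target signs negates activity. Phenotype
association uses the signal-to-noise-ranked gene list: one-tailed mode
tests the whole target set, two-tailed mode tests the two arms at opposite
ends (`ES(pos) - ES(neg)`), both against label permutations. This is a
declared construction: the source describes the intent (one- and
two-tailed regulon enrichment) without formulas.

## Immune-cell layer

Cell-type scores are ssGSEA scores per signature averaged per cell type
(unweighted). Spillover compensation solves `spillover * corrected = raw`
per sample by least squares with negative solutions clipped to zero; with
an identity matrix this is `max(raw, 0)`, a projection. The published
calibration of scores to abundances is out of scope: raw averaged scores
feed the correction directly, and signatures plus spillover matrix are
user-supplied inputs (synthetic in all tests).

The univariate screen is a logistic regression of the activity indicator
on each score (activity is binary, hence logistic; the source does not
name the family), with a rank-sum fallback under complete separation.
LASSO selection is an L1-penalized logistic path with lambda chosen by
cross-validated deviance under the 1-SE rule (a conservative convention
matching the goal of a small "most pertinent" set); fold assignment is
seeded. Gene-cell association uses Pearson correlation by default with a
Spearman option.

## The synthetic world

Every input has a generator, a pure function of its config (seed
included), returning truth objects alongside the data.

* GWAS pairs: per variant, the exposure effect is observed with noise
  `se_x`; the outcome effect is `beta_causal * gamma + alpha * [pleiotropic]`
  plus noise, with balanced (mean-zero) or directional pleiotropy — the
  flag exists because the Egger intercept is only powered under
  directional pleiotropy. Instrument strength is parameterized by a target
  F statistic (default 100, comfortably past the F = 10 filter, chosen so
  tests can plant weak instruments deliberately); allele pairs are
  non-palindromic and shared between tables so harmonization is lossless
  by construction. LD is identity unless block structure is requested.
* QTL catalogs: strong cis instruments per gene; a known subset of genes
  carries sign-randomized true effects with odds ratios in a configured
  range, so both risk and protective genes exist.
* Expression: baseline i.i.d. normal (array-like continuous data after
  normalization — deliberately not counts), 500 genes by default with
  12/12/12 active/inactive/control samples; risk genes shift up and
  protective genes down by `activity_effect` (in SD units) in active
  samples; TF targets are `effect_strength * tf + noise` with optional
  signs and a group effect on the TF itself; cell-signature genes shift
  per group by configured abundances. Defaults (unit noise, 1-SD effects,
  a 500-gene panel) were fixed once as a plausible miniature of a
  whole-blood array study; the panel is small so that planted effects
  occupy a realistic fraction (a few percent to ~10%) of the transcriptome.

What a green test establishes is limited by this world: genes are
independent given the planted structure (no co-expression background), LD
is block-toy, expression is Gaussian, and signatures do not overlap. Power
statements therefore certify the machinery, not performance on any real
cohort. BH-adjusted DE power in particular depends on how many genes are
truly shifted; power checks plant a realistic DE fraction (about 20% of a
small panel) rather than a single needle in a null haystack.

## Numerical and degenerate-input choices

Expression ranking ties break by gene id; clumping ties by variant id;
equal-frequency binning ties by first occurrence. Harmonization with an
empty variant intersection, selection with zero survivors, estimators
below their minimum instrument counts, empty gene-set intersections, and
singular spillover matrices are all hard errors with named subjects.
Summary-statistic writers serialize at full precision (`%.17g`) so
read-write round trips are exact. Seeds are mandatory wherever randomness
exists; the pipeline derives per-stage seeds by hashing stage names so a
stage can be rerun in isolation.

## Configuration format

The pipeline config is JSON (read via jsonlite); thresholds default to the
values above and any can be overridden per run. Reports are JSON for
structure and TSV for matrices, so the acceptance machinery can diff them.
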