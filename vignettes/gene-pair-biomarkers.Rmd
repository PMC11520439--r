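---
title: "Gene-pair relative-expression biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair relative-expression biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairdx)
```

## The problem

Transcriptome case/control studies rarely come from one platform. Pooling
cohorts measured on different arrays or sequencing chemistries confounds
any statistic built on absolute expression: per-gene intensities shift
with reagents, probes, and normalization pipelines, and those shifts are
usually correlated with the cohort — and therefore, in collections where
some cohorts are all-case or all-control, with the phenotype itself.
Batch-correction methods estimate and subtract these effects; `pairdx`
takes the complementary route of building features that never see them.

## The pair feature

For genes $i, j$ and sample $k$ with expression $g_{ik}, g_{jk}$, the
relative-expression feature is

$$r_{ijk} = I(g_{ik} - g_{jk}), \qquad
I(x) = \begin{cases} +1 & x > 0 \\ -1 & x \le 0. \end{cases}$$

Only the *within-sample ordering* of the two genes enters. Any strictly
increasing per-sample transformation — rescaling, log transforms, quantile
shifts, scanner gain — leaves every $r_{ijk}$ unchanged, so cohorts can be
column-concatenated after the transform with no numeric mixing and no
batch correction. Exact ties map to $-1$; ties have measure zero on real
intensity data but are common in small synthetic fixtures, so the
convention matters for reproducibility and is fixed here once.

Pair orientation is canonical (lexicographically smaller gene first),
fixed before any statistic is computed. The screen below is symmetric
under orientation and the model coefficients absorb the sign, so any
consistent convention is equivalent; fixing one makes serialized models
portable.

Enumerating all pairs is quadratic: 10,762 genes already yield
`n_possible_pairs(10762)` = 57,904,941 combinations. Candidate pairs are
therefore restricted to genes co-annotated in a pathway collection (GMT
format, e.g. KEGG from MSigDB), which keeps the feature space in the
thousands and biologically interpretable. Pairs are built on the genes
common to all cohorts in the analysis.

## Screening reversed pairs

A pair is informative when its $\pm 1$ state distribution differs between
cases and controls ("reversal"). Each pair's 2×2 table (state × group) is
tested with the two-sided Fisher exact test, using the minimum-likelihood
two-sided convention (sum of hypergeometric probabilities of all tables
with the observed margins that are no more probable than the observed
one, with the customary $1+10^{-7}$ comparison tolerance — stated so
independent implementations agree). Bonferroni correction runs over the
pairs actually tested (the post-deduplication candidate list, not the
57.9 M unrestricted pairs: only tested hypotheses are corrected), and
significance is declared at adjusted $p < 10^{-20}$.

The threshold is deliberately extreme. Pooled cohort collections carry
residual label–batch confounding whenever cohort composition is
imbalanced; that confounding shifts pair-state frequencies by at most the
composition imbalance, which bounds the attainable evidence far above
$10^{-20}$, while genuinely reversed pairs at realistic effect sizes and
a few hundred samples reach $10^{-40}$ and beyond. The stringent level
therefore buys false-positive immunity at little cost in power — the
package's tests assert exactly this: under a strongly batch-shifted,
label-imbalanced null, pooled per-gene t-tests reject for most genes at
the conventional 0.05 level while the pair screen at $10^{-20}$ stays
empty. The threshold is applied to the *adjusted* p-value (Bonferroni is
the named family-wise procedure; we do not substitute a false-discovery
step-up).

## Stability-selected sparse classification

Screening leaves a candidate set that is still redundant (pairs within a
pathway are correlated). The classifier stage runs, by default, 100
random stratified 8:2 splits of the discovery samples; on each split an
L1-penalized logistic regression (glmnet) is fitted to the training part
with the penalty chosen by internal cross-validation at the
one-standard-error rule, and the held-out part is scored. When the
held-out AUC exceeds 0.8, every pair with a non-zero coefficient is
credited one occurrence. This attaches the AUC > 0.8 gate to the repeat
(a single ±1 feature rarely reaches 0.8 alone, so a per-pair reading of
the gate would select almost nothing); repeats whose split model
generalizes poorly simply do not vote.

Pairs occurring in strictly more than 50 of the repeats (tunable over a
grid of 10, 20, …, 100 against a disjoint evaluation set; ties go to the
smaller threshold) become the candidate panel. The final model is an
L1-penalized logistic fit restricted to the panel, with the penalty
maximizing 10-fold cross-validated AUC; zero-coefficient pairs are pruned
from the returned model. The split in penalty rules is intentional: the
conservative 1-SE rule for the two *selection* stages (stability repeats,
and the Cox selection below), where parsimony and stability are the goal,
and the CV-optimal penalty for the final *predictive* fit. Random forest
and gradient-boosted-tree fits on the same ±1 features are provided as
comparators for the AUC report only; the sparse linear model is the
deliverable because its coefficients name the biomarkers.

All tie-breaks (candidate ordering, threshold ties) are lexicographic on
gene ids; every random step draws from a named substream of one master
seed, so any stage can be re-run in isolation without disturbing the
others and the whole chain is bit-reproducible.

AUC is computed in the Mann–Whitney form
$(\#\text{concordant} + 0.5\,\#\text{tied})/(n_+ n_-)$ via ranks — the
exact quantity, not a trapezoid approximation — and is invariant under
monotone transforms of the scores.

## Pair-based prognosis

For survival, the pairs of the final diagnostic panel are filtered by
univariate Cox regression (two-sided Wald $p < 0.05$, unadjusted — this
stage is a liberal pre-filter, and no multiplicity correction is applied
at it by design), then fitted jointly with an L1-penalized Cox model
(penalty by cross-validated partial likelihood, 1-SE rule); pairs with
zero coefficients are pruned. The model defines the linear risk score
$s_k = \sum_p \beta_p r_{pk}$ — no baseline hazard term, since only the
ranking of patients matters for stratification and ROC.

Patients are split at the median score; `score >= cutoff` is high-risk.
With ±1 features, score ties are common, so the tie policy is explicit
(ties go high); with all scores tied the whole cohort is "high", a
documented degenerate case. For external validation the training
cutoff can be supplied to `median_split()` in place of the cohort's own
median; the default is the cohort's own median. Groups are compared with
Kaplan–Meier curves and the two-group log-rank test.

Discrimination at clinical horizons (defaults 1, 3, 5 time units) uses
the cumulative-cases / dynamic-controls time-dependent AUC: cases are
subjects with observed events by the horizon, controls those event-free
beyond it, weighted by inverse probability of censoring
($1/\hat G(T_i^-)$ for cases, $1/\hat G(t)$ for controls, $\hat G$ the
Kaplan–Meier estimate of the censoring distribution). Subjects censored
before the horizon enter through the weights only. The convention is
fixed here because published analyses often name only a ROC package;
with zero censoring the estimator reduces exactly (to $10^{-10}$ in the
package's tests) to the plain AUC on the dichotomized outcome.

## The synthetic generator

Every stage above is validated by recovery from simulated data with full
ground truth, generated by `synthetic_config()` / `generate_study()`:

1. baseline gene means $\mu_g \sim N(8, 2)$ (log2 scale), per-sample
   expression $N(\mu_g, 1)$;
2. per-cohort per-gene additive batch offsets $N(0, \sigma_b)$;
3. planted pairs: per sample, the pair state is Bernoulli with the
   group's configured reversal rate and imposed with a margin
   $\delta \sim U(0.5, 1.5)$ (log2 units) around the two genes' current
   midpoint — large enough to survive the unit noise most of the time,
   and the documented difficulty knob;
4. optional per-sample distortion: affine ($a \sim U(0.5,2)$,
   $b \sim U(-2,2)$) or a strictly increasing piecewise-linear map with
   five random knots — both leave every pair feature unchanged, which
   the tests assert bit-for-bit;
5. a pathway partition that co-locates every planted pair (planted pairs
   may not share genes, so configured rates stay exact);
6. exponential proportional-hazards survival for cases,
   $T \sim \text{Exp}(\lambda_0 e^{\sum_p \beta_p r_p})$, censored
   uniformly on $(0, c_{\max})$.

Batch offsets are drawn *before* the reversal margins are imposed. This
ordering is essential to the truth contract: gene-specific offsets of
realistic size (SD 2 on a log2 scale) exceed the planted margin more
often than not, so planting first would let the batch stage overwrite the
configured reversal rates cohort by cohort and the generator's own truth
table would be wrong. Planting last (before the order-preserving
distortions) realizes the configured rates exactly in every cohort while
null pairs still absorb the full batch effect. Batch effects here are
additive per (cohort, gene); multiplicative sample-level effects are
covered by the affine distortion.

What the generator does *not* emulate: probe-level microarray artifacts,
correlated gene–gene expression structure within pathways,
missing values, dropout, or non-proportional hazards. Passing recovery
tests therefore demonstrates correctness of the pipeline's logic and its
batch-effect immunity under the stated model — not performance on any
particular real cohort collection.

### Preset study conditions

The tests and the acceptance script use three fixed presets:

- `preset_diagnostic()`: 3 cohorts × (50 cases + 50 controls), 200 genes
  in 10 pathways of 20, five planted pairs at reversal rates 0.9 (case)
  / 0.1 (control), batch shift SD 2.0, affine distortion. The pooled
  150/150 design gives planted Fisher p-values near $10^{-80}$ —
  comfortably below the $10^{-20}$ screen — while ~1,900 null candidate
  pairs stay far above it.
- `preset_prognostic()`: one cohort of 300 cases + 50 controls, six
  planted survival pairs with reversal rate 0.5 in both groups (so the
  feature varies freely among the cases that carry survival times) and
  log hazard ratios ±1, ±0.9, ±0.8; baseline rate 0.1, uniform censoring
  on (0, 20) (≈ 45% censoring).
- `preset_table1()`: nine cohorts with the case/control counts of the
  real collection the method was developed on (including single-class
  cohorts), as a realistic-shape template.

Problem sizes throughout (hundreds of samples, hundreds of genes, ~2,000
candidate pairs, 100 stability repeats) were chosen as the smallest
conditions under which the statistical claims are comfortably
testable — recovery margins are wide at these sizes, and a full
pipeline run takes well under a minute on one core.

## Numerical and edge-case decisions

- Exact ties in expression map to $-1$; whether tied observations should
  instead be excluded is undocumented in common practice, so the printed
  indicator convention is followed literally.
- Fisher two-sided p-values use the minimum-likelihood convention; the
  implementation (vectorized hypergeometric masses) is verified against
  brute-force enumeration over every 2×2 table with total ≤ 40 at
  relative tolerance $10^{-12}$, and spot-checked against
  `stats::fisher.test`.
- `significant` is strictly `p_adj < alpha`; Bonferroni caps at exactly
  1, so a threshold of 1 marks nothing significant.
- Degenerate stability splits cannot occur under stratification, but a
  single-candidate panel falls back to an unpenalized logistic fit (a
  lasso path needs two predictors).
- Constant pair features (two genes whose baseline means differ by more
  than the noise never reverse) are skipped by the univariate Cox filter
  with a message, and the enrichment universe is the measured gene set,
  not the genome — the only defensible default when no universe is
  stated.
- Missing values are rejected, not imputed: the intended input is the
  complete matrix over commonly detected genes.

## Known limitations

- The screen tests marginal reversal only; a pair informative purely
  through interaction with another pair will not be found.
- Bonferroni at $10^{-20}$ is conservative by construction; in small
  cohorts (tens of samples) no pair can reach it and the screen will
  correctly refuse to nominate biomarkers.
- IPCW weights assume censoring independent of the risk score; heavy
  informative censoring would bias the time-dependent AUC.
- The pipeline treats the supplied cohorts as one discovery collection
  with an internal 8:2 split; fully external evaluation cohorts are
  supported by running the fitted model on separately loaded data rather
  than by the pipeline driver itself.
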