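---
title: "Methods: ratio classifiers, score banding and diagnostic comparison"
author: "septikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio classifiers, score banding and diagnostic comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septikit)
```

## The model

septikit builds classifiers for a specific clinical question: among ICU
patients with systemic inflammation, which ones have sepsis (an
infection-positive host response) rather than infection-negative
inflammation such as the aftermath of major surgery? The classifier
family is deliberately narrow. Per-gene log2 intensities $I[g, s]$ are
replaced by pairwise log-ratios

$$\mathrm{ratio}_{A,B}(s) = \log_2 I[A,s] - \log_2 I[B,s],$$

and a classifier is the sum of two such ratios over four distinct
genes. The ratio transform has two practical virtues: it cancels any
per-sample additive offset on the log scale (global scaling,
normalisation residue), and it converts the weak information in four
individually mediocre genes into two strongly oriented contrasts — for
the canonical panel, two up-regulated genes (PLAC8, LAMP1) each divided
by a down-regulated one (PLA2G7, CEACAM4).

On the RT-qPCR side, threshold cycle is inversely related to log2
abundance, $C_t \approx \alpha - \beta \log_2 I$ with $\beta > 0$, so
the same classifier becomes a signed sum of four Ct values with
coefficients fixed at $\pm 1$:
$-C_t(\mathrm{PLAC8}) + C_t(\mathrm{PLA2G7}) - C_t(\mathrm{LAMP1}) +
C_t(\mathrm{CEACAM4})$.
Because the coefficients sum to zero, the $\alpha$ offset cancels and
the Ct-scale score is an affine image (slope $\beta$) of the
expression-scale score — a property the test suite asserts on synthetic
paired data.

## Discovery procedure

1. **Prefilter** (`prefilter_genes()`): genes are ranked by oriented
   univariate Mann-Whitney AUC. This is a generic stand-in for the
   machine-learning enrichment that would precede a ratio screen on
   transcriptome-wide data; the screen itself is the point here.
2. **Ratio screen** (`screen_all_ratios()`): every unordered pair in
   the pool is evaluated once and oriented so AUC $\ge 0.5$. Ranking
   uses the empirical midrank AUC, which is invariant under the choice
   of log base (a base change rescales every feature by the same
   positive constant), so "log2 everywhere" is a convention, not an
   assumption.
3. **Greedy pairing** (`greedy_pair_search()`): the top ratio seeds the
   classifier; the partner is the ratio among the top `pool_k`
   (default 100) candidates that maximises the AUC of the summed score,
   under the constraint that the two ratios use four distinct genes.
   The distinctness constraint mirrors the final four-gene panel and
   prevents degenerate cancellation such as
   $(A - B) + (B - A)$.

Ties in any ranking are broken by the larger absolute standardised mean
difference of the feature, then lexicographic gene ids, so every run is
deterministic without randomisation.

### Training AUC is an objective, not an estimate

The AUC maximised by the greedy search is reported as `training_auc`
and printed with an explicit caveat. Selection over many candidate
ratios inflates it; on null data the top training AUC is well above
0.5, and the test suite asserts both the inflation and the fact that it
shrinks as the cohort grows. A practical consequence, measured on
synthetic cohorts with a planted signature at effect $\pm 1.5$ noise-SD
and 74/31 samples: in roughly a third of seeds the greedy search
returns three of the four planted genes plus one background gene whose
ratio happens to edge out the true partner *on the training objective*
(margins of 0.002–0.005 AUC). This is inherent to maximising empirical
AUC over ~100 correlated candidates at this sample size — it does not
disappear when the planted effect is raised, because near the AUC
ceiling the objective cannot separate the planted combination from a
lucky near-duplicate. Users who need a stable gene set should rerun
discovery across resamples and keep recurrent ratios, rather than
trusting a single maximiser.

## Scoring, bands and probabilities

- **Cutoff** (default 3.100): the boundary is assigned to the positive
  class (`score >= cutoff`). The cutoff is used in a regime that favours
  sensitivity, so ties go to the call that avoids missing sepsis.
- **Bands** (default edges 4, 6, 9): intervals are half-open on the
  right — $(-\infty, 4)$, $[4, 6)$, $[6, 9)$, $[9, \infty)$ — so the
  bands partition the score axis; a score of exactly 6.0 falls in the
  `6-9` band and 9.0 in `>9`. Printed band labels elsewhere ("4 to 6")
  are ambiguous at the edges; the half-open convention is our
  resolution and is stated in the user docs.
- **Likelihood ratios**: per band,
  $LR = \frac{\text{cases in band}/\text{total cases}}
             {\text{controls in band}/\text{total controls}}$,
  with no continuity correction in the point estimate — a band with
  cases but no controls is reported as $LR = \infty$ (post-test
  probability 1), and zero cases give $LR = 0$. Interval estimates for
  2x2 likelihood ratios use the log method with 0.5 added to all cells
  only when some cell is zero.
- **Post-test probability**: pre-test odds times LR, converted back to
  a probability. With pre-test probability equal to the cohort
  prevalence, the prevalence-weighted mixture of band post-test
  probabilities recovers the pre-test exactly (law of total
  probability); the tests assert this to 1e-12.
- **Platforms**: scores from other RT-qPCR chemistries are mapped onto
  the reference chemistry by per-platform affine shifts. The shifts are
  configuration, never hard-coded, and default to the identity; the
  reference platform is the Asuragen chemistry.
- Scores are reported to 3 decimal places, matching the cutoff's
  precision.

## Evaluation statistics

- **AUC** is everywhere the midrank Mann-Whitney probability; the test
  suite pins it to an exhaustive concordant-pair-counting oracle on
  thousands of small instances, including heavy ties.
- **Bootstrap CIs** are stratified (resampling within class),
  percentile 2.5/97.5, default 2000 replicates, bit-reproducible under
  a seed.
- **Binormal smoothing** fits by method of moments on the raw scores:
  $a = (\bar x_1 - \bar x_0)/s_1$, $b = s_0/s_1$,
  $AUC = \Phi(a/\sqrt{1+b^2})$. Moments were chosen over a Box–Cox or
  ML fit because they are closed-form and deterministic; for
  heavy-tailed scores the empirical method is the fallback and the
  binormal fit refuses degenerate (zero-variance) groups.
- **DeLong's test** uses placement values; the paired form subtracts
  the between-marker covariance. The implementation agrees with
  `pROC::roc.test(method = "delong")` to 1e-10 in the tests, and its
  variance equals the grouped delete-one jackknife.
- **Venkatraman's test** compares entire ROC curves. Paired form: the
  statistic sums, over all cuts of the joint ranks, the absolute
  difference in classification errors between the two markers; the
  null swaps the two markers within subjects. Unpaired form: the
  statistic integrates the absolute TPR difference over FPR and the
  null permutes marker membership within the case pool and within the
  control pool. p-values are $(\text{exceedances}+1)/(\text{reps}+1)$,
  default 2000 permutations. Ties are broken by first occurrence so a
  run is deterministic given the seed.
- **Proportion CIs** (sensitivity, specificity, PPV, NPV, accuracy) are
  Wilson score intervals — well-behaved at the boundaries that occur
  routinely here (sensitivity 1, specificity 0). Published tables
  computed with other interval methods may differ slightly in the CI
  digits; point estimates are unaffected.
- **NRI** for paired binary tests reduces to the difference in
  sensitivity (NRI+) and specificity (NRI−); inference uses the
  paired-proportion variance of the reclassification differences.
- **Balance check**: a case/control split is unbalanced when the
  observed count falls outside the central 95% acceptance region of
  Binomial$(N, 1/2)$; the exact two-sided binomial p-value is reported
  alongside.
- All tests are two-sided at $\alpha = 0.05$.

Whether a DeLong comparison should be paired or unpaired depends on the
design; both are provided, and results record which was used.

## Multivariate comparison engine

Clinical covariates pass a univariate logistic Wald screen
($p \le 0.05$; the choice of Wald over a t-test is ours and is recorded
here because either is defensible), then a forward greedy search adds,
at each step, the covariate maximising the mean test AUC under repeated
stratified 1:1 cross-validation (default 50 repeats). Design choices:

- the same seeded splits are reused for every candidate at every step,
  so models are compared on common resamples rather than fresh noise;
- logistic fits carry a fixed ridge penalty of $10^{-6}$ on
  standardised covariates — invisible at the estimation scale but
  sufficient to keep the IRLS solve defined when a half-split of a
  small cohort is separable, which happens often;
- covariates are z-scored and median-imputed with training-fold
  statistics only (no leakage); missing-data handling is our choice, as
  the upstream procedure is silent on it;
- `forced_in` parameters enter first regardless of rank (to reproduce
  designs like "molecular score plus clinical parameters"), and
  `forced_out` parameters never enter.

## What the synthetic cohorts emulate — and what they do not

`sim_spec()` defaults encode a discovery-style cohort: 74 cases vs 31
controls; four signature genes at effects $\pm 1.5$ noise-SD on log2
scale (two up in cases, two down) over a null Gaussian background of
200 genes with SD 1 and baseline 8; Ct conversion with
$\alpha = 30$, $\beta = 1$ and 0.25 cycles of Ct noise. Validation-style
cohorts used in tests mirror the combined validation design: 95 cases,
213 controls, 37 "possible" samples (prevalence 30.8%, ambiguous
fraction 10.7%), with a procalcitonin-like covariate (effect 1.2 SD)
and a severity-score-like covariate (effect 0.4 SD) so that the
covariate-vs-score AUC contrast can be exercised. The gene count,
baseline, noise and Ct parameters are our choices of a plausible
regime, made once; effects and cohort sizes follow the stated study
conditions.

The "possible" class is drawn as a mixture of the case and control
models. Its default mixture weight is the case prevalence among
known-status samples, which makes the "possible" score distribution
coincide with the pooled known-status distribution by construction —
matching the empirically observed KS-indistinguishability of ambiguous
patients. A 50/50 weight is available via
`sim_spec(possible_case_weight = 0.5)`, but at a 30% prevalence it
separates the two distributions by up to 0.2 in CDF and a KS test
detects that reliably, which is why it is not the default.

What the generator does *not* emulate: transcriptome-wide correlation
structure (background genes are independent), batch effects, platform
drift beyond an affine shift, non-Gaussian expression, or any
microbiology. Passing tests therefore demonstrate correctness of the
algorithms under the model's assumptions, not clinical performance on
real cohorts.

## Numerical conventions and degenerate inputs

- Midrank ties throughout; `AUC(s) + AUC(-s) = 1` holds exactly.
- Missing Ct values yield no score and are flagged, never imputed.
- Ct values outside $(0, 50]$ are rejected at read time; simulated Ct
  values are clipped into the range with a message.
- QC boundary conventions follow the assay's printed rules exactly:
  RT-qPCR yield $\ge 2$ ng/µl inclusive; microarray A260/A280 $> 1.6$
  and integrity $> 5$ strict.
- Deterministic tie-breaks everywhere; every randomised procedure takes
  an explicit seed and is bit-reproducible.

## Problem sizes in the test suite

The property-based tests run at sizes chosen to make their assertions
sharp but cheap: 1000 random instances (≤ 12 per class) for the
AUC/pair-counting identity; a fixed 8/8 paired instance with a $10^5$
permutation oracle for the DeLong p-value; 200 seeded null runs of 500
permutations each for the Venkatraman type-I error and 1000 for the
t-mode error; 20 seeds at 74/31 for signature recovery; 50 seeds at
~300 samples for the "possible"-class indistinguishability property.
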