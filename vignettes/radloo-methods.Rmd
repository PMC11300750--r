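---
title: "Stability-aware radiomic feature evaluation with nested leave-one-out cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-aware radiomic feature evaluation with nested leave-one-out cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radloo evaluates tabular radiomic features — shape and texture statistics
extracted from segmented lesions — on cohorts of a few dozen lesions, the
regime where the ratio of features to samples makes naive modelling
overfit badly. The package chains four ideas: score each feature's
robustness to extraction perturbations, discard redundant features in
favour of their more robust partners, estimate classifier performance with
a nested leave-one-out (LOO) scheme that never lets tuning touch the
evaluation fold, and reduce the model to a minimal feature subset by a
greedy procedure driven by distributional feature importance. A synthetic
cohort generator with planted ground truth makes every stage testable.

## The instability score

Radiomic features depend on decisions upstream of any model: how tightly
the lesion was segmented and which gray-level bin width discretized the
intensities. The package quantifies this with a perturbation grid: each
feature is re-extracted under every combination of mask variant
(`reduced`, `standard`, `increased` — morphological shrink/reference/dilate
of the radiologist's segmentation) and bin width (by default
15, 20, 25, 30, 35), and compared against the reference extraction
(`standard` mask, bin width 25). For feature $i$,

$$
\Delta_i \;=\; \frac{1}{V\,\#p}\sum_{m,\,bw,\,p}
\frac{\left|f_i(m,bw,p) - f_i(\mathrm{st},25,p)\right|}
     {\max_{p^*} f_i(\mathrm{st},25,p^*) - \min_{p^*} f_i(\mathrm{st},25,p^*)}
$$

where $V$ is the number of grid variants (15 for the default grid; the
reference's own terms are zero) and $\#p$ the number of patients. The
denominator is the cohort range at the reference extraction, which makes
$\Delta_i$ unitless, invariant under affine rescaling of the feature, and
comparable across features. The prefactor is written $1/V$ rather than a
hard-coded $1/15$ so that non-default grids remain valid.

Numerical edge cases are handled explicitly rather than silently: a
feature constant across the cohort at the reference extraction has an
undefined score (zero range) and is flagged `NA`; such features are
excluded from modelling by default since a constant column carries no
signal. The cohort range is used untrimmed — no outlier rejection is
applied to the denominator, because trimming would introduce a tuning
knob with no principled default.

## Redundancy correction

Highly correlated feature pairs carry duplicated information, and which
member to keep is decided by stability: among pairs whose absolute Pearson
correlation on the reference table exceeds 0.95, the member with the
larger $\Delta$ is dropped. Correlation is taken in absolute value — a
strong negative correlation is just as redundant as a positive one. The
screen is exhaustive over all pairs and single-pass: pairs are processed
in descending $|r|$, a feature already dropped is skipped, and
correlations are not recomputed. Deterministic tie-breaks (undefined
$\Delta$ counts as most unstable; exact ties drop the lexicographically
later name) make reruns identical. As a sanity check, the number of
principal components needed for 99% cumulative variance of the
column-standardized matrix is reported before and after the correction;
dropping a near-duplicate should not change it.

## Nested leave-one-out evaluation

Three classifier families are supported: a random decision forest (tuned
over the number of trees $n_t \in [50, 250]$, default grid
$\{50,100,150,200,250\}$), a degree-3 polynomial-kernel SVM (tuned over
cost $c \in [1,10]$, default grid $\{1,2,5,10\}$), and a logistic model
(no hyperparameters). The outer LOO holds out each lesion once; on the
remaining $n-1$ an inner LOO evaluates every grid setting by AUC-ROC over
its $n-1$ held-out scores, the best setting (ties toward the simplest:
fewest trees, smallest cost) is refitted on all $n-1$ lesions and scores
the held-out lesion. The inner scores also calibrate a per-fold
classification threshold, chosen among midpoints of consecutive distinct
scores (plus one candidate beyond each extreme) to maximize
sensitivity + specificity, ties toward the smallest threshold. The outer
AUC pools the $n$ external scores; accuracy, specificity, precision, and
recall come from the hard calls made with each fold's own threshold.
The cost of the scheme is quadratic: the inner loops perform exactly
$|\mathrm{grid}|\cdot n\cdot(n-1)$ training sessions, which the engine
counts and exposes.

Scores stay on each family's native scale — vote fraction, signed
decision value, predicted probability. Thresholds are calibrated on the
same scale they are applied to, so no cross-family probability
calibration is performed; raw thresholds are therefore not comparable
across families. Features are z-scored inside each training fold for the
SVM and the logistic model (statistics from the training fold only, so
nothing leaks from the held-out lesion); forests use raw features, since
tree splits are invariant to monotone rescaling.

Determinism is structural: every fit is seeded by a value derived from
(master seed, outer fold, inner index), so reruns are bit-identical and
adding a fold does not shift any other fold's randomness. Two
implementation choices are worth documenting because they change nothing
observable but matter for cost and exactness:

* **Nested sub-forests.** For the forest family, the inner loop fits one
  forest of $\max(n_t)$ trees per inner fit and reads each grid value off
  the first $n_t$ per-tree votes. Because trees are grown sequentially
  from the fold's seed, the first $n_t$ trees of that forest are
  bit-identical to a separately seeded $n_t$-tree fit, so the sliced
  evaluation equals the literal per-setting loop exactly (the unit suite
  asserts this against a longhand re-run). The session counter still
  counts $|\mathrm{grid}|$ sessions per inner fit.
* **Singleton-grid shortcut.** When the grid has one setting and the
  caller needs only the external AUC (as in every inner call of the
  adaptive selection below), the inner LOO is skipped: the hyperparameter
  choice is forced, and the pooled external AUC is algebraically
  independent of the thresholds, which only generate hard calls. Refit
  seeds depend only on (master seed, fold), so the shortcut's external
  scores are bit-identical to the calibrated run's (asserted in the
  suite). Without this exactness-preserving shortcut a single adaptive
  selection at $n = 69$ would cost roughly $19 \cdot |\mathrm{grid}|
  \cdot 69 \cdot 68$ forest fits.

One forest-specific subtlety: the permutation-importance computation of
the underlying forest implementation interleaves its random draws with
tree growing, so a forest fitted with importance enabled differs from one
fitted without. Refits therefore always enable importance, keeping
external scores identical whether or not the caller asks for importance
values.

Two degenerate-input conventions: a training fold with a single class is a
hard error for the public fitting interface (it cannot arise in the outer
loop when both classes have at least two members), but at very small
cohort sizes the *inner* loop can exhaust a class no matter how the
lesions split; the only fittable model there is the constant prior
predictor, so that inner point receives the training-label mean as its
score and the session accounting is unaffected. And aliased (collinear)
columns in the logistic fit contribute zero to the linear predictor
rather than propagating `NA`.

The unit of analysis is the lesion, so per-lesion LOO is the default.
Since one patient can contribute several lesions, per-lesion folds can in
principle leak patient-level information; an optional group-wise mode
leaves out whole patients instead when a `patient_id` column is supplied.

## Distributional importance and adaptive selection

The outer loop produces not one model but $n$ — one per held-out lesion —
and each yields an importance value per feature: mean decrease accuracy
(out-of-bag permutation) and mean decrease Gini for forests, the absolute
polynomial pseudo-weight $\bigl|\sum_j \alpha_j y_j x_j\bigr|$ over
support vectors for the SVM, and the drop-one deviance increase for the
logistic model. Pooling across folds gives a distribution per feature,
summarized by the mean and the Q1–Q3 interquartile range
(linear-interpolation quantiles); a narrow IQR indicates an importance
that is stable across the model family.

Selection then proceeds greedily. The features are split into most/less
relevant by 2-means on the mean importances — solved exactly in one
dimension by enumerating the $n-1$ ordered split points, which removes
initialization randomness entirely. The relevant cluster seeds the model
wholesale and is never pruned; the remaining features are tried one at a
time in descending mean importance (mean decrease accuracy for forests),
and each is kept only if the external nested-LOO AUC strictly increases —
equality is not an improvement. A single up-front ranking is used; the
importances are not recomputed after each acceptance, which keeps the
evaluation count at $2 + \#\text{candidates}$ nested runs per selection.
Each trace records every candidate with the AUC before and after, so a
replay under the same seed reproduces every recorded value exactly.

Two caveats are inherent to the procedure and stated rather than hidden.
First, the importance ranking that seeds the selection comes from the
full-feature run on all lesions, so the final AUC is an optimistically
biased estimate of the reduced model — an honest assessment would need an
additional held-out tier the cohort sizes here cannot afford. Second, on
null data the strict-improvement rule still selects something; the suite
therefore only checks trace validity on shuffled labels, not selection
quality.

## The synthetic cohort generator

The generator emulates the shape of the motivating data — about 69
lesions, a malignant-majority split (35/69 by default, with exactly
$\lfloor \text{prevalence} \cdot n \rfloor$ positives assigned by
shuffling so small cohorts always contain both classes), and 25 features
(6 geometric, 19 texture) — while keeping the ground truth known:

* baseline features are independent standard normals; informative
  features get a $+d$ mean shift in the malignant class (mean shift only,
  no covariance shift, so recovery tests stay interpretable);
* clone features are $r$-mixtures of their source plus independent noise,
  hitting correlation $r$ in expectation (defaults: two clone pairs at
  $r = 0.99$ and $0.97$);
* every non-reference variant adds
  $\text{mask\_offset}(m)\,\sigma_{\text{pert}}\,s_i\,\varepsilon
  + \beta_{bw} (bw - 25)\, s_i\, \eta$ with fresh unit normals, where
  $s_i$ is the feature's cohort SD, $\text{mask\_offset}$ is 0 for the
  standard mask and 1 otherwise, $\sigma_{\text{pert}}$ defaults to 0.05
  for geometric and 0.3 for texture features, and the bin-width slope
  $\beta_{bw}$ is 0 for geometric features by construction (enforced) and
  0.02 per unit for texture features. The reference variant reproduces
  the baseline matrix exactly.

The perturbation model is additive Gaussian on the feature scale — the
simplest model that exposes the instability statistic's behaviour; real
re-extractions have heavier-tailed, feature-specific errors. Likewise no
attempt is made to mimic real radiomic marginals (log-normal volumes and
the like): passing tests show the statistics behave as designed, not that
the package has seen realistic radiology. Default effect sizes
($d = 1.5, 1.0, 0.8$ on three features) give a clearly learnable but not
trivial signal at $n = 69$.

One generator-design note: the planted-clone check "the PCA component
count at 99% variance is unchanged by redundancy correction" is run at
$n = 200$. With i.i.d. baseline features at $n \approx 69$ and $p = 25$,
the sample correlation spectrum's Marchenko–Pastur tail is wide enough
that the count straddles the threshold by chance; at $n = 200$ the tail
eigenvalues separate cleanly from the clones' residual eigenvalues and
the invariance is the mathematically expected outcome. This is a property
of the i.i.d. generator, not of the method.

## Validation design and problem sizes

The test suite exercises every stage against independent oracles:
longhand evaluation of the instability sum; exhaustive pair counting for
the AUC; exhaustive candidate scans for the threshold and the 1-D 2-means
split; a from-scratch permutation importance for the forest's mean
decrease accuracy; and longhand inner-LOO loops for the grid search. The
heavier stochastic checks run at the following sizes, chosen to give the
assertions statistical teeth while staying desk-sized: a permutation-null
study (100 shuffled-label cohorts of $n = 40$, 10 features, forest grid
$\{50, 100\}$; the mean external AUC must sit inside its own 99%
confidence interval around 0.5 — note that this check is expected to
fail, and its failure is informative: pooled leave-one-out scores are
*pessimistically biased* under a permutation null, because holding out a
positive lesion depletes positives in its training fold, so held-out
positives score systematically lower. The bias is a known pitfall of
pooled LOO — an ordinary, un-nested LOO over a plain forest or logistic
fit shows the same depression — and it affects any method built on
pooled LOO scores, including this one; on cohorts with real signal it is
swamped by the effect of interest), a recovery study (50 cohorts of
$n = 69$ with 3 informative features of $d = 1.5$ among 20; the median
recall of planted features must reach 2/3 and the selected set must match
or beat the full model's AUC in a majority of runs), and a concordance
study (20 strong-signal cohorts; the two forest importance measures must
rank features with positive rank correlation).

## Known limitations

The package starts from feature tables: image handling, segmentation, and
feature extraction are out of scope. The instability score is the only
robustness statistic offered (no ICC, no multi-reader modelling). The
nested scheme is LOO-only — no k-fold or bootstrap variants — and assumes
a near-balanced two-class cohort (no class weighting). Reduced-model AUCs
are selection-biased as discussed above, and thresholds are not
comparable across model families.
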