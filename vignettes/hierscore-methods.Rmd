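---
title: "Interpretable hierarchical questionnaire classification with Monte Carlo dropout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable hierarchical questionnaire classification with Monte Carlo dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierscore)
```

## The problem and the model

Mental-health clinics screen patients with sum-score questionnaires: each
item response maps to a small integer, the integers are summed, and the sum
is compared against severity thresholds. `hierscore` classifies patients
into four treatments (depression, panic, social phobia, specific phobia)
with a model built around exactly that structure, so that its internal
quantities are familiar objects to clinical users.

The input is a fixed battery of 91 features: the PHQ-9 (ten items including
the functional-impairment item), GAD-7 (7), SIAS (20), PDSS (7), the
24-item Fear Questionnaire (FQ), three MANSA quality-of-life items, five
ordinal/binary demographics and three one-hot groups (previous
anxiety/depression diagnosis DAD0–3, income source INC_1–7, treatment
applied for APP_1–4). Every ordinal item is min–max normalized to $[0,1]$
over its *schema-declared* range — never over observed data — so training
and prediction scaling are identical by construction. Reverse-keyed SIAS
items are flipped before scaling, so "larger means more severe" holds for
every encoded feature.

The classifier is a two-level hierarchy:

* **Pseudosum scores.** For each instrument $g$ with encoded items $x_g$,
  a learned score $s_g = \mathrm{ReLU}(w_g^\top x_g)$. The weighted sum
  mimics the traditional sum-score (score layers have no bias for the same
  reason); the ReLU guarantees a score can never be negative. The three FQ
  avoidance subscales (agoraphobia, blood–injury, social) feed a
  second-level total-phobia node the same way.
* **Softmax output.** The pseudoscores and the direct features (FQ items 1,
  17, 18 and 24, MANSA, demographics, one-hot dummies) are stacked into
  $X_s$, and class logits are $z_c = W_c^\top X_s + B_c$ with
  $p_c = \mathrm{softmax}(z)_c$ — a multiclass logistic regression over
  interpretable intermediate quantities.

A single-class formulation of the output layer can be written with a
per-class sigmoid $\sigma(W_c^\top X_s + B_c)$; we treat that expression as
the pre-normalization class score and always normalize across the four
classes with the softmax, so the outputs form a probability vector.

### Fear Questionnaire wiring

The standard Marks–Mathews key is used: item 1 (main target phobia
avoidance) and item 18 (global phobia severity) are clinically meaningful
on their own and bypass the score layer, as do items 17 and 24 ("any
other..." catch-alls); items 2–16 form the three 5-item avoidance subscales
(agoraphobia {5,6,8,12,15}, blood–injury {2,4,10,13,16}, social
{3,7,9,11,14}) whose pseudoscores combine into `fq_total`; items 19–23 form
the anxiety–depression subscale (`fq`). The subscale membership is exposed
in `load_schema()` rather than hard-wired in the network code.

### SIAS reverse scoring

Items 5, 9 and 11 are reverse-scored, the standard instrument key. Because
clinics occasionally use variant keys, the set is a parameter of
`load_schema()`.

## Training

`train_model()` minimizes categorical cross-entropy plus an L1 (default) or
L2 penalty with factor $\lambda$ on **all weights and no biases**, by
mini-batch Adam. Defaults mirror the reference training regime: 2000 epochs,
batch size 32, Adam at its canonical defaults
($\eta = 10^{-3}, \beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$),
$\lambda = 0.001$, dropout rate $p = 0.05$. Batches are reshuffled every
epoch from the run seed and the last partial batch is kept. L1 is the
shipped default because it drives the weights of unneeded items to zero,
which is what makes the weight-based explanations terse; L2 is available
and selected the same way through `cross_validate_regularization()`
(stratified 5-fold, balanced-accuracy criterion, ties toward the smaller
factor).

**Non-negative score weights.** Clinical sum-scores only add; a negative
item weight inside a score would break the analogy. By default score-layer
weights are projected onto $w \ge 0$ after every optimizer step
(`nonneg_score_weights = TRUE`). The flag exists because the unconstrained
variant is also coherent (the ReLU then does real work clipping negative
sums); output-layer weights are never constrained — detracting features are
part of the explanation vocabulary.

**Initialization.** Output weights start uniform on $(-0.05, 0.05)$. Score
layers start uniform on $(0, 0.05)$ when constrained: clamping a symmetric
init would park half the score weights exactly at zero, and with L1 under
Adam (whose per-step penalty displacement is roughly the learning rate
regardless of gradient size) a zero weight with a weak data gradient tends
to stay dead. Under the unconstrained flag the symmetric init is used.

**Dropout placement.** Bernoulli masks at the shared rate $p$ are applied to
the *input of every weight layer*: the encoded items before the score
layers, the subscale scores before the total-phobia node, and the full
$[ \text{scores} \,\|\, \text{direct} ]$ vector before the output layer —
including the direct demographic path, which is that path's first weight
layer. Masks use inverted scaling (activations divided by $1-p$), so the
$p \to 0$ limit equals the deterministic forward pass exactly.

## Monte Carlo dropout inference

`mcd_predict()` repeats the stochastic forward pass $N$ times with fresh
masks; the resulting $N \times 4$ sample matrix is the patient's predictive
distribution. The per-class sample mean $\mu_c$ is the reported probability
(confidence), the per-class sample variance $\sigma_c^2$ (population
convention) the epistemic uncertainty. $N$ defaults to 500 — large enough
for visually stable violins and stable $\mu_c$ (Monte Carlo error
$\sqrt{\sigma_c^2/N}$), small enough for interactive use; it is a parameter
everywhere. Determinism: identical (model, record, $N$, seed) give an
identical sample matrix. The point class is the argmax of $\mu$, ties broken
toward the lowest class index.

`overlap_report()` summarizes between-class ambiguity: for each class pair,
the fraction of samples in which the lower-mean class's probability exceeds
the higher-mean class's, with exact ties credited one half (the
Mann–Whitney convention, which makes a symmetric pair come out at exactly
1/2 in expectation). Pairs above a threshold (default 0.05) are flagged as
competing treatments. `violin_data()` turns the samples into a Gaussian-KDE
density on a fixed $[0,1]$ grid (Silverman bandwidth, trapezoid-normalized;
a zero-variance sample degenerates to a unit point mass at the nearest grid
cell) plus box statistics; quantiles use linear interpolation between order
statistics (R type 7), the single supported method.

## Explanations

Transparency means the numbers shown are the numbers used: explanation
functions read the same weight arrays the forward pass multiplies by.

* `global_class_weights()` ranks the signed output-layer weights per class.
* `standardized_coefficients()` multiplies each score-layer weight by the
  standard deviation of its *encoded* feature over the training cohort
  (population convention). Encoded — not raw — scales are used because the
  weights act on encoded inputs; this also makes the coefficients invariant
  to re-expressing an item on a stretched raw range. Constant features get
  coefficient zero regardless of weight.
* `local_contributions()` decomposes one patient's class logit as
  $z_c = \sum_s W_{c,s} X_s + B_c$ with dropout-free $X_s$, exactly (the
  reconstruction identity is tested to $10^{-9}$); a `node` argument
  decomposes one pseudoscore into item contributions the same way. MCD
  spread and explanations are deliberately never mixed: explanations use
  deterministic weights, uncertainty is reported separately.
* `stability_analysis()` retrains across seeds and reports how often each
  feature tops a class (strict argmax, lowest-index ties) and how many
  features cover 80% of the cumulative absolute weight — the sparsity
  comparison under which L1 needs fewer features than L2.

## The synthetic cohort generator

The clinical data the model targets cannot be redistributed, so
`generate_cohort()` creates cohorts with the statistical structure the model
assumes, and every downstream module is exercised against them.

Per record: the class label comes from configured proportions (default
33.6 / 33.6 / 24.1 / 8.7%, the reference clinical layout; counts by deterministic
largest-remainder apportionment, then shuffled). Each instrument draws a
shared latent severity $g \sim N(0,1)$, and item latents
$u_i = \mu + \sqrt{\rho}\, g + \sqrt{1-\rho}\, \varepsilon_i$ are cut at
equal-probability normal thresholds onto the item's allowed values — one
knob $\rho$ (default 0.5) controls within-instrument correlation, exactly
the structure a sum-score presumes. The class's signature instrument
(depression→PHQ-9, panic→PDSS, social→SIAS, specific→FQ avoidance items)
has its latent mean raised by $4 \cdot \mathrm{effect\_size}$, which moves
expected item values by roughly `effect_size` of the item range in the
middle of the scale; the baseline latent mean is $-0.5$ (patients score low
on instruments irrelevant to their presentation). Default `effect_size` is
0.4; the `reference_cohort_config()` preset uses 0.6, a deliberately
well-separated regime, and class totals 358/359/257/94 ($N = 1068$) chosen
so the default 75% stratified split lands exactly on 269/269/193/70
training and 89/90/64/24 test records. Demographics come from fixed
marginal tables plausible for an internet-delivered CBT clinic, with a mild
configurable class coupling on APP/DAD/HasPhobia (default 0.3), since
treatment-application variables are informative in practice.

What the generator does **not** emulate: cross-instrument comorbidity
structure (a depressed patient's elevated GAD-7), item-specific difficulty
profiles, missingness, and any real joint demographic distribution. Passing
tests on these cohorts therefore demonstrate that the machinery — encoding,
optimization, uncertainty, explanation, evaluation — behaves as specified
on data matching the model's assumptions; they say nothing about clinical
accuracy on real cohorts.

`planted_weights_cohort()` inverts the roles: features are uniform and
labels are sampled from a known model's own probabilities, giving ground
truth for parameter-recovery checks.

## Numerical and design choices

* Softmax is computed with max-subtraction; sampled and deterministic
  probability vectors sum to 1 within $10^{-12}$.
* `stratified_split()` apportions per-class training counts by largest
  remainder against a total of `round(fraction * n)`, ties toward the
  earlier class, then samples membership within class — per-class counts
  are as close to the fraction as integers allow, and splits partition the
  cohort exactly.
* Metric presentation rounds at two decimals, half-up, and only at
  presentation; undefined metrics (empty row or column) are `NA` plus an
  explicit flag, never a silent zero, so aggregates are not corrupted.
* One-vs-rest AUC is the rank-based Mann–Whitney statistic (average ranks,
  ties half credit), cross-checked against an independent implementation in
  the tests.
* Model files are JSON with doubles at 17 significant digits, which
  round-trips IEEE doubles bit-exactly; files record the schema version and
  feature order and refuse to load against a mismatched schema.
* Missing or out-of-range data are hard errors (the intended population is
  complete records); there is no imputation.

## Problem sizes used by the test suite

The suite exercises deployment-scale structure at desk-scale cost: the
end-to-end check trains 300 epochs on the 801-record synthetic training
split and MCD-evaluates the 267-record test split with $N = 500$
(balanced accuracy ≥ 0.9 under the well-separated preset); the sparsity
comparison trains L1 and L2 at $\lambda = 0.001$ for 300 epochs on 800
records; parameter recovery trains 150 epochs on ten planted cohorts of
5000 records at $\lambda = 10^{-4}$. Light regularization is used for
recovery because the planted-uniform task has weak per-item gradients, and
at $\lambda = 0.001$ the L1 penalty's Adam-normalized pull can kill score
nodes before their output weights bootstrap — the same reasoning behind the
feasible-region initialization above. For the same reason a *second-level*
planted signature (`fq_total`) is not reliably recoverable and the planted
ground truth uses first-level nodes; recovering structure through two
stacked ReLU layers under strong L1 is a known limitation.

## Known limitations

* With correlated predictors, L1 may keep one of two near-equivalent items
  and zero the other; retraining can swap which one survives. The
  stability analysis quantifies this; it is inherent to sparse linear
  explanations.
* MCD variance reflects weight-perturbation (epistemic) uncertainty only;
  it is not a calibrated posterior and carries no aleatoric component.
* Severity bands for the traditional sum-scores follow the conventional
  published thresholds (e.g. PHQ-9 5/10/15/20, GAD-7 5/10/15, PDSS
  2/6/10/14/17, SIAS 34/43); FQ bands are descriptive conveniences, as the
  instrument has no canonical cut-offs.
* The CLI's figure outputs require `ggplot2` at run time; all plotted
  quantities are available as plain data through `violin_data()` and the
  explanation tables, which is the tested surface.
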