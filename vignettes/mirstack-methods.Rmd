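---
title: "Stacked meta-prediction of pre-miRNA hairpins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked meta-prediction of pre-miRNA hairpins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstack)
```

## The problem

Computational pre-miRNA predictors decide whether an RNA hairpin is a
genuine miRNA precursor or a pseudo-hairpin. Established tools — MiPred,
MIReNA, miRPara, ProMiR, triplet-SVM — were each tuned on their own
training sets and toward their own operating points: some maximize
sensitivity at the cost of specificity, others the reverse, and their
accuracy shifts when they are moved to a new, larger benchmark. Yet their
*mistakes are different*: the number of samples that at least one of two
predictors gets right (the pairwise coverage) is far larger than what any
single predictor gets right. That gap is exactly the head-room available
to a combiner, and `mirstack` implements the combiner: a stacked
meta-predictor that feeds the five raw outputs, after staged non-linear
preprocessing, into a small logistic neural network.

`mirstack` deliberately does **not** re-implement or invoke the five base
predictors. Its unit of input is the *score table*: one row per hairpin,
one column per predictor, each cell in that predictor's native output
dialect (`Yes`/`No`, `1`/`NA`, a bounded score, or a heavy-tailed
probability ratio with `NA` and `0` as distinct outcomes). Everything
downstream — preprocessing, training, validation, evaluation — operates on
such tables, whether they come from real predictor runs or from the
package's synthetic generator.

## Preprocessing: three staged transforms

The network needs numeric inputs on a common scale, and *how* the scores
are put on that scale matters.

**Stage I (numericalize + normalize).** Binary tokens become +1
(positive call) and −1 (negative call). Each numeric column is min–max
mapped onto $[-1, 1]$ using bounds fitted on the training data:
$x \mapsto 2\,(x - \min)/(\max - \min) - 1$. The reference procedure
targets the open interval $(-1,1)$; min–max scaling attains the endpoints
on the training extremes, a deliberate, documented deviation without
practical consequence. `NA` cells of numeric columns carry no stage-I
rule of their own, so they are pooled with the raw value 0 (the other
"no-signal" outcome) before scaling; this keeps stage I a pure
numericalize-and-scale step.

**Stage II (sentinels + log).** ProMiR-style scores span eight orders of
magnitude, so after stage I almost all of them collapse near −1 and the
column carries little usable signal (this package's own noiseless-panel
experiments reproduce that pathology). Stage II therefore routes
designated heavy-tailed columns through a shifted logarithm first:
`NA` → −30, exact 0 → −25, positive $x$ → $\ln x$, then min–max as in
stage I. The base is the natural log: with it, the two sentinels sit
strictly *below* the log of the smallest score the dialect can emit
($\ln 10^{-10} \approx -23.03 > -25 > -30$), so the ordering
"no call < zero score < any numeric score" survives the transform; a
base-10 log would put $10^{-10}$ at −10 and break that motivation. The
sentinel values are fixed constants of the method (they were chosen
empirically in the reference work, with no stated objective) and are
configurable but not fitted.

**Stage III (PCA rotation).** The stage-II feature matrix is column-
centred and rotated by the eigenvector matrix $E$ of its covariance:
$Y' = (Y - \bar Y)\,E$. The rotation is fitted on the *training fold
only* and replayed on test/validation folds — fitting it on the pooled
data would leak information across folds; published results that pooled
may therefore differ slightly. PCA uses the covariance, not the
correlation, because stage II has already placed all columns on $[-1,1]$.
Determinism conventions: eigenvectors are ordered by descending
eigenvalue and sign-fixed so each column's largest-magnitude entry is
positive.

Degenerate inputs: a constant numeric column maps to 0 and is flagged
(avoids division by zero); values outside the fitted range at apply time
are clipped to $[-1,1]$, keeping the network's input domain closed; PCA
requires more samples than predictors ($N > M$).

## The meta-learner

A fully connected $M \to H \to 1$ network with the logistic function
$\sigma(z) = 1/(1+e^{-z})$ in every hidden node and the output node, so
scores live in $(0,1)$; a score $\ge 0.5$ is a positive call (the
threshold is inclusive). $M$ equals the ensemble size (2–5); the tuned
default is $H = 20$, and sizes outside the explored range 5–60 warn
rather than fail.

Training is per-sample (shuffled) gradient descent on squared error
against 0/1 targets — the classical choice for logistic-output networks
of this design; log-loss is available by configuration. The reference
procedure leaves the optimizer, learning rate, initialization and epoch
cap unreported, so they are configuration surface here: learning rate
0.1, weights i.i.d. uniform on $[-0.5, 0.5]$, biases zero, cap 1000
epochs, everything seeded. The inner loop is compiled (Rcpp) and draws
its shuffles from R's RNG, so runs are reproducible from `set.seed()`
and the compiled epoch is replayed *exactly* by a pure-R reference
implementation in the test suite; analytic gradients are additionally
checked against central finite differences.

**Early stopping.** After each epoch the accuracy on a held-out test
subset is recorded. When it has not exceeded its running maximum for
`patience` (default 100) consecutive epochs, training stops and the
snapshot from the best epoch is returned — the conservative reading of
"stop when the test accuracy stops increasing". Ties go to the earliest
epoch (least drift). One visible consequence: on an easy panel the
monitor accuracy can saturate at 1.0 within an epoch or two, and the
returned snapshot is then an undertrained net whose scores hover near
0.5 — correct on the monitor, occasionally borderline on validation.
This is inherent to accuracy-monitored early stopping, not a defect of
the optimizer.

## Validation protocol

Stratified $k$-fold cross-validation with a three-way rotation: fold $r$
validates, fold $(r+1) \bmod k$ is the early-stopping test subset, the
remaining folds train. (The reference protocol says only that "another
subset" serves as the test subset; the fixed rotation keeps runs
deterministic.) Folds are built by a seeded within-class shuffle dealt
round-robin, so per-fold class counts differ from the stratified ideal
by at most one; $k \ge 3$ is required so the three roles stay disjoint.
Transforms (including PCA) are fitted per rotation on the training folds
only; the network is re-initialized each rotation with a derived seed.
All four metrics are averaged identically over rotations and reported
with standard errors $\mathrm{SD}/\sqrt{k}$ (SD with the $n-1$ divisor).

## Evaluation

Sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy
$(TP+TN)/N$, and the Matthews correlation coefficient with the standard
square-root-of-marginal-products denominator; MCC of a degenerate caller
(a zero marginal) is defined as 0. Print methods show percentages at one
decimal and MCC at two — the conventional table precision — while full-
precision values are retained.

The agreement analysis restricts to one class and counts, per predictor,
its true calls $T_i$, and per pair the overlap $O_{ij}$ (both correct)
and non-redundant union $U_{ij} = T_i + T_j - O_{ij}$ (at least one
correct). $U_{ij}$ divided by the class size is a *coverage ceiling*: no
combiner of the pair can beat it on that class. The package ships the
published benchmark counts of the five predictors on the D163
(163 + 168) and D1679 (1679 + 674) reference datasets as plain-text
fixtures, so all derived metrics and ceilings are recomputable offline.
Eight published off-diagonal cells contradict the union identity against
their own table's diagonals; they are flagged `consistent = 0` in the
fixture and excluded from identity checks, and the published Triplet-SVM
row of the small-benchmark metric table (which contradicts the agreement
diagonals) is likewise not used as a check target.

## The synthetic generator

Real panels would require running five external predictors over curated
hairpin sets, which is out of scope. The generator stands in for that:
per sample, each predictor calls correctly with probability equal to its
configured sensitivity (positives) or specificity (negatives), shifted
by $\rho\,(u - 0.5)$ where $u \sim U(0,1)$ is a shared latent difficulty
— a transparent way to induce correlated errors ($\rho$ defaults to 0.3)
while leaving marginals unchanged. The emitted cell is then drawn from
the predictor's dialect given the call: MiPred-like positives uniform on
[50, 91] and 0 otherwise; miRPara-like uniform on [0.8, 1] / 0;
MIReNA-like `Yes`/`No`; triplet-SVM-like `1`/`NA`; ProMiR-like positives
log-uniform on [0.017, 3240] and negatives a 0.5/0.25/0.25 mixture of
log-uniform [1e-10, 1e-2], exact 0, and `NA`. Default operating points
are the five predictors' published large-benchmark values.

`generate_complementary_panel()` builds the regime where stacking pays
most: each predictor errs on its own disjoint, randomly placed 15% slice
of each class, so every individual accuracy is 0.85 while the coverage
ceiling of any pair — and of the full set — is exactly 1.0.

What passing tests on these panels shows, and what it does not: the
generator reproduces the *dialects*, configured *marginals* and a
tunable *dependence knob*, so it validates the pipeline's mechanics and
the combiner's ability to exploit complementary errors. It does not
reproduce the true dependence structure of the real predictors (only
implicitly characterized by the published agreement counts), sequence-
level difficulty, or dataset shift; cross-validated accuracies on
synthetic panels are therefore statements about the method, not
predictions of accuracy on real hairpin collections.

## Problem sizes and numerical choices

The shipped checks use panel sizes chosen to make the statistics stable
while staying desk-scale: complementary-panel cross-validation at
$n = 2000$ over 5 seeds; generator calibration at $n = 10000$ (binomial
z-scores); the ensemble-size sweep at $n = 600$ with $k = 3$ over 5
seeds; PCA orthonormality and variance conservation asserted to $10^{-8}$;
gradients to $10^{-6}$ relative against central differences with step
$10^{-5}$. Duplicate filtering compares raw cells (the strictest
reading), groups by (label, prediction vector) so samples of different
classes never collapse, and picks survivors with a seeded draw iterated
in canonical group order.

## Worked example

```{r example, eval = FALSE}
panel <- generate_complementary_panel(1000, 1000, seed = 1)

# individual predictors top out at 0.85 by construction
calls <- binarize_calls(panel)
apply(calls, 2, function(cl) mean(cl == panel$labels))

# the stacked meta-predictor recovers what the coverage ceiling allows
res <- run_cv(panel, k = 5, preprocess = "III",
              config = ann_config(n_inputs = 5, n_hidden = 20, seed = 1),
              seed = 1)
res

# or as a single fitted model with the usual methods
fit <- mirstack(panel, seed = 1)
summary(fit)
head(predict(fit, panel, type = "response"))
```

## Known limitations

* The package consumes predictor *outputs*; producing them (sequence
  handling, secondary-structure prediction, the five external tools) is
  out of scope by design.
* Published cross-validated meta-accuracies on the real benchmarks are
  not reproducible without those external runs; the package instead
  recomputes every published quantity that is derivable from printed
  counts, and validates the pipeline end-to-end on synthetic panels.
* The trainer is plain seeded SGD: no momentum, mini-batching,
  regularization, or multiple hidden layers — matching the reference
  design, not the state of the art.
* Whether normalization bounds and the PCA rotation should be fitted
  per training fold or on the pooled data is ambiguous in the reference
  description; this implementation fits per fold (no leakage), which may
  make its cross-validated numbers conservative by comparison.
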