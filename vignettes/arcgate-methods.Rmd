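---
title: "Predicting gamma-passing-rate classes from VMAT control-point sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gamma-passing-rate classes from VMAT control-point sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arcgate)
```

## The problem

Before a stereotactic VMAT plan is delivered, patient-specific quality
assurance (PSQA) measures each arc with portal dosimetry and summarizes
agreement with the planned dose as a gamma passing rate (GPR, percent of
points passing a 2%/2 mm criterion).  Measurement happens late: if an arc
fails, the plan goes back to optimization after the physics workflow has
already spent its time.  `arcgate` models the arc-level QA outcome *from
the plan itself*, so a likely failure is flagged minutes after
optimization instead of hours later at the machine.

The prediction target is deliberately a three-class action label rather
than a number or a pass/fail bit:

* **Ideal** — GPR ≥ 95%: expected to pass cleanly;
* **Investigate** — 85% ≤ GPR < 95%: a physicist should look;
* **Replan** — GPR < 85%: likely failure, worth re-planning now.

Boundary semantics are exact: 85 maps to Investigate and 95 to Ideal.  The
two thresholds are configurable (clinics retune such limits), but GPR is
always carried as a percentage in `[0, 100]`.

## Sequence encoding

A VMAT arc is an ordered sequence of 90–180 control points.  Each control
point is flattened to a vector of exactly 127 features, in this fixed
order:

| position | content |
|---|---|
| 1 | control-point index (raw 0-based ordinal) |
| 2 | cumulative meterset weight (0–1) |
| 3–6 | jaw positions X1, X2, Y1, Y2 (mm at isocenter, IEC 61217 signs) |
| 7 | gantry angle (raw degrees, no unwrapping across 0/360) |
| 8–127 | 120 MLC leaf positions (bank A 1–60, then bank B 1–60), mm |

Units are left as stored in the plan; model weights depend on this layout,
so it is part of the exported-model contract.  Arcs are zero-padded at the
sequence end to one common length (never truncated), and each sample
remembers its true length.

Where the field order or transformations were genuinely open, we fixed
them as follows: raw ordinal index (not normalized), raw gantry degrees,
and an *optional* per-feature min-max normalization fitted on training
data only (`model_config(normalize = TRUE)`).  Normalization is off by
default because the reference protocol does not mention it, but the raw
scale disparity (index up to 180 vs meterset in `[0,1]`) measurably slows
gradient training, so end-to-end demonstrations in this package enable it.

## Class balancing and splitting

Clinical GPR cohorts are heavily left-skewed; the reference cohort of 468
arcs splits 370/65/33 across Ideal/Investigate/Replan.  SMOTE fills every
minority class up to the majority count: a synthetic sample is
`x + u (z − x)` with `x` a real minority sample, `z` one of its `k = 5`
nearest same-class neighbours (Euclidean distance on the flattened padded
sequence — padding zeros participate), and `u ~ U(0,1)`.  Real samples are
never altered; synthetic ones are flagged so provenance survives
downstream.

Two deliberate consequences are worth stating.  First, SMOTE runs *before*
the 80/20 stratified split by default, which leaks synthetic neighbours of
test samples into training; this matches the reference protocol, and
`gpr_pipeline(smote_first = FALSE)` provides the leakage-free variant.
Second, interpolated control-point sequences are generally *not* machine
deliverable; nothing is filtered, but
`synthetic_deliverability_fraction()` quantifies how often the five
deliverability constraints are violated.

The split rounds the per-class test count with round-half-to-even
(`370 × 0.2 = 74` exactly, giving 888 training and 222 test samples from
a balanced 1110).

## The classifier

A stacked LSTM consumes the padded sequence: 3 layers of hidden width 64,
no dropout, followed by a linear head from the final hidden state to three
logits.  Each layer carries one combined bias vector per gate block (gate
order input/forget/cell/output), so the parameter count is
`4H(in + H + 1)` per layer plus `3H + 3` for the head.  By default the
head reads the hidden state at the *last padded* time step — the whole
zero-padded sequence passes through the recurrence, the reading consistent
with feeding fixed-size tensors; `model_config(readout = "length_aware")`
reads each arc's last real step instead.  Both modes are exact in the
forward pass; tests pin them against an independent scalar recurrence.

Training minimizes mean cross-entropy with Adam at a starting learning
rate of 1e-2, minibatches of 64 reshuffled each epoch (last short batch
kept), for up to 1000 epochs.  Early stopping watches validation loss
with a patience of 500 epochs; any strict decrease resets the counter, no
minimum delta, and the parameters of the best-validation epoch are
restored at stop.  One integer seed drives initialization (uniform
`±1/√H`), shuffling, dropout masks and SMOTE, making a pipeline run
bit-reproducible.  An optional global gradient-norm clip
(`train_control(grad_clip = )`) is available because LSTMs at lr 1e-2
occasionally hit exploding-gradient steps; it is off by default.

Prediction takes the argmax of the softmax; exact ties break toward the
lower ordinal (Replan first), the conservative direction for QA.

## Cross-validation protocol

The reference protocol uses an unusually fold-rich scheme: validation
folds of 2 samples per class partition the balanced training set, giving
`296 / 2 = 148` folds of size 6.  Each fold trains from a fresh seeded
initialization (fold seed = base seed + fold index, so concurrent and
sequential execution agree), records per-epoch loss, accuracy and
one-vs-all sensitivity/specificity, and may stop early.  Curves are
averaged across folds with last-value carry-forward for folds that
stopped early; the averaged curve therefore always lies inside the
per-fold envelope.  The final epoch budget is the mean stopping epoch,
rounded half up, and the deployed model is retrained on the *entire*
training set for exactly that many epochs with no hold-out.

## Evaluation

`evaluate_model()` reports the 3×3 confusion matrix (rows truth, order
Ideal/Investigate/Replan), one-vs-all sensitivity `TP/(TP+FN)` and
specificity `TN/(TN+FP)` in percent (2 decimals), overall accuracy
(1 decimal), and per-class ROC/AUROC built from softmax probabilities with
thresholds at the sorted unique scores, ties grouped, trapezoid area —
equivalent to the normalized Mann–Whitney statistic, which the tests
verify, alongside agreement with pROC.  Macro-averages are included but
secondary.  The published 222-arc confusion matrix is kept in the test
suite as an exact oracle for all seven derived metrics.

## The synthetic cohort generator

No clinical data ships with this package; the generator exists so the
entire pipeline is trainable and testable.  It emulates the *shape* of a
single-isocenter multi-target cranial SRS/SRT cohort:

* ~117 plans of 3–5 arcs (≈468 arcs), 90–180 control points per arc;
* Millennium-120 geometry: 60 opposing pairs, 0.5 cm central leaves,
  small stereotactic jaw openings (X half-width 25–60 mm);
* deliverability by construction: monotone meterset from 0 to 1, monotone
  gantry over a 358° span, leaves inside the jaw aperture, ≥ 0.5 mm
  opposing gap, ≤ 5 mm leaf travel per control point;
* modulation controlled by a dimensionless complexity in `[0,1]` scaling
  a constrained random walk of the leaves (complexity 0 → static
  aperture).

Labels come from a complexity-driven model that is *a stand-in defined by
this package*, not a clinical claim: with `C(arc)` the mean
per-control-point leaf travel normalized by mean aperture width,

```
GPR = clip(118 − 800·C + ε, 0, 100),   ε = −(LogNormal(−0.7, 1.0) − mean)
```

The log-normal deficit gives the heavy left tail portal dosimetry shows;
the baseline above 100 makes low-modulation arcs saturate at 100.0 the way
real cohorts do.  Per-arc complexity is drawn from Beta(0.6, 4).  These
defaults were calibrated once, against the generator's own realized
complexity distribution, to the clinical summary statistics (mean GPR
≈ 96, SD ≈ 8, class mix ≈ 79/14/7%) and then frozen; the test suite
checks the calibration on full-size cohorts.

What passing tests on this cohort show: the pipeline's mechanics, its
invariants, and that the classifier can learn a genuine
complexity-to-class signal end-to-end.  What they do not show: clinical
performance.  Real GPR depends on machine condition, delivery accuracy
and measurement noise, none of which the label model contains; its
complexity→GPR mapping is also far cleaner than reality.

## Scaled study conditions

The full reference protocol (148 folds × up to 1000 epochs, hidden 64)
is a multi-hour computation.  The package's end-to-end demonstrations and
acceptance checks run a scaled version chosen to finish in minutes on one
CPU while exercising every stage: a cohort of ~300 arcs (75 plans, 90–120
control points), hidden size 16, 6 cross-validation folds whose
validation sets partition a per-class-trimmed copy of the training set,
at most 100 epochs per fold with patience 25, minibatch 64, the reference
learning rate 1e-2 with gradient clipping at norm 5, and normalization
enabled.  Under these conditions the held-out accuracy is well above the
70% training goal; the test suite asserts that bound rather than any
exact figure, since the quantity is stochastic across seeds.

## Deployment

`export_model()` writes a versioned, self-contained JSON exchange file:
architecture, input signature (`n × L × 127`), class names, full-precision
weights, and the normalization parameters when fitted — model and
preprocessing travel together.  `load_exported_model()` reconstructs a
predictor, and `parity_check()` verifies native-vs-exported agreement
(logits within 1e-4, class agreement 1.0 on non-tied samples).
`predict_plan()` is the clinical entry point: plan file in, one row per
arc out (predicted class plus three probabilities), with inference well
under a second per plan.

## Numerical choices and edge cases

* Meterset monotonicity and endpoints are validated to 1e-6; arcs failing
  them are rejected at parse time.
* `pad_arcs()` refuses to truncate; padding is idempotent.
* Fold planning requires equal class counts divisible by the per-fold
  validation size and reports the remainder otherwise.
* Sensitivity/specificity raise errors on degenerate matrices (empty
  truth row, all-one-class) rather than returning NaN.
* AUROC on constant scores is exactly 0.5 by tie grouping.
* Softmax is computed with max-subtraction; losses use a 1e-300 floor.

## Known limitations

* The DICOM-RT reader shells out to a bundled pydicom helper; it needs a
  `python` with pydicom on the PATH.  The JSON dialect is the native
  format.
* The label model's clean complexity→GPR mapping means synthetic
  accuracy overstates what clinical data would give.
* SMOTE-before-split leaks information by design fidelity; use
  `smote_first = FALSE` for honest generalization estimates.
* The exported JSON format is this package's own; it is not an ONNX
  file, though it is designed to be trivially consumable by other
  runtimes.
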