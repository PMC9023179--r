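---
title: "Methods: models, conventions and design choices in periopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in periopnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`periopnet` predicts operating-room time requirements as two ordered 4-class
outcomes — surgery duration and anesthesia-emergence duration — from 24
preoperative attributes, and combines the two predictors serially: the
predicted surgery class becomes input A24 of the emergence predictor. This
vignette records the modelling assumptions, every tunable that matters, and
the design decisions taken where the problem statement left the design open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The prediction problem

Both outcomes are classification, not regression, problems: durations are
deliberately coarsened into four right-closed bins (surgery: hourly up to
240 min; emergence: (0,15], (15,40], (40,50], (50,60] min) because exact
durations are dominated by irreducible intraoperative uncertainty while the
bin is what a scheduler actually consumes. The right-closed convention makes
exactly 60 minutes "up to one hour", matching the ≤ phrasing of the first
bin; it is applied uniformly. The emergence bin (15,40] is far wider than
its neighbours; we implement the printed scheme as-is and treat the question
of whether that width is intentional as out of scope.

Records whose outcome falls on or beyond the cap (surgery ≥ 240 min,
emergence ≥ 60 min) are excluded by `clean()`, which also enforces the
categorical level sets and finiteness. A configurable IQR outlier fence is
provided but **off by default**: beyond the duration caps, no concrete
outlier rule is prescriptive, so a silent default would manufacture
exclusions.

## 2. The preprocessing algorithm

The pipeline composes clean → bin/encode → normalize → balance → augment →
partition.

**Normalization.** Only the target interval [0.1, 0.9] is prescriptive; the
map itself is our choice and we use the simplest one consistent with it,
the affine min–max map `x ↦ 0.1 + 0.8 (x − min)/(max − min)` fitted
per attribute. A constant attribute maps to the midpoint 0.5. Categorical
attributes are first encoded as the ordinal integer codes of their printed
level numbering and then normalized like any other attribute — a single
numeric representation for "all the data". Values outside the fitted range
(possible when parameters fitted on one set are applied to another) map
outside [0.1, 0.9] and are not clipped.

**Automatic balancing.** Class `i` (size `n_i`) is replicated by the
integer multiple `m_i` minimising `|m · n_i − n_max|`; exact ties go to the
larger multiple, as the bracket form `2n_max/(k−2) ≥ n_i > 2n_max/k → m =
(k−1)/2` forces. The implementation uses the closed form
`m = ⌊(2 n_max − n_i) / (2 n_i)⌋ + 1` in exact integer arithmetic; a
brute-force argmin oracle verifies it exhaustively for all
`1 ≤ n_i ≤ n_max ≤ 500` in the acceptance suite. Replicas are **exact
copies** (tagged `balanced-replica`): balancing and noise enhancement are
separate stages, and conflating them would make the balancing multiple and
the enrichment multiple non-orthogonal. A class with zero records is
skipped with a warning rather than an error, so small synthetic fixtures
with empty classes still run.

**Noise augmentation.** Enrichment to `M` times the input size adds, for
each record, `M − 1` copies with independent uniform noise on
[−0.03, +0.03] added to every (already normalized) input cell, labels
unchanged. Only the noise *bounds* are prescriptive; uniform is the maximum
entropy choice on a bounded interval and we do not clip the result. The
phrase "increased by three times" is ambiguous between *final size = 3×*
and *+3× (4× total)*; we adopt the total-size reading as the default and
make `multiple` an ordinary parameter, so the other reading is `M + 1`.

**Partition.** 60/20/20 by uniform seeded shuffle, sizes
`⌊0.6n⌋ / ⌊0.2n⌋ /` remainder.

**Ordering modes.** The faithful flow balances and augments *before*
partitioning, which means exact replicas and noisy near-copies of one
source record can land in training and test simultaneously — an optimistic
bias on synthetic and real data alike. We keep that flow as
`paper_faithful` (the default, because it is the documented procedure) and
provide `leakage_safe`, which partitions the original records first and
balances/augments the training split only; the provenance tags and the
stage report make the mode of any run auditable. Accuracies from
`paper_faithful` runs should be read as measuring the pipeline, not
generalisation.

## 3. The MLP core

A fully connected network, 24 inputs → L hidden layers of H units → 4
softmax outputs, cross-entropy loss, mini-batch Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8), batch 100, the last partial batch used. Choices the
problem statement leaves open, and what we did:

* **Hidden activation**: unstated; ReLU by default (switchable to
  tanh/sigmoid) — the standard choice for MLPs of this depth.
* **Learning rate**: unstated beyond "Adam"; the Adam default 0.001.
* **Initialization**: unstated; seeded fan-in-scaled Gaussians
  (`sd = √(2/fan_in)`), recorded via the seed so builds are reproducible.
* **Dropout**: inverted dropout after each hidden layer; `p = 0` draws no
  random numbers, so it is *exactly* the dropout-free network, RNG stream
  included — the dropout experiment's baseline row is therefore an exact
  replicate, not a statistical twin.
* **Determinism**: one seed governs initialization, shuffling and masks;
  training has an exact epoch-prefix property (the first E epochs of a
  longer run equal an E-epoch run), which the tests assert.

No early stopping, schedules, weight decay or batch normalization: none are
part of the procedure being implemented.

**A note on loss magnitudes.** Published loss tables for systems of this
kind sometimes cluster near 0.61–0.70 even at ~95% accuracy, which is
inconsistent with 4-class softmax cross-entropy (uniform scores give
ln 4 ≈ 1.386; 95% accuracy with calibrated scores gives ≪ 0.3). Our loss
is the standard mean multi-class cross-entropy; absolute loss values from
differently conventioned reports are not comparable to ours and are not
acceptance quantities.

## 4. Selection protocol

The grid is {3,4,5,6} layers × {64,128,256,512} widths, 10 replicates per
cell with seeds derived deterministically from one master seed
(Lehmer-style mixing mod 2³¹−1), summarised as Mean/Std/Max/Min per split
plus total runtime per architecture.

* **t-test variant**: the comparisons are phrased directionally
  ("significantly better"), and near-equal means reportedly give p ≈ 0.49 —
  the signature of a one-tailed test. We therefore use a one-tailed,
  pooled-variance two-sample t-test by default, with Welch and two-sided
  variants as options. Two identical replicate vectors give p = 0.5,
  flagged degenerate. No multiple-testing correction is applied, matching
  the raw pairwise protocol; the selection object reports the number of
  comparisons so a reader can apply their own.
* **Selection rule**: within each layer count, the width with the best mean
  testing accuracy wins unless a cheaper width is not significantly worse
  (α = 0.05) and saves runtime, in which case the cheaper one is taken; the
  per-layer winners then compete under the same rule. Every comparison is
  recorded in a trace (p, runtimes, saving %, keep/demote). Runtime is
  wall-clock per architecture over all replicates — reported for the
  decision, never an acceptance quantity, because it is hardware-bound.
* **Pairing**: replicate t-tests are unpaired; nothing indicates the
  original comparisons shared splits across cells, and our replicates
  differ in initialization and shuffling, not data.

## 5. The serial system

Stage 2 is trained on **true** surgery classes; the cascade is purely an
evaluation-time rewiring in which the stage-1 prediction replaces A24 and
is pushed through the **same fitted normalization map** as the true class
it replaces. This identity of encodings is what makes the exactness
properties hold: a perfect stage 1 yields bitwise-identical stage-2 inputs,
hence combined accuracy equal to oracle accuracy, and any divergence
between cascade and oracle predictions is confined to stage-1 errors. Both
properties are asserted per-sample in the tests. A `train_on_predictions`
variant is deliberately **not** the default; it would change stage 2's
training distribution and break the oracle comparison.

## 6. The synthetic cohort: what it does and does not establish

The generator is a stated world, not a tuning knob. Defaults: 2,000 cases;
surgery class probabilities (0.40, 0.30, 0.20, 0.10) — imbalanced so the
balancing stage is exercised; continuous physiology attributes drawn from
truncated normals over published adult reference ranges with
`sd = range/20`, class-conditional means shifted by `effect_size` (default
1.5, acceptance fixture 3) within-class standard deviations per class step;
surgical grade agreeing with the surgery class with probability 0.8; the
emergence class drawn from a fixed row-stochastic matrix with ≈0.88–0.90
diagonal mass and stochastically increasing rows; durations uniform within
their class bins. Marginal ranges, level sets, determinism and the monotone
dependence are all tested exhaustively per cohort.

What it does **not** emulate: the real attribute correlation structure,
missing data (complete-case data are assumed), any site- or
surgeon-specific effects, and realistic class overlap at `effect_size = 3`
— that fixture is *designed* to be nearly separable so that learning-sanity
thresholds measure the trainer, not the data. A green acceptance suite
therefore establishes that the pipeline's algorithms are implemented
correctly and that training behaves qualitatively as expected (enrichment
and longer training help; dropout does not, absent overfitting); it says
nothing about clinical accuracy on hospital data.

## 7. Numerical conventions

* Argmax ties in prediction break toward the lowest class index.
* Cross-entropy clamps probabilities at 1e-12 to avoid −∞ on saturated
  softmax outputs.
* Binning uses exact right-closed `findInterval` arithmetic; the balancing
  multiple uses integer division, so no floating-point boundary case can
  flip a multiple.
* Seeds: every stage derives its seed from the master seed and fixed salts;
  all derived seeds stay below 2³¹.

## 8. Scaled-down testing

The full protocol (16 cells × 10 replicates × 200 epochs on ~15k records)
is hours of CPU; the test suite runs the same code paths at reduced scale
(toy grids, 2 replicates, few epochs) and the acceptance suite fixes one
medium fixture (n = 2,000, 4-256, ≤50 epochs, ~5 min). The enrichment
comparison in the acceptance suite uses (M = 3, 25 epochs) against
(M = 10, 50 epochs) — the doubled-epochs contrast at sizes that fit the
budget; the canonical (M, E) ladder remains the default of
`enrichment_experiment()`.

## 9. Known limitations

* `paper_faithful` mode's optimistic bias (section 2) is inherent to the
  documented flow; use `leakage_safe` for honest generalisation estimates.
* The generator's independence of attributes given the class is a
  simplification; accuracy on it upper-bounds nothing about real cohorts.
* Runtime accounting is wall-clock and hardware-bound; only runtime
  *ratios* on one machine are meaningful, and only the decision rule, not
  the seconds, is tested.
* The CLI covers the simulate/run orchestration; per-stage subcommands
  beyond that are thin wrappers over the exported functions, which are the
  supported programmatic interface.
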