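---
title: "Multi-subject transfer learning for motor-imagery EEG: models, protocol and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-subject transfer learning for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitransfer)
```

## The problem

Four-class motor imagery (left hand, right hand, feet, tongue) modulates
the power of sensorimotor rhythms: imagining a movement desynchronises the
mu (8–12 Hz) and beta (18–26 Hz) bands over class-specific scalp regions
(event-related desynchronisation, ERD). A classifier trained on a pool of
*source* subjects transfers poorly to a new *target* subject because
anatomy, electrode placement and idiosyncratic rhythms shift the feature
distribution between subjects. `mitransfer` implements a complete pipeline
for this setting:

1. **Pre-training (cloud side):** leave-one-subject-out (LOSO) training of
   dual-branch attention CNNs on the source cohort, with optional
   genetic-algorithm (GA) channel selection over the 22-electrode 10–20
   montage.
2. **Online retraining (edge side):** a prequential, session-divided
   loop over several target subjects sharing one model — each block of
   trials is first *predicted* with the currently saved classifier, then
   used to *retrain* it under a freeze level, a reduced learning rate and
   a save-if-improved rule.
3. **Accounting:** exact parameter and multiply-accumulate (MAC) counts
   per layer, so the cost of every freezing strategy is known.

A synthetic ERD generator provides the test bed: everything in the test
suite and the acceptance script runs on data generated in code.

## The network family

All variants share one architecture; they differ only in the stage-1
temporal filter bank (Table: FCNNA 96 filters of width 60, XFCNN 16×60,
LFCNN 8×48; stage 2 always 16 filters of width 64; depth multiplier 2 in
stage 1 and 1 in stage 2; separable kernels 16 wide). The forward graph
is:

* a shared **temporal convolution** (1×KE1, `F1` filters) acting as a
  learned filter bank over the raw 22×T window;
* **branch A**: a depthwise *spatial* convolution (22×1, depth `D`,
  valid) that collapses the channel axis into `F1·D` learned spatial
  filters, then batch norm, ELU;
* **branch B**: a channel average followed by a separable temporal
  convolution (1×16) to `F1·D` maps, batch norm, ELU — a cheap
  "global rhythm" pathway complementing the spatial filters;
* concatenation (2·F1·D maps) and a **convolutional attention block**:
  spatial attention (feature-wise mean/max, a 1×7 convolution, a sigmoid
  gate over time) followed by channel attention (global average and max
  descriptors, per-path two-layer bottleneck MLPs at ratio 2, summed
  sigmoid gate over features);
* a 1×1 **projection** to 16 maps, the **stage-2 temporal convolution**
  (1×64), a per-map gain (the stage-2 depthwise step — the spatial axis
  is already collapsed, so with depth multiplier 1 it reduces to a
  scalar per map), a parallel stage-2 separable branch, average pooling
  (1×16) at the branch ends, a second attention block, and a dense
  softmax over the 4 classes.

With a 22×1125 input this yields 361,638 parameters / 195.7 M MAC for
FCNNA and 31,982 / 29.8 M for LFCNN — within a few percent of the
published totals for this family (358.2 K / 184 M and 31.86 K / 35 M),
whose exact attention and dense dimensions are not public. Pooling is
concentrated at the stage-2 branch ends (a single 1×16 window) rather
than split across stages; this keeps the stage-2 temporal convolution on
the unpooled time axis, which is what places the smaller variants' MAC
totals in the published range.

```{r accounting}
m <- build_model(model_variant("FCNNA"), 22, 1125)
count_total_params(m)
total_mac(m) / 1e6
```

## The layer registry and freeze levels

Fine-tuning freezes a *prefix* of the flat layer registry. The registry
is a freeze ordering, not the execution order: entries are grouped so
that the four published depths land on semantic boundaries —

* **6** — the stage-1 temporal filter bank (+ its norm): "only
  time-domain filters preserved";
* **16** — adds both spatial depthwise blocks;
* **26** — adds both separable-convolution blocks;
* **44** — extends through the first attention block's spatial attention,
  its average-path MLP and the max-path first dense.

The stage-2 temporal convolution and everything from the first attention
block's max-path output dense onward stay trainable at level 44; at that
depth FCNNA retains 107.9 K trainable parameters (published: 114.5 K).
Because every channel-dependent weight (the spatial depthwise filters)
sits at or below index 16, trainable counts at levels ≥ 16 are identical
with and without channel selection — the published property that made the
freeze strategy attractive for selected-channel models.

```{r freeze}
sapply(freeze_levels(), function(lv)
  count_trainable_params(set_freeze_level(m, lv)))
```

Frozen entries are excluded from the optimiser *and* their batch-norm
layers run in inference mode with frozen statistics, so a frozen prefix
is bit-identical after any amount of training (asserted in the tests).

## Training machinery

The forward/backward passes are written in vectorised R over
(features, time, channels, batch) arrays, with the convolution,
batch-norm and ELU kernels in compiled code; every analytic gradient is
validated against central finite differences in the test suite. The
optimiser is Adam (β₁ = 0.9, β₂ = 0.999); the pre-training default
learning rate is 0.0009 ("LR0"), and the transfer grid uses
LR1 = 1e-4, LR2 = 9e-5, LR3 = 1e-5. Batch size defaults to 64
(clamped to the data). Loss is categorical cross-entropy. Dropout
(rate 0.25) follows each branch; batch-norm momentum is 0.9, chosen so
that running statistics converge within the short desk-scale training
runs used throughout the package (with the conventional 0.99, inference
statistics lag the weights by hundreds of steps and systematically
understate early-training accuracy). A checkpoint rule keeps the weights
of the epoch with the highest monitored training accuracy.

## The synthetic generator

`generate_subject()` emulates the statistical structure the method
assumes, not raw EEG realism:

* 22 channels at 250 Hz, 7 s trials (baseline 0–2 s, imagery 2–6 s with
  0.1 s cosine ramps, rest 6–7 s);
* 1/f ("pink") background noise on every channel;
* narrow-band rhythms on the informative channels; on a class-`c` trial
  the rhythm power of class `c`'s band on class `c`'s channels drops by
  the ERD depth (default 0.6) during the imagery interval;
* rhythm-to-noise ratio 10 dB on informative channels;
* a per-subject random orthonormal channel rotation (matrix exponential
  of a scaled skew-symmetric draw) creating inter-subject shift, plus a
  smaller per-session drift rotation.

Two layouts are provided: `"sensorimotor"` (18 informative channels
following contralateral hand / midline foot / central tongue topography)
and `"focal6"` (six informative channels: three disjoint mu-band pairs
for classes 1–3 and a beta-band footprint over all six for class 4),
used by the channel-selection studies because the ground-truth set is
small and known. What passing tests on this generator show is that the
pipeline recovers *planted, band-limited, spatially localised* class
structure under distribution shift; they cannot show robustness to real
EEG artifacts, non-stationarities, electrode impedance changes or
rhythm asymmetries, which the generator does not model.

## Channel selection

`ga_select()` is a plain generational GA over 22-bit masks: tournament-2
selection, uniform crossover (0.8), bit-flip mutation (0.02), 2 elites,
population 24 by default, with all-zero candidates repaired and fitness
values cached by mask. Following the published practice the search is
repeated 2–3 times and the best mask over *all* evaluated individuals is
kept. The fitness of a mask is cross-subject accuracy: train the variant
on all source subjects but one, restricted to the mask, and score the
held-out subject.

Training a CNN from scratch for every mask is the full-fidelity path and
is supported, but a search at desk scale uses the warm-started fitness:
a base model is first trained once on the full montage, and each mask's
model copies every channel-count-independent parameter from it while the
spatial depthwise filters are *restricted to the masked channels* (row
subsetting). A short fine-tune (default 3 epochs) then yields a fitness
that reflects how much of the learned spatial-filter mass the mask
retains — masks covering the informative channels score high immediately.
This amortises the expensive temporal-feature learning across the whole
search and, on the planted-signal cohort, makes the fitness rank masks
by their overlap with the informative set.

## The online protocol

`make_divisions()` reproduces the published session grids exactly at the
nominal 600-trial size — six divisions (0–90, …, 450–600) or four
(0–140, 140–280, 280–420, 420–600) — and falls back to equal splits with
the remainder absorbed by the last range elsewhere (the same shape as the
printed grids, whose last range is the largest). `build_schedule()`
alternates subjects within each division, so several target subjects
share one model over interleaved rehabilitation sessions; 140 and 90
seven-second trials make 17- and 11-minute sessions respectively.

For each schedule entry `online_tl_run()`:

1. predicts the entry's trials with the currently *saved* classifier and
   records the prequential accuracy (measured strictly before any update
   — a sentinel-corruption audit in the tests verifies zero lookahead);
2. retrains the working model on the subject's accumulated trials —
   5 warm-up epochs for a subject's first session, the configured epochs
   (grid 30/50/100/200) afterwards — at the configured learning rate and
   freeze level;
3. persists the weights as the new saved classifier only if the
   session-end monitored accuracy (on the entry's trials) improved on
   the best so far, so the persisted sequence is non-decreasing.

Design choices on points the protocol leaves open: retraining uses the
*instructed* cue labels by default (in a rehabilitation setting the cue
is known; a pseudo-label mode training on the model's own predictions is
provided but non-default); each entry retrains on its own subject's
accumulated pool rather than a cross-subject mixture; and the whole run
is repeated `n_runs = 3` times (seeds s, s+1, s+2) with means reported.
Reports carry per-entry, per-subject (trial-weighted) and group-average
accuracies ("AVG all" and every pair).

## Problem sizes used in the tests and acceptance script

The validation studies run at desk scale, chosen once as the smallest
sizes at which the examined effects are statistically visible: windows of
2 s from cue onset decimated to 62.5 Hz (channel selection) or 50 Hz
(transfer), the LFCNN variant, 100 trials per session for the
planted-signal cohort (200 per subject), 32 per session for the transfer
study, warm-started GA fitness with 3 fine-tune epochs, and transfer
pre-training of 80 epochs. The decimation is standard practice for
rhythms living below 30 Hz and cuts classifier cost proportionally; the
4 s imagery interval at full length and rate is supported and simply
costs more. Full-scale runs (22 channels, 4.5 s windows at 250 Hz,
hundreds of trials, 1000-epoch pre-training) use the same code paths.

## Numerical choices and degenerate inputs

* Glorot-uniform initialisation, deterministically seeded; two builds
  from one seed are identical, and every stochastic entry point
  (generation, training, GA, the online loop) restores the caller's RNG.
* Batch-norm ε = 1e-3; attention max-pooling breaks ties toward the
  first index; softmax subtracts the column maximum.
* Trials shorter than the widest kernel are a configuration error;
  single-class training warns but runs; empty masks and empty schedules
  error.
* `train_model()` with 0 epochs is the identity (used for the no-update
  baseline).

## Known limitations

* The attention/dense dimensions of the published architecture are not
  public; totals here match the published accounting to within a few
  percent but not exactly, and the registry's freeze boundaries encode
  this package's reconstruction.
* The generator's shift model (orthonormal channel rotations) is a
  convenient stand-in for inter-subject variability; real shifts are not
  orthonormal.
* The GDF reader/writer covers the subset of GDF 2.20 needed for
  cue-annotated motor-imagery sessions (one record per trial, uniform
  sampling, event codes 768–772) and is not a general biosignal parser.
* Training runs on the CPU; the engine is sized for desk-scale
  experiments and edge-scale fine-tuning, not for full-scale
  pre-training sweeps.
* With only tens of training trials and the full 22-channel montage the
  higher-capacity variants tend to memorise the sample before extracting
  band-power structure (a linear classifier on log band power solves the
  same data easily); benchmark-scale cohorts do not hit this regime, and
  the desk-scale studies avoid it through channel restriction, warm
  starts and moderate trial counts.
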