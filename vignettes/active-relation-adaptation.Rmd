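---
title: "Cross-subject sEMG activity recognition with active relation-network adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject sEMG activity recognition with active relation-network adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface electromyography (sEMG) classifiers for human activity recognition
degrade sharply on people they were not trained on: electrode placement,
skin impedance, anatomy and movement style all shift the signal
distribution between subjects. `emgadapt` implements an active-learning
adaptation framework for this cross-subject setting. A model pre-trained
on source subjects is adapted to a new target subject with a small,
deliberately chosen labeling budget, along two complementary routes:

* **backward strategy** — gradient fine-tuning of the model parameters on
  a small set of actively selected, newly labeled target windows;
* **forward strategy** — replacing the model's *template set* (its second
  input, see below) with representative target windows, which changes the
  model's behaviour without touching any parameter.

## The model

The classifier is a twin **relation network**. Its two inputs are a query
window `x` (shape `1 × N × L`: one matrix of `N` channels by `L = 200`
samples, i.e. a 200 ms window at 1 kHz) and a template set `T` holding
`K` labeled windows for each of the `C` classes (the *shots*; `K = 5` by
default).

A shared feature extractor `G` — two convolution blocks, each a
`1 × 3` convolution with 16 filters (stride 1, same padding), batch
normalization, Softsign activation and `1 × 2` max pooling — maps every
window to a `16 × (L/4)` feature map. For each class, the feature maps of
its `K` templates are summed into a single class map; the query's map is
replicated `C` times and concatenated channel-wise with each class map,
producing `C` relation matrices with 32 feature channels.

A relation head — two convolution blocks (no pooling), then a
100-unit fully connected block with batch norm, Softsign and 30%
dropout, then a single sigmoid unit — scores each relation matrix
independently, yielding a *relation score* `r_c ∈ (0, 1)` per class:
the learned similarity between the query and class `c`'s templates. The
predicted class is the argmax (ties to the lowest class index). Scores
are similarities, not probabilities — they need not sum to one.

There are three heads with identical topology: the main classifier `F`
and two auxiliary classifiers `F1`, `F2` used only for data screening.

## Objectives

* Pre-training minimizes a relation-score cross-entropy over labeled
  source windows. The literal positive-only form `−log r_y` is exposed as
  `ce_loss()`, but as a *training* objective it is degenerate — a head
  that outputs 1 for every class minimizes it — so training uses the
  binary cross-entropy variant, which adds `−log(1 − r_c)` for every
  wrong class (`ce_loss(..., negatives = TRUE)`).
* The discrepancy between two heads on one window is the per-class mean
  Manhattan distance `d(a, b) = (1/C) Σ_c |a_c − b_c|` (`manhattan_d()`).
* Auxiliary training minimizes
  `CE(F1) + CE(F2) − Ldis`, where `Ldis` (`ldis()`) is the batch mean of
  `d(r1, r) + d(r2, r) + d(r1, r2)` over *unlabeled target* windows: the
  two auxiliary heads stay accurate on the source while being pushed
  apart on the target, so their disagreement traces the region around
  the decision boundary. The extractor and main head are frozen here —
  bit-exactly, which the tests assert.

## Data screening and the adaptation loop

For each unlabeled target window the total discrepancy
`D(x) = d(r1, r2) + d(r, r1) + d(r, r2)` is computed, and the acquisition
score `S(x) = D(x) − mean(D over source windows)` subtracts the source
mean as a domain offset (rank-preserving; the source pool may be
subsampled, 2000 windows by default). The pool is partitioned into the
`n1` highest-S windows — **important data**, near the boundary — and the
`n2` lowest — **confident data**, near the domain centre. An oracle
(standing in for the human annotator) labels both, counting each window
against the budget once.

Each `adapt()` round then:

1. discrepancy-trains the auxiliary heads;
2. scores and partitions the pool, labeling `n1 + n2` windows
   (`n1 = 250`, `n2 = 50·C` by default);
3. rebuilds the template set from the confident windows — embeddings from
   the frozen extractor, pooled PCA to 3 dimensions, K-means into `K`
   clusters per class (10 restarts, 300-iteration cap), one
   nearest-to-centroid *real* window per cluster (centroids themselves
   are never used as templates); classes with fewer than `K` confident
   windows keep their previous templates, with a warning —
   and fine-tunes the extractor and main head on the cumulative sample
   set.

## Training procedure and presets

Optimization is Adam with an exponential step decay
`lr(e) = lr0 · 0.95^⌊e/2⌋`. The `"classic"` preset uses the method's
reference schedule — 100 epochs, batch 64, `lr0 = 0.5`; that learning
rate is aggressive for Adam, and the preset exists for completeness and
comparison. The `"stable"` preset (default; 16
epochs, batch 32, `lr0 = 0.01`, at most 600 source windows visited per
epoch) is what the experiment harness and the test suite use.

Two training choices deserve emphasis:

* **Episodic pre-training with a warm-up.** If the template branch is
  fed one fixed template set throughout training, the heads memorize it
  as a constant and *any* later template swap — the entire forward
  strategy — collapses accuracy (we measured drops from ~92% to below
  30% on a held-out subject). Pre-training therefore re-draws the `K`
  templates per class from the source split at every minibatch after a
  short warm-up phase (40% of epochs) against one fixed draw; the
  warm-up learns discriminative features quickly, the episodic phase
  generalizes the similarity. This is the standard relation-network
  episode protocol.
* **Auxiliary initialization.** After pre-training, `F1` and `F2` are
  seeded, slightly perturbed copies of the trained main head
  (`aux_init_sd = 0.01`), so all three classifiers start near-identical
  and the `−Ldis` term grows their disagreement from zero.

The CE term of the auxiliary objective uses the labeled source split: at
round one no labeled target data exist, so this is the only consistent
reading. Fine-tuning continues incrementally across rounds on the
cumulative sample set, against the current (target) template set.

## The synthetic cohort

`generate_cohort()` emulates a gait experiment: each subject cycles
through `C = 4` activity classes (the gait phases) in ~350 ms segments
with 20% duration jitter. Per channel, a band-limited (20–450 Hz)
unit-variance noise carrier is amplitude-modulated by a raised-cosine
activation envelope whose class-by-channel weights mimic muscle
synergies. Subject individuality enters through log-normal per-channel
gains (`gain_sigma`), log-normal per-subject jitter of the
class-by-channel weights (`channel_weight_sigma`, the main driver of the
cross-subject gap that survives per-channel peak normalization), a
row-stochastic nearest-neighbour channel-mixing matrix standing in for
electrode shift (`mixing_strength`), an envelope timing shift
(`shift_sigma_ms`) and per-class activation scales
(`envelope_scale_sigma`). Defaults (0.35 / 0.5 / 0.35 / 15 ms / 0.25,
noise floor 0.05) were chosen once to produce a clear but recoverable
cross-subject gap — source-only accuracy around 60–90% on a held-out
subject against within-subject ceilings above 95%.

What the simulator does *not* emulate: motor-unit physiology, fatigue,
non-stationarity within a trial, label noise from real gait-phase
detection hardware, and correlated multi-day electrode re-placement.
Passing tests therefore demonstrate that the machinery behaves as the
framework intends under a controllable distribution gap — not that the
same accuracy numbers would be obtained on any particular real dataset.

## Evaluation protocol

Experiments are leave-one-subject-out (`loso_run()`): each subject in
turn is the unseen target, the rest are the source. The held-out
subject's windows are split into a temporally contiguous adaptation pool
(first half, the only part the labeling oracle may touch) and a disjoint
evaluation half. This split matters: with 200 ms windows advanced by
25 ms, adjacent windows share 87.5% of their samples, and evaluating on
the same pool that supplied the labeled windows rewards scattering
labels everywhere regardless of their information content.

Metrics (`classification_metrics()`) are accuracy, precision and recall
in percent; for more than two classes, precision and recall are
one-vs-rest macro-averages (micro-averages are also reported, since the
binary-form definitions do not pin down the multi-class average).

The default study scale — 4 subjects, 9 channels, 1 kHz, 20 s per
subject (793 windows each), 5 seeded replicates, 5 auxiliary epochs — is
the package's choice for routine, single-CPU reproduction of every
claimed property; all of it is configurable upward.

## Numerical choices

* Cross-entropy clamps scores to `[1e−7, 1 − 1e−7]`.
* Batch norm uses `eps = 1e−5`, momentum 0.1 for running statistics;
  evaluation always uses running statistics, training always uses batch
  statistics.
* Weight initialization is seeded Glorot-uniform; the three heads are
  initialized independently.
* Argmax ties break toward the lowest class index; K-means medoid ties
  toward the first nearest member; partition ties toward the lower
  window index. All are deterministic and tested.
* Windows are 0-based, half-open `[start, start + L)`; a window's label
  is the majority per-sample label of its span, and windows without a
  strict majority (label transitions) are flagged but kept.
* The backward passes of every layer are hand-derived and verified
  against central finite differences in the test suite.

## Known limitations

* The relation heads' episodic convergence has a plateau phase; very
  short training (a handful of epochs) can leave the model at base-rate
  predictions. The warm-up/episodic split mitigates but does not remove
  this; the loss trajectory attribute of `pretrain()` makes it easy to
  check.
* The bottom-`n2` confident set can be class-skewed when classes differ
  in transfer difficulty; uncovered classes fall back to their previous
  templates rather than receiving fresh ones.
* Timing columns in `template_count_study()` are informational only and
  hardware-dependent.
* A stated nominal window shape of `1 × 9 × 200` at a sampling rate of
  1111.11 Hz is internally inconsistent with a 200 ms window (which is
  ≈ 222 samples at that rate); this package always computes `L` from
  `window_ms × fs`, so at 1111.11 Hz a 200 ms window has 222 samples.
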