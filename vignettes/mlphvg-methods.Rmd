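---
title: "Multiscale limited penetrable horizontal visibility graphs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale limited penetrable horizontal visibility graphs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mlphvg)
```

## The method

A univariate series $\{x(i)\}_{i=1}^N$ is mapped onto a family of networks in
three steps.

**Coarse-graining.** At scale factor $s$ the series is reduced to
$M = \lfloor N/s \rfloor$ points by averaging consecutive non-overlapping
windows,
$$y^{(s)}(j) = \frac{1}{s} \sum_{i=(j-1)s+1}^{js} x(i),$$
discarding any trailing remainder — the convention of the multiscale-entropy
literature. At $s = 1$ the series is untouched.

**Visibility.** Each coarse-grained sample becomes a node, kept in time
order. In the horizontal visibility graph (HVG) two samples $i < j$ are
linked iff every in-between sample lies strictly below both endpoints,
$$y(n) < \min\{y(i), y(j)\} \quad \text{for all } i < n < j.$$
The limited penetrable variant (LPHVG) relaxes this: an in-between sample
with $y(n) \ge \min\{y(i), y(j)\}$ is a *blocker*, and the link exists iff
the number of blockers is at most the penetrable distance $L$. $L = 0$
recovers the HVG exactly, and edge sets are monotone in $L$; $L$ adds
robustness of the topology against noise-induced occlusions. Adjacent
samples always connect, so every graph is connected.

**Network statistics.** Per node, the clustering coefficient
$C_i = \tau_{i,\Delta} / \tau_i$ is the number of closed triplets centred on
$i$ over the number of triplets $\tau_i = \binom{\deg_i}{2}$ ($C_i = 0$ when
$\deg_i < 2$). Two summaries form the per-scale feature pair:

* the **average clustering coefficient** $\bar C = \frac{1}{M}\sum_i C_i$
  (zeros included), and
* the **clustering coefficient entropy**
  $E_C = -\sum_i p_i \ln p_i$ with $p_i = C_i / \sum_j C_j$ taken over nodes
  with $C_i > 0$.

Classification of two signal classes uses these two-dimensional feature
vectors at a chosen scale with a support vector machine, evaluated by
leave-one-out cross-validation and by 10×-repeated stratified 10-fold
cross-validation (mean of the ten per-repeat accuracies).

## Tie handling and other numerical choices

* **Ties block.** The visibility criterion is strict, so an in-between
  sample *equal* to the lower endpoint obstructs the line. A constant series
  therefore yields the path graph. Endpoints of equal height may still
  connect when everything between them is strictly lower.
* **Blocker definition.** A blocker is $y(n) \ge \min\{y(i), y(j)\}$ — the
  exact negation of the strict criterion, which is what makes $L = 0$ reduce
  to the HVG edge-for-edge.
* **Entropy conventions.** Natural logarithm (a base change only rescales
  and cannot affect classification); normalization over strictly positive
  $C_i$; an all-zero profile maps to $E_C = 0$. $E_C$ is bounded by
  $\ln \#\{i : C_i > 0\}$.
* **Amplitude invariance.** Visibility depends only on order relations among
  sample heights, so all graphs — and hence all features — are invariant
  under $x \mapsto a x + b$ with $a > 0$. This is asserted by tests.
* **Construction.** The fast builder (C++) scans outward from each node,
  keeping the in-between window as a sorted array; the scan stops once the
  window holds more than $L$ values $\ge$ the left endpoint, after which no
  farther link is possible whichever endpoint is lower. A literal
  double-loop reference implementation (`build_lphvg_oracle`) with a full
  blocker count per pair is shipped and the two are required to agree
  edge-for-edge on randomized inputs.
* **SVM tie-break.** A decision value of exactly 0 predicts class 0, for
  determinism. Training folds with zero variance in every feature dimension
  fall back, with a warning, to majority-class prediction (ties toward 0).
* **Non-finite samples** are rejected at load time with the offending line
  number; silently dropping them would change the graph topology invisibly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scales` | `1:5` | coarse-graining factors (dimensionless); each scale must leave ≥ 2 points |
| `L` | `1` | penetrable distance (count of tolerated blockers); `1` is the setting used throughout the EEG analysis |
| `kernel`, `cost`, `gamma` | radial, 1, `1/d` | SVM configuration (`svm_config()`); 2-D features make results insensitive to these within reason |
| `standardize` | `TRUE` | center/scale features with *training-fold* statistics only |
| `k`, `repeats` | 10, 10 | stratified k-fold protocol; accuracy is the mean of the per-repeat accuracies |

The scale list is a genuinely open choice — the method itself does not fix
an upper scale — so it is a user parameter with the documented default
`1:5`, which keeps even a 4096-sample series above 800 nodes at the largest
scale. Stratified (rather than plain) partitions are used in the k-fold
protocol to guarantee both classes in every training fold; on balanced
100 + 100 data the two coincide in expectation.

## What the synthetic data emulates — and what it does not

The package is fully testable without external recordings. The generators
(all seed-deterministic, RNG state restored afterwards) provide:

* `gen_iid()` — uniform noise; for uncorrelated continuous series the HVG
  mean degree converges to the exact limit 4, used as a closed-form
  correctness check at $N = 10^5$ (observed $|\bar k - 4| < 0.05$).
* `gen_periodic()` — a sinusoid tiled from one exactly-computed period so
  the signal is bitwise periodic; its HVG degree sequence is then exactly
  periodic away from the boundaries, another structural check.
* `gen_logistic()` — logistic-map trajectories: fully chaotic at $r = 4$,
  period-2 at $r = 3.2$.
* `gen_two_class_dataset()` — the surrogate for the benchmark contrast
  between healthy surface EEG and ictal intracranial EEG: class 0 is an
  AR(1) process with coefficient 0.9 (short-memory linear background),
  class 1 is logistic-map chaos ($r = 4$, random initial condition), a
  minimal conventional pair differing in *nonlinear temporal structure*.
  Defaults are 100 signals per class of length 4096, matching the benchmark
  set sizes and the order of its 4097-sample segments. Every series is
  standardized to zero mean and unit variance, so no amplitude cue exists
  and any separation must come through the network topology — the pathway
  the method claims to measure.

The surrogate is *not* physiological EEG: it has no 1/f spectrum, no
artifacts, no nonstationarity, and its two classes are far cleaner than real
ictal-vs-background segments. Passing the end-to-end test (accuracy
$\ge 0.95$ under both protocols at scale 2, $L = 1$) shows the pipeline is
wired correctly and discriminates temporal structure; it does not certify
clinical performance on real recordings.

## Problem sizes used by the tests and acceptance script

Randomized construction checks use 100 series of lengths 10–500 against the
literal reference builder; the closed-form degree check uses one series of
$10^5$ samples; the end-to-end experiment uses the full 100 + 100 × 4096
surrogate. These sizes give stable statistics (the mean-degree estimate at
$10^5$ has standard error well below the 0.05 band) while completing in
minutes on one CPU.

## Known limitations

* Worst-case construction time is quadratic for adversarial monotone
  series, where no early termination is possible; typical (noisy) series
  scan only a short window per node.
* Only the horizontal, undirected, unweighted visibility family is
  implemented — no natural visibility graphs, weighted/directed variants,
  or streaming updates.
* The classifier surface is deliberately the fixed two-dimensional feature
  pair; no feature selection or probability calibration is provided.
* EDF/BDF containers are not parsed; export recordings to single-column
  text first.
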