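---
title: "Compression indices for maternal-fetal heart-rate analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression indices for maternal-fetal heart-rate analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`ctgcompress` asks whether compression-based complexity indices, computed
on simultaneous fetal (FHR) and maternal (MHR) heart-rate series, separate
acidemic (umbilical arterial pH < 7.15) from non-acidemic deliveries. The
pipeline is: simulate (or load) paired 4 Hz recordings of roughly the last
two hours of labour; clean artifacts; decompose each channel into a slow
trend and a fast residual; cut labeled 10-minute windows; symbolize each
component with a Lloyd-Max quantizer; compute three families of
compression indices per window; balance the rare acidemic class with
SMOTE; and evaluate nine feature subsets with cross-validated classifiers.

The underlying modelling assumptions are:

* heart-rate series decompose additively into a slow baseline drift
  (periods of minutes) and fast beat-scale variability, so a centered
  moving average separates physiologically distinct components;
* information content, as estimated by a lossless compressor or a
  finite-context model, is a clinically meaningful summary: reduced
  complexity of fetal variability marks pathology;
* maternal-to-fetal coupling is informative, and is directional — the
  package always measures the fetal signal *given* the maternal one
  (NRC(fetal ‖ maternal)), i.e. the dependence of the fetus on the
  mother.

## The three indices

With a segment serialized to one byte per sample, the **compression
ratio** is original length over DEFLATE-compressed length. The
**normalized compression distance** between two segments is
`(C(xy) - min(C(x), C(y))) / max(C(x), C(y))` with `C` the compressed
byte length and `xy` the concatenation (always fetal-then-maternal in the
pipeline, since the value depends on the order).

The **normalized relative compression** needs a symbolic representation.
An extended-alphabet finite-context model is trained on the conditioning
sequence `y` only: sliding over `y` with step 1, it counts how often each
`d`-symbol block follows each `k`-symbol context. The target `x` is then
coded in consecutive non-overlapping `d`-blocks after `k` bootstrap
symbols; a block costs `-log2 P(block | context)` bits with the additively
smoothed estimate `P = (count + alpha) / (context_total + alpha * A^d)`.
Contexts are the `k` symbols immediately preceding a block and may
straddle block boundaries. Per-block cost is capped at `d log2 A` bits and
bootstrap/partial symbols are charged `log2 A` bits each, which guarantees
`NRC = bits / (|x| log2 A)` lies in [0, 1]; values pinned near 1 flag
conditioning sequences that explain nothing beyond chance.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| sampling rate `fs` | 4 | Hz | CTG standard |
| trend window | 17 | samples | 8 samples per side = 2 s real-time delay; preserves decelerations while smoothing |
| segment length | 10 | min | convention for heart-rate complexity studies |
| minimum partial segment | >5 | min | shorter windows give unstable indices |
| artifact band | [60, 200] | bpm | physiologic FHR range |
| beat-to-beat jump limit | 25 | bpm | artifact threshold |
| interpolation limit | 2 | s | longer gaps are replicated, not interpolated |
| MHR scale shift | +50 | bpm | brings maternal rates into the artifact band |
| alphabet `A` | 20 | symbols | Lloyd-Max codebook size |
| context order `k`, depth `d` | 6, 6 | symbols | the model's operating point for these signals |
| smoothing `alpha` | 1 | pseudo-count | proper probabilities, standard FCM choice |
| SMOTE replicas | 6 | per original | grows 7 acidemic cases to 49 vs 54 |
| SMOTE neighbors `k` | 5 | — | canonical SMOTE default |
| collinearity cut | 0.5 | abs. Pearson r | redundancy reduction |
| majority test rows | 7 | per fold | balanced 7 + 7 test sets |

## The synthetic cohort generator

No public accession exists for the clinical recordings, so the generator
is a first-class module emulating their statistical structure: 61
subjects (7 acidemic / 54 non-acidemic), 4 Hz, nominal 120 minutes with a
small per-subject shortfall (duration uniform on [118, 120] min, matching
recordings that stop just short of two hours), maternal sample losses at
an expected fraction of 1e-4, and occasional brief out-of-band artifact
spikes for the cleaning rules to exercise.

Both channels are baseline + slow sinusoid mixture (periods of at least
2 minutes, so the wander lands in the trend component) + stationary AR(1)
noise with lag-1 coefficient 0.95 (so the fast variability lands in the
residual). The fetal channel adds Gaussian-shaped acceleration and
deceleration bumps (15–60 s wide) and a lagged (2 s), centered copy of
the maternal fluctuations scaled by a coupling gain. The acidemia effect
is one dimensionless knob: at `effect_size = e`, acidemic fetal fast-noise
standard deviation is divided by `1 + e` (reduced complexity) and the
acidemic coupling gain multiplied by `1 + e` (stronger dependence on the
mother). At `e = 0` the groups are exchangeable by construction. The
magnitude of the real-world group difference is unknown, so `effect_size`
is a knob, not an estimate; the package default of 1 represents a clearly
present but not extreme effect.

What the generator does **not** emulate: beat-level RR dynamics,
uterine-contraction coupling, deceleration morphology tied to
contractions, non-stationary labour progression, or gestational-age
effects. Passing tests on synthetic cohorts therefore demonstrate that
the pipeline recovers the kind of effect it assumes (variance and
coupling shifts), not that the published clinical effect sizes are
reproduced.

```{r}
library(ctgcompress)
cohort <- generate_cohort(cohort_config(seed = 1))
plot_subject(cohort[1, ])
```

## Numerical choices and degenerate inputs

* **Lloyd-Max**: levels initialize at the `L` equally spaced empirical
  quantiles (deterministic, robust to skew); iterations run on the sorted
  sample with cumulative sums, so each step is O(L log n); convergence at
  a maximum level shift below 1e-6 bpm or 500 iterations; an empty cell
  re-seeds its level at the midpoint of its boundaries; a value equal to
  a boundary quantizes upward.
* **Cleaning**: a jump > 25 bpm invalidates the later sample unless its
  predecessor is already invalid; rules are re-applied up to 5 passes
  because a repair can create a fresh boundary step; a long gap at the
  recording start (no preceding block to replicate) falls back to the
  following valid block.
* **Segmentation** is anchored at the recording end: `h2-f` is always the
  last 10 minutes before the recording stops, which is the clinically
  critical window; any partial window therefore falls at `h1-a`.
* **Serialization**: one byte per sample, nearest integer, clamped to
  [0, 255]. Residual components are serialized with a +128 offset —
  they are zero-centered, and without the offset the clamp would erase
  every negative fluctuation.
* **Quantizer scope**: one codebook per (subject, channel, component),
  fitted on the full preprocessed series and reused across that subject's
  windows, so over-time comparisons share an alphabet mapping. Trend and
  residual get separate codebooks (their dynamic ranges differ by an
  order of magnitude).
* **Over-time reference**: the subject's first kept window of the same
  channel and component; the reference window's own over-time features
  are undefined and excluded.
* **Collinearity filter**: columns are walked in a canonical order
  (family, component, hour, slot) and the earliest member of each
  correlated group survives — deterministic. Correlations are computed on
  training rows only, and the retained set frozen before prediction, so
  the filter cannot leak test information.
* **Aggregation**: pooled predictions across folds, then one metric set
  (per-fold averaging is available as an option); the two differ in
  general and pooling is the regression-tested contract.
* **AUC** uses the rank (Mann-Whitney) formulation, identical to the
  trapezoidal area under the empirical ROC with tie handling; constant
  scores give 0.5.
* **DEFLATE backend**: base R's `memCompress(type = "gzip")` at its fixed
  library-default setting; the exact ratio values are
  backend-dependent, which is why runs fix a single backend.

## Known limitations

**Replica-mediated leakage.** SMOTE is applied to the whole feature table
before cross-validation, as the balanced 103-row table and the 89/14 fold
arithmetic require. The replica-aware folds keep the held-out original
and its own replicas out of training, but replicas of the *other*
originals are convex combinations that can lie arbitrarily close to the
held-out case (which served as their interpolation neighbor), and the
test set itself contains the held-out original's replicas, which lean
toward training originals. The test suite and the acceptance script
measure the consequence directly: on null cohorts (`effect_size = 0`,
where the groups are exchangeable) the pooled custom-CV AUC concentrates
far above chance. Pooled scores on SMOTE-balanced tables should therefore
be read as upper bounds; the package exposes the `origin` column in its
prediction output so users can score original cases only, and
`cv = "stratified"` plus `plan = NULL` (no balancing) for stricter
designs.

**Desk-scale problem sizes.** The test suite exercises the full 61-subject
cohort for parameter recovery and smaller cohorts (tens of subjects,
45–120 minute recordings) elsewhere; the exhaustive coder-vs-oracle check
enumerates every sequence up to length 8 (binary) / 6 (ternary) for all
`k, d` ≤ 2 and samples longer cases randomly. These sizes are the
package's chosen trade-off between coverage and a test suite that runs in
minutes.

**Other limitations.** The compression-ratio family depends on the byte
serialization and compressor; absolute values are not comparable across
backends. The finite-context smoothing mass `alpha * A^d` dominates
segment-length counts at the default `A = 20, d = 6`, compressing the
dynamic range of NRC values toward its upper region; group contrasts
survive, but absolute NRC levels should not be over-interpreted. The
generator's acidemia knob conflates complexity loss and coupling gain by
design; effects that move only one of the two can be simulated by setting
the group coupling gains explicitly.
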