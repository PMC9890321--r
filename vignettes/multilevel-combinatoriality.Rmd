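---
title: "Methods: quantifying multi-level combinatoriality in vocal sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying multi-level combinatoriality in vocal sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vocalcomb)
```

## The analytical model

`vocalcomb` treats a vocal repertoire as a two-level combinatorial system.
The observable units live on three tiers of a time-aligned annotation:
*segments* (the smallest units, bounded by silences of at most ~0.025 s or
sudden spectral shifts), *calls* (ordered sequences of 1–7 segments) and
*combinations* (ordered sequences of 2–5 calls whose inter-call silences are
at most ~0.5 s; silences above 1 s separate discrete vocalisations). Two
questions are asked of such a system:

1. **Are the unit classes real?** If hand-assigned segment classes capture
   genuine acoustic categories, spectrograms should cluster by class in an
   unsupervised low-dimensional projection, and predictors unrelated to
   class (caller, group, site, sex) should not explain the layout.
2. **Is assembly ordered?** If units are combined under sequential rules,
   the first-order forward transition probabilities should differ from what
   frequency-preserving random assembly produces.

Both analyses are deliberately assumption-light: the projection is
non-parametric (UMAP on flattened spectrograms), the cluster statistic is
the silhouette score on the projected coordinates, and the sequence test is
a randomisation test whose null is generated from the data itself. The main
substantive assumptions are (i) first-order dependence — the test probes
P(next | current) only and says nothing about longer-range structure — and
(ii) exchangeability of units across sequences under the null, which is what
the random reassignment implements.

## The transition permutation test

For a corpus of sequences over alphabet $A$, transition counts are taken
over adjacent ordered pairs *within* sequences (no cross-sequence pairs, no
artificial start/end tokens) and row-normalised:
$\hat p(i \to j) = n_{ij} / \sum_k n_{ik}$. States with no outgoing
transition keep an all-zero row rather than an arbitrary distribution.

The null distribution per cell is built by repeatedly permuting the pooled
tokens and refilling the original sequence-length profile. This preserves
both each type's total frequency and the multiset of sequence lengths;
preserving lengths is an interpretation choice — the randomised corpora then
carry exactly as many transition slots as the observed one, which makes the
per-cell statistics comparable draw by draw.

Per cell, with $m$ null draws in which the row is defined:

* lower and upper tail proportions $p_L = \#\{v \le \hat p\}/m$,
  $p_G = \#\{v \ge \hat p\}/m$ (ties counted into both tails — the
  conservative convention);
* two-tailed $p = \max\!\big(\min(1,\, 2\min(p_L, p_G)),\ 1/(m+1)\big)$,
  the floor being the Monte-Carlo resolution;
* significance at level $\alpha$: the observed value lies outside the
  central $1-\alpha$ mass, i.e. $p_L < \alpha/2$ or $p_G < \alpha/2$.

With 10,000 iterations the smallest reportable p-value is
$1/10001 \approx 0.0001$ and the smallest two-tailed value with one draw in
a tail is $0.0002$. Cells whose preceding state never has an outgoing
transition (in the data, or in every null draw) are reported `NA` rather
than given the floor; the tests distinguish "impossible to evaluate" from
"extremely unlikely".

The test is validated three ways in the suite: against exhaustive
enumeration of all distinct token-to-slot assignments on corpora of at most
8 tokens (the enumeration oracle lives in the test helpers, independent of
the package code paths); by type-I calibration on structureless corpora
(200 replicates of 200 sequences; the binomial confidence interval of the
flagged-cell rate covers 5%); and by parameter recovery — corpora sampled
from a known chain return every cell within three binomial standard errors
at over 10,000 observed transitions.

## Spectrogram standardisation

Each unit's audio is cut from its recording after a zero-phase Butterworth
band-pass (default order 5, 0.4–8 kHz, applied forward-backward with
`signal::filtfilt`; the band covers the repertoire's spectral content and
the filter edges must stay below Nyquist). The magnitude of a one-sided
STFT (Hann window, 512 samples, hop 128 at 44.1 kHz — values in the
lineage of spectrogram-projection work on birdsong, exposed in
`preprocess_config()`) is mapped through a 64-band triangular Mel filterbank
spanning the same band, then compressed as `log1p(x / log_floor)` with
`log_floor = 0.01` on the linear magnitude scale (the corpus is
noise-reduced or synthetic; the floor only sets the compression knee).

Durations vary by an order of magnitude between classes, so the time axis is
rescaled before padding: a unit of duration $d$ occupies
$w(d) = \mathrm{round}\!\big(64 \cdot \log(1 + d/\tau) / \log(1 + D/\tau)\big)$
columns, with $\tau = 0.01$ s and $D$ the longest unit duration in the
dataset. The map is monotone, the longest unit fills all 64 columns, and
anchoring $D$ per dataset makes the transform self-contained and
deterministic. Columns are linearly interpolated to width $w$; the signal is
left-aligned and zero-padded on the right (an arbitrary but fixed choice).
Units shorter than one analysis window (11.6 ms at the defaults) cannot be
transformed; `build_dataset()` skips them with a warning rather than
fabricating content.

## Projection and cluster evaluation

UMAP runs on the flattened 4096-component rows with `n_neighbors = 15`,
`min_dist = 0` (the recommendation when the projection feeds a clustering
statistic) and Euclidean metric, single-threaded so a seed fully determines
the layout. One numerical choice matters and is worth recording: the
layout is initialised from **PCA**, not the spectral default. When classes
are well separated the nearest-neighbour graph is disconnected, and uwot's
spectral initialisation then places the components at arbitrary mutual
positions and scales (it warns about the initial embedding's standard
deviation); layouts come out fragmented, with silhouette scores far below
what the feature-space geometry supports. PCA initialisation preserves the
global structure (on a diagnostic corpus: raw-space silhouette 0.77, 1-NN
label purity 1.0; PCA-initialised projection S ≈ 0.89 versus ≈ 0.26 for
spectral). The init is deliberately left unscaled — shrinking it to a small
standard deviation compresses the between-class geometry again. Degenerate
inputs are handled explicitly: if every row is identical the points are
collapsed to the origin (any layout would be arbitrary), and if PCA fails on
near-zero-variance input the projection falls back to a seeded random
initialisation.

Silhouette coefficients are computed per point on the 2-D coordinates
(`cluster::silhouette`), following the projection-evaluation lineage; the
package exposes the coordinates so a user can instead evaluate in the
feature space if preferred. $S$ is their mean. The permuted-label test
compares the observed per-point coefficients with coefficients computed
after randomly permuting the labels, via `stats::kruskal.test`; by default a
single permuted labelling is drawn (matching the paired
observed-vs-permuted design), with `n_perm` available for pooled, stabler
nulls. Degrees of freedom are reported exactly as computed (1 for the
two-group comparison). All predictors of one dataset are evaluated on one
shared projection, and every evaluation report carries per-individual point
counts so over-representation of a caller is visible. `balanced_subsample()`
downsamples every class to the smallest class count for
imbalance-sensitivity reruns.

## The synthetic corpus generator

The generator exists so the whole pipeline can be exercised against known
ground truth. Its defaults are fixed at the regime of the field system the
package is designed around: 222 combinations from 23 individuals in 16
groups across two sites (~65% female callers); calls of 1–7 segments and
combinations of 2–5 calls with truncated-geometric length distributions
(decay 0.62 and 0.4, giving mean call length ≈ 2.4 segments and mean
combination length ≈ 2.5 calls); truncated-normal silence distributions
with between-segment gaps of mean 0.008 s and max 0.025 s, between-call
gaps of mean 0.113 s capped at the 0.5 s combination threshold, and
uniform 1.2–2.0 s silences between combinations; and the observed two-level
transition structure as the default chain (segment level: LH→DS 1.0,
NL→DS 0.8, NL→SH 0.2, DS→SH 0.75, DS→LH 0.18, DS→DS 0.07, SH→DS 0.49,
SH→SH 0.27, SH→LH 0.23, SH→NL 0.01; call-group level: other→LH 0.65,
other→other 0.34, other→lone-NL 0.01, lone-NL→other 1.0, LH→other 0.67,
LH→LH 0.33). The segment-chain start distribution and the call-group start
distribution are not published quantities; they default to the observed
class frequencies (0.368/0.160/0.136/0.336) and to an other-heavy mix
(0.55/0.35/0.10) respectively.

When both levels are imposed, calls are drawn from the segment chain by
rejection until they match the group demanded by the call-group chain; this
conditioning slightly distorts realized segment-level frequencies, so for
chain-recovery experiments the generator accepts
`call_group_transition = NULL` and samples calls unconditionally, letting
call groups emerge.

Acoustics are invented (no per-class frequency values are published): DS a
4000→1500 Hz linear sweep, LH a 2200 Hz tone of ~0.35 s, SH a 4200 Hz tone
of ~0.08 s, NL band-limited noise in 800–2800 Hz, all inside the analysis
band, with 5 ms raised-cosine edges. Coarticulation — a unit's acoustic
form depending on its within-call position — is emulated by parameter
shifts keyed on (class, positional category): the bundled rules shift
LH-preceding-DS tones by +800 Hz and move the noise band of NL-in-combination
by +900 Hz. A frequency/band shift was chosen over an amplitude change as
the shifted parameter because it survives log-amplitude compression
unambiguously; the rule mechanism accepts `amp_scale` as well.

What the generator does *not* emulate — and therefore what passing tests do
not show about field data: background noise and its hand-profiled
reduction, amplitude and reverberation effects, within-class acoustic
variation beyond duration jitter and the injected positional shifts,
individual voice signatures, and any long-range sequential dependence.
Synthetic classes are cleanly separable by construction, so silhouette
scores on synthetic corpora sit above those attainable on real recordings;
the tests assert the direction and order of the structure (S > 0.4 where
the study regime shows S ≈ 0.45–0.58), not its exact magnitude.

## Problem sizes and determinism

The test suite runs on rendered corpora of 60 combinations (~380 segments),
type-I calibration on 200 corpora of 200 sequences at 1,000 iterations, and
chain recovery on ~3,000 combinations (~10,500 transitions); the exact-oracle
comparison uses 40,000 Monte-Carlo draws so that the Monte-Carlo sampling
noise is small against the 0.02 convergence bound being checked. The
acceptance script runs the full pipeline at the study scale (222
combinations, ~1,400 segments) with 10,000-iteration transition tests.
Every stochastic step — sequence sampling, audio rendering, subsampling,
projection, label permutation, corpus randomisation — takes an explicit
seed, and results bundles record all seeds and parameters in a JSON
manifest.

## Known limitations

* First-order only: the transition test cannot detect higher-order or
  long-range rules, and is not a model of the sequence process.
* The permuted-label Kruskal–Wallis test inherits the discreteness of
  silhouette ranks; with a single permuted labelling its H statistic is
  itself somewhat variable between seeds (exposed via `n_perm`).
* Tie handling in the Monte-Carlo test is conservative; on very small or
  highly tied corpora the realised type-I rate falls slightly below the
  nominal level.
* Between-call gap statistics pool only calls inside combinations; gaps
  around discrete calls are not "between-call silences" under the level
  definitions, though the alternative pooling would be easy to add.
* A combination tier, when absent from an annotation file, is derived from
  the calls by the silence rule rather than annotated independently.
* Reading is limited to long-format TextGrids and mono 16-bit PCM WAV.
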