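---
title: "Methods: encoding models and functional archetypes for bout-locked activity"
author: "kinenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models and functional archetypes for bout-locked activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kinenet models how the activity of reticulospinal neurons (RSNs) — the
brainstem population that carries descending locomotor commands to the spinal
cord — relates to the swim kinematics of larval zebrafish. The unit of
analysis is the *bout*: a discrete swimming episode a few hundred
milliseconds long, separated by quiescent intervals. The package implements
the full chain from tail-angle traces to population decoding:

1. bout segmentation and a 152-feature kinematic descriptor per bout;
2. bout-type identification by evidence-accumulation consensus clustering;
3. single-neuron Poisson encoding models with relaxed elastic-net
   regularization;
4. functional-archetype identification from model-predicted kinematic
   modulation;
5. equal-density tuning curves, recruitment summaries, and population
   decoding of swim type and kinematics from simulated Poisson spiking.

Every stage is driven by a synthetic-session generator that plants known
bout types and neuron coefficients, so the pipeline can be validated against
ground truth without any raw recordings.

## The synthetic-session generator

### What it emulates

Tail posture is represented as the cumulative bend angle
$\gamma_{s,t}$ along $s = 1..11$ tail segments at 1 kHz (positive =
rightward bend). A session is a concatenation of rest periods
(sub-threshold jitter: a slow ~1.3 Hz wobble under 0.5° plus white noise,
keeping envelope < 7° and tail-tip speed < 200°/s) and bout waveforms drawn
from a 7-type taxonomy with left/right variants:

| type | carrier (Hz) | tip amplitude (°) | turn bias (°) | duration (ms) | notes |
|------|-------------|------------------|---------------|---------------|-------|
| F1   | 56–64 | 18–24 | ~1  | 120–180 | fastest forward swim |
| F2   | 42–48 | 17–22 | ~1  | 130–200 | |
| F3   | 35–39 | 16–20 | ~1.5| 150–210 | |
| F4   | 28–31 | 13–16 | ~2  | 230–290 | slow, long forward swim |
| T1   | 22–25 | 38–44 | 6–9 | 150–190 | contraversive 2nd half-beat |
| T2   | 15–18 | 22–26 | 44–54 | 260–320 | ipsiversive 2nd half-beat |
| J    | 13–17 | 18–22 | 4–6 | 200–280 | caudal gain profile, vergence step 8–12° |

Each waveform is a carrier sinusoid at the type's tail-beat frequency under
a 10 ms attack / 40 ms cosine-release envelope, plus a slow half-sine turn
bias (square-root-shaped so that, for the strong-bias T2 type, the bias
outruns the carrier's first trough and the second half-beat stays
ipsiversive), multiplied by a per-segment gain profile — linear
rostral→caudal for F/T types, caudally saturating for J-turns, which pins
the J caudal bend fraction (`fcC1`) above 0.5. Eye traces are
piecewise-constant at 60 Hz sample-and-hold with a vergence step spanning
each J-bout. There is no canonical waveform-level parameterization of these
types; the ranges here
were calibrated once so that (a) the qualitative orderings hold — vigor,
tail-beat frequency and angular velocity descend along F1→F2→F3→F4→T1→T2→J,
half-beat amplitudes peak at the turns, J has the lowest vigor — and (b)
the 14 labels are mutually separable under the clustering pipeline. Both
properties are properties of the real taxonomy, which is defined by being
clusterable in the first place.

Perfectly clean waveforms would make every consensus iteration return the
identical partition, which silently disables the evidence-accumulation
mechanism the clustering relies on. The generator therefore adds
within-bout variability mimicking postural drift and tracking noise: a
2–6 Hz wobble under the bout envelope (up to 12 % of the tip amplitude),
per-segment gain jitter, and 5 % amplitude jitter. This brings within-type
bout-vector correlations to ~0.65–0.95, comparable to tracking data.

What the generator does *not* emulate: hydrodynamics or biophysically
realistic swimming, image-based tracking artifacts (dropped frames,
segment-swap errors), behavioral state drift across a session, sensory
context, or real anatomical geometry (anatomical labels are synthetic tags
assigned independently of archetype within each hemisphere). Passing tests
therefore demonstrate that the pipeline recovers structure *of the kind
assumed by the analysis*; they do not certify performance on artifacts the
generator does not model.

### Planted neurons

Per-bout spike counts are Poisson,
$y_{ij} \sim \mathrm{Pois}(\exp(x_i \beta_j + \beta_{0j}))$, with each
neuron's $\beta_j$ an archetype template plus independent Gaussian jitter
(`noise_sd`, default 0.02) on every coordinate. The eight templates express
the canonical tuning phenomenology: ar1 monotone in tail-beat frequency;
ar2 band-pass near 30 Hz through vigor/duration/mid-band Fourier weights;
ar3 selective for only the fastest swims (positive high-band, negative
mid-band Fourier weights — in a linear model, "active only above ~30 Hz"
must be carried by frequency-band predictors, not by mean TBF, which is
graded across all types); ar4/ar5 left/right rectilinear direction coding
with suppressed J response; ar6/ar7 left/right J-specific caudal curvature;
ar8 a symmetric J scaffold (vergence, long gated periods, suppressed
vigor). Because the predictors are unit-SD but uncentered, the drawn
baseline log-rate is re-anchored per neuron so that $\exp(\beta_0')$
equals the neuron's mean firing rate over the bout set (default 0.5–2
spikes/bout, the scale of deconvolution-inferred counts).

An optional calcium path renders AR(1) fluorescence from spike trains,
detrends with a sliding-percentile baseline, standardizes by a robust (MAD)
noise estimate, and recovers counts with a simple thresholded-difference
AR(1) deconvolver; any deconvolver with the same signature can be plugged
into `per_bout_counts()`.

## Segmentation and features

Bouts open where the 40 ms-boxcar-smoothed tail-tip angular speed exceeds
800 °/s and the 9 ms envelope exceeds 7°, close where speed falls below
200 °/s and envelope below 10° (hysteretic in between), and are discarded
under 61 ms. Intervals are half-open `[start, end)` in ms. Laterality is
the sign of the first half-beat's bend angle at segment 9.

The 152-feature catalogue is: vigor (`vigmax`, `vig120`), turning
(`intcum60ms`), asymmetry (`morphAI`, `morphAI2`), signed extremes
(`max_angl`, `max_vel`), per-half-beat amplitudes and angular velocities
for half-beats 1–4 at segments 5–11 (56), half-beat periods (4), bend
localization fractions (`fcR1`, `fcM1`, `fcC1`), shape ratios (3),
tail-beat frequency (`mean_TBF`, `max_TBF`), Fourier power at integer
frequencies 1–70 Hz of the segment-9 angle (70), ocular features (6), and
duration. Beyond the individually named features, the catalogue's exact
composition is a design choice of this package, constrained to the
documented totals (152 features, 72 lateralized, 225 predictors).

Two conventions deserve note. `morphAI` is $(n_L - n_M)/120$ where $n_M$
is the time (ms, of the first 120) the tail-tip angle spends on the side
*opposite* its dominant direction and $n_L = 120 - n_M$: counting
instantaneous zero crossings toward the dominant side makes an exclusively
one-sided bout score exactly +1, the definition's stated endpoint. Fourier
power is computed on the segment-9 excerpt zero-padded to 1000 ms, so FFT
bins fall exactly on the integer-Hz grid.

Features are 99 %-winsorized on the pooled table using order-statistic
(type-1) quantiles — the clip points are then data values, making
winsorization exactly idempotent — and z-scored within fish for the
clustering/PCA path. Degenerate features (too few half-beats, missing eye
coverage) are median-imputed per fish before modeling, with the imputation
count recorded.

### The 225-column predictor matrix

72 lateralized features become positively-signed left/right pairs: signed
features (the 56 half-beat amplitudes/velocities, `intcum60ms`, `morphAI`,
`morphAI2`, `max_angl`, `max_vel`, and the 6 ocular features) are rectified
on their own sign, $x_L = \max(-x, 0)$, $x_R = \max(x, 0)$; unsigned
side-dependent features (`period_1`, `period_3`, and the 3 ratios) are
gated by bout laterality. The remaining 80 features pass through and the
motion-error nuisance regressor is appended: $2 \times 72 + 80 + 1 = 225$
columns. Columns are scaled to unit SD *without centering* — centering
would destroy the rectified pairs' nonnegativity and their at-most-one-side
structure, which is the entire point of the split. The designation of
exactly which 72 features are lateralized is likewise a reconstruction
constrained by the printed counts. Whether `morphAI2` splits on its own
sign or gates on laterality is undocumented; it splits on its own sign here,
consistent with the other signed asymmetry measures.

## Dimensionality

Effective dimensionality is the participation ratio
$d = (\sum_i \lambda_i)^2 / \sum_i \lambda_i^2$ of a covariance
eigenspectrum ($1/(n-1)$ normalization, eigenvalues below
$10^{-12}\lambda_1$ truncated). The SVD predictor basis factors the
*uncentered* predictor matrix $X = U \Sigma V^\top$ (the predictors are
already on a common scale, and the models carry a free intercept), giving
the decorrelated rotated matrix $X_{svd} = XV$; coefficients fitted there
map back as $\beta_{svd} = V \hat\gamma_{svd}$, preserving predictions
exactly.

## Poisson encoding models

For neuron spike counts $y_i$ over bouts with predictor rows $x_i$:
$$ y_i \sim \mathrm{Pois}(\mu_i), \qquad \mu_i = e^{x_i \beta + \beta_0}, $$
with log-likelihood $\ell = \sum_i (y_i \log \mu_i - \mu_i - \log y_i!)$,
deviance $D = 2(\ell_{sat} - \ell)$ (saturated model $\mu_i = y_i$,
$0 \log 0 \equiv 0$), and goodness of fit the cross-validated fraction of
deviance explained $R^2 = 1 - D_{model}/D_{null}$, deviances summed over
held-out folds.

The **naive elastic net** minimizes
$-\ell/n + \lambda(\alpha \|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2)$ over a
100-point log-spaced $\lambda$ path from $\lambda_{max}$ (the smallest
penalty giving $\beta = 0$) down to $10^{-3}\lambda_{max}$. The **relaxed
elastic net** (`renet()`) runs, for each
$\alpha \in \{0.001, 0.25, 0.5, 0.75, 0.999\}$: the $\lambda_1$ path; at 10
equally spaced path positions, a cross-validated ridge refit restricted to
the selected support, with $\lambda_2$ chosen by the
largest-penalty-within-1-SE rule; and returns the
$(\alpha, \lambda_1, \lambda_2)$ minimizer of cross-validated deviance,
with coefficients exactly zero outside the selected support. Ridge
(`fit_ridge()`) is the same machinery constrained to $\alpha = 0$.
`fit_best_basis()` fits in both the kinematic and SVD bases and keeps the
higher-$R^2$ model.

Design choices that were genuinely open:

* **Penalty-selection convention.** The 1-SE rule is applied uniformly —
  for $\lambda_2$ in the relaxation stage (where it is part of the
  procedure's definition) and for the $\lambda$ of the naive and ridge
  comparators. A mixed convention (1-SE for the relaxation, CV-minimum for
  the comparators) systematically handicaps the relaxed model by exactly
  the 1-SE margin and, in planted simulations, inverts the relaxed ≥ naive
  ordering that motivates relaxation in the first place. Under the uniform
  convention the relaxation benefit is reproduced because it is real: the
  1-SE naive fit over-shrinks, and the restricted ridge refit undoes that
  shrinkage.
* **Reported $R^2$.** By default the cross-validated deviance of the
  selected model, as produced by the selection procedure itself
  ($R^2 = 1 - \mathrm{cvm}/\mathrm{cvm}_{null}$), i.e. the standard
  penalized-regression workflow. A fully nested variant that reselects the
  support inside every training fold is available
  (`r2_method = "refit"`).
* **Solver.** glmnet performs the inner penalized path solves; its
  solutions are certified in the test suite against a subgradient (KKT)
  checker (residuals < 1e-4) and against dense grid search on small
  problems (objective agreement within 1e-3). Numerical care: predictors
  are centered inside the solver wrappers (the unpenalized intercept
  absorbs the shift, so the optimum is unchanged, but Poisson IRLS on
  uncentered rectified columns conditions badly); the full 100-point
  $\lambda$ path is forced (glmnet truncates auto-paths once deviance
  saturates); linear predictors are clipped at ±30 in prediction paths;
  responses must be nonnegative integers (inferred counts are rounded
  before fitting).

## Consensus clustering

One engine serves both the bout-type and archetype pipelines:

1. **Batch clustering.** Average-linkage agglomerative clustering with
   correlation distance within batches (fish for bouts, random subsets of
   ≤ 4000 for neurons), dendrogram cut at a fixed height. Average linkage
   is used throughout: it is robust with correlation distances and has no
   centroid-inversion pathologies. Constant vectors, whose correlation is
   undefined, go to a reported degenerate pool. The bout pipeline cuts at
   correlation 0.9 — i.e. correlation-*distance* 0.1. The fine cut is the
   only reading that yields a batch-cluster library of the intended
   granularity (tens per fish rather than a handful): the 56 signed half-beat features force
   r ≈ 0.4 between same-side bouts of *any* type, so a 0.9-distance cut
   would collapse each fish to a handful of side-blobs. The archetype
   pipeline cuts at distance 0.2, below the irreducible overlap between
   J-selective templates (a left-J and an all-J response correlate ~0.7 by
   indicator structure alone) and far above within-template spread.
2. **Merging with evidence accumulation.** Pairwise batch-cluster
   distances are centroid correlation distances *divided by* the median
   intra-cluster distance of the more compact cluster (floored at a
   configurable ε, default 0.05), so tight clusters resist spurious
   merging; "scaled by" is ambiguous between multiply and divide, and the
   divide convention is the one with that protective property. Iterations:
   bouts re-represent the data in the first m = 5..15 principal components
   and cut each scaled-distance dendrogram at its longest link; archetypes
   cut at minimum cluster counts k = 10..50. The co-assignment fractions
   form the evidence matrix EA.
3. **Longest-link cut of 1 − EA.** "Longest link" means the largest
   increment between consecutive merge heights — a gap statistic that is
   stable when the tallest merge is the root. Scaled distances are
   ratio-scaled and span orders of magnitude, so for those dendrograms the
   increment is assessed on the log axis; 1 − EA lives in [0, 1] and uses
   the linear axis. Degenerate evidence is handled explicitly: an identity
   EA (no pair ever co-clustered, e.g. fewer batch-clusters than the
   minimum-cluster schedule) keeps the batch-clusters as they stand.
4. **Trim, curate, assign.** Clusters are trimmed to members within the
   70th percentile of centroid distance; automated curation replaces
   manual inspection with reproducible rules (drop clusters smaller than
   `min_size`, default 20, or with median intra-distance above
   `max_dispersion`, default 0.5). Bout clusters mixing lateralities are
   split by the sign of `theta_1_s9` (zero values follow the majority).
   Finally *all* items are assigned to the nearest centroid within a
   threshold — each cluster's own trim threshold for bouts (restricted to
   same-laterality clusters), twice it for archetypes — or left
   unclassified. Per-cluster thresholds are used rather than a global one.

On planted data this recovers the 7 × 2 bout taxonomy (14/14 labels,
ARI 1.0 on classified bouts, roughly a third of bouts unclassified;
unclassified bouts are a designed feature of the thresholded assignment,
which on real recordings leaves roughly half of bouts unassigned) and the
8 planted archetypes (ARI ≥ 0.98).

## Archetypes, tuning, recruitment

Kinematic modulation is $\hat Z = X_g \hat\beta$ over a common bout sample
drawn evenly across (bout type × fish), with
$\hat y = e^{\hat Z + \hat\beta_0}$; neurons with best-model $R^2 > 0.3$
enter clustering on $\hat Z$. Summaries per archetype: mean
model-predicted activity per bout type (two-stage mean), mean coefficient
vector (SVD-basis fits back-mapped first), and anatomical composition.
Recruitment matrices are cell-type × bout-type two-stage means with
companion correlation matrices and a PCA excluding J-turn columns;
lateralization is tested per (cell type × bout type) with two-sided
Mann–Whitney U on cells' mean counts, right- vs left-sided. Tuning curves
use 10 equal-density bins (quantile edges; ties merge bins) and report
mean ± SEM across member neurons.

## Decoding

A virtual population of 288 neurons is sampled stratified by anatomical
label; rates over a 700-bout sample (even across the 14 labels) come from
the neurons' models; spikes are Poisson. Pooling is at single-cell,
anatomical-label, or archetype resolution (within-group means). Bout type
is decoded with grouped-penalty multinomial LASSO (a predictor is active
for all classes or none), kinematics with multi-response (`mgaussian`)
LASSO, both ten-fold cross-validated; confusion matrices and per-target
$R^2$ come from prevalidated (held-out) predictions at the CV-optimal
penalty. "Number of predictors" on error-versus-predictor-count curves is
the count of predictors with any nonzero coefficient at each path point.
The default kinematic target panel is 20 standardized features spanning
vigor, frequency, per-half-beat angles/velocities, asymmetry and duration.
Ten iterations are aggregated as mean ± SEM. On planted populations,
archetype pooling achieves the lowest cross-validated error at matched
small predictor counts (≤ 8) for both decoders, and label shuffling
collapses accuracy to chance (1/14).

## Problem sizes used by the test suite

The packaged validation runs at desk scale: solver-oracle problems with
p ≤ 3, n ≤ 100; sparse recovery with n = 3000 bouts, p = 20; the
relaxation-benefit comparison over 50 planted neurons at ~400 bouts with
all 225 predictors; archetype recovery with 800 neurons over a 400-bout
common sample; bout-taxonomy recovery with 4000 bouts from 8 fish; and the
full decoding suite at full scale (288 cells, 700 bouts, 10
iterations). These sizes were chosen as the smallest at which the planted
effects are comfortably resolved.

## Known limitations

* The feature catalogue and lateralized-feature designation are
  reconstructions constrained by printed counts and definitions.
* The generator's bout types are parametric stand-ins; real locomotor
  space is a graded continuum with rarer intermediate and escape-type
  swims that are not modeled.
* Temporal structure within bouts (spike timing, history effects) is out
  of scope; the encoding unit is the per-bout count.
* Calcium rendering/deconvolution is a deliberately simple optional path;
  the core contract is integer per-bout counts.
* All session artifacts travel as CSV/JSON rather than binary containers;
  in-memory objects carry the same schema.
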