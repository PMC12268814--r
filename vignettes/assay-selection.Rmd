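---
title: "Kinetic feature extraction and in-silico multiplex assay selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic feature extraction and in-silico multiplex assay selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexrank)
```

## The problem

Single-channel multiplex PCR with amplification-curve analysis (ACA)
detects several targets in one well by telling the targets apart from the
*shape* of their real-time amplification curves rather than from separate
fluorescent channels. Designing such an assay means choosing, for each
target, one primer set out of several candidates, so that the resulting
mix produces maximally distinguishable curves. Testing all combinations
wet-lab is infeasible (the combinations grow as the product of the
per-target options), so candidate mixes are ranked *in silico* from
singleplex data: each candidate's multiplex behaviour is approximated by
pooling the singleplex curves of its assigned primer sets, under the
assumption — empirically supported by strong singleplex-to-multiplex
feature correlations — that each set's kinetic signature is maintained in
the multiplex reaction.

`plexrank` implements this workflow end to end: curve fitting, quality
filtering, kinetic feature extraction, feature screening, candidate
scoring and ranking, and classifier-based evaluation, plus a seeded
synthetic-data generator so the whole pipeline is testable without
laboratory data.

## The curve model

Each amplification curve is fitted with an asymmetric five-parameter
sigmoid

$$F(t) = \frac{F_m}{\left(1 + e^{-S_c (t - C_s)}\right)^{A_s}} + F_b,$$

where $F_m$ is the fluorescence gain, $F_b$ the baseline, $S_c$ (per
cycle) controls the slope, $C_s$ (cycles) the position — linked to the
cycle threshold — and $A_s$ the asymmetry between the exponential and
plateau phases ($A_s = 1$ recovers the symmetric logistic). The first and
second derivatives have closed forms, and with
$u = e^{-S_c (t - C_s)}$:

* the maximum slope sits at $x_{ms} = C_s + \ln(A_s)/S_c$;
* the extrema of $F''$ are the roots of
  $A_s^2 u^2 - (3 A_s + 1) u + 1 = 0$.

We use these exact expressions rather than numerical optimisation for the
fiducial points: they are cheaper, cannot fail to bracket, and the test
suite cross-checks them against grid search and numerical maximisation.
Only the threshold crossings $x_s$ and $x_e$ (where $F'$ equals a set
fraction of its maximum) need root-finding, which is safe because $F'$ is
unimodal.

All three evaluators use softplus (log-space) forms so that extreme
arguments return the exact asymptotes instead of overflowing.

### Fitting

`fit_sigmoid()` minimises the unweighted residual sum of squares with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, cost tolerance
1e-10, at most 5,000 function evaluations). Starting values are data
driven — baseline from the minimum, gain from the range, centre from the
half-range crossing, slope from the maximum finite-difference slope
scaled by $4/F_m$ (the symmetric maximum-slope identity), $A_s = 1$ —
and bounds keep the optimiser out of degenerate regimes while admitting
strong asymmetry ($A_s \in [0.01, 20]$, $S_c \in (0, 10]$). Optimiser
failure is reported as `converged = FALSE`, never as an error, so batch
fitting of panels containing junk curves proceeds.

```{r fit-example}
p <- sigmoid_params(Fm = 1000, Fb = 50, Sc = 0.8, Cs = 25, As = 2)
curve <- eval_sigmoid(p, 1:45)
fit <- fit_sigmoid(1:45, curve)
summary(fit)
```

## Kinetic features

From the fitted parameters, `locate_fiducials()` finds five fiducial
points — exponential-phase start $x_s$, accelerating-curvature peak
$x_{p1}$, maximum-slope point $x_{ms}$, decelerating-curvature peak
$x_{p2}$, plateau start $x_e$ — and `extract_features()` derives the
feature vector: the five parameters plus spans ($x_e - x_s$,
$x_{p2} - x_{p1}$), peak heights ($F'(x_{ms})$, $F''(x_{p1})$,
$-F''(x_{p2})$), and asymmetry ratios including $A_2/A_1$, the ratio of
the fluorescence rises of the plateau-approach and exponential phases.
$A_1$ and $A_2$ are computed as differences of $F$ at the fiducials —
exactly the integrals of $F'$ over those intervals, with no quadrature.

Two design choices matter here:

* **The threshold is relative.** $TH$ is a fraction (default 0.05) of
  the maximum slope, not an absolute value. An absolute threshold would
  break the scale invariance the features need; with a relative one, the
  ratio features are invariant to fluorescence rescaling and every span
  and shape feature is invariant to shifts of $C_s$. That shift
  invariance is the *mechanism* of concentration robustness: template
  dilution delays the curve (moves $C_s$) but leaves its shape alone.
* **Feature scope.** The selected default feature vector is
  `slope_ms`, `curv_p1`, `neg_curv_p2` and `Sc`
  (`feature_names_selected()`): the maximum slope and both curvature
  peak heights are strongly target-separating and concentration-robust,
  and `Sc` is retained for continuity with single-feature scoring.
  The peak span $x_{p2}-x_{p1}$ is computed but not selected by
  default: a feature of this kind can be robust on average yet collapse
  for one particular target, which is what the per-target consistency
  floor in `select_features()` (minimum per-target mean silhouette,
  default −0.05) guards against.

Standardisation (`standardize_features()`) centres each feature and
divides by its **population** standard deviation (denominator $n$); the
convention is fixed package-wide and matters only as a constant factor,
but is stated so results are exactly reproducible.

## Feature screening

`screen_features()` + `select_features()` operationalise three criteria:

1. **Separability** — the mean silhouette score (MSS) of the feature
   across targets, $\mathrm{MSS} = \frac1N \sum_i
   \frac{b_i - a_i}{\max(a_i, b_i)}$, with $a_i$ the mean intra-target
   distance and $b_i$ the mean distance to the nearest other target. The
   gate is relative: MSS at least `mss_ratio` (default 2) times the
   median MSS of all candidate features, and positive.
2. **Concentration robustness** — the Kruskal–Wallis test across
   concentration groups must *fail* to reject at $\alpha = 0.01$ in
   every reaction-efficiency regime. This is a screening heuristic, not
   an equivalence test, and is documented as such. Dunn's post-hoc
   z-tests (tie-corrected, Holm-adjusted by default) localise which
   concentration pairs drive any rejection.
3. **Singleplex–multiplex consistency** — Pearson $r \ge 0.85$ between
   feature values computed on per-primer-set median curves under both
   reaction conditions. Multiplexing lowers reaction efficiency, so
   absolute feature values drop, but a strong linear relation preserves
   the inter-target distance structure after standardisation.

## Candidate scoring and ranking

For a candidate mix, `simulate_multiplex()` pools the singleplex feature
vectors of its assigned primer sets; `score_candidate()` standardises the
pooled set and computes all pairwise inter-target distances, summarised
as the Average and Minimum Distance Scores (ADS, MDS). Two distance
kinds are available:

* **median** — Euclidean distance between per-feature medians: fast but
  blind to within-target spread;
* **clustering** — the two-cluster mean silhouette: overlapping targets
  score near zero no matter how far apart their medians are.

Three strategies package these choices (`strategy_config()`): S1 is the
single-feature (`Sc`) median baseline, S2 the multi-feature median
variant, S3 the multi-feature clustering variant. S1 and S2 coincide
exactly when the feature set is reduced to `Sc`, which the tests verify.
`simulate_overlap_panel()` constructs the instructive failure case: a
primer set whose `Sc` median is far from the other targets (so S1 ranks
its mix first) but whose shape features are so variable that its cluster
overlaps both other targets (so S3 ranks it last).

Standardisation is applied per candidate — each candidate's pooled
dataset independently — so that scores are comparable across candidates
built from different primer sets.

Ranking follows a rank-sum rule: candidates are ordered by the sum of
their rank by descending ADS and their rank by descending MDS, with
equal sums sharing a rank (two mixes can legitimately tie for a place);
listing order on ties is by mix id for determinism.

## ACA evaluation

`aca_train()` is a deliberately simple, deterministic k-nearest-neighbour
classifier (k = 5) on standardised selected features, behind a pluggable
interface: the evaluation machinery only needs *a* classifier that is
reproducible and honest about separability. Ties break to the
lexicographically smallest label; a hand-rolled implementation is used
because reference k-NN implementations break ties randomly, which would
defeat the bit-reproducibility guarantee. Evaluation schemes:

* `cross_validate()` — stratified k-fold (default 30) with one pooled
  out-of-fold confusion matrix;
* `loco_evaluate()` — leave-one-concentration-out: a drop relative to
  k-fold indicates concentration leakage into the features (e.g.
  including $C_s$ when concentration varies);
* `panel_ensemble()` — majority vote over all partition-level
  predictions of a digital-PCR panel, ties to the smallest label.

## The synthetic generator

`generate_singleplex()` draws per-curve parameters around per-primer-set
profile means with lognormal jitter (positivity-preserving,
mean-preserving), applies the concentration law
$C_s \leftarrow C_s + 3.3 \log_{10}(c_{\mathrm{ref}}/c)$ (3.3 cycles per
decade, the shift of a fully efficient reaction), synthesises fluorescence
on a 45-cycle unit grid and adds Gaussian noise (default SD 0.5% of
$F_m$). Default parameter CVs are 2–6%, typical of well-behaved digital
PCR partitions. `generate_multiplex()` attenuates $F_m$ and $S_c$ by
factors 0.8 (with 2% jitter), emulating the efficiency loss of primer
competition while preserving the linear singleplex-multiplex relation.
`generate_contaminants()` produces flat/NTC, low-gain and
low-efficiency traces with ground-truth labels for filter testing.
Shape parameters are concentration-independent *by construction*.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about laboratory data: primer–primer interaction
artifacts, nonspecific amplification with non-sigmoid shapes, baseline
drift, inhibitor kinetics, well-to-well crosstalk, and platform
(qPCR vs digital PCR) distribution shifts. Green tests show the
algorithms are correct under the stated statistical model, not that any
particular wet-lab assay will reach a given accuracy.

## Preprocessing filter

`filter_curves()` is a three-gate stand-in for unsupervised curve-quality
filtering: relative gain ≥ 0.10, converged fit with $R^2 \ge 0.99$, and
effective slope coefficient ≥ 0.1 per cycle. The effective slope
coefficient is $4 F'(x_{ms})/F_m$ — the $S_c$ of the symmetric sigmoid
with the same relative maximum slope. Raw fitted $S_c$ is unsuitable as
a gate because the five-parameter model is degenerate on slow ramps: a
genuinely low-efficiency curve can be refitted with a larger $S_c$
compensated by a small $A_s$, while the effective slope is invariant to
this trade-off. Gates are checked in order (flat/low-gain, poor fit,
low efficiency) and the first failure is reported; the filter is
deterministic, idempotent, and monotone in its thresholds.

## Numerical and design notes

* Second-derivative extrema via the exact quadratic root rather than
  bracketed optimisation (cross-checked numerically in tests).
* $TH$ crossings by `uniroot` after stepping outward in units of
  $1/S_c$ until the derivative falls below threshold.
* Flat input to `fit_sigmoid()` short-circuits to
  `converged = FALSE`, $R^2 = 0$ rather than invoking the optimiser.
* `kruskal.test` and `p.adjust` provide the rank test and the Holm
  adjustment; the Dunn z-statistic (tie-corrected pooled variance) is
  computed in-package.
* All RNG is confined to generator/fold-assignment entry points that
  take explicit seeds; scoring and ranking are RNG-free, so the full
  pipeline is byte-reproducible.

## Problem sizes

The shipped tests and the acceptance script size their simulations to
run comfortably on one CPU: the 7-plex preset uses 2 primer sets per
target, 4 concentrations and 4–6 replicate curves per cell (336–504
curves, 128 candidate mixes); classifier evaluations use 504 curves
(72 per target); robustness checks use 200 seeded replicates of a
4-decade dilution series. All sizes are arguments, so larger studies
only change a number.

## Limitations

Scores rank candidates under the pooled-singleplex approximation; they
do not model primer thermodynamics, and a top-ranked mix still needs
wet-lab confirmation. The Kruskal–Wallis robustness gate controls the
false-rejection rate, not equivalence. MSS-based distances assume the
selected features are on comparable scales after standardisation and
that targets form single clusters per feature space — multimodal
within-target behaviour (e.g. two amplicon populations) would need a
different distance.
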