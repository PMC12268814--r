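# plexrank

In-silico selection of single-channel multiplex PCR assays from
amplification-curve kinetics.

## What problem this solves

Amplification-curve analysis (ACA) lets one fluorescent channel detect
several targets in a single PCR well: a classifier tells the targets
apart from the *shape* of their real-time amplification curves. For that
to work, the assay designer must pick, for each target, one primer set
out of several candidates so that the combined mix produces maximally
distinguishable curves — and the number of combinations grows as the
product of the per-target options, far beyond what can be tested in the
lab. `plexrank` ranks all candidate mixes computationally from
*singleplex* data alone, for molecular-diagnostics developers building
multiplex panels (e.g. respiratory-pathogen assays) on standard qPCR or
digital PCR instruments.

## The method

Every curve is fitted with an asymmetric five-parameter sigmoid

$$F(t) = \frac{F_m}{\left(1+e^{-S_c(t-C_s)}\right)^{A_s}} + F_b$$

and kinetic features are extracted from the fitted curve and its analytic
derivatives: the maximum slope $F'(x_{ms})$ at
$x_{ms} = C_s + \ln(A_s)/S_c$, the heights of the second-derivative
peaks $F''(x_{p1})$ and $-F''(x_{p2})$, phase spans and asymmetry
ratios. These shape features are invariant to shifts of $C_s$, which
makes them robust to template concentration. Features are screened by
three criteria: inter-target separability (mean silhouette score,
$\mathrm{MSS} = \frac1N\sum_i (b_i-a_i)/\max(a_i,b_i)$),
concentration robustness (Kruskal–Wallis across dilution groups,
robust iff $p > 0.01$, with Dunn post-hoc localisation) and
singleplex-to-multiplex consistency (Pearson $r \ge 0.85$ on
median-curve features).

Each candidate mix is scored by pooling its primer sets' singleplex
feature vectors and computing all pairwise inter-target distances —
either median-based (distance between per-feature medians) or
clustering-based (two-cluster silhouette, which penalises overlapping
targets) — summarised as the Average and Minimum Distance Scores (ADS,
MDS) and combined into a rank-sum ranking. Strategy S1 uses only $S_c$
with median distances, S2 the selected multi-feature vector with median
distances, S3 the same features with clustering distances. Selected
assays are evaluated with a deterministic k-NN ACA classifier under
stratified 30-fold and leave-one-concentration-out cross-validation,
with optional panel-level majority voting.

A seeded synthetic-data generator (sigmoid parameters with lognormal
jitter, 3.3-cycle $C_s$ shift per 10-fold dilution, multiplex
efficiency attenuation, NTC/flat/low-efficiency contaminants) makes the
whole pipeline testable without laboratory data.

## Worked example

```r
library(plexrank)

# fit one noisy curve and inspect its kinetics
p <- sigmoid_params(Fm = 1000, Fb = 50, Sc = 0.8, Cs = 25, As = 2)
set.seed(1)
fit <- fit_sigmoid(1:45, eval_sigmoid(p, 1:45) + rnorm(45, 0, 5))
summary(fit)
#> Five-parameter sigmoid fit
#>   n = 45 cycles [1, 45]
#>       Fm       Fb       Sc       Cs       As
#> 999.3256  51.3245   0.7793  24.7455   2.3308
#>   RSS = 737.8, R^2 = 0.999926, converged = TRUE (9 iter)
#>   fiducials: x_s = 22.214, x_p1 = 24.377, x_ms = 25.831, x_p2 = 27.286, x_e = 31.173
#>   max slope = 237.1 at x_ms

# rank all 128 candidate 7-plex mixes of the synthetic preset panel
sc  <- scenario_preset_7plex(seed = 1)
cfg <- pipeline_config(output_dir = tempfile(), scenario = sc, seed = 1)
res <- run_pipeline(cfg)
head(res$scores, 3)
#>    mix_id strategy       ads       mds rank
#> 68   PM68       S3 0.8029026 0.3978836    1
#> 67   PM67       S3 0.8030834 0.3969635    2
#> 84   PM84       S3 0.7995514 0.3970544    3
res$report
#> ACA evaluation (kfold): accuracy = 1.0000 over 168 curves, 10 folds
#>   feature-space MSS = 0.5532
```

The fit recovers the injected parameters from noisy data ($R^2$ above
0.999); the pipeline fits and filters 336 synthetic singleplex curves,
extracts features, scores all $2^7 = 128$ candidate primer mixes under
the clustering-based strategy S3 (ADS/MDS are mean/minimum pairwise
inter-target silhouette distances; larger is better), and
cross-validates ACA classification of the top-ranked mix — here
perfectly separable, with a feature-space mean silhouette of 0.55.
Each stage's table is also written as CSV to `output_dir`, and
`inst/cli/plexrank.R` exposes the same stages as shell subcommands
(`synth`, `fit`, `filter`, `features`, `rank`, `classify`, `pipeline`).

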