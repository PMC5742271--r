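# dyadrec

Cross-recurrence analysis of dyadic movement coupling from object-tracker
output.

## What it is for

Developmental and social-interaction researchers often film two partners —
for example a parent animating a toy in front of a 5-month-old infant — and
want to know whether, at what delay, and how symmetrically the partners'
movements are coupled. `dyadrec` takes the per-frame bounding boxes
produced by any object tracker (one CSV per tracked feature:
`frame,x,y,w,h,valid`), turns each trajectory into a categorical
movement-direction time series, and quantifies the coupling between the two
series with categorical cross-recurrence quantification analysis (CRQA).

The core quantities:

- **Diagonal-wise lag profile.** For two aligned categorical series
  `p` (parent, leader axis) and `f` (infant, follower axis), the recurrence
  rate at lag τ (frames) is

  ```
  RR(τ) = 100 / (N − |τ|) · Σ_t 1[ p(t) = f(t − τ) ],   τ = −L … L
  ```

  each diagonal of the recurrence plot normalized by its own length. A
  parent lead of Δ frames peaks at τ = −Δ: negative lags mean the parent
  leads, positive lags the infant.
- **Baselines.** A shuffled surrogate (permute the infant series,
  preserving category frequencies) estimates chance-level recurrence; a
  random-pairing baseline (pair the parent with k = 5 infants from other
  dyads, trimming each pair to the shorter length) estimates task-driven
  recurrence.
- **Anisotropic CRQA.** Laminarity, trapping time, and maximum line of the
  vertical vs horizontal line structures of the recurrence plot.
  Horizontal lines measure how long the parent dwells in a state matching
  the infant; vertical lines the reverse. Horizontal-dominant values mean
  the parent's movement is the more sustained, regular one.
- **Inference.** Linear mixed models of RR with Condition (real vs
  baseline) × Lag (51-level factor, reference −4 s) fixed effects and a
  per-dyad random intercept, fitted by ML (lme4/lmerTest), compared by
  likelihood-ratio tests; per-lag interaction t-tests with Satterthwaite
  degrees of freedom locate the significant coupling window; four-window
  Bonferroni t-tests compare individual profiles.

Because suitable public recordings rarely exist, the package ships a
synthetic leader–follower generator (`generate_dyad()`,
`generate_cohort()`) with known ground truth (lag, directional noise,
frame dropout) so the entire pipeline is testable end to end.

## Worked example

```r
library(dyadrec)

# a synthetic dyad: parent leads by 6 frames (240 ms at 25 fps),
# 10% directional noise, 5% tracker dropout
d  <- generate_dyad(dyad_sim_params(n_frames = 600, lag_frames = 6, seed = 1))
ps <- categorize(interpolate_gaps(d$parent), "detailed", role = "parent")
is <- categorize(interpolate_gaps(d$infant), "detailed", role = "infant")

prof <- lag_profile(ps, is, max_lag_s = 4)
peak_lag(prof)
#> $lag_ms
#> [1] -240
#> $lag_frames
#> [1] -6
#> $rr
#> [1] 85.83474
#> $leader
#> [1] "parent-leading"

# chance level for comparison
bl <- shuffled_baseline(ps, is, n_shuffles = 10, seed = 2)
round(mean(bl$rr), 1)
#> [1] 29.7

# asymmetry of the recurrence plot
m <- acrqa_measures(cross_recurrence_matrix(ps, is))
round(unlist(m[c("lam_v", "lam_h", "tt_v", "tt_h")]), 3)
#> lam_v lam_h  tt_v  tt_h
#> 0.906 0.942 4.155 5.816
```

The peak at −240 ms says the infant's movement direction echoes the
parent's 240 ms earlier — the injected lag. Recurrence at the peak (86%)
far exceeds the shuffled baseline (30%), and the horizontal measures
exceed the vertical ones because the follower's movement is the noisier
of the two.

`run_pipeline()` executes the whole workflow (trajectories → categories →
profiles → baselines → aCRQA → mixed models) from a YAML/JSON config or an
R list and writes CSV/JSON artifacts plus a manifest; a thin CLI wrapper
lives at `inst/scripts/dyadrec.R`.

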