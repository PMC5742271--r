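---
title: "Quantifying dyadic movement coupling with categorical cross-recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic movement coupling with categorical cross-recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadrec)
```

## The problem

Two partners in a face-to-face interaction — here the motivating case is a
parent animating a toy while a young infant tracks it with head movements —
produce two simultaneous movement streams. The scientific questions are:
(1) are the streams coupled beyond chance and beyond what the shared task
induces, (2) who leads and by how much, and (3) is the coupling symmetric,
or is one partner's movement the more regular, sustained one?

`dyadrec` answers these from the humblest possible observable: per-frame
bounding boxes emitted by an object tracker (such as a
tracking-learning-detection tracker) for one feature per partner, at a
video sampling rate of 25 frames/s by default.

## From boxes to movement categories

Tracker output is a CSV per feature (`frame,x,y,w,h,valid`). Frames the
tracker lost are repaired by linear interpolation of box center and size
between the last known frame and the first available one
(`interpolate_gaps()`); the tracker's accuracy — percent of frames tracked
— is always scored *before* repair (`tracking_accuracy()`). Gaps touching
the series boundary have no bracketing observation on one side; we fill
them by nearest-valid constant extrapolation and warn, a choice the user
can avoid by cropping. Interpolated coordinates are not rounded to integer
pixels (rounding is easy to add upstream but discards information).

Each frame-to-frame displacement of the box center is then coded as a
movement direction (`categorize()`), under either of two schemes:

* **simple** (3 codes): 0 none, 1 right, 2 left — horizontal component
  only;
* **detailed** (9 codes): 0 none, 1 left, 2 up-left, 3 up, 4 up-right,
  5 right, 6 down-right, 7 down, 8 down-left.

Two conventions matter and are fixed package-wide: pixel coordinates
follow the image convention (y grows downward, so "up" means decreasing
y), and category boundaries are per-axis sign tests with a dead-zone of
half-width `eps` — not angular sectors. `eps = 0` by default, i.e. only
exact ties count as "no movement"; trackers that emit sub-pixel jitter
should raise it (units: pixels). The simple code is always the horizontal
collapse of the detailed code, a property the tests enforce. An optional
`mirror_x` flag negates the horizontal axis of one series before
comparison, for camera geometries where the partners face each other and
the same physical direction appears mirrored.

## Diagonal-wise cross-recurrence

With both series trimmed to a common length N (`trim_pair()` removes the
tail of the longer), the cross-recurrence plot is the N×N binary matrix
with the parent series on the horizontal axis (j) and the infant on the
vertical (i), and a point wherever the codes match. The lag profile
(`lag_profile()`) is the per-diagonal recurrence rate,

$$RR(\tau) = \frac{100}{N-|\tau|}\sum_t \mathbf 1[\,p(t)=f(t-\tau)\,],
\qquad \tau = -L,\dots,L,$$

computed by an O(N·L) shifted comparison without materializing the matrix;
the test suite proves the shifted path identical to summing matrix
diagonals. Each diagonal is normalized by its own overlap N−|τ| rather
than by N, avoiding edge bias at large |τ| (whether the original analysis
normalized per diagonal or globally is not documented; per-diagonal is the
convention of the profile functions in common use, and a global variant
would only rescale the profile tails). With this sign convention a parent
lead of Δ frames peaks at τ = −Δ, so negative peak lags mean
parent-leading. The default window is ±4 s: 201 one-frame lag bins at
25 fps.

Peak ties are resolved toward lag 0, then toward the negative (parent)
side, always with a warning — ties essentially only occur in degenerate
profiles, but a tool should not be silent about them.

## Baselines

Two controls bracket the real profile (`shuffled_baseline()`,
`random_pair_baseline()`):

* **Shuffled**: permute the infant series and recompute the profile. This
  preserves both marginal category distributions exactly, so its expected
  RR is $100\sum_c p_c q_c$ at every lag — 33.3% for independent uniform
  3-category series, 11.1% for 9 — and it is flat in expectation. The
  number of shuffles defaults to 1, the most literal single-surrogate
  reading; raising it only reduces Monte-Carlo variance.
* **Random pairing**: average the profile of the parent against k = 5
  infants from *other* dyads (own infant excluded), each pairing trimmed
  to the shorter length. Residual structure here reflects the task, not
  the dyad.

Both are bit-reproducible given a seed; cohort runs derive per-dyad
sub-seeds from one master seed by a deterministic counter
(`derive_seeds()`), so results do not depend on processing order.

## Anisotropic CRQA

Classical RQA summarizes diagonal lines, which is awkward for coarse
categorical series; instead we quantify the plot's vertical and horizontal
line structures (`acrqa_measures()`): laminarity (share of recurrent
points in lines of length ≥ `lmin`), trapping time (mean such line
length), and maximum line. `lmin` defaults to 2, the usual
recurrence-toolbox convention (any smaller value would count isolated
points as lines). Lines are maximal runs, not wrapped at borders, and the
main diagonal is *not* excluded — in cross-recurrence between two
different systems it carries no trivial self-match.

Line lengths are reported in recurrence points; `ms_from_points()`
converts at 1000/fps ms per point (40 ms at 25 fps). Published aCRQA
tables sometimes mix unit conventions (point counts converted at 25 ms per
point alongside a stated 25 fps rate); we deliberately expose the raw
point counts and one explicit conversion rather than guessing a time base.

Across a cohort, `asymmetry_test()` runs paired t-tests of vertical minus
horizontal per measure; negative t means the horizontal (parent) lines are
longer/denser — the parent's movement dwells longer in any state matching
the infant than vice versa.

## The inferential layer

`profile_long_table()` stacks per-dyad real and baseline profiles —
subsampled from 201 to 51 lag bins at 6.25 Hz (`subsample_profile()`
keeps every 4th frame lag, endpoints and 0 included) — into a long table,
and `fit_profile_models()` fits three nested linear mixed models of RR by
maximum likelihood with a per-dyad random intercept:

| model | fixed effects | fixed-effect coefficients (51 lags) |
|---|---|---|
| null | — | 1 |
| additive | Condition + Lag | 52 |
| full | Condition × Lag | 102 |

Lag is an *unordered factor* with reference −4 s (not a continuous
covariate): each lag, and each condition-by-lag interaction, is contrasted
against the profile edge, which is where coupling should be absent.
Counting the two variance components (random-intercept and residual), the
full model estimates 104 parameters. `likelihood_ratio()` compares nested
fits: full vs additive has 50 df, additive vs null 51 df on this grid. The
accompanying effect size is reported as $V = \sqrt{\chi^2/(N\,\mathrm{df})}$;
this is one convention among several for converting a chi-square to an
effect size, and we document it rather than matching any particular
published variant.

`interaction_significance_window()` extracts the 50 interaction
coefficients, tests each with Satterthwaite-approximated degrees of
freedom (via lmerTest), and reports the contiguous lag ranges significant
at α = 0.05, together with a per-lag paired Cohen's d computed from the
per-dyad real-minus-baseline RR at that lag. Note these 50 tests share
the reference-lag term and are therefore positively correlated: their
per-cohort false-positive count is nominal on average (~5%) but
over-disperses across cohorts, which is why calibration checks average
over replicates.

`windowed_ttests()` implements the four-window Bonferroni procedure
(windows of ⌊bins/4⌋ lags, remainder to the last; significance at
α/4). Pairing adapts to the input: for a single recording the rr values
are paired by lag bin within each window (df = bins−1, the form matching
published single-dyad analyses); for a cohort each dyad contributes one
window-mean per condition and the test pairs dyads (df = dyads−1). Both
cannot be a single default because they answer different questions — one
recording vs a group — so the package chooses by input shape and reports
df explicitly.

## The synthetic generator

`generate_dyad()` builds a leader whose box center sweeps left–right
sinusoidally (amplitude 150 px, period 2 s on a 752×582 px image) with
sparse ±1 px vertical jitter (probability 0.15 per transition), and a
follower whose *direction category* at transition t copies the leader's at
t−Δ, with fixed 3 px step magnitude. The coupling is injected in exactly
the categorical space the pipeline measures; coupling positions instead
would entangle the generator with categorization choices. Degradations:
with probability `noise_p` a follower transition's category is replaced
uniformly at random; each frame of either trajectory is dropped (marked
invalid) with probability `dropout_p`, exercising interpolation.

Defaults are fixed once and used by tests and the acceptance script
alike: 600 frames (24 s), Δ = 6 frames (240 ms), `noise_p` = 0.1,
`dropout_p` = 0.05. `generate_cohort()` replicates a 21-dyad study with
episode lengths uniform on 15–41.08 s (375–1027 frames at 25 fps).

What the generator does *not* emulate: smooth pursuit dynamics (the
follower moves in 8-connected unit directions), tracker false positives
(boxes locked onto the wrong object), amplitude coupling, or mirrored
camera geometry (available separately via `mirror_x`). Passing tests
therefore demonstrate that the pipeline recovers direction-space coupling
under dropout and categorical noise — not that any particular real corpus
is well tracked.

## Numerical choices and degenerate inputs

* Lag windows must be an integer number of frames (`max_lag_s · fps`);
  subsampling requires an integer stride. Violations are errors, not
  silent rounding.
* Profiles demand N > L; matrices demand equal lengths (`trim_pair()`
  first — the error says so).
* Empty recurrence plots yield all-zero aCRQA measures with
  `defined = FALSE` rather than NA-poisoned tables; orientations with
  recurrent points but no qualifying line get `lam = maxl = 0` and a
  per-orientation flag.
* Zero-variance paired differences yield t = 0/d = 0 when all differences
  are zero (genuinely no effect) and an undefined flag otherwise (effect
  with no sampling variance).
* All library functions restore the caller's RNG state; randomness enters
  only through explicit `seed` arguments.

## Problem sizes used in validation

The shipped validation uses series of 375–1027 frames (the episode-length
range the generator emulates), 100-replicate exact-agreement checks for
the recurrence computations, 20-seed recovery checks for peak-lag and
interaction-window inference, 200 simulated cohorts for likelihood-ratio
calibration, and 500 for the familywise error of the windowed procedure —
sizes at which the Monte-Carlo error of each check is small relative to
the property being asserted.

## Known limitations

* Categorization is sign-based; diagonal movement at shallow angles maps
  to diagonal categories regardless of angle, which is by design but
  coarse.
* The mixed models treat RR values at different lags of the same profile
  as exchangeable residuals; neighboring lags are in fact correlated.
  The likelihood-ratio calibration shows the model-level tests remain
  near-nominal under the null, but per-lag inference should be read
  jointly (windows), not lag by lag.
* `eps` interacts with tracker pixel quantization: with float tracker
  output and `eps = 0`, the "no movement" category almost never fires.
* The random-pairing baseline needs a pool of same-task dyads; with few
  dyads its variance is substantial.
```{r session, echo = FALSE}
sessionInfo()
```
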