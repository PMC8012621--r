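---
title: "Methods: simulating and analyzing multi-agent pursuit codes"
author: "pursuitglm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing multi-agent pursuit codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pursuitglm` rebuilds, on synthetic data with known ground truth, the
computational machinery used to ask whether a neural population carries
*multicentric* (world- and avatar-centric) codes for multiple agents during
continuous pursuit and evasion: a virtual pursuit task simulator, a
linear-nonlinear (LN) Poisson tuning-model framework with forward model
selection, map-comparison and mixed-selectivity statistics, maximum-likelihood
population decoding, and behavioral classifiers. Nothing here touches real
recordings; every analysis runs against ensembles whose tuning is planted, so
each stage has a parameter-recovery test surface.

# The task world

A subject-controlled avatar (circle, 15 px diameter, speed cap 23 px per
16.67 ms frame) pursues one or two evading prey (30 px squares) and avoids a
pursuing predator in a 1920 x 1080 px field. Capture is any overlap between
the avatar circle and a prey square; trials end at first capture, at capture
by the predator, or at a 20 s timeout. Prey value (0.3-0.7 mL) and prey speed
are deliberately confounded, predators appear on 25% of trials and a second
prey on 50%, and all agents start at least 400 px from the avatar.

The prey evaluates 15 candidate positions spaced equally on the circle of
radius equal to its per-frame speed and takes the cheapest in-bounds one
(falling through to the next-cheapest when the best is off screen; ties break
to the lowest candidate index everywhere, for determinism). Its cost is a
center-bias surface plus a sigmoidal cost of avatar proximity that is exactly
zero beyond a cutoff. The predator uses the same candidate construction with
a single rule: minimize distance to the avatar.

Unstated constants were fixed once, as follows, and are all exposed in
`world_config()` / `prey_policy()` / `subject_policy()`:

* **Evasion sigmoid**: cutoff 400 px (matched to the minimum initial
  distance, so prey start quiescent), midpoint 200 px, slope 0.02 /px,
  scale 2.
* **Center bias**: quadratic bowl normalized to [0, 1] over the field,
  weight 1 — the simplest surface that makes the prey drift centerward.
* **Inertia**: the subject's commanded velocity may change by at most 30% of
  the speed cap per frame, preventing instantaneous reversals without
  inventing dynamics.
* **Predator speed**: 0.8 x the subject cap, so predator trials are
  survivable.
* **Prey speeds**: 14, 16, 18, 20, 22 px/frame for values 0.3-0.7 mL.
  The experiment staircased these online; fixed increasing defaults preserve
  the value-speed confound the task description states. The online staircase
  is an optional training device, not an analysis component, and is omitted.

Subject policies span the agent family used to classify behavioral
strategies: aim at the target prey's position extrapolated `tau` frames
forward (tau = +30 predictive, -30 reactive, 0 pure homing), plus an
avoidance vector away from the predator weighted by a distance sigmoid with
a narrow (150 px midpoint) or broad (500 px) range, and a degenerate
random-walk policy (bounded turning, full speed) that ignores the prey. In
this world the predictive agent captures in roughly three quarters of
single-prey trials, the reactive agent essentially never does, and the random
walk captures nothing within the timeout — the orderings the strategy
classification relies on.

# Synthetic LN ensembles

Ground-truth neurons follow the LN form: the expected spike count in frame
`t` is `exp(bias + sum_i w_i[bin_i(t)])`, with one weight per bin of each
tuned variable (15 x 15 position grids; 12 circular bins of 30 degrees for
headings and relative angle; 12 linear speed bins; 12 log-spaced
subject-prey distance bins from contact at 22.5 px to 1000 px — the 12-bin
convention mirrors the stated direction/speed binning, since the
avatar-centric bins are not published). Heading is the velocity direction;
frames slower than 0.5 px/frame inherit the last valid heading, because
heading is undefined at rest.

Filters are draws from a Gaussian process over bin space with
squared-exponential covariance `exp(-d^2 / (2 * smoothness^2))` (circular
variables use wrapped distance), mean-centered, sampled by eigendecomposition
with clipped eigenvalues because the kernel is numerically rank-deficient on
dense grids. `smoothness` is therefore interpretable: the empirical
inter-bin correlation of sampled filters at lag `d` matches the kernel, which
the tests check. Baseline rates are drawn so `exp(bias)/dt` lands in a
1-20 spikes/s range (2-10 in the recovery tests, matching cingulate rates).
Two departures from the pure LN form support the mixed-selectivity analyses:
an optional multiplicative `interaction` gain applied when a chosen
variable's bin falls in a stated segment, and an `additive` combination mode
that sums per-variable rates in the rate domain (the alternative the MF/AF
statistic must reject). Spikes are independent Poisson draws per frame.

# Fitting, cross-validation, selection

The penalized objective is the negative Poisson log-likelihood (constant
`log n!` dropped) plus `beta` times the squared difference of adjacent-bin
weights (rows and columns penalized separately on position grids, wrapped on
circular variables, chained on linear ones) and a lasso penalty `lambda`
(smoothed with eps = 1e-8) for discrete variables. Defaults `beta = 20`,
`lambda = 1` were chosen by cross-validated log-likelihood on a handful of
synthetic neurons, mirroring the published hyperparameter procedure; both
are arguments everywhere. The objective and gradient are computed in one
C++ pass over the frames and minimized by L-BFGS-B from zero initialization
(the objective is convex; a 500-iteration cap is flagged, never silent).
Unvisited bins keep parameters — the smoothness penalty couples them to
neighbors — but profiles report them as missing.

Cross-validation partitions the session into 50 contiguous chunks assigned
round-robin to 10 folds: contiguity limits leakage through the strong
temporal autocorrelation of the task state, round-robin keeps folds balanced
across the session. Performance is the spike-normalized held-out
log-likelihood increase over the mean-firing-rate null trained on the same
folds (LLi); the null's LLi is identically zero. Forward selection adds, at
each step, the candidate with the largest median LLi, accepting it only if
a one-sided Wilcoxon signed-rank test across the 10 paired folds is
significant at alpha = 0.05 and the median strictly increases; a neuron whose
best single model fails is "not tuned to any". The bias is refit in every
candidate model. Fold fits warm-start from the full-data fit, which changes
nothing statistically (convexity) and saves most of the compute. Predator
variables should only be fitted for sessions with at least 50 predator
trials, mirroring the exclusion used on the real data; the analysis scripts
fit them on predator-present frames separately.

On 20-minute synthetic sessions at 2-10 spikes/s this machinery recovers the
exact planted variable set in well over 80% of neurons, recovered position
profiles correlate above 0.9 with ground truth, and on homogeneous Poisson
neurons the per-step false-inclusion rate stays near the nominal 5% — the
held-out comparison penalizes overfitting, so the best-of-k selection step
does not inflate it.

# Maps and map comparison

`response_profile()` converts one variable's weights to spikes/s with the
scaling factor that marginalizes out the other variables,
`alpha = exp(bias) * prod_{i != j} mean(exp(w_i))`. `adaptive_smooth()` is
the presentation estimator: around each bin a circle grows until
`N_spikes >= a / (N_occ^2 r^2)` (scale `a` = 10,000); "inside" is strict, so
the smallest circle holds the bin alone and dense data reproduce the raw
occupancy-normalized map exactly — the natural reading that makes the
no-smoothing limit hold. Bins never satisfying the criterion are missing,
and the estimator conserves no global quantity (documented, expected).

SPAEF, the map-similarity score, is
`1 - sqrt((A-1)^2 + (B-1)^2 + (C-1)^2)` with `A` the Pearson correlation,
`B` the CV ratio (second map over first — the one deliberately asymmetric
component), and `C` the histogram intersection of the z-scored maps. The
shared histogram uses a Freedman-Diaconis width on the pooled z-values with
breaks symmetric about zero; symmetry makes the mirror-map identity
(`SPAEF = -1` for a reflection of a histogram-symmetric map) exact rather
than approximate. Constant maps are an error (undefined correlation and CV).
Effect size is peak minus trough over visited bins; cohorts are summarized
by the median with a 1,000-resample percentile bootstrap. Tuning-profile
clustering centers the profiles, projects onto the top two principal
components, and k-means-partitions the projection (default k = 4, 50
restarts, seedable); the source material describes "k-nearest neighbor"
clustering with an elbow at 4, which is read as k-means — k-NN is not a
clustering of this kind.

# Mixed selectivity

Position bins are sorted by firing rate and split into equal-count segments
(2 for MF/AF, 3 for the range analysis; remainder bins join the top
segment, ties break by bin index, so the labels are rank-based). Per-segment
tuning curves of a second variable come from the frames spent in that
segment. Regressing the high-segment curve on the low-segment curve
(ordinary least squares, unweighted bins — occupancy weighting is not
described in the source and is deliberately not applied) gives the
multiplicative factor MF (slope) and additive factor AF (intercept over the
neuron's mean rate). A purely multiplicative neuron with planted gain k
yields MF near k and AF near 0; a rate-domain additive neuron yields MF near
1 and AF near the planted offset — the double dissociation, confirmed by the
range-vs-mean analysis (curve range grows with segment mean rate only under
multiplicative interaction; under noiseless additive shifts the range is
constant and the correlation undefined). MF estimates carry the usual
errors-in-variables attenuation when the regressor curve is noisy, so cohort
medians, not single neurons, are the meaningful statistic. The range-vs-mean
statistic has a further caveat the analysis scripts make visible: with
Poisson spiking, higher-rate segments have noisier curve estimates and hence
inflated empirical ranges, so even additive cohorts show a positive median
correlation at realistic spike counts. It confirms multiplicativity
alongside MF/AF (where the planted dissociation is recovered cleanly); it is
not diagnostic on its own.

The reward-condition control matches occupancy between low- and high-value
halves of a session by random frame removal per direction bin, then matches
total spike counts. Removing further frames for the spike match would break
the just-established occupancy equality, which the procedure's stated audit
(occupancy difference exactly zero *and* spike totals within one) requires;
spike totals are therefore matched by randomly thinning spike counts, which
preserves occupancy exactly. The stochastic decimation repeats 50 times for
averaging. Reward encoding itself is the least-squares slope of the mean
rate over the last second of each trial on prey value, with a two-sided
test and a binomial population test against alpha.

# Population decoding

Decoding follows the generative route: spikes are simulated from each
neuron's *selected* model (unselected variables contribute zero weight), and
the decoder exhaustively scores every candidate bin of the target variable
by the summed Poisson log-likelihood over a 121-bin (2000 ms) window across
neurons, holding the other variables at their true binned values (the
per-variable errors imply one variable is decoded at a time; a joint grid is
neither stated nor tractable). Ties take the lowest bin index. Because each
row of the one-hot design is a single active bin, the window log-likelihood
reduces to per-neuron sufficient statistics (total spikes and summed
exponentiated base rate), making the exhaustive scan cheap; the tests pin it
to a literal triple-loop oracle.

A static-state decoder over a 2 s window estimates the window's dominant
state, while the avatar can cross the field several times within one window.
Scored against the state at the window end, the error is dominated by that
within-window movement (a ~130 px floor, flat in ensemble size); scored
against the window-average state — the quantity the decoder actually
estimates; the source does not state its reference point — the median
position error falls monotonically as the ensemble grows from 40 to 160
neurons with no sign of saturation, the distributed-code signature. Errors
are reported in natural units: px for positions, degrees wrapped to
[0, 180] for circular variables, px/s for speeds.

# Behavioral classifiers

**TBTS** (trajectory-based trial sorting) resolves which of two prey is
being pursued. Per frame and prey it multiplies three per-trial min-max
normalized components — an angle difference, the signed change of
subject-prey distance, and a DTW distance between the subject's and prey's
last 10 frames (Euclidean local cost; the window length is not published) —
smooths the product with a 5-frame boxcar, and labels the argmin prey;
trials whose label changes are flagged as switches. The angle component is
the angle between the subject's step heading and the *bearing to the prey*.
The source's wording ("angle differences between subject's and each prey's
trajectory") also admits a step-heading-vs-step-heading reading, but that
reading carries no information before the prey starts evading and, on
simulator trials with a policy-defined target, labels only ~80-93% of frames
correctly with 35-60% switch-flagged trials — irreconcilable with the ~5%
switch-trial rate the source excludes. The bearing reading measures pursuit
intent directly and labels >99% of frames with a few percent of switches,
so it is adopted. Min-max normalization (per component, per trial) is
likewise an implementation choice: the three raw components have
incompatible units and the source multiplies them without comment.

**Chase/avoid** labels each frame from three signals per agent pair:
distance change, velocity dot product, and the change of the dot product.
Avoid requires all three positive for the subject-predator pair; chase
requires shrinking subject-prey distance with a positive subject-prey dot
product; otherwise neither. The full chase criterion is not published; this
symmetric sign rule is exposed and documented. Avoid is checked first, so
the two labels are exclusive by construction; without a predator, avoid is
undefined and only chase is scored.

# What the generator does and does not emulate

The synthetic world reproduces the task's geometry, physics, trial
structure, and the LN spiking model with its interaction variants, so green
tests establish that the pipeline recovers what was planted at realistic
rates, durations, and occupancies. It does not emulate: non-Poisson spiking
(bursting, refractoriness), slow drifts in excitability, the online
prey-speed staircase, gaze (accepted by the GLM only as a generic 2-D
variable), or a subject whose policy itself switches between pursuit and
evasion mid-trial. Headline numbers from the recorded macaques (tuned
fractions, SPAEF of -0.33, 8.5-degree direction error) depend on those
unmodeled properties and on the animals themselves; the package reproduces
the *patterns* (anticorrelated kernels, the MF/AF dissociation, monotone
decoding curves, a 0% random-walk capture rate), not those numbers.

# Numerical notes

* Degrees are wrapped with a guard against the `x %% 360 == 360`
  floating-point edge.
* Candidate tie-breaks use a 1e-9 tolerance so exact geometric ties (e.g. a
  predator coincident with the subject) resolve to the lowest index rather
  than to rounding noise.
* `make_folds()` is a pure function of the session length; fold boundaries
  are reproducible by construction.
* All stochastic entry points (`run_trial`, `run_session`,
  `occupancy_matched_split`, `error_curve`, `cluster_profiles`) take seeds
  and restore the caller's RNG state.
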