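---
title: "Modeling two-point discrimination in epiretinal prosthesis users"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling two-point discrimination in epiretinal prosthesis users}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tpdiscrim` models why users of an epiretinal implant — a 6×10 grid of
225 μm disk electrodes at 575 μm pitch on the inner retinal surface — often
merge two stimulated electrodes into a single percept, and why detection
thresholds are frequently far above the ~50 μA a flush electrode over
healthy tissue would need. The package chains three models: planar
axon-bundle geometry, a logistic psychophysical model, and a current-spread
simulator. This vignette records the assumptions, parameter meanings,
numerical choices, and the open design decisions we resolved, in enough
detail that a reader can judge what the package's passing tests do and do
not establish about real data.

## Stage I: axon-bundle geometry

Epiretinal electrodes sit on the nerve fiber layer, so stimulation can
activate retinal ganglion-cell axons passing far from their somas; percepts
elongate along the fiber trajectory. To quantify pair-wise axonal sharing
we build a planar map of 400 axon bundles.

**Coordinates.** Retinal micrometers, fovea at the origin, +x toward the
optic disc (nasal retina, right eye), +y superior. The optic disc sits at
(15°, 2°) in visual-angle units converted at 288 μm/°. Visual-field plots
flip the y axis; stored data are always retinal. All geometry is planar —
the distance measures this stage feeds to the regression are planar, so
bundle depth is deliberately not modeled.

**Trajectories.** Each bundle follows the published spiral family in polar
coordinates around the disc, `φ(r) = φ₀ + b (r − r₀)^c` with `r₀ = 4°`,
where `b` and `c` are smooth tanh functions of the start angle `φ₀` with
separate superior/inferior branches (log-scale offsets `beta_sup = −1.9`,
`beta_inf = 0.5`; all constants sit in `trajectory_params`). The angle is
measured from the *nasal* horizontal: the temporal raphe lies at ±180°.
With the angular origin placed temporally instead, the arcuate branch of
the family leaves the macula bare of fibers, which contradicts both anatomy
and the assumption that every electrode sits on a bundle; the nasal origin
reproduces the expected structure (papillomacular fibers nearly straight,
arcuate fibers sweeping around the macula toward the raphe).

**Raphe.** The temporal raphe is modeled as a parabola with vertex at the
disc center and axis along the disc-frame abscissa, which is rotated 15°
inferior to the horizontal (configurable). The parabola opens toward the
fovea; its interior wedge is the raphe zone. Bundles are clipped walking
from the disc outward so that no polyline acquires vertices on both signed
sides of the parabola. The curvature default (0.013 μm⁻¹) makes the wedge
roughly ±2° tall at the fovea's eccentricity.

**Distance measures.** All bundle queries are vertex-based on polylines
resampled to a uniform 10 μm arc-length step (20 μm in the heavier pipeline
runs; tests verify that doubling the density moves no distance by more than
the coarse step). For a pair (e₁, e₂): *physical* is the Euclidean
center-to-center distance; *to-axon* is `min(d_e1a2, d_e2a1)` where
`d_eiaj` is the distance from electrode i's center to the bundle beneath
electrode j (nearest bundle, ties to the lowest index); *along-axon* is the
arc length along the fellow bundle from the foot of the to-axon minimum to
the vertex beneath the fellow electrode. We considered measuring the arc to
the own bundle's closest approach to the fellow bundle instead, but all
bundles converge at the disc, so that closest approach degenerates to the
disc end and the measure tracks eccentricity rather than pair separation.
Under the definition used here the three measures form the expected
approximate right triangle (to-axon roughly orthogonal to the gently curving
fibers, physical distance as hypotenuse), and their correlation structure on
plausible placements (r ≈ 0.59 physical–to-axon, 0.86 physical–along, 0.34
to-axon–along) matches the strongly asymmetric pattern reported for this
task. Because the three distances carry ~2 degrees of freedom, only
physical and to-axon enter the regression.

## Stage II: the logistic two-point model

Trials are preprocessed by the task's rules: catch trials removed, "no
percept" (count 0) trials discarded, counts above 3 binned to 3, and counts
≥ 2 collapsed into the binary outcome "two percepts seen". The model is

P("2"|2) = logistic(β₀ + β_amp·A + β_dist·d + [β_axon·x]),

with A the pair's mean detection-threshold amplitude (μA) — not the 2×
stimulation amplitude, which is recorded separately — d the physical and x
the to-axon distance (μm).

**Fitting.** Hand-written IRLS (weighted least squares via `lm.wfit`),
converging when the log-likelihood improves by < 1e-10, at most 100
iterations. Frozen coefficients enter the linear predictor as an offset.
Separation is detected as a diverging coefficient norm (|β_j|·sd(x_j) > 50,
far beyond any plausible logit scale) and flagged as non-convergence.
`stats::glm` is the independent cross-check in the test suite, never the
implementation, so the frozen-coefficient machinery and the cross-check
remain separate routes. The outcome may be fractional (expected response
frequencies), which the package uses for population-level projections.

**Published coefficient sets.** `tpd_coefficients()` carries the two-factor
weights in two printed precisions; the amplitude weight appears both as
−0.003014 and rounded as −0.00314. The full-precision set is the default
because it reproduces the published 75% iso-performance inversions to the
micron; the rounded variant is available as `"two_factor_rounded"`.

**Inversion.** Iso-performance distances come from the closed form
`d = (logit(p) − β₀ − β_amp·A − β_axon·x)/β_dist`; with
`axon_equals_distance = TRUE` the axon term moves into the denominator
(`β_dist + β_axon`), which is the "minimal axonal stimulation" reading
where a pair's shared bundle is as far away as the fellow electrode itself.
The round-trip `predict_p2(m, A, iso_distance(m, A, p)) = p` holds to 1e-9
and is asserted as a property.

**Fixed-weight augmentation.** Because physical and to-axon distance are
strongly correlated, the free three-factor fit redistributes weight between
them and its coefficients are hard to interpret. The package therefore
freezes the two-factor weights and refits only the axon coefficient. By
default the intercept is refit alongside the new factor; a strict mode
freezes it too. We kept the refit default after checking both variants
against the published minimal-axon inversion values: the refit variant lands
within ~3% of them, the strict variant ~7% high.

**Detection thresholds.** Yes/no staircase data are pooled and fit with a
two-parameter logistic in amplitude; the threshold is the 50% point
(−β₀/β₁). Degenerate inputs (one response class, separation, flat response)
are flagged rather than silently extrapolated. Wilson score intervals
summarize response proportions.

## Stage III: current spread, dip, and the parameter sweep

The simulator is a scoreboard model: each electrode contributes a local
patch of retinal current and axonal streaks are deliberately excluded (the
axonal effect is what Stage II estimates). Current from one disk electrode
at a point at distance r (mm) is `I = I₀ / (1 + (k·r)^a)`; the two
electrodes of a pair superpose linearly.

**Distance convention.** The kernel's r could be measured to the disk
center, the nearest disk-surface point, or the rim circle. The printed
worked examples for a 1,400 μm pair at a = 1.5, k = 15 (midpoint current 26
μA at 150 μm lift and 93 μA at 750 μm, peak normalized to 100 μA) pin this
down: computed before implementation, the disk-center convention gives
23.1/93.7 μA (dips 76.9%/6.3% vs the printed 74%/7%), while the other two
conventions give 29.1/98.2 μA and miss the 750 μm case badly. No convention
reproduces the printed values exactly — they differ by a few μA from any
literal reading — so the calibrated default is `"center"`, and all three
remain available in `spread_params()`.

**Threshold factorization.** `I₀ = θ_lift · θ_rd · θ_baseline`.
θ_baseline = 50 μA is the flush-electrode threshold over undamaged retina;
θ_lift is the reciprocal of the peak on-plane attenuation at the given lift
(closed form `1 + (k·h)^a` under the center convention, computed
numerically and verified against that form to 0.01 μA); θ_rd ≥ 1 is the
residual multiplicative elevation we attribute to retinal damage.
`find_threshold()` solves "peak retinal current = θ_rd·θ_baseline"
numerically; since the peak is linear in I₀ the solve is exact. The
"θ = 0" ablations are interpreted as *neutral* factors (damage factor 1,
lift 0 μm): the factorization is multiplicative, so a literal zero would
nullify the threshold rather than remove the factor.

**Dip.** `dip = 100·(I_max − I_mid)/I_max`, with I_max the global on-plane
maximum of the summed field and I_mid the exact midpoint value. For
equal-amplitude pairs the maximum lies on the inter-electrode axis
(projecting any point onto the axis shortens the distance to both disks),
so the sweep uses a 1-D line search (`pair_dip()`), asserted in tests
against the 2-D grid-plus-refinement of `pair_field()`. The dip is exactly
invariant to scaling both currents — which is why damage, a pure current
scaling, cannot change the criterion distance, and why the stimulation
amplitude rule (twice threshold, capped at 660 μA) is bookkeeping rather
than a driver of the results. The criterion distance (smallest separation
in [250, 8000] μm with dip ≥ criterion) is found by bisection to 1 μm on
the monotone dip-distance curve.

**The sweep and its acceptance rules.** The grid spans a ∈ [1, 3] (step
0.25), k ∈ [6, 20] mm⁻¹ (step 1), dip criterion ∈ {25, …, 95}% (a 75%
two-point judgment is assumed to need a dip above 20%), θ_rd ∈ [1, 13], and
lift ∈ [0, 1000] μm. The θ_rd range is bounded above by the acceptance rule
itself (thresholds ≤ 660 μA). For θ_rd and lift — continuous nuisance
factors with no natural step — we use fine steps (0.25 and 25 μm): with
coarser steps, whether a parameterization family passes the contour gate
depends on whether its best alignment happens to fall near a grid point,
and the accepted ensemble flips discontinuously between nearby references.
A record is accepted when its single-electrode threshold lies in
[177, 660] μA (the span of the observed participant thresholds up to the
charge-density cap) and its family's iso-dip contour matches the reference
contour with a root-mean-square amplitude residual below 20 μA ("mean
squared error in μA" implies an RMS reading; a literal mean-of-squares
option is available). The residual is evaluated by interpolating both
curves to amplitude-as-a-function-of-distance on a 50-point common grid
over their overlapping distance support, with the reference spanning its
177–660 μA amplitude range.

**The reference contour.** The sweep's reference is the 75% iso-performance
contour under minimal axonal stimulation, built by the frozen-weight
procedure at the population level: electrode-pair designs are laid out over
the package's own geometry using the study's per-session electrode subsets,
with per-electrode thresholds drawn uniformly within each participant's
published interquartile range and array placements drawn from a plausible
prior (offsets within ±600 μm of the fovea, rotations −50° to −20°); the
expected probability of reporting two percepts is computed from the
published three-factor coefficients; the axon coefficient is refit against
those expected frequencies with the two-factor weights frozen; and the
model is inverted with the to-axon distance tied to the physical distance.
Fitting expected frequencies rather than sampled binary responses removes
trial-level noise from the reference — noise that the hard acceptance rules
would otherwise amplify into discontinuous changes of the accepted set —
and pooling 15 placement draws averages over placement variability. The
sampled-trial route remains available through `gen_trial_set()` /
`fit_logistic()` and is exercised by the tests.

**Ensemble summaries.** `ablate_and_summarize()` recomputes each accepted
record's threshold and criterion distance with the chosen factor
neutralized and reports the median, interquartile range, and central 95%
range of the distances, in μm and degrees. Damage ablation is verified to
move no distance by more than 1 μm (scale invariance); lift ablation
recomputes distances at lift 0.

## The synthetic-data generators

The generators emulate the *statistical* structure of the task: every pair
of a session's electrode subset tested `n_reps_per_pair` times (default 3,
the per-run repetition count), ~25% randomly interspersed no-stimulation
catch trials with a 5% false-alarm rate, reported counts that are 2 with
the model probability and 1 otherwise, overlaid with small nuisance rates
of "0" (2%, discarded downstream, independent of the outcome) and "3" (3%,
applied only to would-be "2" reports, collapsed downstream — so neither
overlay biases the binary outcome), and mean amplitudes derived from
per-electrode thresholds drawn within each participant's published IQR.
Everything is a pure function of (config, seed); byte-identical CSV output
is asserted in tests.

They do *not* emulate: real fundus-derived placements (placements are a
configurable prior, not estimates from images), temporal stimulus dynamics
(pulse-train parameters are metadata only), percept drawings, brightness or
shape cues, criterion drift across sessions, or between-subject response
differences (subject identity is not a model factor). Consequently, a green
test suite establishes that the pipeline recovers what it assumes — correct
preprocessing, unbiased coefficient recovery at realistic trial counts,
correct inversions and sweep mechanics — not that the fitted coefficients
describe any particular patient.

## Problem sizes and tolerances

Default runs use 400 bundles sampled at 10–20 μm (the invariants are
step-relative); the full sweep evaluates ~2.2 million parameterizations in
about a minute on one CPU, with criterion distances bisected to 1 μm and
thresholds solved to 0.01 μA. Statistical tests use 5,000-trial recovery
sets (within 3 SE), 500-replicate coverage checks at 1,000 trials each
(93–97% band for nominal 95% Wald intervals), and a fixed seed throughout.

## Known limitations

The geometry is planar and the bundle-beneath-electrode assignment is
deterministic nearest-bundle; to-axon distances inherit the trajectory
model's errors, which are largest near the raphe. The current-spread
kernel is radially symmetric and ignores conductivity structure (membranes,
fibrosis, fluid), which the damage factor absorbs only as a scalar. The
sweep's accepted ensemble depends on unprinted grid conventions; its
medians are stable under the fine default grids but the no-ablation median
sits near the upper edge of the plausible range implied by the published
summaries, reflecting that the accepted parameterizations' threshold
distribution — not printed anywhere — is the main unconstrained degree of
freedom. θ_rd is, by construction, whatever threshold elevation lift does
not explain; interpreting it strictly as retinal damage is a modeling
choice, not an observation.
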