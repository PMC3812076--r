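---
title: "Methods: run/stop segmentation of bacterial tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run/stop segmentation of bacterial tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `runstop`, the
assumptions it rests on, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and the known
limitations — in particular what the simulation-based validation does and
does not demonstrate about real tracking data.

## Data representation

A track is an ordered sequence of 2D centroid positions at a fixed frame
interval Δt (seconds); coordinates are in micrometres, frame indices are
0-based, and time is `frame * dt`. All inference operates on the derived
framewise quantities: the speed `v_t` of each displacement and the signed
angle change `θ_t` between consecutive displacements, wrapped to (−π, π].
A track of T frames yields T−1 speeds and T−2 angle changes. States are
coded package-wide as 1 = stop and 2 = run, one state per displacement.

If a displacement has exactly zero length its polar angle is undefined, so
the adjacent angle changes are recorded as 0 and *flagged*. Flagged steps
are never used when estimating angle densities, and during inference they
fall back to a speed-only emission (the angle factor is replaced by the
circular uniform 1/2π). This situation arises only for noiseless simulated
stationary phases; any measurement noise makes it a probability-zero
event. The constant 0 is arbitrary by design — the flag guarantees it is
never interpreted.

## The two-state hidden Markov model

Displacements are modelled as emissions of a hidden two-state Markov
chain. The transition matrix is parameterised by the mean dwell times:
`p12 = dt/tau12` (stop to run) and `p21 = dt/tau21` (run to stop), which
requires `dt < min(tau12, tau21)` — the camera must sample faster than the
dwell times it is asked to resolve. The initial distribution is the
stationary distribution of the chain, `pi_stop = tau12/(tau12 + tau21)`:
tracks begin at arbitrary times of a process assumed stationary. The
first displacement of a track has no preceding angle, so it enters the
likelihood through the speed component only, weighted by `pi`. (Whether
the first observation should carry an emission term at all is a modelling
choice; conditioning it on `pi` with the speed-only emission uses the
information that is actually available at that step.)

The emission density is empirical and *previous-state dependent*:

* the speed component `b_j(v)` is the kernel density estimate (KDE) of
  framewise speeds observed in the non-motile mutant for the stop state
  and in the non-chemotactic mutant for the run state;
* the angle component `b_ij(θ)` uses the non-motile angle KDE for every
  pair (i, j) involving a stop — (stop,stop), (run,stop) and, crucially,
  (stop,run) — and the non-chemotactic angle KDE for (run,run) only.

The (stop,run) assignment is the reason the standard HMM formulation must
be relaxed: the apparent heading of a stopped cell is dominated by
localisation noise, so the angle observed when a run resumes is measured
against an essentially random reference direction and must be judged
against the broad stop-phase distribution, not the tight run-phase one.
Judging it against the run-phase density would systematically misread
stop-to-run transitions as continued stopping. The dependence extends the
emission to one preceding state only, so the process remains Markov and
the forward–backward recursions carry through with `b_ij` replacing
`b_j`. The mapping is stored in the model object (`angle_map`) and can be
overridden.

Speed and angle components are treated as independent (separable). Joint
(v, θ) densities would need far more mutant data to estimate reliably;
separability is the pragmatic assumption and its cost is shared by every
method compared.

Inference uses per-step rescaled forward and backward recursions
(implemented in C++); the scaling factors accumulate the log-likelihood,
and the posterior run probability of each displacement follows from the
normalised product of forward and backward variables. Hard state
sequences are obtained by rounding posteriors at 0.5, with the tie going
to run — a measure-zero event under continuous densities, fixed for
determinism. There is deliberately no Viterbi decoding: downstream
statistics use posterior marginals.

`tau12` and `tau21` are estimated by minimising the negative
log-likelihood pooled over all censored tracks (individual tracks are far
too short to fit alone). The surface is smooth with a unique interior
minimum on data containing both states, so a deterministic
box-constrained quasi-Newton optimiser (L-BFGS-B) suffices; bounds are
`[1.5 dt, 60] s` on both parameters with start point `(5 dt, 25 dt)`.
Confidence intervals are percentile bootstrap over track-level resamples
(default 1000 iterations, 2.5th/97.5th percentiles).

**Non-identifiability.** A dataset without stops leaves the likelihood
essentially independent of `tau12`. This is detected after convergence:
if the estimate sits on a box bound, or the posterior stop occupancy at
the optimum is below max(1, 1e−4 × total displacements), the fit aborts
with a classed error (`runstop_nonidentifiable`) rather than returning an
arbitrary number. The occupancy criterion is the operational form of "no
stops were inferred anywhere". A caveat found during validation: at
moderate noise, the slowest genuine swimmers of a never-stopping
population (the left tail of the run-speed distribution) can overlap the
stop-speed density and acquire real stop posterior mass, in which case
the likelihood *is* (wrongly) informative about `tau12` and no error can
be raised on statistical grounds. The no-stop safeguard is therefore a
low-noise guarantee, not an unconditional one.

The speed-only variant replaces every angle density by the circular
uniform; it is exactly equivalent to the full model when the empirical
angle densities happen to be uniform, and serves both as an ablation and
as the method of choice when no informative angle prior exists.

## Empirical observation densities

Speed densities are Gaussian-kernel KDEs on [0, `v_max`], reflected at
both boundaries (0 and `v_max`) so no kernel mass leaks outside the
permissible range; `v_max` equals the censoring threshold `rho_fs`, which
is why speeds above it must never reach the HMM. Angle densities are
circular KDEs: samples are wrapped to (−π, π] and kernel mass is
re-wrapped across ±π, so the estimate is periodic and integrates to one
over a period. Grids have 2^14 (speed) and 2^10 (angle) points;
evaluation is by linear interpolation.

Bandwidths default to the diffusion plug-in selector of Botev, Grotowski
and Kroese (solved by fixed point on a DCT grid), which avoids arbitrary
histogram bin widths. Two guards apply, both of which matter in practice:

* **Effectively discrete samples.** Plug-in selectors assume an
  absolutely continuous density and collapse towards zero bandwidth on
  heavily tied data. If fewer than max(10, 10%) of the sample values are
  distinct at 8 significant digits, the selector falls back to
  Silverman's rule (which handles even constant samples). Noiseless
  simulated run speeds — one atom per run — are the canonical case.
* **Grid representability.** Bandwidths are floored at twice the
  evaluation-grid spacing; a kernel narrower than the grid cannot be
  represented and would alias.

Two positivity floors protect the recursion. The speed densities gain an
additive constant `floor_eps` (default 1e−6 per µm/s): wildtype tracks
are invisible when the mutant priors are built, so a wildtype speed may
fall where the mutant KDE is numerically zero, and a zero emission
declares the displacement to be in *neither* state, breaking the
two-state assumption. The same argument applies verbatim to the angle
densities (a large angle where the run-phase KDE has underflowed), so the
package floors them too. A source dataset with too few valid angle
changes (fewer than `min_angle_samples = 10`; a noiseless stationary
strain has none) contributes the circular uniform instead — the correct
isotropic limit for a direction that carries no information.

The heuristic baseline needs a single cutoff speed: the smallest speed
above the mode of the stop density at which the run density exceeds it,
located by linear interpolation (an error if the densities never cross —
the populations are not separable). This intersection rule does not
minimise the overlap region exactly, but matches how the threshold is
chosen in practice.

## Censoring

Three stages, each motivated by a distinct failure mode of high-throughput
tracking:

1. any framewise speed above `rho_fs` (default 100 µm/s) discards the
   whole track — implausible jumps indicate misassociation between
   frames. The default sits far above a ~40 µm/s mean swimming speed;
   it should be chosen per dataset from the non-chemotactic speed
   distribution.
2. minimum bounding diameter below `mbd_min` (default 10 µm) discards
   tracks that never leave a small neighbourhood: non-motile cells and
   very short tracks. Applied to motile strains only — it would remove
   essentially every track of a non-motile strain, whose summary rows are
   reported as not-applicable.
3. the top ⌈5%⌉ of the remainder by median absolute three-point curvature
   discards helical/tortuous swimmers that neither automated nor manual
   segmentation can handle. A *fraction* (rather than a curvature
   threshold) lets the same configuration censor datasets of very
   different scales. The removal count is exactly `ceiling(fraction * n)`
   — the ceiling convention is the unique integer rule consistent with
   the published per-stage counts this stage is validated against — with
   ties broken by original track order for determinism.

The minimum bounding diameter is computed exactly by Welzl's
move-to-front algorithm (with a deterministic pseudo-shuffle so results
never depend on the RNG state); curvature is the circumradius reciprocal
`4·area/(abc)` of each consecutive position triple, zero for collinear or
degenerate triples. The effective mean speed divides the bounding
diameter by `(T−1)·dt`, which makes the normalised effective mean speed
exactly 1 for a straight constant-speed track — the interpretation the
summary is designed around.

## The simulator

The generator emulates a run-and-stop velocity-jump process: exponential
run and stop durations (means `tau21`, `tau12`), a constant Weibull
run speed per run, uniform reorientation at the end of every stop, frozen
position during stops, sampling on the frame grid, and additive
independent Gaussian noise on every recorded coordinate. Defaults —
τ12 = 0.14 s, τ21 = 0.86 s (classical single-cell tracking values for
*E. coli*), Δt = 0.02 s, 500 tracks × 250 frames, Weibull shape 2 with
mean speed 40 µm/s, zero noise — are the reference study conditions; the
Weibull scale is otherwise an order-of-magnitude match to bacterial
swimming, and noise is parameterised directly as a per-coordinate s.d.
σ in µm, convertible to an apparent diffusion coefficient via
`σ = sqrt(2 D Δt)` for comparison with the MSD estimator. The initial
state is drawn from the stationary distribution with a fresh exponential
first dwell (exact, by memorylessness). The continuous ground truth is
recorded before noise; for scoring, each displacement interval
overlapping *any* part of a stop event is labelled a stop, a rule that
can only inflate the stop fraction.

What the simulator deliberately omits: rotational Brownian motion during
runs (real runs curve), helical swimming, correlated or state-dependent
localisation noise, track fragmentation and misassociation, and
population heterogeneity in speed or dwell parameters. Passing the
simulation-based tests therefore demonstrates correctness of the
*inference machinery* under the stated generative model, not robustness
to every artefact of real microscopy data.

## Evaluation conventions

False positives and negatives are counted at the *event* level: an
inferred maximal stop phase sharing no displacement interval with any
true stop phase is one FP, and vice versa for FN. Any shared interval
counts as a match — the most permissive criterion, chosen because the
published definition fixes the unit (phases) but not the overlap rule;
being permissive biases all compared methods equally. Rates are
normalised by the total number of true stop events (ratio of totals) as
the headline, with the mean of per-track ratios also reported, since
"average over all tracks" admits both readings.

Stopwise angles use the single flanking run displacements immediately
before and after a stop event (not averaged run headings); events
touching a track boundary have no defined angle. The two-sample Kuiper
test compares angle distributions: its statistic is invariant to a common
cyclic shift, which is the property that makes it (unlike
Kolmogorov–Smirnov) correct on the circle. The p-value uses the standard
asymptotic series with effective sample size `na·nb/(na+nb)`; exact
small-sample tables are out of scope, and the series is truncated to 1
below λ = 0.4.

Post-processing applies exactly four steps in a fixed order: relabel
running phases shorter than `P_r`, recompute, relabel stopping phases
shorter than `P_s`. Doing runs first deliberately biases rapidly
oscillating stretches towards stops — identifying every stop is valued
above avoiding overlong ones. Boundary-touching phases obey the same
rules as interior ones, keeping the operation a pure, idempotent function
of the label sequence. Defaults `P_r = P_s = 2` frames; the smoother is
off by default for HMM output, where it makes little difference, and is
chiefly a rescue for the heuristic classifier.

## Numerical and scale choices in the validation suite

The test suite validates the forward–backward recursion against an
exhaustive path-sum oracle (tracks of ≤ 8 displacements, tolerance
1e−10), runs the full parameter-recovery experiment at the reference
scale (500 tracks × 250 frames), and exercises the method comparison at
120–150 tracks per strain with noise σ = 0.1 µm — sizes chosen so the
whole suite completes in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted margins. The noise level for
the comparison sits where the methods genuinely differ: stop-phase
apparent speeds (Rayleigh, scale √2σ/Δt ≈ 7 µm/s) overlap the slow tail
of the run-speed distribution, which is what separates the heuristic
from the HMM methods.

## Known limitations

* **The zero-noise condition is singular.** With exactly zero observation
  noise the mutant KDEs degenerate: all stop speeds are exactly 0 and all
  run-run angles exactly 0, so both densities are numerical spikes, and a
  stop shorter than one frame that straddles a frame boundary presents
  only a modestly reduced speed and a single large angle — while its
  partial displacements retain the old heading *exactly* and so sit on
  the degenerate angle spike, which favours the run explanation. The
  parameter-recovery test at σ = 0 accordingly finds the mean stop
  duration only slightly overestimated (the discretisation inflation and
  the missed-short-stop deflation nearly cancel) and the mean run
  duration inflated by the missed events. Any nonzero noise regularises
  both densities, and the expected behaviour — stop duration
  overestimated by roughly 20%, run duration accurate — appears at small
  σ. Real data always carry noise; the singular case matters only for
  synthetic benchmarks.
* The MLE inherits a systematic bias from frame-rate discretisation:
  dwell times comparable to Δt cannot be resolved, and the bias grows
  with noise. Estimates from noisy data should be read with the
  simulation study's bias curves in mind, not as unbiased measurements.
* The censoring thresholds `rho_fs` and `mbd_min` are dataset-dependent
  configuration, not universal constants; defaults suit fast swimmers
  imaged at 50 fps.
* Two hidden states only; no spatial or temporal inhomogeneity of the
  transition matrix (no chemotaxis gradients); 2D projected motion only.
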