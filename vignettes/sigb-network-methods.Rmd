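---
title: "Modelling pulsatile activation of the sigma-B stress-response network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pulsatile activation of the sigma-B stress-response network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sigbnet)
```

## The model

The general stress response of *Bacillus subtilis* is controlled by the
alternative sigma factor sigma-B through a partner-switching module: the
anti-sigma factor RsbW dimerizes (W2) and sequesters sigma-B; the
anti-anti-sigma factor RsbV attacks the W2-sigma-B complex and releases
sigma-B; RsbW is at the same time a kinase that inactivates RsbV by
phosphorylation, and stress phosphatases (RsbQP under energy stress, RsbTU
under environmental stress; lumped here as one total concentration
`P_T(t)`) reactivate RsbV-P. Free sigma-B activates its own operon, which
also encodes RsbW and RsbV at relative synthesis rates `lambda_W` and
`lambda_V`.

`sigbnet` assembles the mass-action rate equations of this module
mechanically from the elementary reactions — dimerization, the two
W2/RsbV binding steps, W2/sigma-B binding, partner displacement,
phosphorylation of RsbV in both W2 complexes, phosphatase binding and
catalysis, uniform dilution of every species at `k_deg`, and operon
synthesis at rates `v_B`, `lambda_W v_B`, `lambda_V v_B` with
`v_B = v0 (1 + f sigma / (K + sigma))`. We deliberately do not transcribe
a printed ODE list: assembling from reactions leaves no ambiguity about
dimer bookkeeping, and the assembly is validated in the test-suite
against the exact total-concentration equations
`dB_T/dt = v_B - k_deg B_T` (and the lambda-scaled analogues), which any
correct assembly must reproduce identically.

Units are micromolar and hours throughout. The RsbW monomer gets its own
equation (`dW/dt = lambda_W v_B - 2 k_bw W^2 + 2 k_dw W2 - k_deg W`);
free phosphatase is eliminated through `P = max(P_T - VPP, 0)` — the
clamp can only engage under a discontinuous drop of the prescribed
`P_T(t)`, which none of the bundled inputs produce.

The default parameters are the published wild-type set (association
3600 /uM/hr, dissociation 18 /hr giving 5 nM partner-complex affinities,
displacement 1800, kinase 36 /hr, phosphatase 180 /hr, `k_deg` 0.7 /hr,
`v0` 0.4 uM/hr, `f` 30, `K` 0.2 uM, `lambda_W` 4, `lambda_V` 4.5). Two
values deserve a note:

* `k_deg` defaults to 0.7 /hr (a ~1 hr doubling time); the ramp-encoding
  experiments use 0.72 /hr as their wild-type reference, which is the
  convention of the figure they reproduce. It is an ordinary argument of
  `sigb_kinetics()`.
* `v0` is chosen so that total sigma-B is ~1 uM in the absence of stress;
  the model delivers 1.08 uM, which the acceptance checks recompute.

## Numerical contract

Simulation uses `deSolve::lsoda` on a compiled right-hand side
(`src/sigb_models.c`), with `rtol = 1e-8`, `atol = 1e-10` uM, and the
step bounded by the input sampling interval for stochastic inputs;
deterministic step/ramp inputs are integrated piecewise between their
breakpoints so discontinuities coincide with solver restarts. The same
rhs exists in plain R (`sigb_rhs()`) as the readable reference; the
test-suite pins the two against each other, keeps the four conservation
identities below 1e-6 relative along trajectories, and cross-checks
every steady state against a damped-Newton root solve started away from
the solution (`steady_state_root()`). Steady states integrate for
`200 / k_deg` hours and then Newton-polish to `|rhs| < 1e-8` uM/hr.
Totals `B_T`, `RsbW_T`, `RsbV_T` are carried as auxiliary states
integrated from their exact production-dilution equations, so the
conservation test compares two independently computed quantities rather
than a tautology.

## Decoupled responses, logarithmic gain and the region map

The feedback structure is analysed by cutting the loop. The
post-translational response `F_P` is the steady-state free sigma-B as a
function of total sigma-B when the operon runs at a constant rate `v`;
because `B_T = v / k_deg` exactly at such a steady state, the curve is
parameterized by `v` (monotone in `B_T`), which is also how folds in the
sigma direction are traversed without a continuation package — each
point warm-starts the next Newton solve, and a warm start is accepted
only if it lands on the prescribed total. The transcriptional response
`F_T` is the closed form `B_T = v0 (1 + f sigma/(K + sigma)) / k_deg`.
Their intersection (a one-dimensional fixed point in log-sigma) is an
independent route to the closed-loop steady state and agrees with the
full-model solve to 1e-4 relative in the tests.

The logarithmic gain `LG_P = d log sigma / d log B_T` is a centered
finite difference with a 1% half-step in log space, computed from two
fresh steady states rather than an interpolated curve when exactness
matters. Its sign gives the effective feedback sign because `F_T` is
increasing.

Classifying the `(lambda_W, lambda_V)` plane needs one decision the
analytic treatment leaves open. In the strong-binding limit the
non-responsive region has identically zero free sigma-B, hence
`LG_P = 0`; with the real 5 nM affinities a leakage of a few nM remains
and — evaluated exactly at the operating point — still carries a residual
log-gain of order -2 even where the response is negligible in absolute
terms (the gain does relax to ~0 at large `B_T`). A pure sign rule would
therefore never produce the non-responsive region. `classify_region()`
keeps the sign rule with a +/-0.05 dead zone and adds a global
non-responsiveness condition: a point is non-responsive when free
sigma-B never exceeds 15% of total sigma-B anywhere along the
post-translational curve. The boundary this produces tracks the analytic
lines `lambda_W = 2 (1 + lambda_V k_deg / k_k)` and
`lambda_W = 2 + lambda_V` to within one unit on the 8x8 integer grid the
acceptance test scans, and step-response pulsing coincides with the
negative-feedback region away from those lines when "pulsing" is scored
with the matching scale (amplitude above 5% of the pre-step `B_T`, and a
peak at least 10% above the final level). The reference phosphatase for
classification is 0.5 uM, the mean used by the competition analyses.

The pulsing threshold in the step size is located by bisection on the
amplitude (floor: 1% of pre-step `B_T`; the source analysis states no
floor). The printed analytic approximation for that threshold is
dimensionally ambiguous, so the package evaluates it verbatim
(`analytic_threshold()`) and the tests assert only trend directions
(threshold rising with `v0` and `lambda_W`, falling with `k_p/k_k`),
which the numeric threshold reproduces.

## The stochastic phosphatase input

Energy-stress input is a gamma-distributed Ornstein-Uhlenbeck burst
process: compound-Poisson jumps with exponentially distributed sizes
(mean `b`, uM) and exponential decay at rate `gamma` between jumps. We
take the jump rate to be `a * gamma`, which makes the stationary law
exactly Gamma(shape `a`, scale `b`) with mean `ab` and variance `ab^2` —
the parameterization in which "mean phosphatase = burst size x burst
frequency" is an identity rather than an approximation. With
`gamma = k_deg = 0.7`/hr (the phosphatase dilutes like every other
protein) and a ~1 hr cell cycle, `a` counts bursts per relaxation time,
i.e. approximately per cell cycle. Trajectories are sampled exactly on a
uniform grid (jump contributions decayed analytically within each bin,
then a one-step recursion), initialized from the stationary law, and
linearly interpolated by the solver.

Defaults, chosen once and used for every stochastic experiment:
`a = 2` bursts/cycle and `b = 0.25` uM. The baseline mean `ab = 0.5` uM
is the fixed mean of the polymerase-competition analyses; `a = 2` puts
the saturating pulse rate `a * gamma ~ 1.4`/hr at the ceiling of the
single-cell pulse rates the model emulates. Burst-encoding sweeps cover
eight log-spaced means from 0.08 to 1.2 uM — from below the ~0.11 uM
step-response threshold into saturation — with 20 traces of 10 h per
level, which keeps the whole sweep under a minute of CPU while leaving
Monte-Carlo errors of a few percent on the per-level means.

What the generator emulates — and what it does not: it reproduces the
gamma-distributed copy-number fluctuations of a burst-expressed protein
with independent size/frequency control; it does not model intrinsic
noise in the sigma-B operon itself, mechanistic
transcription-translation bursting of the phosphatase gene, or cell
division events. Passing tests therefore speak to how the network
filters an extrinsically fluctuating phosphatase, not to full single-cell
stochasticity.

## Pulse statistics and encoding signatures

Pulses are local maxima with prominence above an absolute floor (0.05 uM
for free sigma-B, 0.05 occupancy units for promoter activity) and at
least 0.5 hr apart (the larger of two close peaks wins); amplitude is
peak minus preceding minimum. Absolute rather than per-trace floors keep
counts comparable across stress levels; the headline statistics are
stable to two-fold changes of both knobs (tested). "Target promoter
activity" in the core model is the occupancy `sigma / (K + sigma)` with
the operon's `K`; "target expression" is that activity low-pass filtered
at `k_deg`, the steady-flux level of a stable target protein. Hill fits
use 20 multi-starts on log-spaced `(n, K)` grids with ties broken by
residual then by smaller `n`; dose-response exponents for target
expression are fitted on the stress-induced component (the unstressed
basal expression, occupancy ~0.03, is subtracted first, as usual for
induction curves).

The burst-size/burst-frequency signatures reproduce qualitatively: size
modulation gives amplitudes rising linearly with the mean (R^2 > 0.95 on
free sigma-B; ~4-5-fold in activity units across the sweep) with an
ultrasensitive pulse-frequency onset, while frequency modulation gives
flat amplitudes, linear frequency, and largely overlapping amplitude
CDFs. Two quantitative exponents fall short of the published values
under these conditions, and we report them as computed rather than
adjust the generator: the frequency-versus-mean Hill exponent under size
modulation comes out near 2 (published ~5.6) — with exponential burst
sizes the fraction of bursts crossing the pulsing threshold is
`exp(-J*/b)`, whose maximal log-log steepness caps the effective
exponent near 2 for any detection setting we scanned — and the induced
target-expression exponent comes out near 1.1 (published ~2), limited by
occupancy saturation at `K = 0.2` uM. Reproducing the published
steepness would need a much narrower burst-size distribution or a
stationary shape parameter far above anything consistent with the burst
picture; we prefer the canonical process and honest exponents.

Ramp encoding fixes the final phosphatase level, varies the ramp
duration, and fits the decreasing Hill form to amplitude versus
duration; `K_ramp` is its half-max constant. Across
`k_deg` in 0.36/0.72/1.44 /hr (with `v0` rescaled proportionally so all
totals are unchanged) the amplitude is nonincreasing in ramp duration
and `K_ramp` moves monotonically with `k_deg`, the timescale-separation
signature; the direction of that trend is reported, not asserted a
priori.

## Polymerase competition

The mechanistic extension adds reversible sigma-B/RNApol and
sigma-A/RNApol holoenzyme formation (affinities 1.2 uM and 0.02 uM) and
holoenzyme binding to 0.05 uM of target promoter (affinity 0.1 uM);
operon production becomes basal `v0` plus `(v0 f / p_B_tot)` times the
promoter-bound holoenzyme, so full occupancy recovers the fold change.
Only free sigma-B partner-switches: holoenzyme-bound sigma-B is assumed
unavailable to RsbW because core polymerase and the anti-sigma factor
occupy overlapping surfaces. Dilution of sigma-B holoenzymes removes the
sigma-B moiety and recycles core polymerase and promoter, and sigma-A
species are not diluted — the only bookkeeping under which the fixed
totals (`RNApol_tot`, `A_T`, `p_B_tot`) are conserved exactly while
total sigma-B keeps its production-dilution equation. Basal production
is not polymerase-limited, following the printed reaction scheme.

In the three-sigma model the stress factors are reduced to the
phenomenological response
`sigma_free = X_T / (1 + (X_T / K)^nb / P^mb)` (negative feedback:
nb = 7, mb = 5; positive: nb = 0, mb = 3; K = 5 uM), their totals evolve
as `v0 (1 + f occ) - k_deg X_T` with `occ` their own promoter occupancy,
and the polymerase partition is treated as a fast equilibrium solved by
one-dimensional root finding (sigma-A titrated from its 12 uM total;
clamped free stress sigmas, which their partner networks buffer).
Partition changes are reported relative to the smallest `P_B` scanned.
The negative-feedback variant reproduces the published behaviour (free
sigma-W weakly increasing while polymerase for sigma-B is drawn almost
entirely from the sigma-A pool); in the positive-feedback variant free
sigma-W decreases as published, but the untitrated formula lets free
sigma-W reach ~13 uM, promoter occupancy saturates, and the absolute
polymerase loss still falls mostly on the sigma-A pool — the published
reversal of the partition has no operating regime under the printed
formulas, and the acceptance check reports it red rather than altering
the model.

## Reproducibility

Every stochastic experiment takes one master seed that fans out to
per-trace substream seeds drawn once up front, so ensembles are
reproducible as a whole and any single trace in isolation;
`run_experiment()` writes a manifest with all parameters, the seed, and
every defaulted under-specified constant (pulse thresholds, `gamma`, the
classification reference phosphatase). Identical configurations rerun
bit-identically.

## Known limitations

RsbX and stressosome dynamics, explicit mRNA, SBML interchange, and
formal bifurcation analysis are out of scope; the pulses here are
excitable adaptive transients, not limit cycles. The exact gamma-OU
parameterization used by the original stochastic analyses is not
recoverable from the source text, so the burst-frequency convention
declared above is a package decision; quantities that depend only on the
stationary law (means, variances, CDF comparisons) are insensitive to
it, while fitted exponents of dose responses depend on the scanned range
and are reported together with the range that produced them.
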