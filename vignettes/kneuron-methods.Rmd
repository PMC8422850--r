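---
title: "kneuron: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kneuron: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, the numerical choices, what
the synthetic-data generator does and does not emulate, and the known
limitations of the published parameter sets it implements.

## The model

AVPV kisspeptin neurons are modelled as a single isopotential compartment
with whole-cell capacitance `Cm = 17.62 pF` (the mean of recorded cells),
seven voltage-gated conductances, an Ohmic leak, and a holding current:

* three K⁺ currents — **slow-transient**, **fast-transient**, and
  **residual** — with GHK driving forces and `E_K = −92 mV`;
* three subthreshold inward currents — persistent Na⁺ (**NaP**, E = 50 mV),
  T-type Ca²⁺ (**CaT**, E = 155 mV, activation exponent r = 2), and the
  hyperpolarization-activated current (**HCN**, E = −19.9 mV,
  activation-only) — all Ohmic;
* a transient Na⁺ current (**NaT**) as a three-state Markov scheme
  (C ⇌ O → I → C) with sigmoidal rates `r/(1 + e^{(V+s)/k})` and current
  `ḡ O³ (V − E_Na)`.

One parameter set exists per estrous-cycle stage (`preset("diestrus")`,
`preset("proestrus")`); the NaT channel is identical between stages, on
the experimental grounds that spike threshold and amplitude do not change
with cycle stage. Presets are shipped as versioned JSON files under
`inst/extdata/presets/` (JSON rather than YAML because no YAML parser is
available in the supported dependency set).

### Gating

Every Hodgkin–Huxley gate has steady state `1/(1 + e^{x/K})` with
`x = V − V50` (or `x = V + V50` for the NaP gates, whose tabulated
half-voltages are positive; under this convention NaP half-activation sits
at −50.45 mV, consistent with a subthreshold persistent current). The slope
factor is signed: `K < 0` produces activation, `K > 0` inactivation. This
is a deliberate sign-flip of the conventional `(V50 − V)/K` form, chosen
because the tabulated signed slopes only produce physiological curves this
way.

Time constants use four functional forms (`tau_spec()`): constant,
single-sigmoid, double-sigmoid, and a bell form for NaP inactivation.
Table rows citing specific equation numbers were mapped to forms by their
parameter structure (slow/residual gates → double-sigmoid; fast-m, CaT and
HCN → single-sigmoid, degenerating to a constant when B = 0; NaP-h →
bell), since the printed equation numbering drifts by one relative to the
defining equations.

The fast-transient K⁺ current carries **two** inactivation gates with
fixed time constants (14.55 and 113.55 ms) sharing one steady-state curve.
No mixing weights are published; the package uses equal weights
(w = 0.5/0.5), configurable per `conductance_spec()`. K⁺ activation
exponents are r = 1 throughout (the legible table entries give r = 1 for
NaP and HCN and r = 2 for CaT).

### The GHK driving force

The K⁺ current–voltage relation is
`I = ḡ mʳ h · (V/V_T) · (e^{(V−E)/V_T} − 1)/(e^{V/V_T} − 1)`, with thermal
voltage `V_T = 26.21 mV` (kT/q at the 31 °C recording temperature,
configurable). The printed equation is dimensionally ambiguous: the
prefactor `qV/kT` is dimensionless, so `ḡ × (…)` is formally a
conductance, not a current. Two readings are possible — treat the
prefactor as `V` in mV, or as the dimensionless `V/V_T` and interpret the
product as pA. The package defaults to the **dimensionless** reading
because it is the only one that produces physiological current densities:
with `V` in mV the isolated slow current at +40 mV would be ≈ 63 nA
(≈ 3600 pA/pF, an order of magnitude beyond any recorded density) and no
model could fire at 2–28 pA stimuli. With the default reading the same
simulation gives ≈ 2.1 nA (≈ 122 pA/pF), in the recorded range. The
alternative remains available via
`driving_force(..., ghk_prefactor = "mV")` and
`preset(..., ghk_prefactor = "mV")`. The V → 0 singularity is removable
and evaluated in closed form.

Two reversal-potential constants deliberately coexist: the model channels
use −92 mV; the *analysis* chain divides peaks by the GHK driving force at
the calculated −94 mV (the Nernst potential of the recording solutions at
room temperature, `nernst(145, 3.5, 21)` ≈ −94.4 mV). They are kept
distinct, as in the original workflow.

## Simulation

**Voltage clamp** (`run_voltage_clamp()`) is ideal: the membrane follows
the command exactly, with no series resistance. Step commands are
piecewise-constant, so within each segment every gate ODE has the exact
solution `x(t) = x_∞ + (x_0 − x_∞) e^{−t/τ}` and the reduced Markov pair
(C, O) evolves by a 2×2 matrix exponential. The simulator evaluates these
closed forms at the output grid; `dt` (default 0.05 ms, 20 kHz) only sets
the sampling. Consequently integration error is zero up to floating point,
and the dt-halving and dense-brute-force checks in the test suite pass
with large margin. Recorded current is the summed voltage-gated ionic
current, outward positive; leak and capacitive artifacts belong to the
synthetic rig, not the ideal clamp.

**Current clamp** (`run_current_clamp()`, C++ backend) integrates the
membrane equation with a Strang-type splitting: states advance exactly at
frozen voltage for half a step, the voltage takes a midpoint (RK2) step,
states advance another half step. The exact state update removes the
stiffness of the fast Na⁺ rates (up to ≈ 390 ms⁻¹), so the default
`dt = 0.01 ms` is ample; output is subsampled at 0.05 ms. A replay mode
(`clamp_to_voltage()`) clamps the membrane to an arbitrary sampled
trajectory; the test suite uses it to verify that the current-clamp and
voltage-clamp code paths agree (re-deriving the applied current from a
simulated voltage trace to < 0.01 pA median error).

**Initialization**: every protocol starts from the full steady state at
the holding potential (`steady_state_model()`), the Markov states from the
null space of the rate matrix. Resting potentials are located by scanning
the steady-state I–V for sign changes and taking the root nearest −70 mV —
necessary because the NaP/CaT/NaT window currents create additional
depolarized equilibria that a naive root search can land on.

**Calibration** (`calibrate()`) matches the experimental baseline: Ihold
is set to the analytic steady-state current at −70 mV and g_leak is
iterated so that the input resistance measured exactly as in the
experiment (−5 pA, 500 ms, steady-state deflection) equals 1 GΩ. Internal
tolerances are 10 µV and 0.1%, comfortably inside the stated 50 µV / 0.5%
acceptance bands; convergence takes 2–3 fixed-point iterations. The
calibrated diestrous leak (1.104 nS) lands close to the published 1.06 nS,
an independent consistency check.

## Analysis chain

The analysis functions mirror the recording conventions:

* `offline_leak_subtract()` scales the averaged −5 mV template response to
  each command segment (both the steady leak and the capacitive transient
  at each edge), as used for the long total/slow protocols where P/N
  subtraction is unfeasible;
* `pn_subtract()` implements P/−5 correction from five fifth-amplitude
  sub-sweeps;
* `peak_current()` takes the maximum over the test-pulse window — the
  whole pulse by default, 70–150 ms after pulse onset for the
  slow-recovery protocol (to skip the fast-transient contamination);
* `normalized_ghk_conductance()` divides peaks by the GHK driving force at
  −94 mV and normalizes to the maximum;
* `fit_boltzmann()` and `fit_exponential()` are port-algorithm
  least-squares fits from three heuristic starts (for the exponential, a
  log-linear regression provides the τ start), lowest residual wins;
  degenerate inputs raise errors rather than returning nonsense.

Round-trip accuracy (simulate → subtract → peaks → GHK → Boltzmann) on the
isolated presets: activation midpoints recover within 0.6 mV (slow), 0.1 mV
(fast, via A−B subtraction), 0.2 mV (residual, via protocol B); the slow
inactivation midpoint recovers within 0.02 mV with the 10-s prepulses. The
residual normalized-conductance slope is shallowed (−10.3 vs −8.85 mV) by
partial inactivation during protocol B's conditioning — an analysis
artifact faithfully reproduced, not a bug. The fast *inactivation*
midpoint recovers ≈ 1.4 mV depolarized of truth because the 200-ms
prepulses do not equilibrate the 113.55-ms inactivation gate; the
protocols are as specified, so this bias is part of the emulated method.

## Maximal-conductance optimization

`pso_gbar()` is a canonical global-best particle swarm (inertia 0.729,
cognitive/social 1.49, reflecting bounds, seeded RNG; swarm 30 × 200
iterations by default — all configurable, since none of these values are
published). The objective (`gbar_objective()`) compares simulated to
target total-K⁺ traces over the first 250 ms of each test pulse by default
(late-trace error is dominated by slow-inactivation mismatch; full-trace
weighting is an option). Because gate kinetics are independent of ḡ, each
channel's clamp current is linear in its ḡ; the objective therefore
precomputes per-channel unit responses once and evaluates candidates as
linear combinations — exactly equal to re-simulating, at a fraction of the
cost. Kinetic parameters are never free in this stage. On a noiseless
self-generated target, a seeded run recovers all three ḡ within 0.2%
(the acceptance bound is 15%).

## The synthetic rig

`sample_cell()` draws per-channel ḡ multipliers (lognormal, median 1,
`sdlog = 0.25`) and passive properties around the recorded population
means (Rs ≈ 15.7 MΩ, Rinput ≈ 980 MΩ, Cm ≈ 17.6 pF, Ihold ≈ −20 pA),
truncated to the study's inclusion criteria, deterministically per seed.
`record_cell()` then simulates the K⁺ currents under ideal clamp
(Na⁺/Ca²⁺/HCN are pharmacologically blocked in the emulated recordings)
and adds what the amplifier would add: the linear leak `g_leak (V − E)`,
the holding-current baseline, capacitive transients at step edges
(amplitude ΔV/Rs, decay τ = Rs·Cm), and white Gaussian noise (default
5 pA). It also emits the averaged −5 mV template and, on request, P/−5
sub-sweeps.

Drugs are multiplicative ḡ suppression only (`drug_condition()`): 20 mM
TEA mainly removes the slow (and part of the residual) component, 5 mM
4-AP mainly the fast. The published constraints are population-level peak
ratios at +40 mV (53.0% under TEA, 76.1% under 4-AP, relative to untreated
cells), not per-component block fractions; `calibrate_drug_factors()`
scales a base factor set along `1 − λ(1 − f₀)` until the noiseless peak
ratio matches the target, and the factors are configuration, not truth
claims. The acceptance test then verifies the ratios on independent
synthetic populations (120 cells per condition, chosen so the Monte-Carlo
standard error of the ratio, ≈ 4%, sits well inside the published bands).

What the generator does **not** emulate — and hence what a green test does
not establish: series-resistance and capacitance *compensation* dynamics,
voltage-dependent (state-dependent) drug unblock, 1/f or line noise,
space-clamp error, and any kinetic effect of drugs. Parameter-recovery
results certify the analysis chain against the model's own world, not
against biology.

## Known limitations of the printed parameter sets

Two features of the published tables, implemented here exactly as printed,
have large dynamical consequences. Both are exposed through the public
constructors (`tau_spec()`, `gating_spec()`, `markov_nat_spec()`), so
alternative readings can be swapped in without touching package code.

1. **Slow/residual inactivation time constants.** The double-sigmoid
   constants for the slow and residual h-gates evaluate to ≈ 64.5 ms
   across the entire physiological range (the B·E product term is
   numerically zero there). This is inconsistent with the multi-second
   inactivation and recovery time courses the protocols were designed to
   measure — the 0–8 s duration grids resolve a 64-ms process only in
   their first point — and strongly suggests a garbled table row.
   The package implements the printed values; the recovered recovery
   τ (64.5 ms) is self-consistent with the model, not with the
   experimental time courses.

2. **The Markov NaT window.** The printed rates leave the open state with
   a large steady-state occupancy (O_ss ≈ 0.4) between −45 and −25 mV:
   the O→I rate is only ≈ 0.06 ms⁻¹ there while I→C recovery (≈ 0.014
   ms⁻¹) persists, so the "transient" channel behaves as a strong
   persistent current in the subthreshold-depolarized range. Combined
   with NaP this creates a stable depolarized equilibrium near −24 mV:
   every suprathreshold current step elicits exactly one spike followed
   by a plateau, so every model's and hybrid's F–I curve saturates at one
   spike per 500-ms step. Three consequences, all verified and documented
   in the acceptance suite and decisions ledger:
   * the headline qualitative result — postinhibitory rebound in the
     proestrous but not the diestrous model — **does** reproduce;
   * rebound also appears for the single HCN swap (the ≈ −19 pA of
     proestrous HCN tail current at release suffices to trigger the
     regenerative window), so the "all-three-inward-currents-required"
     hybrid pattern does not reproduce as printed;
   * swap-suite F–I orderings hold only degenerately (ties), and the
     proestrous-K rheobase ties rather than exceeds the diestrous one.

Changing the GHK prefactor, the NaT open-state exponent (O¹ instead of
O³), or the fast-K weights does not repair these; the slow-inactivation
sign alternative (flipping D in the h-tau double sigmoids, which restores
multi-second inactivation) was evaluated and does not remove the plateau
either. The package therefore ships the printed world and reports it
honestly.

Other scoped-out items: temperature (Q10) scaling, stochastic channel
gating, multi-compartment morphology, amplifier realism, and the
experimental group-comparison statistics.
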