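---
title: "Transient kinetics of ligand binding: models, fitting, and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient kinetics of ligand binding: models, fitting, and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopflow)
```

## The scientific problem

Many enzymes gate their active sites with mobile loops. For a
(βα)~8~-barrel cyclase whose β1α1 loop closes over the substrate, the
kinetic questions are: does the loop close before or after the ligand binds
(conformational selection vs induced fit), how fast does it open and close,
whether the closing step also stabilises the complex of the two reaction
products, and whether any of these motions — rather than the chemistry —
limit catalytic turnover. None of these questions can be answered from
equilibrium measurements alone; they require transient kinetics: stopped-flow
fluorescence of a binding reporter, multiple- and single-turnover progress
curves, and equilibrium titrations interpreted against an explicit
mass-action model.

`stopflow` implements that entire analysis chain as composable, tested
pieces, together with a synthetic-data generator that emulates each
experiment with known ground truth, so every fitting stage can be validated
by recovery rather than by eye.

## Kinetic schemes

A scheme is a set of species carrying conserved moieties (enzyme `E`,
substrate `S`, products `I` and `A`) connected by reversible mass-action
reactions. Four built-ins cover the models used throughout:

* **ONE_STEP** (two-state binding): `E + S ⇌ ES`, rates `k1` (1/(µM·s)) and
  `km1` (1/s). The pseudo-first-order relaxation rate is
  `kobs = k1·[S] + km1` — *linear* in ligand.
* **INDUCED_FIT**: `E + S ⇌ ES ⇌ ES_c`; binding first, then the
  loop-closing isomerisation `kconf`/`kmconf`. In the rapid-equilibrium
  limit the slow relaxation is the *hyperbola*
  `kobs = kmconf + kconf·[S]/(KD1 + [S])`, with `KD1 = km1/k1`.
* **CONF_SELECTION**: `E ⇌ E_c`, `E_c + S ⇌ ES_c`; the conformational step
  precedes binding. Its `kobs`–concentration profile is also nonlinear; the
  package deliberately never claims to distinguish it from induced fit on
  `kobs` data alone (that requires enzyme-excess vs ligand-excess
  asymmetry experiments that are out of scope).
* **TERNARY**: both products bind independently to the free enzyme and to
  the opposite binary complex (`k2`/`km2` for `I`, `k3`/`km3` for `A`,
  shared between the apo and binary routes — the simplest model consistent
  with independent binding), and the ternary complex is stabilised by a
  conformational step `EIA ⇌ EIA_c` (`k4`/`km4`). Sharing the binding
  constants enforces thermodynamic cycle closure exactly. An `untie`
  option (`tie_binding = FALSE`) relaxes the sharing, since binding to the
  apo enzyme and to a binary complex could in principle differ.

Internal units are µM and s (bimolecular constants in 1/(µM·s)); reported
specificity constants are converted to 1/(M·s). Working in µM keeps the
rate-constant magnitudes within a few orders of magnitude of one another,
which conditions the fits far better than SI molar units would.

Two structural choices were genuinely open and are worth recording. The
conformational step of the induced-fit scheme is placed *after* binding
(on the `ES ⇌ ES_c` arrow), which is what makes `KD1 = km1/k1` the
pre-equilibrium constant appearing in the hyperbolic `kobs` expression.
And the closed ternary complex `EIA_c` does not exchange ligands directly;
ligands enter and leave only through the open state.

## Integration and equilibrium

`integrate_scheme()` integrates the mass-action ODEs with `deSolve::lsoda`
(stiff-capable, adaptive), relative tolerance `1e-8` and absolute tolerance
`1e-12` µM by default. Conserved totals are monitored at every output time;
drift beyond `1e-7` relative raises a warning (or an error/penalty inside
the fitters). When every free-ligand species is in at least 10-fold excess
over total enzyme — the pseudo-first-order (PFO) regime — the enzyme-species
subsystem is linear and is solved *exactly* by eigendecomposition instead
(`method = "auto"` switches automatically). Below 10-fold excess the full
ODE is mandatory and the PFO shortcuts do not engage. A `clamp` argument
holds chosen species constant during numerical integration, which is the
PFO approximation itself and is how the analytic-solution cross-checks are
run.

`equilibrium_state()` solves mass-action equilibrium by parametrising the
equilibrium manifold (`Nᵀ log c = log Keq`) with the conservation moieties
and running a damped Newton iteration on the moiety potentials. The
Jacobian `Mᵀ diag(c) M` is symmetric positive definite, so the iteration is
robust; rate sets violating detailed balance around a cycle are rejected
with an error rather than silently averaged.

## Dead time and the "obscured" criterion

A stopped-flow instrument records nothing during its dead time (~2.0 ms
here; `t_dead` default 0.002 s). Simulation truncates the output at
`t ≥ t_dead` without shifting the time origin, and fitting treats the first
recorded point as `t = t_dead` — the standard stopped-flow convention. A
transient is flagged *dead-time obscured* when ≥ 86% of its total signal
change occurs before `t_dead`; 86% is `1 − e^(−2)`, the amplitude a
`kobs = 1000`/s exponential loses in 2 ms. The threshold is configurable
(`obscured_frac`). The same arithmetic, read backwards, turns an obscured
association at 1 mM ligand into the lower bound
`kon ≥ 1000/s / 1 mM = 10^6 1/(M·s)`.

## Exponential fitting and mechanism discrimination

Transients are fit to `y = Σ Amp_i·exp(−kobs_i·t) + c` (1 or 2 phases) by
Levenberg–Marquardt with a log-spaced multistart on the rates (5 starts by
default); at each rate start the amplitudes and offset are solved exactly
by linear least squares, which makes the multistart cheap and reliable.
Two-phase results are reported fast phase first. Phase count is chosen by
AICc, with a fallback to one phase when the two-phase fit is degenerate
(either amplitude below 3× the residual noise, or rates within 10% of each
other).

All AICc values use the least-squares convention in which `K` counts the
mean-function parameters plus one for the residual variance, and the
small-sample correction term `2K(K+1)/(n−K−1)` (infinite when undefined,
i.e. when `n ≤ K+1`, in which case parsimony wins unless the larger model
halves the residual sum of squares). Model pairs within `|ΔAICc| < 2` are
reported as ambiguous/indistinguishable.

Secondary plots (`kobs` vs concentration) are fit as a line (slope `k1`,
intercept `km1`) or as the rapid-equilibrium hyperbola
(`KD1`, `kconf`, `kmconf`), weighted by `1/se²` when standard errors are
supplied. A hyperbola whose fitted `KD1` exceeds 10× the largest sampled
concentration is flagged unidentifiable — its curvature is not constrained
by the data — and such a "win" over the line is downgraded to ambiguous:
an unconstrained hyperbola degenerating to a line is evidence *for* the
line, not against it. `classify_mechanism()` defaults to the AICc
comparison; an extra-sum-of-squares F-test (`method = "ftest"`,
`alpha = 0.05`) is provided for parity with common stopped-flow practice.

The hyperbolic `kobs` form is the rapid-equilibrium approximation; it
agrees with the exact slow eigenvalue of the linearised two-step system to
within 2% only when binding relaxes at least ~50× faster than the
conformational step (`k1·S + km1 ≥ 50·(kconf + kmconf)`). The exact
two-eigenvalue form (`relaxation_rates_pfo()`) is available whenever that
regime is in doubt.

## Global fitting

`global_fit()` fits shared rate constants to a multi-trace dataset by
direct numerical integration of the scheme, exactly as dedicated
global-analysis programs do. The problem is *separable*: for any candidate
rate set, the per-trace baseline offsets and the species response
coefficients enter the signal linearly and are solved exactly by linear
least squares inside every objective evaluation, so the nonlinear search
runs only over the rate constants. Rates are optimised in log space (which
enforces positivity and equalises scales) inside generous physical box
bounds (`1e-6`–`1e6` in µM/s units, spanning beyond the diffusion limit),
from five seeded log-uniform starting points; the best sum of squares wins,
making the result reproducible for a given seed.

Response coefficients are **shared across traces by default**
(`share_responses = TRUE`; offsets stay per-trace). One dataset recorded on
one instrument with one fluorophore has one response per species, and this
choice is what keeps the conformational-step constants identifiable when
the binding steps themselves relax inside the dead time: with fully
per-trace responses the 16-trace product-binding design admits parameter
sets with 20-fold different `km4` at indistinguishable residuals. The fully
per-trace mode remains available (`share_responses = FALSE`).

Uncertainty comes from the profiled Gauss–Newton covariance (delta method
back to the natural scale) and, preferably, from a residual-resampling
bootstrap (`bootstrap_ci()`, percentile intervals, ≥ 100 resamples,
seeded). Parameters whose standard error exceeds 10× the estimate are
flagged *structurally unidentifiable* rather than printed with fake
precision — the expected fate of binary-complex association rates that are
complete within the dead time, for which the data support only a lower
bound while their ratios (the equilibrium constants) stay well determined.
`compare_models()` discriminates schemes on the same dataset by ΔAICc with
the same indistinguishability threshold of 2.

## Steady-state and single-turnover analysis

Multiple-turnover progress curves (absorbance at 300 nm; the
substrate-product absorptivity difference is 5637 1/(M·cm)) show a linear
steady-state phase preceded by an exponential burst that is a mixing
artifact — it appears identically in control curves without the second
substrate and is therefore excluded, not interpreted. The exclusion rule is
fitted, not a fixed time cut: the curve is fit to
`burst·exp(−kb·t) + m·t + d`, the burst window ends where the exponential
has decayed to < 5% of its amplitude (`t = log(20)/kb`), and the steady
slope is refit linearly from there to 20% substrate depletion. Velocities
are `v = |slope|/(path·Δε)`; the Michaelis–Menten fit
(`v = kcat·E_tot·S/(KM+S)`) is weighted by replicate SEMs when present
(weighted is the default, matching how mean ± SEM data are normally fit).
The specificity constant `kcat/KM` is always *derived*, with relative
errors added in quadrature — never fitted as an independent parameter.
When no turnover is detectable, the velocity detection limit gives the
bound `kcat < v_detect/E_tot`; `v_detect` is a configuration input, implied
by, but never stated alongside, published bounds.

Single-turnover curves (enzyme ≥ 2× substrate, so each substrate molecule
reacts once and product release cannot contribute) are fit to a single
exponential. `diagnose_rate_limiting()` compares the mean single-turnover
`kobs` to `kcat`: a ratio within `[1/3, 3]` — "the same order of
magnitude" made operational — means the chemical step limits turnover; a
single-turnover rate more than 3× faster than `kcat` indicts product
release or another post-chemistry step.

## Equilibrium titrations and ternary synergy

Titration preprocessing applies, at most once each, the dilution
correction `F·(V0+V_added)/V0` and subtraction of the titrated ligand's
intrinsic fluorescence. The default isotherm is the hyperbola
`F = F0 + ΔF_max·[L]/(KD_app + [L])` in *total* ligand — kept as the
default for parity with how such data are usually reported — but when the
protein concentration exceeds `KD_app/5` the free-ligand depletion biases
it, and the quadratic (exact two-component) form is selected automatically.

The TERNARY scheme predicts apparent affinities without new fitting:
`predict_apparent_kd()` scans exact equilibria over ligand concentration at
trace enzyme and returns the half-saturation point of total bound ligand.
At saturating co-ligand the closed form is `KD_intrinsic/(1 + K4)` with
`K4 = k4/km4`: loop closure behind the second binding event is precisely
what makes the products bind synergistically. `synergy()` reports the
measured `KD_binary/KD_ternary` ratio with propagated errors, plus the
amplitude comparison (ternary formation produces the larger fluorescence
change when it drives the conformational transition).

## The synthetic-data generator

Because the generator defines the study conditions for every recovery and
power test, its defaults are fixed once and mirror the printed experimental
designs:

* binding transients: 0.1 µM enzyme, ligand series 0.5–40 µM, dead time
  2 ms;
* product binding: 16 traces — limiting enzyme (0.05 µM) or a pre-formed
  binary complex mixed with 100–250 µM `I`, 250–1000 µM `A`, or both;
  traces are recorded as averages of 5 shots (the standard stopped-flow
  practice of averaging at least five individual shots), so the recorded
  noise is the per-shot σ divided by √5;
* turnover: 0.1 µM enzyme (multiple turnover, substrate 1–40 µM), 20 µM
  enzyme vs 2.5/5/10 µM substrate (single turnover); an optional additive
  mixing-artifact burst, chemistry-independent by construction;
* titrations: 0.2–1 µM protein, exact-equilibrium signals.

Noise is additive i.i.d. Gaussian on the signal, either as a fraction of
the trace amplitude or absolute; seeds are mandatory wherever noise is
drawn, and regeneration under the same truth record is bit-identical. The
generator does **not** emulate photon-shot noise, photobleaching, baseline
drift, flow artifacts beyond the single burst term, or temperature
excursions — so passing recovery tests demonstrate correctness of the
estimators under the stated noise model, not robustness to every
instrumental pathology of real data.

## Numerical choices and problem sizes

Solver tolerances are `rtol 1e-8` / `atol 1e-12` µM; the equilibrium Newton
iteration runs to `1e-12` relative on the conservation equations;
eigendecomposition solutions whose conservation drift exceeds `1e-6` are
rejected inside the optimiser (returning penalty residuals) rather than
trusted. Exponential and isotherm fits use 5-point multistarts with
linear-subproblem initialisation. The test suite runs its simulation
studies at sizes chosen to make the statistical assertions meaningful while
keeping a full run comfortable on a laptop: 100 replicates per class for
the mechanism-discrimination power study, 30 seeds for phase-count
selection, one 16-trace dataset plus 20 replicate datasets × 100 bootstrap
resamples for the global-fit recovery and coverage study, and 200
replicates for the noise-averaging checks.

## Known limitations

* Induced fit and conformational selection are not distinguishable from
  `kobs`-vs-concentration data alone, and the package refuses to pretend
  otherwise; the verdict class is "conformational-step".
* The hyperbolic secondary-plot model is the rapid-equilibrium limit;
  outside that regime use the exact eigenvalue form.
* Binding steps completed within the dead time are reported as flagged
  lower-bounded estimates; their ratios (equilibrium constants) remain
  meaningful.
* Stochastic (Gillespie) simulation, temperature dependence, and
  diffusion-limit corrections are out of scope, as are instrument-vendor
  binary file formats.
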