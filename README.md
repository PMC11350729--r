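# stopflow

Transient kinetics of ligand binding for loop-gated enzymes: mass-action
kinetic schemes, stopped-flow transient fitting, mechanism discrimination,
DynaFit-style global fitting, steady-state and single-turnover analysis,
equilibrium titrations, and a fully seeded synthetic-data generator with
recorded ground truth.

## Who this is for

Enzymologists analysing rapid-mixing (stopped-flow) experiments on enzymes
whose active-site loops open and close during the catalytic cycle — the
motivating system is a (βα)₈-barrel cyclase whose β1α1 loop closes over the
substrate, observed through a fluorescent unnatural amino acid in the active
site. The package answers, with explicit models and honest uncertainty:

* Does ligand binding involve a conformational step (induced fit /
  conformational selection), or is it a simple two-state association?
* What are the microscopic rate constants of binding, loop closure and
  loop opening — including for steps hidden inside the instrument dead time?
* Do the two reaction products bind synergistically through a
  loop-stabilised ternary complex?
* Is chemistry or product release rate-limiting for turnover?

## The models

In the pseudo-first-order regime (ligand in ≥10-fold excess) the observed
relaxation rate encodes the mechanism:

* two-state binding `E + S ⇌ ES`:  `kobs = k1·[S] + k−1` — linear in `[S]`;
* induced fit `E + S ⇌ ES ⇌ ES*` (rapid-equilibrium limit):
  `kobs = k−conf + kconf·[S]/(KD1 + [S])`, `KD1 = k−1/k1` — hyperbolic,
  saturating at `kconf + k−conf`.

The two are discriminated by small-sample AICc (or an F-test). Product
binding is modelled as a five-reaction ternary scheme — each product binds
the apo enzyme and the opposite binary complex with shared constants
(`k2`/`k−2`, `k3`/`k−3`), and a conformational step `EIA ⇌ EIA*`
(`k4`/`k−4`) stabilises the ternary complex — fit globally to 16 traces by
direct numerical integration with per-trace offsets and shared response
coefficients solved by separable linear least squares. Steady-state
turnover uses `v = kcat·E₀·[S]/(KM + [S])` with `kcat/KM` always derived by
Gaussian error propagation; single-turnover decays isolate the chemical
step; a `kobs(ST)/kcat` ratio inside `[1/3, 3]` reads "chemistry
rate-limiting".

See the methods vignette (`vignettes/transient-kinetics.Rmd`) for
assumptions, numerical choices and limitations.

## Worked example

Simulate an induced-fit binding series (0.5–40 µM ligand against 0.1 µM
labelled enzyme, 2 ms dead time, 0.5% noise), fit each transient, and
classify the mechanism from the concentration dependence of `kobs`:

```r
library(stopflow)
library(dplyr)

truth <- rate_params(k1 = 10, km1 = 100, kconf = 40, kmconf = 2)
ds <- gen_transient_series("INDUCED_FIT", truth,
                           concs = c(0.5, 1, 2, 5, 10, 20, 40),
                           responses = c(ES = -0.05, ES_c = -1),
                           sigma = 0.005, seed = 42)

pts <- bind_rows(lapply(ds, function(tr) {
  sel <- select_n_phases(tr)            # 1 vs 2 exponentials by AICc
  k <- sel$fit$coef
  i <- which.max(abs(k$estimate[grepl("^Amp", k$term)]))
  tibble(conc = attr(tr, "conc0")[["S"]],
         kobs = k$estimate[k$term == paste0("kobs_", i)],
         se   = k$se[k$term == paste0("kobs_", i)])
}))

fit_secondary_plot(pts, "hyperbolic")
#> <secondary_fit> hyperbolic, AICc = 42.5601
#> # A tibble: 3 x 3
#>   term   estimate    se
#>   <chr>     <dbl> <dbl>
#> 1 KD1       14.6  1.07
#> 2 kconf     44.0  1.58
#> 3 kmconf     1.44 0.109

classify_mechanism(pts)
#> <mechanism_verdict> conformational-step (delta AICc linear - hyperbolic = 25.61)
```

The fit recovers the conformational rates (`kconf` 44.0 vs 40 true,
saturation near `kconf + kmconf`) and calls the mechanism correctly; `KD1`
comes out somewhat above its true 10 µM because the hyperbola is the
rapid-equilibrium approximation to the exact slow eigenvalue — the bias
disappears in the regime where binding relaxes ≫ faster than the
conformational step (see the vignette).

Steady-state arithmetic works the same way on real numbers. For the
wild-type row of the bundled steady-state table (`kcat = 2.4 ± 0.2` 1/s,
`KM = 4.5 ± 0.5` µM):

```r
propagate_kcat_over_km(2.4, 0.2, 4.5, 0.5)
#> $value
#> [1] 533333.3        # 5.3e5 1/(M s) at 2 significant digits
#> $se
#> [1] 74074.07        # +/- 0.7e5
```

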