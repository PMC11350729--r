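# Synthetic dataset generators with recorded ground truth. These stand in for
# undeposited instrument traces: every generator simulates the stated kinetic
# scheme, truncates the observation at the instrument dead time, adds i.i.d.
# Gaussian noise on the signal, and attaches an `sf_truth` provenance record
# so recovery tests can compare estimates against the generating parameters.

new_truth <- function(scheme_id, params, responses = NULL, c0 = NULL,
                      sigma = NULL, seed = NULL, design = NULL, artifact = NULL) {
  structure(list(scheme_id = scheme_id, params = params, responses = responses,
                 c0 = c0, sigma = sigma, seed = seed, design = design,
                 artifact = artifact), class = "sf_truth")
}

#' @export
print.sf_truth <- function(x, ...) {
  cat("<sf_truth> scheme ", x$scheme_id, ", seed ", x$seed %||% NA,
      ", sigma ", signif(x$sigma %||% NA, 3), "\n", sep = "")
  invisible(x)
}

# averaging n_avg shots scales the per-point noise by 1/sqrt(n_avg)
add_noise <- function(x, sigma, n_avg = 1) {
  if (sigma <= 0) return(x)
  x + stats::rnorm(length(x), sd = sigma / sqrt(n_avg))
}

#' Generate a pseudo-first-order binding transient series
#'
#' Simulates stopped-flow fluorescence transients for a binding scheme at a
#' series of ligand concentrations (the canonical design mixes 0.1 uM
#' labelled enzyme with 0.5-40 uM ligand), truncates at the dead time and
#' adds Gaussian noise. `sigma` is interpreted as a fraction of each trace's
#' noiseless amplitude when `sigma_mode = "fraction"` (default), or as an
#' absolute signal sd.
#'
#' @param scheme_id `"ONE_STEP"`, `"INDUCED_FIT"` or `"CONF_SELECTION"`.
#' @param params True rate constants.
#' @param concs Ligand concentrations (uM).
#' @param E0 Enzyme concentration (uM, default 0.1).
#' @param responses Named response coefficients (signal per uM); default is a
#'   fluorescence quench of -1 per uM of closed (or bound) complex.
#' @param c0 Baseline signal (default 1).
#' @param t_dead Dead time (s, default 0.002).
#' @param sigma Noise level (default 0.005 of the amplitude).
#' @param sigma_mode `"fraction"` or `"absolute"`.
#' @param n_avg Number of averaged shots (noise scales by `1/sqrt(n_avg)`).
#' @param n_points Points per trace.
#' @param t_end End time (s); default adapts to the slowest relaxation rate.
#' @param seed Integer seed (mandatory when `sigma > 0`).
#' @param engine Integration engine passed to [integrate_scheme()].
#' @return An `sf_traceset`; `attr(x, "truth")` holds the `sf_truth` record.
#' @export
gen_transient_series <- function(scheme_id, params,
                                 concs = c(0.5, 1, 2, 5, 10, 20, 40),
                                 E0 = 0.1, responses = NULL, c0 = 1,
                                 t_dead = 0.002, sigma = 0.005,
                                 sigma_mode = c("fraction", "absolute"),
                                 n_avg = 1, n_points = 200, t_end = NULL,
                                 seed = 1, engine = "auto") {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(all(concs > 0))
  scheme <- build_scheme(scheme_id)
  if (is.null(responses)) {
    cplx <- scheme$species$name[scheme$species$role == "complex"]
    responses <- stats::setNames(rep(-1, length(cplx)), cplx)
    if (scheme_id != "ONE_STEP") {
      # the open encounter complex reports weakly; the closed state dominates
      responses[!grepl("_c$", names(responses))] <- -0.25
    }
  }
  traces <- withr::with_seed(seed, lapply(concs, function(L) {
    rates <- relaxation_rates_pfo(
      if (toupper(scheme_id) == "ONE_STEP") "ONE_STEP" else toupper(scheme_id),
      params, L)
    te <- t_end %||% (5 / min(rates))
    tt <- seq(0, te, length.out = n_points + 1)
    init <- stats::setNames(c(E0, L), c("E", "S"))
    traj <- integrate_scheme(scheme, params, init, tt, method = engine)
    tr <- project_observable(traj, responses, c0 = c0, t_dead = t_dead)
    amp <- abs(diff(range(tr$signal)))
    sd_abs <- if (sigma_mode == "fraction") sigma * amp else sigma
    noisy <- add_noise(tr$signal, sd_abs, n_avg)
    new_trace(tr$time, noisy, conc0 = init, t_dead = t_dead,
              observable = "fluorescence", sigma = sd_abs / sqrt(n_avg),
              mix = paste0("E ", E0, " uM + S ", L, " uM"),
              obscured = attr(tr, "obscured"),
              pre_dead_fraction = attr(tr, "pre_dead_fraction"))
  }))
  out <- trace_set(traces)
  attr(out, "truth") <- new_truth(toupper(scheme_id), params, responses, c0,
                                  sigma, seed,
                                  design = list(concs = concs, E0 = E0,
                                                t_dead = t_dead, n_avg = n_avg))
  out
}

#' Generate the 16-trace ternary product-binding dataset
#'
#' Emulates the canonical product-binding design: limiting labelled enzyme
#' (or a preformed binary complex) mixed with an excess of ImGP-like ligand I
#' (100-250 uM), AICAR-like ligand A (250-1000 uM), or both. Sixteen traces:
#' 3x enzyme + I, 3x enzyme + A, 4x enzyme + both, 3x preformed EI + A and 3x
#' preformed EA + I. Binary-complex association is typically complete within
#' the dead time; the observed relaxation reports on the conformational
#' (loop-closing) step that stabilises the ternary complex.
#'
#' @param params True TERNARY rate constants (`k2`, `km2`, `k3`, `km3`,
#'   `k4`, `km4`).
#' @param E0 Enzyme concentration (uM, default 0.05).
#' @param responses Response coefficients; the default quenches mostly on the
#'   closed ternary complex.
#' @param sigma Per-shot noise as a fraction of the dataset's largest
#'   amplitude (default 0; use 0.01 for the 1%-noise condition).
#' @param n_avg Number of averaged shots per recorded trace (default 5, the
#'   standard stopped-flow practice of averaging at least five individual
#'   shots); the recorded noise is `sigma/sqrt(n_avg)`.
#' @param t_end,n_points,c0,t_dead,seed As in [gen_transient_series()].
#' @return An `sf_traceset` of 16 traces with an `sf_truth` attribute.
#' @export
gen_ternary_dataset <- function(params, E0 = 0.05,
                                responses = c(EI = -0.25, EA = -0.2,
                                              EIA = -0.35, EIA_c = -1),
                                sigma = 0, n_avg = 5, c0 = 1, t_dead = 0.002,
                                t_end = 0.12, n_points = 120, seed = 1) {
  scheme <- build_scheme("TERNARY")
  I_set <- c(100, 175, 250)
  A_set <- c(250, 500, 1000)
  mixes <- list()
  for (I in I_set) mixes <- c(mixes, list(list(E = E0, I = I, A = 0, pre = "none")))
  for (A in A_set) mixes <- c(mixes, list(list(E = E0, I = 0, A = A, pre = "none")))
  for (I in c(100, 250)) for (A in c(250, 1000)) {
    mixes <- c(mixes, list(list(E = E0, I = I, A = A, pre = "none")))
  }
  for (A in A_set) mixes <- c(mixes, list(list(E = E0, I = 400, A = A, pre = "EI")))
  for (I in I_set) mixes <- c(mixes, list(list(E = E0, I = I, A = 1250, pre = "EA")))
  stopifnot(length(mixes) == 16L)

  tt <- seq(0, t_end, length.out = n_points + 1)
  inits <- lapply(mixes, function(mx) {
    if (mx$pre == "none") {
      c(E = mx$E, I = mx$I, A = mx$A)
    } else {
      # pre-equilibrate the binary complex, then add the second ligand at t=0
      pre_lig <- if (mx$pre == "EI") c(E = mx$E, I = mx$I) else c(E = mx$E, A = mx$A)
      eq <- equilibrium_state(scheme, params, pre_lig)
      if (mx$pre == "EI") eq[["A"]] <- mx$A else eq[["I"]] <- mx$I
      eq
    }
  })
  noiseless <- lapply(inits, function(init) {
    traj <- integrate_scheme(scheme, params, init, tt, method = "auto")
    project_observable(traj, responses, c0 = c0, t_dead = t_dead)
  })
  max_amp <- max(vapply(noiseless, function(tr) abs(diff(range(tr$signal))),
                        numeric(1)))
  sd_abs <- sigma * max_amp / sqrt(n_avg)
  traces <- withr::with_seed(seed, lapply(seq_along(noiseless), function(i) {
    tr <- noiseless[[i]]; mx <- mixes[[i]]
    new_trace(tr$time, add_noise(tr$signal, sd_abs),
              conc0 = inits[[i]], t_dead = t_dead,
              observable = "fluorescence", sigma = sd_abs,
              mix = if (mx$pre == "none")
                sprintf("E + I:%g A:%g", mx$I, mx$A) else
                sprintf("%s + %s", mx$pre, if (mx$pre == "EI") paste0("A:", mx$A)
                        else paste0("I:", mx$I)),
              obscured = attr(tr, "obscured"),
              pre_dead_fraction = attr(tr, "pre_dead_fraction"))
  }))
  out <- trace_set(traces)
  attr(out, "truth") <- new_truth("TERNARY", params, responses, c0, sd_abs, seed,
                                  design = list(E0 = E0, I = I_set, A = A_set,
                                                t_dead = t_dead, n_avg = n_avg))
  out
}

#' Generate enzyme progress curves
#'
#' Simulates a minimal full catalytic cycle — reversible substrate binding
#' (`kon`/`koff`), irreversible chemistry (`kchem`) and irreversible product
#' release (`krel`) — by full numerical integration (no pseudo-first-order
#' shortcut), and converts remaining substrate to an A300-style absorbance
#' (substrate absorbs `delta_eps` more than product, per uM path-normalised).
#' Modes:
#'
#' * `"multiple_turnover"`: catalytic enzyme (default 0.1 uM) with excess
#'   substrate; optionally adds an additive mixing-artifact burst
#'   `burst_amp * exp(-burst_rate * t)` that carries no chemistry.
#' * `"single_turnover"`: excess enzyme (default 20 uM) over substrate; the
#'   decay rate reports the chemistry step, not product release.
#' * `"control"`: chemistry switched off (no ammonia); only the burst
#'   artifact and noise remain.
#'
#' @param params Named truth constants `kon` (1/(uM s)), `koff`, `kchem`,
#'   `krel` (1/s).
#' @param S0_list Substrate concentrations (uM).
#' @param mode `"multiple_turnover"`, `"single_turnover"` or `"control"`.
#' @param E0 Enzyme concentration (uM); defaults 0.1 (MT/control), 20 (ST).
#' @param burst_amp,burst_rate Mixing-artifact burst (A units, 1/s); the
#'   burst is additive and independent of the chemistry.
#' @param sigma Absolute noise sd in A units (default 2e-4).
#' @param delta_eps Substrate-product absorptivity difference
#'   (A per uM per cm, default 0.005637).
#' @param t_end,n_points,seed Simulation grid and noise seed.
#' @return A list of `sf_progress` curves: tibbles (`time`, `absorbance`)
#'   with metadata attributes, and an `sf_truth` attribute on the list.
#' @export
gen_progress_curves <- function(params, S0_list, mode = c("multiple_turnover",
                                                          "single_turnover",
                                                          "control"),
                                E0 = NULL, burst_amp = 0, burst_rate = 30,
                                sigma = 2e-4, delta_eps = 0.005637,
                                t_end = NULL, n_points = 400, seed = 1) {
  mode <- match.arg(mode)
  E0 <- E0 %||% if (mode == "single_turnover") 20 else 0.1
  if (mode == "single_turnover" && any(E0 < 2 * S0_list)) {
    stop("single turnover requires enzyme at >= 2x the substrate", call. = FALSE)
  }
  scheme <- turnover_scheme()
  p <- params
  if (mode == "control") p[["kchem"]] <- 0
  curves <- withr::with_seed(seed, lapply(S0_list, function(S0) {
    te <- t_end %||% default_progress_tend(p, E0, S0, mode)
    tt <- seq(0, te, length.out = n_points + 1)
    traj <- integrate_scheme(scheme, p, c(E = E0, S = S0), tt, method = "ode")
    A <- delta_eps * (traj$S + traj$ES) +
      if (burst_amp != 0) burst_amp * exp(-burst_rate * tt) else 0
    A <- add_noise(A, sigma)
    x <- tibble::tibble(time = tt, absorbance = A)
    class(x) <- c("sf_progress", class(x))
    attr(x, "E_tot") <- E0
    attr(x, "S0") <- S0
    attr(x, "mode") <- mode
    attr(x, "ammonia") <- mode != "control"
    attr(x, "delta_eps") <- delta_eps
    attr(x, "sigma") <- sigma
    x
  }))
  attr(curves, "truth") <- new_truth("TURNOVER", params, sigma = sigma,
                                     seed = seed,
                                     design = list(E0 = E0, S0 = S0_list,
                                                   mode = mode),
                                     artifact = list(burst_amp = burst_amp,
                                                     burst_rate = burst_rate))
  curves
}

turnover_scheme <- function() {
  species <- tibble::tibble(
    name = c("E", "S", "ES", "EP", "P"),
    role = c("enzyme-state", "ligand", "complex", "complex", "ligand"),
    E = c(1L, 0L, 1L, 1L, 0L),
    S = c(0L, 1L, 1L, 1L, 1L))
  reactions <- tibble::tibble(
    reactants = list(c("E", "S"), "ES", "EP"),
    products = list("ES", "EP", c("E", "P")),
    kf_name = c("kon", "kchem", "krel"),
    kr_name = c("koff", "", ""))
  build_scheme(species = species, reactions = reactions)
}

default_progress_tend <- function(p, E0, S0, mode) {
  if (mode == "single_turnover") {
    k <- max(p[["kchem"]], 1e-6)
    5 / k
  } else if (p[["kchem"]] > 0) {
    KM <- (p[["koff"]] + p[["kchem"]]) / p[["kon"]]
    vmax <- p[["kchem"]] * p[["krel"]] / (p[["kchem"]] + p[["krel"]]) * E0
    0.3 * S0 / max(vmax * S0 / (KM + S0), 1e-9)   # ~30% depletion
  } else {
    2
  }
}

#' Generate equilibrium titration series
#'
#' Computes equilibrium binding signals on a concentration grid via
#' [equilibrium_state()] — full ligand-depletion physics, no hyperbolic
#' shortcut — and adds Gaussian noise. For the `"TERNARY"` scheme a fixed
#' co-ligand concentration can be supplied to generate ternary-formation
#' designs.
#'
#' @param scheme_id `"ONE_STEP"` (binary binding; `params` need `k1`, `km1`
#'   so that `KD = km1/k1`) or `"TERNARY"`.
#' @param params True rate constants.
#' @param concs Total titrated-ligand concentrations (uM, nondecreasing).
#' @param P0 Protein concentration (uM, default 0.2).
#' @param ligand For TERNARY: `"I"` or `"A"`, the titrated ligand.
#' @param co_conc For TERNARY: fixed total co-ligand concentration (uM).
#' @param F0 Baseline fluorescence; `dF_max` maximal change at saturation
#'   (negative = quench).
#' @param sigma Absolute noise sd (signal units).
#' @param seed Integer seed.
#' @return An `sf_titration` tibble (`conc`, `F`) with metadata attributes
#'   and an `sf_truth` attribute.
#' @export
gen_titration_series <- function(scheme_id, params, concs, P0 = 0.2,
                                 ligand = "I", co_conc = 0, F0 = 1,
                                 dF_max = -0.8, sigma = 0, seed = 1) {
  scheme_id <- toupper(scheme_id)
  scheme <- build_scheme(scheme_id)
  stopifnot(!is.unsorted(concs))
  frac_bound <- vapply(concs, function(L) {
    totals <- if (scheme_id == "ONE_STEP") {
      c(E = P0, S = L)
    } else if (ligand == "I") {
      c(E = P0, I = L, A = co_conc)
    } else {
      c(E = P0, A = L, I = co_conc)
    }
    eq <- equilibrium_state(scheme, params, totals)
    bound <- if (scheme_id == "ONE_STEP") eq[["ES"]] else {
      if (ligand == "I") eq[["EI"]] + eq[["EIA"]] + eq[["EIA_c"]]
      else eq[["EA"]] + eq[["EIA"]] + eq[["EIA_c"]]
    }
    bound / P0
  }, numeric(1))
  FF <- withr::with_seed(seed, add_noise(F0 + dF_max * frac_bound, sigma))
  x <- tibble::tibble(conc = as.numeric(concs), F = FF)
  class(x) <- c("sf_titration", class(x))
  attr(x, "P0") <- P0
  attr(x, "ligand") <- if (scheme_id == "ONE_STEP") "S" else ligand
  attr(x, "co_conc") <- co_conc
  attr(x, "sigma") <- sigma
  attr(x, "truth") <- new_truth(scheme_id, params, c0 = F0, sigma = sigma,
                                seed = seed,
                                design = list(concs = concs, P0 = P0,
                                              ligand = ligand,
                                              co_conc = co_conc,
                                              dF_max = dF_max))
  x
}

#' Free ammonia from total ammonium at a given pH
#'
#' Henderson-Hasselbalch free-base fraction:
#' `NH3 = total / (1 + 10^(pKa - pH))`. With the canonical pKa of 9.27 at
#' 25 C, 100 mM total ammonium at pH 8.5 corresponds to about 14.5 mM free
#' NH3 — the nucleophile concentration actually available to the cyclase
#' reaction.
#'
#' @param total_mM Total ammonium (mM), > 0.
#' @param pH,pKa Solution pH and ammonium pKa (defaults 8.5 and 9.27), both
#'   in (0, 14).
#' @return Free NH3 (mM).
#' @examples
#' free_ammonia(100, pH = 8.5)
#' @export
free_ammonia <- function(total_mM, pH = 8.5, pKa = 9.27) {
  if (total_mM <= 0) stop("total ammonium must be > 0", call. = FALSE)
  if (pH <= 0 || pH >= 14 || pKa <= 0 || pKa >= 14) {
    stop("pH and pKa must lie in (0, 14)", call. = FALSE)
  }
  total_mM / (1 + 10^(pKa - pH))
}
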