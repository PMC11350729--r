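#' Integrate a kinetic scheme
#'
#' Numerically integrates the mass-action ODE system of a [build_scheme()]
#' scheme with a stiff-capable adaptive solver (deSolve's `lsoda`). Internal
#' units are uM for concentrations and s for time. Conserved moiety totals are
#' checked against the initial totals at every output time.
#'
#' When every free-ligand species is held effectively constant — the
#' pseudo-first-order (PFO) regime, i.e. the ligand exceeds the total enzyme
#' by at least `pfo_ratio` — `method = "auto"` switches to an exact solution
#' of the linear(ised) system by eigendecomposition, which is both faster and
#' free of truncation error. `method = "ode"` forces numerical integration,
#' `method = "pfo"` forces the linear path (erroring if the regime does not
#' apply).
#'
#' @param scheme A `kinetic_scheme`.
#' @param params Named rate constants (see [rate_params()]).
#' @param init Named initial concentrations (uM), one per species (missing
#'   species start at 0).
#' @param times Numeric vector of output times (s), starting at 0 or later.
#' @param method `"auto"`, `"ode"` or `"pfo"`.
#' @param rtol,atol Relative / absolute solver tolerances (defaults 1e-8,
#'   1e-12 uM).
#' @param pfo_ratio Ligand/enzyme excess ratio that triggers the linear path
#'   under `"auto"` (default 10).
#' @param clamp Species names whose concentrations are held constant during
#'   integration (the pseudo-first-order approximation applied to the chosen
#'   species). The `"pfo"` method implicitly clamps every free-ligand
#'   species.
#' @return A tibble with column `time` and one concentration column per
#'   species (uM).
#' @examples
#' sc <- build_scheme("ONE_STEP")
#' p <- rate_params(k1 = 0.1, km1 = 1)
#' traj <- integrate_scheme(sc, p, c(E = 0.1, S = 10), seq(0, 2, 0.01))
#' @export
integrate_scheme <- function(scheme, params, init, times,
                             method = c("auto", "ode", "pfo"),
                             rtol = 1e-8, atol = 1e-12, pfo_ratio = 10,
                             clamp = NULL, drift_action = c("warn", "error", "silent")) {
  drift_action <- match.arg(drift_action)
  method <- match.arg(method)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  y0 <- init_vector(scheme, init)
  if (any(y0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (is.null(clamp) && pfo_applicable(scheme, y0, pfo_ratio))
      "pfo" else "ode"
  }
  if (method == "pfo") {
    clamp <- scheme$species$name[scheme$species$role == "ligand"]
    out <- integrate_linear_excess(scheme, params, y0, times)
  } else {
    out <- integrate_ode(scheme, params, y0, times, rtol, atol, clamp)
  }
  check_conservation(scheme, out, y0, clamp = clamp, action = drift_action)
  out
}

init_vector <- function(scheme, init) {
  spn <- scheme$species$name
  y0 <- stats::setNames(numeric(length(spn)), spn)
  if (length(init)) {
    unknown <- setdiff(names(init), spn)
    if (length(unknown)) {
      stop("unknown species in `init`: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    y0[names(init)] <- as.numeric(init)
  }
  y0
}

# ligand excess test: every free-ligand species either absent or in
# >= ratio-fold excess over total enzyme moiety
pfo_applicable <- function(scheme, y0, ratio) {
  M <- scheme$moieties
  if (!"E" %in% colnames(M)) return(FALSE)
  e_tot <- sum(y0 * M[, "E"])
  if (e_tot <= 0) return(FALSE)
  lig <- scheme$species$name[scheme$species$role == "ligand"]
  all(vapply(lig, function(s) y0[[s]] == 0 || y0[[s]] >= ratio * e_tot, logical(1)))
}

integrate_ode <- function(scheme, params, y0, times, rtol, atol, clamp = NULL) {
  kv <- scheme_rate_values(scheme, params)
  topo <- scheme_topology(scheme)
  N <- topo$N; ridx <- topo$ridx; pidx <- topo$pidx
  kf <- kv$kf; kr <- kv$kr
  nr <- length(kf)
  clamp_idx <- match(clamp, scheme$species$name)
  deriv <- function(t, y, parms) {
    v <- numeric(nr)
    for (j in seq_len(nr)) {
      vf <- kf[j] * prod(y[ridx[[j]]])
      vr <- if (kr[j] > 0) kr[j] * prod(y[pidx[[j]]]) else 0
      v[j] <- vf - vr
    }
    dy <- as.vector(N %*% v)
    if (length(clamp_idx)) dy[clamp_idx] <- 0
    list(dy)
  }
  t0 <- times[1]
  tt <- if (t0 > 0) c(0, times) else times
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; last successful time t = ",
         signif(max(sol[, "time"]), 6),
         " — consider tighter tolerances", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  if (t0 > 0) sol <- sol[-1, , drop = FALSE]
  neg <- min(as.matrix(sol[, -1, drop = FALSE]))
  if (neg < -100 * atol - 1e-9 * max(y0)) {
    stop("negative concentration (", signif(neg, 3),
         ") beyond tolerance; the system may be stiff — tighten `atol`",
         call. = FALSE)
  }
  out <- tibble::as_tibble(sol)
  names(out)[1] <- "time"
  out[-1][out[-1] < 0] <- 0
  out
}

# Exact solution when free ligands are constant: enzyme-containing species
# evolve as x' = A x, solved by eigendecomposition.
integrate_linear_excess <- function(scheme, params, y0, times) {
  kv <- scheme_rate_values(scheme, params)
  spn <- scheme$species$name
  lig <- spn[scheme$species$role == "ligand"]
  dyn <- setdiff(spn, lig)
  idx <- stats::setNames(seq_along(dyn), dyn)
  A <- matrix(0, length(dyn), length(dyn), dimnames = list(dyn, dyn))
  for (j in seq_len(nrow(scheme$reactions))) {
    r <- scheme$reactions$reactants[[j]]; p <- scheme$reactions$products[[j]]
    rd <- setdiff(r, lig); pd <- setdiff(p, lig)
    if (length(rd) != 1 || length(pd) != 1) {
      stop("reaction ", j, " is not linear in enzyme species; ",
           "pseudo-first-order path does not apply", call. = FALSE)
    }
    cf <- kv$kf[j] * prod(y0[intersect(r, lig)])   # prod over empty = 1
    cr <- if (kv$kr[j] > 0) kv$kr[j] * prod(y0[intersect(p, lig)]) else 0
    A[idx[rd], idx[rd]] <- A[idx[rd], idx[rd]] - cf
    A[idx[pd], idx[rd]] <- A[idx[pd], idx[rd]] + cf
    if (cr > 0) {
      A[idx[pd], idx[pd]] <- A[idx[pd], idx[pd]] - cr
      A[idx[rd], idx[pd]] <- A[idx[rd], idx[pd]] + cr
    }
  }
  eg <- eigen(A)
  co <- solve(eg$vectors, y0[dyn])
  E <- exp(outer(times, eg$values))        # n_times x n_modes, possibly complex
  # x_i(t) = sum_k V[i, k] co_k e^{lambda_k t}
  X <- Re(E %*% t(eg$vectors * rep(co, each = nrow(eg$vectors))))
  colnames(X) <- dyn
  X[X < 0 & X > -1e-12] <- 0
  out <- tibble::tibble(time = times)
  for (s in spn) {
    out[[s]] <- if (s %in% lig) rep(y0[[s]], length(times)) else X[, s]
  }
  out
}

check_conservation <- function(scheme, traj, y0, tol = 1e-7, clamp = NULL,
                               action = "warn") {
  M <- scheme$moieties
  tot0 <- drop(crossprod(M, y0))
  C <- as.matrix(traj[scheme$species$name])
  tots <- C %*% M
  # a clamped species acts as a buffered reservoir: its moieties are not
  # conserved by construction
  buffered <- colSums(M[clamp, , drop = FALSE] > 0) > 0
  for (m in seq_along(tot0)) {
    if (length(buffered) && buffered[m]) next
    if (tot0[m] > 0) {
      dev <- max(abs(tots[, m] - tot0[m])) / tot0[m]
      if (dev > tol) {
        msg <- paste0("conserved total for moiety ", colnames(M)[m],
                      " drifts by relative ", signif(dev, 3))
        if (action == "error") stop(msg, call. = FALSE)
        if (action == "warn") warning(msg, call. = FALSE)
      }
    }
  }
  invisible(traj)
}

#' Equilibrium state of a reversible scheme
#'
#' Solves for the thermodynamic equilibrium concentrations given totals per
#' conserved moiety. All reactions must be reversible (finite equilibrium).
#' Internally the equilibrium manifold `N' log c = log Keq` is parametrised by
#' the conservation moieties and the totals are matched by a damped Newton
#' iteration on the moiety potentials; for schemes with thermodynamic cycles
#' the reaction constants must satisfy detailed balance (the built-in ternary
#' scheme does so by construction through its shared binding constants).
#'
#' @inheritParams integrate_scheme
#' @param totals Named vector of totals per conserved moiety (uM), e.g.
#'   `c(E = 1, S = 10)`.
#' @param tol Relative tolerance on the conservation equations.
#' @return A named numeric vector of species concentrations (uM).
#' @examples
#' sc <- build_scheme("ONE_STEP")
#' equilibrium_state(sc, rate_params(k1 = 1, km1 = 1), c(E = 1, S = 1))
#' @export
equilibrium_state <- function(scheme, params, totals, tol = 1e-12) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  kv <- scheme_rate_values(scheme, params)
  if (any(kv$kr <= 0)) {
    stop("scheme contains an irreversible reaction; no finite equilibrium",
         call. = FALSE)
  }
  M <- scheme$moieties
  moi <- colnames(M)
  tot <- stats::setNames(numeric(length(moi)), moi)
  tot[names(totals)] <- as.numeric(totals)
  if (any(tot < 0)) stop("totals must be >= 0", call. = FALSE)

  spn <- scheme$species$name
  # species fully absent because a constituent moiety total is zero
  absent_m <- moi[tot == 0]
  alive <- rowSums(M[, absent_m, drop = FALSE]) == 0
  live_m <- moi[tot > 0]
  res <- stats::setNames(numeric(length(spn)), spn)
  if (!any(alive) || length(live_m) == 0) return(res)

  # handle k_f = 0 (no formation): complexes formed solely through such a
  # reaction cannot exist at equilibrium unless formed by another route;
  # treat kf = 0 as Keq = 0 by dropping the species if it becomes unreachable.
  if (any(kv$kf == 0)) {
    # zero-association edge: remove product complexes reachable only that way
    for (j in which(kv$kf == 0)) {
      p <- setdiff(scheme$reactions$products[[j]], spn[!alive])
      other <- vapply(seq_len(nrow(scheme$reactions)), function(jj) {
        jj != j && kv$kf[jj] > 0 && any(p %in% scheme$reactions$products[[jj]])
      }, logical(1))
      if (!any(other)) alive[match(p, spn)] <- FALSE
    }
  }

  Ml <- M[alive, live_m, drop = FALSE]
  topo <- scheme_topology(scheme)
  keep_rx <- vapply(seq_len(nrow(scheme$reactions)), function(j) {
    all(c(scheme$reactions$reactants[[j]], scheme$reactions$products[[j]])
        %in% spn[alive]) && kv$kf[j] > 0
  }, logical(1))
  Nl <- topo$N[alive, keep_rx, drop = FALSE]
  lnK <- log(kv$kf[keep_rx] / kv$kr[keep_rx])
  # particular solution of N' ln c = ln Keq (least squares), consistency check
  if (ncol(Nl) > 0) {
    ls <- qr(t(Nl))
    lnc0 <- qr.coef(ls, lnK)
    lnc0[is.na(lnc0)] <- 0
    resid <- drop(t(Nl) %*% lnc0) - lnK
    if (max(abs(resid)) > 1e-8) {
      stop("rate constants violate detailed balance around a cycle; ",
           "equilibrium is not defined by mass action", call. = FALSE)
    }
  } else {
    lnc0 <- numeric(sum(alive))
  }
  # Newton on moiety potentials alpha: c = exp(lnc0 + Ml alpha),
  # g(alpha) = Ml' c - tot  (Jacobian Ml' diag(c) Ml, SPD)
  tgt <- tot[live_m]
  alpha <- log(pmax(tgt, 1e-300)) - log(pmax(colSums(Ml), 1))  # rough start
  names(alpha) <- live_m
  cfun <- function(a) exp(pmin(lnc0 + drop(Ml %*% a), 700))
  for (it in 1:200) {
    cc <- cfun(alpha)
    g <- drop(crossprod(Ml, cc)) - tgt
    if (max(abs(g) / pmax(tgt, 1e-300)) < tol) break
    J <- crossprod(Ml, Ml * cc)
    step <- tryCatch(solve(J, g), error = function(e) g / pmax(diag(J), 1e-300))
    lam <- 1
    f0 <- sum((g / tgt)^2)
    repeat {
      a_new <- alpha - lam * step
      g_new <- drop(crossprod(Ml, cfun(a_new))) - tgt
      if (sum((g_new / tgt)^2) < f0 || lam < 1e-10) break
      lam <- lam / 2
    }
    alpha <- a_new
  }
  res[spn[alive]] <- cfun(alpha)
  res
}

#' Pseudo-first-order relaxation rates of the built-in binding schemes
#'
#' In the pseudo-first-order regime (ligand in large excess, treated as
#' constant at `L`) the one-step scheme relaxes with a single rate
#' `k1*L + km1`; the induced-fit and conformational-selection schemes relax
#' with the two eigenvalue magnitudes of the linearised 2x2 rate matrix,
#' returned fast-first.
#'
#' @param builtin_id `"ONE_STEP"`, `"INDUCED_FIT"` or `"CONF_SELECTION"`.
#' @param params Named rate constants.
#' @param L Ligand concentration (uM), `>= 0`.
#' @return Numeric vector of relaxation rates (1/s), sorted decreasing.
#' @examples
#' relaxation_rates_pfo("ONE_STEP", rate_params(k1 = 0.1, km1 = 1), L = 10)
#' @export
relaxation_rates_pfo <- function(builtin_id, params, L) {
  builtin_id <- match.arg(toupper(builtin_id),
                          c("ONE_STEP", "INDUCED_FIT", "CONF_SELECTION"))
  if (L < 0) stop("ligand concentration must be >= 0", call. = FALSE)
  p <- function(nm) params[[nm]]
  if (builtin_id == "ONE_STEP") {
    return(p("k1") * L + p("km1"))
  }
  A <- if (builtin_id == "INDUCED_FIT") {
    # states (ES, ES_c); free enzyme eliminated through conservation
    rbind(c(-(p("k1") * L + p("km1") + p("kconf")), -p("k1") * L + p("kmconf")),
          c(p("kconf"), -p("kmconf")))
  } else {
    # states (E_c, ES_c)
    rbind(c(-(p("kconf") + p("kmconf") + p("k1") * L), -p("kconf") + p("km1")),
          c(p("k1") * L, -p("km1")))
  }
  sort(abs(Re(eigen(A, only.values = TRUE)$values)), decreasing = TRUE)
}

#' Hyperbolic concentration dependence of the observed binding rate
#'
#' The rapid-equilibrium induced-fit expression for the slow relaxation rate:
#' `kobs(S) = kmconf + kconf * S / (KD1 + S)`, the saturating form expected
#' when a fast binding pre-equilibrium precedes a conformational step. At
#' `S = 0` it equals `kmconf`; at saturation it approaches `kconf + kmconf`.
#'
#' @param params Named constants containing `kconf`, `kmconf` and either
#'   `KD1` or both `k1` and `km1` (then `KD1 = km1/k1`).
#' @param S Substrate concentration(s), uM, `>= 0`.
#' @return kobs (1/s), vectorised over `S`.
#' @examples
#' kobs_hyperbolic(c(KD1 = 10, kconf = 40, kmconf = 2), S = 10)
#' @export
kobs_hyperbolic <- function(params, S) {
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  KD1 <- if ("KD1" %in% names(params)) params[["KD1"]] else
    params[["km1"]] / params[["k1"]]
  if (KD1 <= 0) stop("KD1 must be > 0", call. = FALSE)
  params[["kmconf"]] + params[["kconf"]] * S / (KD1 + S)
}

#' Project species trajectories onto an instrument observable
#'
#' Computes `signal(t) = c0 + sum_i r_i * [X_i](t)` and truncates the output
#' to `t >= t_dead`, the stopped-flow dead time during which no signal is
#' recorded. A trace whose pre-dead-time signal change exceeds the
#' `obscured_frac` fraction of the total change is flagged as dead-time
#' obscured: at the default 0.86 (= 1 - exp(-2)) a single-exponential process
#' with `kobs = 1000` per s is flagged at the canonical 2.0 ms dead time.
#'
#' @param traj Trajectory tibble from [integrate_scheme()] (must start at
#'   `t = 0` for the obscured-fraction diagnostic to be meaningful).
#' @param responses Named vector of response coefficients (signal per uM).
#' @param c0 Baseline signal.
#' @param t_dead Dead time (s), default 0.002.
#' @param observable `"fluorescence"` or `"absorbance"`.
#' @param obscured_frac Flag threshold on the pre-dead-time amplitude
#'   fraction.
#' @return An `sf_trace` tibble (`time`, `signal`) with metadata attributes;
#'   `attr(x, "obscured")` is `TRUE` when the transient is lost in the dead
#'   time, and `attr(x, "pre_dead_fraction")` gives the fraction lost.
#' @export
project_observable <- function(traj, responses, c0 = 0, t_dead = 0.002,
                               observable = "fluorescence",
                               obscured_frac = 0.86) {
  if (t_dead < 0) stop("t_dead must be >= 0", call. = FALSE)
  unknown <- setdiff(names(responses), names(traj))
  if (length(unknown)) {
    stop("responses name unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  C <- as.matrix(traj[names(responses)])
  sig <- c0 + drop(C %*% as.numeric(responses))
  tt <- traj$time
  total <- sig[length(sig)] - sig[1]
  pre <- if (t_dead <= tt[1]) 0 else {
    s_dead <- stats::approx(tt, sig, xout = t_dead, rule = 2)$y
    if (abs(total) > 0) abs(s_dead - sig[1]) / abs(total) else 0
  }
  keep <- tt >= t_dead
  if (!any(keep)) stop("dead time exceeds the simulated time range", call. = FALSE)
  new_trace(tt[keep], sig[keep], t_dead = t_dead, observable = observable,
            obscured = pre >= obscured_frac, pre_dead_fraction = pre)
}

#' Construct a time-signal trace
#'
#' Light container for a single stopped-flow or spectrophotometer trace: a
#' tibble with `time` (s, strictly increasing) and `signal` columns plus
#' metadata attributes (initial totals, dead time, observable type, noise
#' sigma, mix description).
#'
#' @param time,signal Numeric vectors of equal length; `time` strictly
#'   increasing.
#' @param conc0 Named initial total concentrations (uM).
#' @param t_dead Dead time (s).
#' @param observable `"fluorescence"` or `"absorbance"`.
#' @param sigma Noise standard deviation estimate (signal units).
#' @param mix Free-text mix description.
#' @param ... Further metadata attributes.
#' @return A tibble of class `sf_trace`.
#' @export
new_trace <- function(time, signal, conc0 = NULL, t_dead = 0,
                      observable = "fluorescence", sigma = NA_real_,
                      mix = "", ...) {
  if (length(time) != length(signal)) stop("time/signal length mismatch", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!is.null(conc0) && any(conc0 < 0)) stop("concentrations must be >= 0", call. = FALSE)
  x <- tibble::tibble(time = as.numeric(time), signal = as.numeric(signal))
  class(x) <- c("sf_trace", class(x))
  attr(x, "conc0") <- conc0
  attr(x, "t_dead") <- t_dead
  attr(x, "observable") <- observable
  attr(x, "sigma") <- sigma
  attr(x, "mix") <- mix
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  x
}

#' @export
print.sf_trace <- function(x, ...) {
  cat("<sf_trace> ", nrow(x), " points, t = [", signif(min(x$time), 4), ", ",
      signif(max(x$time), 4), "] s, ", attr(x, "observable") %||% "signal",
      if (isTRUE(attr(x, "obscured"))) " [DEAD-TIME OBSCURED]", "\n", sep = "")
  if (!is.null(attr(x, "conc0"))) {
    cat("  conc0 (uM):", paste(names(attr(x, "conc0")),
                               signif(attr(x, "conc0"), 4),
                               sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
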