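# Global (multi-trace) fitting of kinetic schemes by direct numerical
# integration: shared rate constants across traces, per-trace response
# coefficients and offsets solved exactly by separable linear least squares,
# Levenberg-Marquardt refinement in log-rate space.

#' Bundle traces for a global fit
#'
#' @param ... [new_trace()] objects (or a single list of them).
#' @return A list of traces with class `sf_traceset`.
#' @export
trace_set <- function(...) {
  traces <- list(...)
  if (length(traces) == 1L && is.list(traces[[1]]) && !inherits(traces[[1]], "sf_trace")) {
    traces <- traces[[1]]
  }
  stopifnot(all(vapply(traces, inherits, logical(1), "sf_trace")))
  structure(traces, class = "sf_traceset")
}

#' @export
print.sf_traceset <- function(x, ...) {
  cat("<sf_traceset> ", length(x), " traces\n", sep = "")
  invisible(x)
}

# simulate species trajectories for one trace at its recorded times
simulate_trace_conc <- function(scheme, params, trace, engine, rtol = 1e-8,
                                atol = 1e-12) {
  conc0 <- attr(trace, "conc0")
  integrate_scheme(scheme, params, conc0, trace$time,
                   method = engine, rtol = rtol, atol = atol,
                   drift_action = "silent")
}

# Precompute everything the objective needs for one trace. The linear
# (pseudo-first-order) path reduces each residual evaluation to a small
# eigendecomposition; the ODE path falls back to lsoda.
prep_trace <- function(scheme, trace, engine, response_species) {
  y0 <- init_vector(scheme, attr(trace, "conc0"))
  spn <- scheme$species$name
  lig <- spn[scheme$species$role == "ligand"]
  dyn <- setdiff(spn, lig)
  nr <- nrow(scheme$reactions)
  rd <- pd <- integer(nr); fmul <- rmul <- numeric(nr)
  linear_ok <- TRUE
  for (j in seq_len(nr)) {
    r <- scheme$reactions$reactants[[j]]; p <- scheme$reactions$products[[j]]
    rdy <- setdiff(r, lig); pdy <- setdiff(p, lig)
    if (length(rdy) != 1 || length(pdy) != 1) linear_ok <- FALSE else {
      rd[j] <- match(rdy, dyn); pd[j] <- match(pdy, dyn)
      fmul[j] <- prod(y0[intersect(r, lig)])
      rmul[j] <- prod(y0[intersect(p, lig)])
    }
  }
  M_dyn <- scheme$moieties[dyn, , drop = FALSE]
  cons_m <- which(colnames(M_dyn) %in% c("E"))
  list(y0 = y0, times = trace$time, dyn = dyn,
       resp_idx = match(response_species, dyn),
       rd = rd, pd = pd, fmul = fmul, rmul = rmul,
       linear_ok = linear_ok,
       cons_vec = if (length(cons_m)) M_dyn[, cons_m[1]] else NULL,
       cons_tot = if (length(cons_m)) sum(M_dyn[, cons_m[1]] * y0[dyn]) else NULL)
}

# concentrations of the response species at the trace times, or NULL when the
# solution is numerically untrustworthy (conservation broken)
sim_resp_fast <- function(pr, kf, kr) {
  n <- length(pr$dyn)
  A <- matrix(0, n, n)
  for (j in seq_along(kf)) {
    cf <- kf[j] * pr$fmul[j]
    A[pr$rd[j], pr$rd[j]] <- A[pr$rd[j], pr$rd[j]] - cf
    A[pr$pd[j], pr$rd[j]] <- A[pr$pd[j], pr$rd[j]] + cf
    if (kr[j] > 0) {
      cr <- kr[j] * pr$rmul[j]
      A[pr$pd[j], pr$pd[j]] <- A[pr$pd[j], pr$pd[j]] - cr
      A[pr$rd[j], pr$pd[j]] <- A[pr$rd[j], pr$pd[j]] + cr
    }
  }
  eg <- tryCatch(eigen(A, symmetric = FALSE), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  if (is.complex(eg$values) && all(Im(eg$values) == 0)) {
    eg$values <- Re(eg$values); eg$vectors <- Re(eg$vectors)
  }
  co <- tryCatch(solve(eg$vectors, pr$y0[pr$dyn]), error = function(e) NULL)
  if (is.null(co)) return(NULL)
  E <- exp(outer(pr$times, eg$values))
  X <- E %*% t(eg$vectors * rep(co, each = nrow(eg$vectors)))
  if (is.complex(X)) X <- Re(X)
  if (!all(is.finite(X))) return(NULL)
  if (!is.null(pr$cons_vec) && pr$cons_tot > 0) {
    drift <- max(abs(X %*% pr$cons_vec - pr$cons_tot)) / pr$cons_tot
    if (drift > 1e-6) return(NULL)
  }
  X[, pr$resp_idx, drop = FALSE]
}

#' Global fit of a multi-trace dataset to a kinetic scheme
#'
#' Fits shared rate constants to several traces simultaneously. For each
#' candidate rate set every trace is simulated by direct numerical
#' integration of the scheme (or by the exact pseudo-first-order linear
#' solution when the ligand is in >= 10-fold excess, `engine = "auto"`), and
#' the per-trace baseline offsets and species response coefficients are
#' solved exactly by linear least squares — the separable structure of the
#' problem. The rate constants are refined by Levenberg-Marquardt in log
#' space (enforcing positivity), from `n_starts` log-uniform perturbations of
#' the starting values; the best sum of squares wins, making the result
#' deterministic for a given seed.
#'
#' Parameters whose standard error exceeds 10x their estimate are flagged
#' structurally unidentifiable (typical for association steps completed
#' within the instrument dead time, which the data only bound from below).
#'
#' @param traces A [trace_set()] (>= 2 traces, each with `conc0` metadata).
#' @param scheme A `kinetic_scheme`.
#' @param start Named vector of starting values for all scheme rate
#'   constants.
#' @param free Names of the rate constants to fit (default: all in `start`
#'   that the scheme uses); the rest stay fixed.
#' @param response_species Species with free response coefficients
#'   (default: all complex-role species).
#' @param share_responses Share the species response coefficients across all
#'   traces (default `TRUE`; offsets stay per-trace). One dataset recorded on
#'   one instrument with one fluorophore has one response per species, and
#'   sharing them is what keeps the conformational-step constants
#'   identifiable when the binding steps relax within the dead time. Set
#'   `FALSE` for fully per-trace responses.
#' @param engine `"auto"`, `"ode"` or `"pfo"` (see [integrate_scheme()]).
#' @param weights `"uniform"` (default) or `"sigma"` (per-trace `1/sigma^2`
#'   from the trace metadata).
#' @param n_starts Number of multistart perturbations (default 5).
#' @param seed Integer seed for the multistart perturbations.
#' @param spread Multistart log10 half-width around `start` (default 1).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `global_fit_result`: `coef` tibble (`term`,
#'   `estimate`, `se`, `flagged`), `responses` tibble (per trace), `rss`,
#'   `aicc`, `n_obs`, per-trace `fitted`/`residuals`, and the inputs needed
#'   to refit (used by [bootstrap_ci()]).
#' @export
global_fit <- function(traces, scheme, start, free = NULL,
                       response_species = NULL, share_responses = TRUE,
                       engine = c("auto", "ode", "pfo"),
                       weights = c("uniform", "sigma"),
                       n_starts = 5, seed = 1, spread = 1, maxiter = 100,
                       lower = 1e-6, upper = 1e6) {
  engine <- match.arg(engine)
  weights <- match.arg(weights)
  if (length(traces) < 1) stop("global fit needs at least one trace", call. = FALSE)
  if (length(traces) < 2) {
    warning("global fit on a single trace is usually under-determined; ",
            "expect identifiability flags", call. = FALSE)
  }
  if (is.null(free)) free <- intersect(names(start), scheme$rate_names)
  if (length(free) == 0) stop("at least one free parameter required", call. = FALSE)
  if (any(start[free] <= 0)) {
    stop("free rate constants need positive starting values", call. = FALSE)
  }
  if (is.null(response_species)) {
    response_species <- scheme$species$name[scheme$species$role == "complex"]
  }
  if (engine == "auto") {
    all_pfo <- all(vapply(traces, function(tr) {
      pfo_applicable(scheme, init_vector(scheme, attr(tr, "conc0")), 10)
    }, logical(1)))
    engine <- if (all_pfo) "pfo" else "ode"
  }
  wts <- lapply(traces, function(tr) {
    if (weights == "sigma" && is.finite(attr(tr, "sigma")) && attr(tr, "sigma") > 0) {
      rep(1 / attr(tr, "sigma")^2, nrow(tr))
    } else rep(1, nrow(tr))
  })
  lower <- rep_len(lower, length(free)); upper <- rep_len(upper, length(free))

  preps <- lapply(traces, prep_trace, scheme = scheme, engine = engine,
                  response_species = response_species)
  use_linear <- engine == "pfo" && all(vapply(preps, `[[`, logical(1), "linear_ok"))
  kf_idx <- match(scheme$reactions$kf_name, free)
  kr_idx <- match(scheme$reactions$kr_name, free)
  kv0 <- scheme_rate_values(scheme, start)
  signals <- lapply(traces, `[[`, "signal")
  sw <- lapply(wts, sqrt)

  params_full <- start
  nt <- length(traces)
  nre <- length(response_species)
  rows <- split(seq_len(sum(lengths(signals))),
                rep(seq_len(nt), lengths(signals)))
  sim_all <- function(k) {
    kf <- ifelse(is.na(kf_idx), kv0$kf, k[kf_idx])
    kr <- ifelse(is.na(kr_idx), kv0$kr, k[kr_idx])
    lapply(seq_len(nt), function(i) {
      if (use_linear) {
        sim_resp_fast(preps[[i]], kf, kr)
      } else {
        params_full[free] <- k
        traj <- tryCatch(
          simulate_trace_conc(scheme, params_full, traces[[i]], engine),
          error = function(e) NULL)
        if (is.null(traj)) NULL else as.matrix(traj[response_species])
      }
    })
  }
  # precomputed weighted means for profiling out the per-trace offsets in the
  # shared-response case (indicator columns are orthogonal to weighted-
  # centred regressors)
  wsum <- vapply(seq_len(nt), function(i) sum(wts[[i]]), numeric(1))
  ybar <- vapply(seq_len(nt), function(i)
    sum(wts[[i]] * signals[[i]]) / wsum[i], numeric(1))
  yc_w <- unlist(lapply(seq_len(nt), function(i)
    sw[[i]] * (signals[[i]] - ybar[i])))

  # linear subproblem: offsets always per trace; responses shared or per trace
  solve_linear <- function(Xs) {
    if (share_responses) {
      n_all <- length(yc_w)
      Xc_w <- matrix(0, n_all, nre)
      xbar <- vector("list", nt)
      for (i in seq_len(nt)) {
        xb <- drop(crossprod(Xs[[i]], wts[[i]])) / wsum[i]
        xbar[[i]] <- xb
        Xc_w[rows[[i]], ] <- sw[[i]] * (Xs[[i]] - rep(xb, each = nrow(Xs[[i]])))
      }
      beta <- tryCatch(qr.coef(qr(Xc_w), yc_w), error = function(e) rep(0, nre))
      beta[is.na(beta)] <- 0
      resid_w <- yc_w - drop(Xc_w %*% beta)
      offs <- vapply(seq_len(nt), function(i)
        ybar[i] - sum(xbar[[i]] * beta), numeric(1))
      list(resid_w = resid_w,
           fitted = lapply(seq_len(nt), function(i)
             offs[i] + drop(Xs[[i]] %*% beta)),
           coef = lapply(seq_len(nt), function(i)
             stats::setNames(c(offs[i], beta), c("offset", response_species))))
    } else {
      per <- lapply(seq_len(nt), function(i) {
        X <- cbind(1, Xs[[i]])
        cf <- qr.coef(qr(X * sw[[i]]), signals[[i]] * sw[[i]])
        cf[is.na(cf)] <- 0
        fitted <- drop(X %*% cf)
        list(resid_w = sw[[i]] * (signals[[i]] - fitted), fitted = fitted,
             coef = stats::setNames(cf, c("offset", response_species)))
      })
      list(resid_w = unlist(lapply(per, `[[`, "resid_w")),
           fitted = lapply(per, `[[`, "fitted"),
           coef = lapply(per, `[[`, "coef"))
    }
  }
  resid_fn <- function(logk) {
    Xs <- sim_all(exp(logk))
    if (any(vapply(Xs, is.null, logical(1)))) {
      return(rep(1e3, sum(lengths(signals))))
    }
    solve_linear(Xs)$resid_w
  }

  starts <- list(pmin(pmax(log(start[free]), log(lower)), log(upper)))
  if (n_starts > 1) {
    pert <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i)
        starts[[1]] + log(10) * stats::runif(length(free), -spread, spread))
    })
    starts <- c(starts, pert)
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, log(lower)), log(upper))
    # iteration-cap chatter from individual starts is not actionable; the
    # converged flag on the result carries the outcome
    fit <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(st, fn = resid_fn,
                           lower = log(lower), upper = log(upper),
                           control = minpack.lm::nls.lm.control(maxiter = maxiter)),
        warning = function(w) {
          if (grepl("lmdif|lmder|maxiter", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("global fit failed to converge from any start", call. = FALSE)

  logk <- best$par
  est <- exp(logk)
  names(est) <- free
  n_obs <- sum(vapply(traces, nrow, integer(1)))
  n_resp <- if (share_responses) nt + nre else nt * (1 + nre)
  p_tot <- length(free) + n_resp
  rss <- best$deviance
  s2 <- rss / max(n_obs - p_tot, 1)
  cov_log <- tryCatch(s2 * solve(best$hessian / 2),
                      error = function(e) matrix(NA_real_, length(free), length(free)))
  se <- est * sqrt(pmax(diag(cov_log), 0))
  flagged <- is.finite(se) & (se / est > 10)
  flagged[!is.finite(se)] <- TRUE

  sol <- solve_linear(sim_all(est))
  fitted <- sol$fitted
  residuals <- lapply(seq_len(nt), function(i) signals[[i]] - fitted[[i]])
  resp_tb <- dplyr::bind_rows(lapply(seq_len(nt), function(i) {
    tibble::tibble(trace = i, term = names(sol$coef[[i]]),
                   estimate = unname(sol$coef[[i]]))
  }))

  structure(list(
    coef = tibble::tibble(term = free, estimate = unname(est), se = unname(se),
                          flagged = unname(flagged)),
    responses = resp_tb,
    rss = rss, n_obs = n_obs, n_par = p_tot,
    aicc = aicc_ls(rss, n_obs, p_tot),
    fitted = fitted, residuals = residuals,
    converged = best$info %in% 1:4,
    scheme = scheme, traces = traces, start = start, free = free,
    response_species = response_species, share_responses = share_responses,
    engine = engine, weights = weights, cov_log = cov_log,
    lower = lower, upper = upper,
    data_id = dataset_signature(traces)),
    class = "global_fit_result")
}

dataset_signature <- function(traces) {
  sum(vapply(traces, function(tr) sum(tr$time) + sum(tr$signal), numeric(1)))
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result> ", length(x$traces), " traces, ", x$n_obs,
      " points, engine = ", x$engine, "\n  SSR = ", signif(x$rss, 6),
      ", AICc = ", signif(x$aicc, 6), "\n", sep = "")
  print(x$coef)
  if (any(x$coef$flagged)) {
    cat("  flagged parameters are structurally unidentifiable (SE/value > 10)\n")
  }
  invisible(x)
}

#' Derived equilibrium constants of a global fit
#'
#' Dissociation and isomerisation equilibrium constants are ratios of fitted
#' rate constants, recomputed on demand from the current estimates.
#'
#' @param result A `global_fit_result`.
#' @return A tibble (see [derived_constants()]).
#' @export
derived_constants_fit <- function(result) {
  est <- stats::setNames(result$coef$estimate, result$coef$term)
  fixed <- result$start[setdiff(names(result$start), result$coef$term)]
  derived_constants(c(est, fixed))
}

#' Residual-resampling bootstrap intervals for a global fit
#'
#' Resamples residuals within each trace (with replacement), adds them back
#' to the fitted curves, and refits from the converged estimate. Percentile
#' intervals are reported; the procedure is reproducible for a given seed.
#'
#' @param result A converged `global_fit_result`.
#' @param n_boot Number of bootstrap replicates (>= 100 for reported CIs;
#'   smaller values warn).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param max_fail Maximum tolerated fraction of non-converged replicates.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `n_boot_used`.
#' @export
bootstrap_ci <- function(result, n_boot = 100, seed = 1, level = 0.95,
                         max_fail = 0.2) {
  stopifnot(inherits(result, "global_fit_result"))
  if (!result$converged) stop("bootstrap requires a converged fit", call. = FALSE)
  if (n_boot < 100) {
    warning("n_boot < 100: intervals are reported but poorly resolved", call. = FALSE)
  }
  est <- stats::setNames(result$coef$estimate, result$coef$term)
  start_full <- result$start
  start_full[names(est)] <- est
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      lapply(seq_along(result$traces), function(i)
        sample(result$residuals[[i]], replace = TRUE))
    })
  })
  boots <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  n_fail <- 0
  for (b in seq_len(n_boot)) {
    traces_b <- result$traces
    for (i in seq_along(traces_b)) {
      traces_b[[i]]$signal <- result$fitted[[i]] + draws[[b]][[i]]
    }
    fit_b <- tryCatch(
      global_fit(traces_b, result$scheme, start_full, free = result$free,
                 response_species = result$response_species,
                 share_responses = result$share_responses,
                 engine = result$engine, weights = result$weights,
                 n_starts = 1, maxiter = 50,
                 lower = result$lower, upper = result$upper),
      error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) {
      n_fail <- n_fail + 1
    } else {
      boots[b, ] <- fit_b$coef$estimate
    }
  }
  if (n_fail / n_boot > max_fail) {
    stop("bootstrap unstable: ", n_fail, "/", n_boot,
         " replicates failed to converge", call. = FALSE)
  }
  a <- (1 - level) / 2
  tibble::tibble(
    term = names(est), estimate = unname(est),
    lower = apply(boots, 2, stats::quantile, probs = a, na.rm = TRUE),
    upper = apply(boots, 2, stats::quantile, probs = 1 - a, na.rm = TRUE),
    n_boot_used = n_boot - n_fail)
}

#' Compare two global fits of the same dataset
#'
#' Model discrimination by AICc: the lower-AICc model is preferred;
#' `|delta AICc| <` `threshold` is reported as indistinguishable.
#'
#' @param result_a,result_b `global_fit_result`s fitted to the same traces.
#' @param threshold Indistinguishability threshold (default 2).
#' @return A list with `delta_aicc` (AICc_a - AICc_b), `preferred`
#'   (`"A"`, `"B"` or `"indistinguishable"`) and both AICc values.
#' @export
compare_models <- function(result_a, result_b, threshold = 2) {
  if (!isTRUE(all.equal(result_a$data_id, result_b$data_id)) ||
      length(result_a$traces) != length(result_b$traces)) {
    stop("results were fitted to different datasets", call. = FALSE)
  }
  delta <- result_a$aicc - result_b$aicc
  preferred <- if (is.na(delta) || abs(delta) < threshold) "indistinguishable"
    else if (delta < 0) "A" else "B"
  list(delta_aicc = delta, preferred = preferred,
       aicc_a = result_a$aicc, aicc_b = result_b$aicc)
}
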