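# Phenomenological fitting of stopped-flow transients: sums of exponentials,
# AICc phase selection, secondary plots (kobs vs concentration) and
# mechanism classification.

# Small-sample corrected AIC for a least-squares fit. K counts the mean
# function parameters plus one for the residual variance (the standard
# least-squares AIC convention). Infinite when the small-sample correction
# is undefined (n <= K + 1). RSS is floored to keep noiseless fits
# comparable.
aicc_ls <- function(rss, n, k) {
  k <- k + 1
  rss <- max(rss, n * 1e-30)
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a transient to a sum of exponentials
#'
#' Fits `y = sum_i Amp_i * exp(-kobs_i * t) + c` with 1 or 2 phases by
#' Levenberg-Marquardt least squares. Rate starting values come from a
#' log-spaced grid spanning the sampled time range (multistart); for each
#' rate start the amplitudes and offset are solved exactly by linear least
#' squares before the nonlinear refinement. For two phases the result is
#' ordered fast phase first (`kobs_1 > kobs_2`).
#'
#' @param trace A data frame with columns `time` and `signal` (an
#'   [new_trace()] object works directly).
#' @param n_phases 1 or 2.
#' @param n_starts Number of multistart rate guesses (default 5).
#' @return An object of class `exp_fit`: list with `n_phases`, a `coef`
#'   tibble (`term`, `estimate`, `se`), `rss`, `sigma` (residual sd),
#'   `aicc`, `residuals`, `fitted` and the input data.
#' @examples
#' tr <- tibble::tibble(time = seq(0, 2, 0.01),
#'                      signal = 0.5 * exp(-3 * time) + 0.1)
#' fit_exponential(tr, 1)$coef
#' @export
fit_exponential <- function(trace, n_phases = 1, n_starts = 5) {
  stopifnot(n_phases %in% c(1, 2))
  tt <- trace$time; yy <- trace$signal
  if (length(tt) < 5 * (2 * n_phases + 1)) {
    stop("too few points: need >= ", 5 * (2 * n_phases + 1),
         " for a ", n_phases, "-phase fit", call. = FALSE)
  }
  if (stats::sd(yy) == 0) {
    stop("constant signal: degenerate input for an exponential fit", call. = FALSE)
  }
  t0 <- tt[1]
  ts <- tt - t0   # shift so amplitudes refer to the first observed point
  tr_span <- max(ts) - min(ts)
  dt <- min(diff(ts))
  rate_grid <- exp(seq(log(0.5 / tr_span), log(2 / dt), length.out = n_starts))

  # linear LS for amplitudes/offset at fixed rates
  lin_amp <- function(rates) {
    X <- cbind(vapply(rates, function(k) exp(-k * ts), numeric(length(ts))), 1)
    qr.coef(qr(X), yy)
  }
  resid_fn <- function(par) {
    k <- exp(par[seq_len(n_phases)])
    a <- par[n_phases + seq_len(n_phases)]
    cc <- par[2 * n_phases + 1]
    yy - (drop(vapply(k, function(kk) exp(-kk * ts), numeric(length(ts))) %*% a) + cc)
  }
  best <- NULL
  starts <- if (n_phases == 1) {
    lapply(rate_grid, function(r) r)
  } else {
    lapply(rate_grid, function(r) c(r, r / 25))
  }
  for (st in starts) {
    ab <- lin_amp(st)
    par0 <- c(log(st), ab)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("exponential fit failed to converge", call. = FALSE)

  par <- best$par
  k <- exp(par[seq_len(n_phases)])
  a <- par[n_phases + seq_len(n_phases)]
  cc <- par[2 * n_phases + 1]
  # covariance in the internal (log k, a, c) parametrisation, then delta rule
  n <- length(yy); p <- length(par)
  rss <- best$deviance
  s2 <- rss / max(n - p, 1)
  cov_i <- tryCatch(s2 * solve(best$hessian / 2), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(cov_i), 0))
  se_k <- k * se[seq_len(n_phases)]
  se_a <- se[n_phases + seq_len(n_phases)]
  se_c <- se[2 * n_phases + 1]
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; a <- a[ord]; se_k <- se_k[ord]; se_a <- se_a[ord]
  if (any(k <= 0) || any(!is.finite(k))) {
    stop("exponential fit degenerate: non-positive rate", call. = FALSE)
  }
  terms <- c(paste0("kobs_", seq_len(n_phases)), paste0("Amp_", seq_len(n_phases)), "c")
  fitted <- yy - resid_fn(par)
  structure(list(
    n_phases = n_phases,
    coef = tibble::tibble(term = terms,
                          estimate = as.numeric(c(k, a, cc)),
                          se = as.numeric(c(se_k, se_a, se_c))),
    rss = rss, sigma = sqrt(s2),
    aicc = aicc_ls(rss, n, p),
    residuals = yy - fitted, fitted = fitted,
    data = tibble::tibble(time = tt, signal = yy),
    t_ref = t0,
    converged = best$info %in% 1:4), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> ", x$n_phases, " phase(s), AICc = ", signif(x$aicc, 6), "\n", sep = "")
  print(x$coef)
  invisible(x)
}

coef_of <- function(fit, term) {
  fit$coef$estimate[match(term, fit$coef$term)]
}

#' Choose between a single- and double-exponential description
#'
#' Fits both 1- and 2-phase models and keeps the one with the lower AICc.
#' The 2-phase fit is discarded as degenerate — falling back to 1 phase —
#' when either fitted amplitude is insignificant (below 3x the residual
#' noise or below 3x its own standard error) or the two rates differ by
#' less than 10%. The amplitude-vs-SE check is what rejects the classic
#' pathology of a single exponential split into two strongly correlated
#' phases of indistinguishable rate.
#'
#' @inheritParams fit_exponential
#' @return A list with `fit` (the selected `exp_fit`), `n_phases`,
#'   `delta_aicc` (AICc_1phase - AICc_2phase; positive favours 2 phases) and
#'   `degenerate_2phase`.
#' @export
select_n_phases <- function(trace, n_starts = 5) {
  f1 <- fit_exponential(trace, 1, n_starts)
  f2 <- tryCatch(fit_exponential(trace, 2, n_starts), error = function(e) NULL)
  if (is.null(f2)) {
    return(list(fit = f1, n_phases = 1L, delta_aicc = NA_real_,
                degenerate_2phase = TRUE))
  }
  k1 <- coef_of(f2, "kobs_1"); k2 <- coef_of(f2, "kobs_2")
  amps <- abs(c(coef_of(f2, "Amp_1"), coef_of(f2, "Amp_2")))
  se_amps <- f2$coef$se[match(c("Amp_1", "Amp_2"), f2$coef$term)]
  degen <- any(amps < 3 * f2$sigma) ||
    any(!is.finite(se_amps)) || any(amps < 3 * se_amps) ||
    (k1 / k2 < 1.1)
  delta <- f1$aicc - f2$aicc
  if (degen || f1$aicc <= f2$aicc) {
    list(fit = f1, n_phases = 1L, delta_aicc = delta, degenerate_2phase = degen)
  } else {
    list(fit = f2, n_phases = 2L, delta_aicc = delta, degenerate_2phase = FALSE)
  }
}

#' Fit a secondary plot of observed rates against concentration
#'
#' The concentration dependence of the observed relaxation rate encodes the
#' binding mechanism: one-step binding gives a line
#' `kobs = k1 * S + km1` (slope = association constant, intercept =
#' dissociation constant), while binding followed by a conformational step
#' gives, in the rapid-equilibrium limit, the saturating hyperbola
#' `kobs = kmconf + kconf * S / (KD1 + S)`.
#'
#' Points with standard errors are fitted by weighted least squares
#' (`weights = 1/se^2`); without SEs the fit is unweighted.
#'
#' @param points Data frame with columns `conc` (uM), `kobs` (1/s) and
#'   optionally `se`.
#' @param model `"linear"` or `"hyperbolic"`.
#' @param n_starts Multistart count for the hyperbolic fit.
#' @return An object of class `secondary_fit` with the model name, a `coef`
#'   tibble, `rss` (weighted), `aicc` and an `identifiability_warning` flag.
#' @examples
#' pts <- tibble::tibble(conc = c(0.5, 1, 2, 5, 10, 20, 40),
#'                       kobs = 2 + 40 * conc / (10 + conc))
#' fit_secondary_plot(pts, "hyperbolic")$coef
#' @export
fit_secondary_plot <- function(points, model = c("linear", "hyperbolic"),
                               n_starts = 5) {
  model <- match.arg(model)
  conc <- points$conc; kobs <- points$kobs
  se <- if ("se" %in% names(points) && !all(is.na(points$se))) points$se else NULL
  n_min <- if (model == "linear") 4 else 5
  if (length(conc) < n_min) {
    stop("need >= ", n_min, " concentrations for a ", model, " fit", call. = FALSE)
  }
  if (max(conc) / min(conc) < 4) {
    warning("concentration range spans < 4-fold; secondary fit poorly constrained",
            call. = FALSE)
  }
  w <- if (is.null(se)) rep(1, length(conc)) else 1 / se^2
  # a point with an unusable SE gets the median weight rather than breaking
  # or dominating the fit
  bad_w <- !is.finite(w) | w <= 0
  if (all(bad_w)) w <- rep(1, length(conc))
  else if (any(bad_w)) w[bad_w] <- stats::median(w[!bad_w])
  n <- length(conc)
  flag <- FALSE
  if (model == "linear") {
    fit <- stats::lm(kobs ~ conc, weights = w)
    # noiseless generative data trip lm's perfect-fit warning; SEs are ~0
    # there and the message carries no information
    cf <- withCallingHandlers(
      summary(fit)$coefficients,
      warning = function(w) {
        if (grepl("perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    est <- c(k1 = unname(cf["conc", 1]), km1 = unname(cf["(Intercept)", 1]))
    ses <- c(unname(cf["conc", 2]), unname(cf["(Intercept)", 2]))
    rss <- sum(w * stats::residuals(fit)^2)
    coef_tb <- tibble::tibble(term = c("k1", "km1"), estimate = unname(est), se = ses)
    aicc <- aicc_ls(rss, n, 2)
    fitted <- stats::fitted(fit)
  } else {
    resid_fn <- function(par) {
      KD1 <- exp(par[1]); kconf <- par[2]; kmconf <- par[3]
      sqrt(w) * (kobs - (kmconf + kconf * conc / (KD1 + conc)))
    }
    kd_grid <- exp(seq(log(min(conc) / 2), log(max(conc) * 4), length.out = n_starts))
    best <- NULL
    for (kd in kd_grid) {
      # amplitudes linear at fixed KD1
      X <- cbind(conc / (kd + conc), 1)
      ab <- qr.coef(qr(X * sqrt(w)), kobs * sqrt(w))
      fit <- tryCatch(
        minpack.lm::nls.lm(c(log(kd), max(ab[1], 1e-6), max(ab[2], 0)),
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
    if (is.null(best)) stop("hyperbolic secondary fit failed", call. = FALSE)
    KD1 <- exp(best$par[1]); kconf <- best$par[2]; kmconf <- best$par[3]
    rss <- best$deviance
    s2 <- rss / max(n - 3, 1)
    cov_i <- tryCatch(s2 * solve(best$hessian / 2),
                      error = function(e) matrix(NA_real_, 3, 3))
    se3 <- sqrt(pmax(diag(cov_i), 0))
    ses <- c(KD1 * se3[1], se3[2], se3[3])
    if (KD1 > 10 * max(conc) || (is.finite(ses[1]) && ses[1] > 100 * KD1)) {
      warning("hyperbolic fit unidentifiable: KD1 not constrained by the ",
              "sampled concentration range", call. = FALSE)
      flag <- TRUE
    }
    coef_tb <- tibble::tibble(term = c("KD1", "kconf", "kmconf"),
                              estimate = c(KD1, kconf, kmconf), se = ses)
    aicc <- aicc_ls(rss, n, 3)
    fitted <- kmconf + kconf * conc / (KD1 + conc)
  }
  structure(list(model = model, coef = coef_tb, rss = rss, aicc = aicc,
                 identifiability_warning = flag,
                 data = tibble::tibble(conc = conc, kobs = kobs,
                                       se = se %||% NA_real_),
                 fitted = fitted),
            class = "secondary_fit")
}

#' @export
print.secondary_fit <- function(x, ...) {
  cat("<secondary_fit> ", x$model, ", AICc = ", signif(x$aicc, 6),
      if (x$identifiability_warning) "  [identifiability warning]", "\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' Classify the binding mechanism from a secondary plot
#'
#' Fits both the linear (one-step, two-state) and hyperbolic
#' (conformational-step) models to the same `kobs` vs concentration points
#' and compares them by AICc. `|delta AICc|` below `threshold` is reported as
#' ambiguous. A hyperbolic verdict is reported as "conformational-step": the
#' concentration dependence of `kobs` alone cannot distinguish induced fit
#' from conformational selection.
#'
#' @inheritParams fit_secondary_plot
#' @param threshold Ambiguity threshold on `|delta AICc|` (default 2).
#' @param method `"aicc"` (default) or `"ftest"`: the F-test treats the line
#'   as the null model and calls a conformational step when the extra-sum-of-
#'   squares test rejects at `alpha` (common stopped-flow practice; note the
#'   models are nested only in the large-KD1 limit).
#' @param alpha F-test significance level.
#' @return An object of class `mechanism_verdict`: list with
#'   `classification` (`"two-state"`, `"conformational-step"` or
#'   `"ambiguous"`), `delta_aicc` (AICc_linear - AICc_hyperbolic; positive
#'   favours the conformational-step model), an F-test p-value, and both
#'   fits.
#' @export
classify_mechanism <- function(points, threshold = 2, n_starts = 5,
                               method = c("aicc", "ftest"), alpha = 0.05) {
  method <- match.arg(method)
  f_lin <- withCallingHandlers(
    fit_secondary_plot(points, "linear"),
    warning = function(w) invokeRestart("muffleWarning"))
  f_hyp <- tryCatch(
    withCallingHandlers(
      fit_secondary_plot(points, "hyperbolic", n_starts),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(f_hyp)) {
    # hyperbola unfittable (e.g. too few points): the line is the only model
    return(structure(list(classification = "two-state", delta_aicc = -Inf,
                          linear = f_lin, hyperbolic = NULL,
                          threshold = threshold),
                     class = "mechanism_verdict"))
  }
  delta <- f_lin$aicc - f_hyp$aicc
  if (is.nan(delta)) {
    # both AICc undefined (too few points for the correction): parsimony —
    # keep the line unless the hyperbola fits meaningfully better
    delta <- if (f_hyp$rss < 0.5 * f_lin$rss) Inf else -Inf
  }
  n <- nrow(f_lin$data)
  f_p <- if (f_hyp$rss < f_lin$rss && n > 3) {
    f_stat <- (f_lin$rss - f_hyp$rss) / (f_hyp$rss / (n - 3))
    stats::pf(f_stat, 1, n - 3, lower.tail = FALSE)
  } else 1
  classification <- if (method == "ftest") {
    if (f_p < alpha) "conformational-step" else "two-state"
  } else if (!is.finite(delta)) {
    if (delta < 0) "two-state" else "conformational-step"
  } else if (abs(delta) < threshold) {
    "ambiguous"
  } else if (delta > 0) "conformational-step" else "two-state"
  # an unidentifiable hyperbola on linear data is no evidence for a step
  if (classification == "conformational-step" && f_hyp$identifiability_warning) {
    classification <- "ambiguous"
  }
  structure(list(classification = classification, delta_aicc = delta,
                 f_pvalue = f_p, linear = f_lin, hyperbolic = f_hyp,
                 threshold = threshold, method = method),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("<mechanism_verdict> ", x$classification,
      " (delta AICc linear - hyperbolic = ", signif(x$delta_aicc, 4), ")\n", sep = "")
  invisible(x)
}
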