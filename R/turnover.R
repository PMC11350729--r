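# Steady-state (Michaelis-Menten) and single-turnover analysis of enzyme
# progress curves, plus the rate-limiting-step diagnosis comparing the two.

#' Spectrophotometric assay constants
#'
#' Substrate turnover is followed at 300 nm, where the substrate absorbs more
#' strongly than the product: the default absorptivity difference is
#' 5637 1/(M cm) (substrate minus product), and the substrate analogue used
#' for concentration determination has eps300 = 6069 1/(M cm).
#'
#' @param delta_eps300 Substrate-product absorptivity difference, 1/(M cm).
#' @param eps300_analogue Analogue absorptivity for stock quantification,
#'   1/(M cm).
#' @param path_cm Cuvette path length (cm).
#' @return A named list of class `assay_constants`.
#' @export
assay_constants <- function(delta_eps300 = 5637, eps300_analogue = 6069,
                            path_cm = 1) {
  stopifnot(delta_eps300 > 0, eps300_analogue > 0, path_cm > 0)
  structure(list(delta_eps300 = delta_eps300,
                 eps300_analogue = eps300_analogue,
                 path_cm = path_cm), class = "assay_constants")
}

#' Convert an absorbance slope to a turnover velocity
#'
#' `v = |slope| / (path * delta_eps)` with the absorptivity difference
#' converted to 1/(uM cm) (5637 1/(M cm) = 0.005637 1/(uM cm)), so an
#' absorbance slope in A/s becomes a velocity in uM/s.
#'
#' @param slope_A_per_s Absorbance change rate (A/s); the sign is ignored.
#' @param constants An [assay_constants()] object.
#' @return Velocity in uM/s.
#' @examples
#' absorbance_to_velocity(1.08231e-3)  # 0.192 uM/s
#' @export
absorbance_to_velocity <- function(slope_A_per_s, constants = assay_constants()) {
  abs(slope_A_per_s) / (constants$path_cm * constants$delta_eps300 * 1e-6)
}

#' Extract the steady-state velocity from a multiple-turnover progress curve
#'
#' Multiple-turnover traces show a linear steady-state phase that can be
#' preceded by an exponential burst (a mixing artifact, also present without
#' the second substrate, and excluded from analysis). The curve is first fit
#' to `A(t) = a * exp(-kb * t) + m * t + d`; the burst window ends where the
#' fitted exponential has decayed to < 5% of its amplitude
#' (`t = log(20)/kb`). The steady-state slope is then refit linearly on the
#' window from the burst end to 20% substrate depletion, and converted to
#' uM/s.
#'
#' @param curve An `sf_progress` curve (columns `time`, `absorbance`) in
#'   multiple-turnover or control mode with `E_tot`/`S0` metadata.
#' @param constants [assay_constants()].
#' @param depletion_frac Fraction of substrate depletion that ends the
#'   steady-state window (default 0.2).
#' @return A list with `v` (uM/s), `se`, `slope` (A/s), `burst`
#'   (amplitude/rate or NULL), and the window used.
#' @export
extract_steady_velocity <- function(curve, constants = assay_constants(),
                                    depletion_frac = 0.2) {
  mode <- attr(curve, "mode") %||% "multiple_turnover"
  if (identical(mode, "single_turnover")) {
    stop("steady-state extraction needs a multiple-turnover or control curve",
         call. = FALSE)
  }
  tt <- curve$time; A <- curve$absorbance
  de <- constants$delta_eps300 * 1e-6 * constants$path_cm
  S0 <- attr(curve, "S0")
  # burst + line fit; fall back to pure line when the burst is not supported
  burst <- NULL
  lin_res <- function(par) {
    A - (par[1] * exp(-exp(par[2]) * tt) + par[3] * tt + par[4])
  }
  lf0 <- stats::lm(A ~ tt)
  start <- c(A[1] - stats::coef(lf0)[1], log(10 / max(tt)),
             stats::coef(lf0)[2], stats::coef(lf0)[1])
  bf <- tryCatch(minpack.lm::nls.lm(start, fn = lin_res,
                                    control = minpack.lm::nls.lm.control(maxiter = 200)),
                 error = function(e) NULL)
  t_burst_end <- 0
  if (!is.null(bf)) {
    amp <- as.numeric(bf$par[1]); kb <- as.numeric(exp(bf$par[2]))
    resid_sd <- sqrt(bf$deviance / length(tt))
    if (abs(amp) > 3 * resid_sd && kb * max(tt) > 3) {
      burst <- list(amplitude = amp, rate = kb)
      t_burst_end <- log(20) / kb
    }
  }
  # end of steady window: depletion_frac of the substrate consumed
  slope0 <- if (!is.null(burst)) bf$par[3] else stats::coef(lf0)[2]
  v0 <- abs(slope0) / de
  t_deplete <- if (!is.null(S0) && v0 > 0) {
    t_burst_end + depletion_frac * S0 / v0
  } else max(tt)
  window <- tt >= t_burst_end & tt <= max(t_deplete, t_burst_end)
  if (sum(window) < 10) {
    stop("steady-state window has < 10 points (burst too long or depletion ",
         "too fast)", call. = FALSE)
  }
  lf <- stats::lm(A[window] ~ tt[window])
  slope <- unname(stats::coef(lf)[2])
  se_slope <- withCallingHandlers(
    summary(lf)$coefficients[2, 2],
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(v = abs(slope) / de, se = se_slope / de, slope = slope, burst = burst,
       window = range(tt[window]))
}

#' Fit the Michaelis-Menten equation to initial velocities
#'
#' `v = kcat * E_tot * S / (KM + S)` by (optionally weighted) least squares.
#' The specificity constant kcat/KM is derived afterwards with full error
#' propagation ([propagate_kcat_over_km()]), never fitted as an independent
#' parameter.
#'
#' @param points Data frame with columns `S` (uM), `v` (uM/s) and optionally
#'   `se`; replicate means with their SEMs fit naturally (weighted, the
#'   default when `se` is present).
#' @param E_tot Total enzyme concentration (uM).
#' @param weighted Use `1/se^2` weights when `se` is available (default
#'   `TRUE`).
#' @return An object of class `mm_fit`: `coef` tibble with `kcat` (1/s),
#'   `KM` (uM) and the derived `kcat_over_KM` (1/(M s)), residuals, `rss`,
#'   and an identifiability flag when KM exceeds 5x the largest substrate
#'   concentration.
#' @export
fit_michaelis_menten <- function(points, E_tot, weighted = TRUE) {
  S <- points$S; v <- points$v
  if (length(S) < 5) stop("need >= 5 substrate concentrations", call. = FALSE)
  if (max(S) / min(S) < 8) {
    warning("substrate range spans < 8-fold; KM poorly constrained", call. = FALSE)
  }
  if (all(v == 0)) stop("all velocities are zero: no signal to fit", call. = FALSE)
  w <- if (weighted && "se" %in% names(points) && !all(is.na(points$se))) {
    1 / points$se^2
  } else rep(1, length(S))
  resid_fn <- function(par) {
    kcat <- exp(par[1]); KM <- exp(par[2])
    sqrt(w) * (v - kcat * E_tot * S / (KM + S))
  }
  vmax0 <- max(v); km0 <- stats::median(S)
  fit <- minpack.lm::nls.lm(c(log(vmax0 / E_tot), log(km0)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  kcat <- exp(fit$par[1]); KM <- exp(fit$par[2])
  n <- length(S)
  s2 <- fit$deviance / max(n - 2, 1)
  cov_log <- tryCatch(s2 * solve(fit$hessian / 2),
                      error = function(e) matrix(NA_real_, 2, 2))
  se_kcat <- kcat * sqrt(max(cov_log[1, 1], 0))
  se_KM <- KM * sqrt(max(cov_log[2, 2], 0))
  flag <- KM > 5 * max(S)
  if (flag) {
    warning("KM > 5x the largest substrate concentration: saturation not ",
            "reached, estimates are lower bounds", call. = FALSE)
  }
  spec <- propagate_kcat_over_km(kcat, se_kcat, KM, se_KM)
  structure(list(
    coef = tibble::tibble(
      term = c("kcat", "KM", "kcat_over_KM"),
      estimate = c(kcat, KM, spec$value),
      se = c(se_kcat, se_KM, spec$se),
      unit = c("1/s", "uM", "1/(M s)")),
    rss = fit$deviance, n = n,
    residuals = v - kcat * E_tot * S / (KM + S),
    fitted = kcat * E_tot * S / (KM + S),
    data = tibble::tibble(S = S, v = v), E_tot = E_tot,
    identifiability_warning = flag), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> kcat = ", signif(x$coef$estimate[1], 3), " 1/s, KM = ",
      signif(x$coef$estimate[2], 3), " uM, kcat/KM = ",
      signif(x$coef$estimate[3], 3), " 1/(M s)\n", sep = "")
  invisible(x)
}

#' Specificity constant with Gaussian error propagation
#'
#' `kcat/KM` in 1/(M s) (the uM -> M conversion multiplies by 1e6), with
#' relative errors added in quadrature:
#' `se(kcat/KM)/(kcat/KM) = sqrt((se_kcat/kcat)^2 + (se_KM/KM)^2)`.
#'
#' @param kcat,se_kcat Turnover number and its SE (1/s).
#' @param KM,se_KM Michaelis constant and its SE (uM).
#' @return List with `value` and `se`, both in 1/(M s).
#' @examples
#' propagate_kcat_over_km(2.4, 0.2, 4.5, 0.5)
#' @export
propagate_kcat_over_km <- function(kcat, se_kcat, KM, se_KM) {
  stopifnot(kcat > 0, KM > 0)
  value <- kcat / (KM * 1e-6)
  rel <- sqrt((se_kcat / kcat)^2 + (se_KM / KM)^2)
  list(value = value, se = value * rel)
}

#' Upper limit on kcat from an activity detection threshold
#'
#' When no turnover is detectable, the velocity detection limit bounds the
#' turnover number: `kcat < v_detect / E_tot`.
#'
#' @param v_detect Smallest detectable velocity (uM/s).
#' @param E_tot Enzyme concentration (uM).
#' @return The bound (1/s); degenerate zero input warns.
#' @examples
#' kcat_upper_limit(2e-4, 0.1)  # < 2e-3 1/s
#' @export
kcat_upper_limit <- function(v_detect, E_tot) {
  stopifnot(v_detect >= 0, E_tot > 0)
  if (v_detect == 0) {
    warning("zero detection limit gives a degenerate bound of 0", call. = FALSE)
  }
  v_detect / E_tot
}

#' Fit a single-turnover decay
#'
#' Under single-turnover conditions the enzyme saturates the substrate
#' (enzyme >= 2x substrate), every substrate molecule reacts in one pass, and
#' the decay rate is unaffected by product release: the curve is fit to
#' `y = a * exp(-kobs * t) + c`.
#'
#' @param curve An `sf_progress` curve in `single_turnover` mode.
#' @return A list with `kobs` (1/s), `se`, and the underlying [fit_exponential()]
#'   object.
#' @export
fit_single_turnover <- function(curve) {
  E_tot <- attr(curve, "E_tot"); S0 <- attr(curve, "S0")
  if (!is.null(E_tot) && !is.null(S0) && E_tot < 2 * S0) {
    stop("mode violation: single turnover requires enzyme >= 2x substrate ",
         "(E_tot = ", E_tot, ", S0 = ", S0, " uM)", call. = FALSE)
  }
  fit <- fit_exponential(
    tibble::tibble(time = curve$time, signal = curve$absorbance), 1)
  list(kobs = coef_of(fit, "kobs_1"),
       se = fit$coef$se[fit$coef$term == "kobs_1"],
       fit = fit, S0 = S0)
}

#' Single-turnover rate summary across substrate concentrations
#'
#' @param curves List of single-turnover `sf_progress` curves.
#' @return A tibble (`S0`, `kobs`, `se`) plus a flatness statistic: the
#'   relative spread `(max - min)/mean` of `kobs` across `S0`, small when the
#'   observed chemistry rate is substrate-independent.
#' @export
single_turnover_summary <- function(curves) {
  tb <- dplyr::bind_rows(lapply(curves, function(cv) {
    st <- fit_single_turnover(cv)
    tibble::tibble(S0 = st$S0 %||% NA_real_, kobs = st$kobs, se = st$se)
  }))
  attr(tb, "flatness") <- (max(tb$kobs) - min(tb$kobs)) / mean(tb$kobs)
  tb
}

#' Diagnose the rate-limiting step from turnover comparisons
#'
#' Single-turnover rates are blind to product release; steady-state kcat
#' includes it. When the two agree (ratio of mean single-turnover kobs to
#' kcat within `[1/3, 3]`, i.e. the same order of magnitude) the chemical
#' step is rate-limiting; a single-turnover rate much faster than kcat
#' (ratio > 3) indicates that product release (or another post-chemistry
#' step) limits turnover.
#'
#' @param mm An `mm_fit` (multiple turnover).
#' @param st A [single_turnover_summary()] tibble (or list of curves).
#' @param bounds Ratio band treated as "same order of magnitude".
#' @return A list with `verdict`, `ratio` (mean ST kobs / kcat), and an
#'   approximate 95% CI on the ratio.
#' @export
diagnose_rate_limiting <- function(mm, st, bounds = c(1 / 3, 3)) {
  if (!inherits(mm, "mm_fit")) stop("`mm` must be an mm_fit", call. = FALSE)
  if (!is.data.frame(st)) st <- single_turnover_summary(st)
  kcat <- mm$coef$estimate[1]; se_kcat <- mm$coef$se[1]
  k_st <- mean(st$kobs)
  se_st <- sqrt(sum(st$se^2)) / nrow(st)
  ratio <- k_st / kcat
  rel <- sqrt((se_st / k_st)^2 + (se_kcat / kcat)^2)
  ci <- ratio * exp(c(-1.96, 1.96) * rel)
  verdict <- if (ratio >= bounds[1] && ratio <= bounds[2]) {
    "chemistry rate-limiting"
  } else if (ratio > bounds[2]) {
    "product release (or post-chemistry step) rate-limiting"
  } else {
    "inconclusive"
  }
  list(verdict = verdict, ratio = ratio, ci = ci,
       kcat = kcat, st_kobs = k_st)
}
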