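# Equilibrium fluorescence titration analysis: preprocessing (dilution and
# intrinsic-ligand-fluorescence corrections), hyperbolic / ligand-depletion
# isotherm fits, model-based apparent-KD predictions and ternary synergy.

#' Preprocess a raw titration series
#'
#' Applies, at most once each: a dilution correction
#' (`F_corr = F * (V0 + V_added)/V0`, restoring the signal the undiluted
#' fluorophore would give) and subtraction of the titrated ligand's intrinsic
#' fluorescence (`F_corr = F - b * [L]`, with `b` in signal per uM).
#'
#' @param raw Data frame with columns `conc` (uM, nondecreasing), `F`, and
#'   `added_volume` (uL, cumulative) when the dilution correction is
#'   requested.
#' @param dilution Apply the dilution correction.
#' @param V0 Initial cuvette volume (uL), required for dilution.
#' @param ligand_background Intrinsic ligand fluorescence coefficient `b`
#'   (signal per uM), or `NULL` to skip.
#' @return An `sf_titration` tibble (`conc`, `F`) with a `corrections`
#'   attribute recording what was applied.
#' @export
preprocess_titration <- function(raw, dilution = FALSE, V0 = NULL,
                                 ligand_background = NULL) {
  stopifnot(all(c("conc", "F") %in% names(raw)))
  if (is.unsorted(raw$conc)) stop("concentrations must be nondecreasing", call. = FALSE)
  FF <- raw$F
  applied <- character()
  if (isTRUE(attr(raw, "corrected"))) {
    stop("series is already corrected; corrections are applied at most once",
         call. = FALSE)
  }
  if (dilution) {
    if (is.null(V0) || !"added_volume" %in% names(raw)) {
      stop("dilution correction needs `V0` and an `added_volume` column",
           call. = FALSE)
    }
    FF <- FF * (V0 + raw$added_volume) / V0
    applied <- c(applied, "dilution")
  }
  if (!is.null(ligand_background)) {
    FF <- FF - ligand_background * raw$conc
    applied <- c(applied, "ligand_background")
  }
  out <- tibble::tibble(conc = raw$conc, F = FF)
  class(out) <- c("sf_titration", class(out))
  for (a in c("P0", "ligand", "co_conc", "sigma")) {
    attr(out, a) <- attr(raw, a)
  }
  attr(out, "corrections") <- applied
  attr(out, "corrected") <- TRUE
  out
}

#' Fit an equilibrium binding isotherm
#'
#' Default model is the hyperbola `F = F0 + dF_max * [L] / (KD_app + [L])`
#' in total ligand concentration — adequate when the protein concentration is
#' well below KD. When the protein concentration exceeds `KD_app/5` the bound
#' ligand depletes the free pool and the hyperbola is biased; the
#' ligand-depletion (quadratic) form
#' `bound = ((P + L + KD) - sqrt((P + L + KD)^2 - 4 P L)) / 2`,
#' `F = F0 + dF_max * bound / P`, is then selected automatically
#' (`model = "auto"`, decided from a pilot hyperbolic fit).
#'
#' @param series An `sf_titration` (or data frame with `conc`, `F`).
#' @param P0 Protein concentration (uM); taken from the series metadata when
#'   absent.
#' @param model `"auto"`, `"hyperbolic"` or `"quadratic"`.
#' @return An object of class `titration_fit`: `coef` tibble (`KD_app`,
#'   `dF_max`, `F0`), the model used, `rss`, residuals, and a
#'   `saturation_warning` flag when the largest concentration is below 2x the
#'   fitted KD.
#' @examples
#' s <- tibble::tibble(conc = c(0, 1, 2, 5, 10, 20, 50),
#'                     F = 1 - 0.8 * conc / (5 + conc))
#' fit_binding_isotherm(s)$coef
#' @export
fit_binding_isotherm <- function(series, P0 = NULL,
                                 model = c("auto", "hyperbolic", "quadratic")) {
  model <- match.arg(model)
  conc <- series$conc; FF <- series$F
  if (length(conc) < 6) stop("need >= 6 concentrations", call. = FALSE)
  P0 <- P0 %||% attr(series, "P0")

  fit_one <- function(quadratic) {
    pred <- function(KD, dF, F0) {
      if (quadratic) {
        b <- ((P0 + conc + KD) - sqrt((P0 + conc + KD)^2 - 4 * P0 * conc)) / 2
        F0 + dF * b / P0
      } else {
        F0 + dF * conc / (KD + conc)
      }
    }
    resid_fn <- function(par) FF - pred(exp(par[1]), par[2], par[3])
    kd_grid <- exp(seq(log(max(min(conc[conc > 0]), 1e-3) / 2),
                       log(max(conc) * 4), length.out = 5))
    best <- NULL
    for (kd in kd_grid) {
      x <- if (quadratic) {
        b <- ((P0 + conc + kd) - sqrt((P0 + conc + kd)^2 - 4 * P0 * conc)) / 2
        b / P0
      } else conc / (kd + conc)
      ab <- qr.coef(qr(cbind(x, 1)), FF)
      fit <- tryCatch(
        minpack.lm::nls.lm(c(log(kd), ab[1], ab[2]), fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
    if (is.null(best)) stop("binding isotherm fit failed to converge", call. = FALSE)
    best
  }

  use_quad <- switch(model, hyperbolic = FALSE, quadratic = TRUE, auto = {
    pilot <- fit_one(FALSE)
    kd_pilot <- exp(pilot$par[1])
    !is.null(P0) && P0 > kd_pilot / 5
  })
  if (use_quad && is.null(P0)) {
    stop("ligand-depletion fit needs the protein concentration `P0`", call. = FALSE)
  }
  best <- fit_one(use_quad)
  KD <- exp(best$par[1]); dF <- best$par[2]; F0 <- best$par[3]
  n <- length(conc)
  s2 <- best$deviance / max(n - 3, 1)
  cov_i <- tryCatch(s2 * solve(best$hessian / 2),
                    error = function(e) matrix(NA_real_, 3, 3))
  se3 <- sqrt(pmax(diag(cov_i), 0))
  sat_warn <- max(conc) < 2 * KD
  if (sat_warn) {
    warning("largest ligand concentration < 2x fitted KD: apparent KD is ",
            "poorly determined", call. = FALSE)
  }
  resid <- if (use_quad) {
    b <- ((P0 + conc + KD) - sqrt((P0 + conc + KD)^2 - 4 * P0 * conc)) / 2
    FF - (F0 + dF * b / P0)
  } else {
    FF - (F0 + dF * conc / (KD + conc))
  }
  structure(list(
    coef = tibble::tibble(term = c("KD_app", "dF_max", "F0"),
                          estimate = as.numeric(c(KD, dF, F0)),
                          se = as.numeric(c(KD * se3[1], se3[2], se3[3]))),
    model = if (use_quad) "quadratic" else "hyperbolic",
    rss = best$deviance, residuals = resid, fitted = FF - resid,
    data = tibble::tibble(conc = conc, F = FF), P0 = P0,
    saturation_warning = sat_warn), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> ", x$model, ": KD_app = ",
      signif(x$coef$estimate[1], 4), " +/- ", signif(x$coef$se[1], 2),
      " uM\n", sep = "")
  invisible(x)
}

#' Predict the apparent KD of a ligand from the ternary scheme
#'
#' Scans [equilibrium_state()] of the TERNARY scheme over the free
#' concentration of the titrated ligand (trace enzyme, so total = free) at a
#' fixed co-ligand concentration, and returns the ligand concentration at
#' half-maximal total enzyme-bound ligand species. Coupling through the
#' loop-closing step (`K4 = k4/km4`) tightens the apparent affinity: at
#' saturating co-ligand the closed-form limit is `KD_intrinsic / (1 + K4)`.
#'
#' @param params TERNARY rate constants.
#' @param ligand `"I"` or `"A"`: the titrated ligand.
#' @param co_conc Fixed co-ligand concentration (uM), `>= 0`.
#' @param E0 Trace enzyme concentration used in the scan (uM).
#' @return Apparent KD (uM).
#' @export
predict_apparent_kd <- function(params, ligand = c("A", "I"), co_conc = 0,
                                E0 = 1e-4) {
  ligand <- match.arg(ligand)
  scheme <- build_scheme("TERNARY")
  stopifnot(co_conc >= 0)
  bound_frac <- function(L) {
    totals <- if (ligand == "I") c(E = E0, I = L, A = co_conc)
              else c(E = E0, A = L, I = co_conc)
    eq <- equilibrium_state(scheme, params, totals)
    b <- if (ligand == "I") eq[["EI"]] + eq[["EIA"]] + eq[["EIA_c"]]
         else eq[["EA"]] + eq[["EIA"]] + eq[["EIA_c"]]
    b / E0
  }
  kd_int <- if (ligand == "I") params[["km2"]] / params[["k2"]]
            else params[["km3"]] / params[["k3"]]
  # bound fraction is L/(L + KD_app): solve bound_frac(L) = 1/2
  lo <- kd_int * 1e-4; hi <- kd_int * 1e4
  stats::uniroot(function(L) bound_frac(L) - 0.5, c(lo, hi), tol = kd_int * 1e-9)$root
}

#' Ternary-complex synergy report
#'
#' Compares the apparent KD of a ligand measured alone (binary) and in the
#' presence of the co-ligand (ternary): `ratio = KD_binary / KD_ternary`
#' (> 1 = synergistic: the co-ligand tightens binding), together with the
#' fluorescence amplitude comparison — ternary-complex formation typically
#' produces a larger signal change when it drives a conformational change.
#'
#' @param fit_binary,fit_ternary `titration_fit`s of the same ligand on the
#'   same enzyme variant, without and with the co-ligand.
#' @param ligand,ligand_ternary Names of the titrated ligand in the two fits
#'   (must match).
#' @return An object of class `synergy_report`: `ratio` with propagated SE,
#'   amplitude ratio, and `flag` in `synergistic`/`neutral`/`antagonistic`.
#' @export
synergy <- function(fit_binary, fit_ternary, ligand = "A",
                    ligand_ternary = ligand) {
  if (!identical(ligand, ligand_ternary)) {
    stop("synergy compares titrations of the same ligand", call. = FALSE)
  }
  kd_b <- as.numeric(fit_binary$coef$estimate[1])
  se_b <- as.numeric(fit_binary$coef$se[1])
  kd_t <- as.numeric(fit_ternary$coef$estimate[1])
  se_t <- as.numeric(fit_ternary$coef$se[1])
  amp_b <- fit_binary$coef$estimate[2]; amp_t <- fit_ternary$coef$estimate[2]
  ratio <- kd_b / kd_t
  se_ratio <- ratio * sqrt((se_b / kd_b)^2 + (se_t / kd_t)^2)
  flag <- if (ratio - 1 > 1.96 * se_ratio) "synergistic"
          else if (1 - ratio > 1.96 * se_ratio) "antagonistic"
          else "neutral"
  structure(list(ratio = ratio, se = se_ratio,
                 kd_binary = kd_b, kd_ternary = kd_t,
                 amp_ratio = amp_t / amp_b, flag = flag),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("<synergy_report> ", x$flag, ": KD ", signif(x$kd_binary, 4), " -> ",
      signif(x$kd_ternary, 4), " uM (ratio ", signif(x$ratio, 3), " +/- ",
      signif(x$se, 2), "), amplitude x", signif(x$amp_ratio, 3), "\n", sep = "")
  invisible(x)
}
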