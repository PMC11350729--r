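# broom-style tidiers: tidy() returns the per-term coefficient table,
# glance() a one-row model summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_phases = x$n_phases, rss = x$rss, sigma = x$sigma,
                 aicc = x$aicc, nobs = nrow(x$data), converged = x$converged)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.secondary_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.secondary_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, aicc = x$aicc,
                 nobs = nrow(x$data),
                 identifiability_warning = x$identifiability_warning)
}

#' Tidiers for stopflow fit objects
#'
#' `tidy()` methods return one row per fitted parameter (`term`, `estimate`,
#' `se`, plus fit-specific columns); `glance()` methods return a one-row
#' summary (fit size, residual sum of squares, AICc, convergence).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.global_fit_result <- function(x, ...) x$coef

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.global_fit_result <- function(x, ...) {
  tibble::tibble(n_traces = length(x$traces), nobs = x$n_obs,
                 n_par = x$n_par, rss = x$rss, aicc = x$aicc,
                 engine = x$engine, converged = x$converged,
                 n_flagged = sum(x$coef$flagged))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, rss = x$rss, E_tot = x$E_tot,
                 identifiability_warning = x$identifiability_warning)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.titration_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.titration_fit <- function(x, ...) {
  tibble::tibble(model = x$model, nobs = nrow(x$data), rss = x$rss,
                 saturation_warning = x$saturation_warning)
}
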