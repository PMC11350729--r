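# ggplot2 autoplot() methods for traces and fit objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods: a trace plots signal vs time; fit objects overlay
#' data and fitted curve (secondary plots on a log concentration axis when
#' the range warrants it).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name stopflow-autoplot
NULL

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.sf_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = attr(object, "observable") %||% "signal",
                  subtitle = attr(object, "mix")) +
    ggplot2::theme_minimal()
}

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.exp_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "signal",
                  subtitle = paste0(object$n_phases, "-phase exponential fit")) +
    ggplot2::theme_minimal()
}

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.secondary_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(conc = seq(min(df$conc), max(df$conc),
                                    length.out = 200))
  cf <- stats::setNames(object$coef$estimate, object$coef$term)
  grid$kobs <- if (object$model == "linear") {
    cf[["km1"]] + cf[["k1"]] * grid$conc
  } else {
    cf[["kmconf"]] + cf[["kconf"]] * grid$conc / (cf[["KD1"]] + grid$conc)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$conc, .data$kobs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "ligand (uM)", y = "kobs (1/s)",
                  subtitle = paste0(object$model, " secondary plot")) +
    ggplot2::theme_minimal()
}

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, ...) {
  df <- object$data
  cf <- stats::setNames(object$coef$estimate, object$coef$term)
  grid <- tibble::tibble(S = seq(0, max(df$S), length.out = 200))
  grid$v <- cf[["kcat"]] * object$E_tot * grid$S / (cf[["KM"]] + grid$S)
  ggplot2::ggplot(df, ggplot2::aes(.data$S, .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "substrate (uM)", y = "v (uM/s)",
                  subtitle = "Michaelis-Menten fit") +
    ggplot2::theme_minimal()
}

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.titration_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "ligand (uM)", y = "fluorescence",
                  subtitle = paste0(object$model, " binding isotherm")) +
    ggplot2::theme_minimal()
}

#' @rdname stopflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.global_fit_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(seq_along(object$traces), function(i) {
    tibble::tibble(trace = factor(i), time = object$traces[[i]]$time,
                   signal = object$traces[[i]]$signal,
                   fitted = object$fitted[[i]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.2,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.3) +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
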