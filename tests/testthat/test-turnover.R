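test_that("absorbance slopes convert to velocities with the assay constants", {
  expect_equal(absorbance_to_velocity(1.08231e-3), 0.192, tolerance = 1e-4)
  expect_equal(absorbance_to_velocity(0), 0)
  expect_equal(absorbance_to_velocity(5.637e-3), 1.0)
  # round trip A <-> uM is exact
  v <- 0.37
  expect_equal(absorbance_to_velocity(v * 0.005637), v)
  # sign is immaterial (the substrate signal decreases)
  expect_equal(absorbance_to_velocity(-5.637e-3), 1.0)
})

test_that("steady-state velocities survive a planted mixing burst", {
  # pure linear depletion, no burst
  tt <- seq(0, 20, 0.05)
  curve <- tibble::tibble(time = tt, absorbance = 0.3 - 0.2 * 0.005637 * tt)
  class(curve) <- c("sf_progress", class(curve))
  attr(curve, "S0") <- 50; attr(curve, "mode") <- "multiple_turnover"
  r <- extract_steady_velocity(curve)
  expect_equal(r$v, 0.2, tolerance = 1e-8)

  # planted burst (amp 0.05 A, 30/s) on top of the linear phase
  curve2 <- curve
  curve2$absorbance <- curve2$absorbance + 0.05 * exp(-30 * tt)
  r2 <- extract_steady_velocity(curve2)
  expect_lt(abs(r2$v - 0.2) / 0.2, 0.01)
  expect_equal(r2$burst$rate, 30, tolerance = 0.05)

  # control curve (null input): no depletion, v indistinguishable from 0
  ctrl <- gen_progress_curves(cycle_truth(), 10, mode = "control",
                              sigma = 2e-4, seed = 5)[[1]]
  rc <- extract_steady_velocity(ctrl)
  expect_lt(rc$v, 3 * rc$se + 1e-4)
})

test_that("Michaelis-Menten fits recover generating parameters", {
  S <- c(1, 2, 4, 8, 16, 40)
  E0 <- 0.1
  v <- 2.4 * E0 * S / (4.5 + S)
  mm <- fit_michaelis_menten(tibble::tibble(S = S, v = v), E0)
  est <- setNames(mm$coef$estimate, mm$coef$term)
  expect_equal(est[["kcat"]], 2.4, tolerance = 1e-5)
  expect_equal(est[["KM"]], 4.5, tolerance = 1e-5)
  expect_equal(est[["kcat_over_KM"]], 2.4 / 4.5e-6, tolerance = 1e-5)

  # saturation sanity: v/E at S >> KM approaches kcat
  expect_equal(v[6] / E0, 2.4 * 40 / 44.5, tolerance = 1e-12)

  expect_error(fit_michaelis_menten(tibble::tibble(S = S, v = rep(0, 6)), E0),
               "no signal")

  # 5% noise, two replicates per concentration: within 10%
  withr::with_seed(13, {
    Sr <- rep(S, 2)
    vr <- (2.4 * E0 * Sr / (4.5 + Sr)) * (1 + 0.05 * rnorm(12))
    mmn <- fit_michaelis_menten(tibble::tibble(S = Sr, v = vr), E0)
  })
  expect_equal(mmn$coef$estimate[1], 2.4, tolerance = 0.1)
  expect_equal(mmn$coef$estimate[2], 4.5, tolerance = 0.1 * 4.5)
})

test_that("error propagation reproduces the published specificity constants", {
  p_wt <- propagate_kcat_over_km(2.4, 0.2, 4.5, 0.5)
  expect_equal(signif(p_wt$value, 2), 5.3e5)
  expect_equal(signif(p_wt$se, 1), 0.7e5)

  p_f23a <- propagate_kcat_over_km(5.5e-3, 0.4e-3, 6.8, 1.3)
  expect_equal(signif(p_f23a$value, 2), 8.1e2)
  # the printed SE (1.6e2) comes from unrounded inputs; printed-input
  # arithmetic gives 1.65e2 - equal to the printed precision of one digit-unit
  expect_lt(abs(p_f23a$se - 1.6e2), 10)

  p_unit <- propagate_kcat_over_km(1, 0, 1, 0)
  expect_equal(p_unit$value, 1e6)
  expect_equal(p_unit$se, 0)
})

test_that("kcat upper limits scale with the detection threshold", {
  expect_equal(kcat_upper_limit(2e-4, 0.1), 2e-3)
  expect_warning(b0 <- kcat_upper_limit(0, 0.1), "degenerate")
  expect_equal(b0, 0)
  expect_equal(kcat_upper_limit(2e-4, 0.2), kcat_upper_limit(2e-4, 0.1) / 2)
})

test_that("single-turnover fits return the decay rate and enforce enzyme excess", {
  tt <- seq(0, 3, 0.01)
  curve <- tibble::tibble(time = tt, absorbance = 0.05 * exp(-2 * tt) + 0.01)
  class(curve) <- c("sf_progress", class(curve))
  attr(curve, "E_tot") <- 20; attr(curve, "S0") <- 10
  attr(curve, "mode") <- "single_turnover"
  st <- fit_single_turnover(curve)
  expect_equal(st$kobs, 2.0, tolerance = 1e-6)

  attr(curve, "E_tot") <- 5
  expect_error(fit_single_turnover(curve), "mode violation")
  expect_error(gen_progress_curves(cycle_truth(), 10, mode = "single_turnover",
                                   E0 = 5), "2x the substrate")
})

test_that("single-turnover rates are substrate-independent for slow chemistry", {
  curves <- gen_progress_curves(cycle_truth(), c(2.5, 5, 10),
                                mode = "single_turnover", sigma = 1e-4,
                                seed = 17)
  tb <- single_turnover_summary(curves)
  expect_lt((max(tb$kobs) - min(tb$kobs)) / mean(tb$kobs), 0.04)
})

test_that("the rate-limiting verdict follows the turnover ratio", {
  mm_like <- structure(list(coef = tibble::tibble(
    term = c("kcat", "KM", "kcat_over_KM"),
    estimate = c(2.4, 4.5, 5.3e5), se = c(0.2, 0.5, 0.7e5))), class = "mm_fit")
  st <- tibble::tibble(S0 = c(2.5, 5, 10), kobs = c(2.0, 2.1, 1.9),
                       se = rep(0.05, 3))
  d <- diagnose_rate_limiting(mm_like, st)
  expect_equal(d$verdict, "chemistry rate-limiting")

  st_fast <- dplyr::mutate(st, kobs = kobs * 10)
  d2 <- diagnose_rate_limiting(mm_like, st_fast)
  expect_match(d2$verdict, "product release")

  st_same <- tibble::tibble(S0 = 1, kobs = 2.4, se = 0.1)
  d3 <- diagnose_rate_limiting(mm_like, st_same)
  expect_equal(d3$ratio, 1)
  expect_equal(d3$verdict, "chemistry rate-limiting")
})
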