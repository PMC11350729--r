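test_that("titration corrections are exact and applied at most once", {
  raw <- tibble::tibble(conc = c(0, 1, 2, 5, 10, 20),
                        F = rep(2, 6), added_volume = c(0, 2, 4, 10, 20, 40))
  # zero added volume: identity
  raw0 <- dplyr::mutate(raw, added_volume = 0)
  out0 <- preprocess_titration(raw0, dilution = TRUE, V0 = 2000)
  expect_equal(out0$F, raw0$F)

  # constant true signal diluted by up to 10%: correction restores it
  V0 <- 400
  diluted <- dplyr::mutate(raw, F = 2 * V0 / (V0 + added_volume))
  out <- preprocess_titration(diluted, dilution = TRUE, V0 = V0)
  expect_equal(out$F, rep(2, 6), tolerance = 1e-12)

  # planted linear ligand background removed exactly
  b <- 0.013
  withbg <- dplyr::mutate(raw, F = 1 - 0.5 * conc / (5 + conc) + b * conc)
  outbg <- preprocess_titration(withbg, ligand_background = b)
  expect_equal(outbg$F, 1 - 0.5 * raw$conc / (5 + raw$conc), tolerance = 1e-12)

  expect_error(preprocess_titration(dplyr::select(raw, -added_volume),
                                    dilution = TRUE, V0 = 400), "added_volume")
  expect_error(preprocess_titration(out, ligand_background = 0.1),
               "at most once")
})

test_that("binding isotherms are recovered exactly and depletion is handled", {
  conc <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  s <- tibble::tibble(conc = conc, F = 1 - 0.8 * conc / (5 + conc))
  f <- fit_binding_isotherm(s, P0 = 0.01)
  est <- setNames(f$coef$estimate, f$coef$term)
  expect_equal(est[["KD_app"]], 5, tolerance = 1e-6)
  expect_equal(est[["dF_max"]], -0.8, tolerance = 1e-6)
  expect_equal(f$model, "hyperbolic")

  # protein at 1 uM, KD 0.5 uM: strong depletion regime
  dep <- gen_titration_series("ONE_STEP", rate_params(k1 = 1, km1 = 0.5),
                              concs = c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 50),
                              P0 = 1, sigma = 0)
  fq <- fit_binding_isotherm(dep)
  expect_equal(fq$model, "quadratic")
  expect_equal(fq$coef$estimate[1], 0.5, tolerance = 0.01 * 0.5)
  # the plain hyperbola is biased on the same data
  fh <- fit_binding_isotherm(dep, model = "hyperbolic")
  expect_gt(abs(fh$coef$estimate[1] - 0.5) / 0.5, 0.05)

  # under-sampled isotherm (max conc = KD/4) warns
  lowc <- tibble::tibble(conc = seq(0, 1.25, length.out = 7),
                         F = 1 - 0.8 * seq(0, 1.25, length.out = 7) /
                           (5 + seq(0, 1.25, length.out = 7)))
  expect_warning(fit_binding_isotherm(lowc, P0 = 0.01), "poorly determined")
})

test_that("ternary coupling tightens the predicted apparent KD", {
  p <- rate_params(k2 = 100, km2 = 5000, k3 = 100, km3 = 20000,
                   k4 = 4, km4 = 1)
  # no co-ligand: intrinsic KD
  expect_equal(predict_apparent_kd(p, "A", co_conc = 0), 200, tolerance = 1e-5)
  # saturating co-ligand: KD/(1 + K4) = 200/5 (trace enzyme and a very
  # large co-ligand reservoir make the analytic limit exact)
  expect_equal(predict_apparent_kd(p, "A", co_conc = 1e9, E0 = 1e-6), 40,
               tolerance = 1e-6)
  # no loop closure (k4 = 0): co-ligand changes nothing
  p0 <- rate_params(k2 = 100, km2 = 5000, k3 = 100, km3 = 20000,
                    k4 = 0, km4 = 1)
  expect_equal(predict_apparent_kd(p0, "A", co_conc = 1e6), 200,
               tolerance = 1e-5)
})

test_that("synergy reports compare apparent affinities and amplitudes", {
  mk_fit <- function(kd, se, amp) {
    structure(list(coef = tibble::tibble(
      term = c("KD_app", "dF_max", "F0"),
      estimate = c(kd, amp, 1), se = c(se, 0.01, 0.01))),
      class = "titration_fit")
  }
  rep1 <- synergy(mk_fit(100, 5, -0.3), mk_fit(50, 2.5, -0.9))
  expect_equal(rep1$ratio, 2)
  expect_equal(rep1$flag, "synergistic")
  expect_equal(rep1$amp_ratio, 3)

  rep2 <- synergy(mk_fit(100, 5, -0.3), mk_fit(100, 5, -0.3))
  expect_equal(rep2$flag, "neutral")

  expect_error(synergy(mk_fit(1, 0.1, 1), mk_fit(1, 0.1, 1),
                       ligand = "A", ligand_ternary = "I"), "same ligand")

  # rescaling every signal leaves the synergy ratio untouched
  rep3 <- synergy(mk_fit(100, 5, -3), mk_fit(50, 2.5, -9))
  expect_equal(rep3$ratio, rep1$ratio)
})

test_that("simulated ternary titrations reproduce the predicted synergy", {
  p <- rate_params(k2 = 100, km2 = 5000, k3 = 100, km3 = 20000,
                   k4 = 4, km4 = 1)
  concs <- c(0, 10, 25, 50, 100, 200, 400, 800, 2000)
  bin <- gen_titration_series("TERNARY", p, concs, P0 = 1, ligand = "A",
                              co_conc = 0, sigma = 0)
  ter <- gen_titration_series("TERNARY", p, concs, P0 = 1, ligand = "A",
                              co_conc = 5000, sigma = 0)
  f_bin <- fit_binding_isotherm(bin)
  f_ter <- fit_binding_isotherm(ter)
  rep <- synergy(f_bin, f_ter)
  predicted <- predict_apparent_kd(p, "A", 0) /
    predict_apparent_kd(p, "A", 5000)
  expect_equal(rep$ratio, predicted, tolerance = 0.1)
  expect_equal(rep$flag, "synergistic")
})
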