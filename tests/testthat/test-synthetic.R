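test_that("generators are deterministic under a fixed seed", {
  p <- induced_fit_truth()
  a <- gen_transient_series("INDUCED_FIT", p, concs = c(5, 20), seed = 3,
                            n_points = 50)
  b <- gen_transient_series("INDUCED_FIT", p, concs = c(5, 20), seed = 3,
                            n_points = 50)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))

  t1 <- gen_titration_series("ONE_STEP", rate_params(k1 = 1, km1 = 5),
                             concs = 0:6 * 5, sigma = 0.01, seed = 9)
  t2 <- gen_titration_series("ONE_STEP", rate_params(k1 = 1, km1 = 5),
                             concs = 0:6 * 5, sigma = 0.01, seed = 9)
  expect_identical(t1$F, t2$F)

  g1 <- gen_ternary_dataset(ternary_truth(), sigma = 0.01, seed = 4,
                            n_points = 30)
  g2 <- gen_ternary_dataset(ternary_truth(), sigma = 0.01, seed = 4,
                            n_points = 30)
  expect_identical(g1[[7]]$signal, g2[[7]]$signal)
})

test_that("zero-noise traces equal the deterministic projection", {
  p <- rate_params(k1 = 0.1, km1 = 1)
  ds <- gen_transient_series("ONE_STEP", p, concs = 10, E0 = 0.1, sigma = 0,
                             seed = 1, n_points = 80)
  sc <- build_scheme("ONE_STEP")
  tt <- seq(0, 5 / 2, length.out = 81)
  traj <- integrate_scheme(sc, p, c(E = 0.1, S = 10), tt, method = "pfo")
  ref <- project_observable(traj, c(ES = -1), c0 = 1, t_dead = 0.002)
  expect_equal(ds[[1]]$signal, ref$signal, tolerance = 1e-12)
})

test_that("noisy replicates average to the noiseless trace", {
  p <- rate_params(k1 = 0.1, km1 = 1)
  ref <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = 0, seed = 1,
                              n_points = 40)[[1]]
  sig <- 0.02
  acc <- matrix(0, 200, nrow(ref))
  for (r in 1:200) {
    acc[r, ] <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = sig,
                                     sigma_mode = "absolute", seed = 100 + r,
                                     n_points = 40)[[1]]$signal
  }
  dev <- abs(colMeans(acc) - ref$signal)
  expect_true(all(dev < 3 * sig / sqrt(200) + 1e-12))
})

test_that("the noise realisation matches the configured sigma", {
  p <- rate_params(k1 = 0.1, km1 = 1)
  sig <- 0.015
  ds <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = sig,
                             sigma_mode = "absolute", seed = 8,
                             n_points = 10000)
  ref <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = 0, seed = 8,
                              n_points = 10000)
  noise <- ds[[1]]$signal - ref[[1]]$signal
  n <- length(noise)
  # chi-square interval on the variance at alpha = 0.01
  stat <- (n - 1) * stats::var(noise) / sig^2
  expect_gt(stat, stats::qchisq(0.005, n - 1))
  expect_lt(stat, stats::qchisq(0.995, n - 1))
  expect_lt(abs(mean(noise)), 3 * sig / sqrt(n))
})

test_that("shot averaging scales the noise by 1/sqrt(n)", {
  p <- rate_params(k1 = 0.1, km1 = 1)
  ref <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = 0, seed = 8,
                              n_points = 4000)[[1]]$signal
  one <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = 0.02,
                              sigma_mode = "absolute", n_avg = 1, seed = 8,
                              n_points = 4000)[[1]]$signal
  avg <- gen_transient_series("ONE_STEP", p, concs = 10, sigma = 0.02,
                              sigma_mode = "absolute", n_avg = 25, seed = 8,
                              n_points = 4000)[[1]]$signal
  expect_equal(stats::sd(avg - ref) / stats::sd(one - ref), 1 / 5,
               tolerance = 0.1)
})

test_that("the ternary dataset has the canonical 16-trace design", {
  # default sampling (1 ms steps) resolves the 2 ms dead time, which the
  # obscured-fraction diagnostic needs
  ds <- gen_ternary_dataset(ternary_truth(), sigma = 0)
  expect_length(ds, 16)
  truth <- attr(ds, "truth")
  expect_s3_class(truth, "sf_truth")
  expect_equal(truth$scheme_id, "TERNARY")
  # binary-only mixes relax at k2*I or k3*A >= 10000/s: lost in the dead time
  binary <- vapply(ds[1:6], attr, logical(1), "obscured")
  expect_true(all(binary))
  frac <- vapply(ds[1:6], attr, numeric(1), "pre_dead_fraction")
  expect_true(all(frac >= 0.86))
})

test_that("progress-curve generation matches steady-state theory", {
  # control curves carry no net depletion
  ctrl <- gen_progress_curves(cycle_truth(), 10, mode = "control", sigma = 0,
                              seed = 1)[[1]]
  expect_lt(abs(ctrl$absorbance[nrow(ctrl)] - ctrl$absorbance[1]), 1e-9)

  # chemistry-limited: steady-state v/E at S0 >> KM (KM ~ 2 uM here, so
  # 400 uM is deep saturation) equals kchem within 2%
  p <- rate_params(kon = 10, koff = 20, kchem = 0.5, krel = 50)
  mt <- gen_progress_curves(p, 400, mode = "multiple_turnover", sigma = 0,
                            seed = 1, E0 = 0.1)[[1]]
  r <- extract_steady_velocity(mt)
  expect_equal(r$v / 0.1, 0.5, tolerance = 0.02)
})

test_that("free ammonia follows the Henderson-Hasselbalch fraction", {
  expect_equal(free_ammonia(100, pH = 8.5, pKa = 9.27), 14.52,
               tolerance = 1e-3)
  # the canonical worked value: 100 mM total at pH 8.5 is ~14.4 mM free base
  expect_equal(free_ammonia(100, pH = 8.5, pKa = 9.27), 14.4, tolerance = 0.01)
  expect_equal(free_ammonia(80, pH = 9.27, pKa = 9.27), 40)
  expect_equal(free_ammonia(100, pH = 13.9, pKa = 9.27), 100, tolerance = 1e-3)
  expect_error(free_ammonia(-1), "> 0")
  expect_error(free_ammonia(100, pH = 15), "0, 14")
})
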