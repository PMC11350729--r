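test_that("the separable step is the optimum of the linear subproblem", {
  # small instance: one trace, one response species; compare the profiled
  # linear solution against a brute-force grid over (offset, response)
  sc <- build_scheme("ONE_STEP")
  p <- rate_params(k1 = 0.1, km1 = 1)
  ds <- gen_transient_series("ONE_STEP", p, concs = c(5, 10), E0 = 0.1,
                             sigma = 0.02, seed = 4, n_points = 60)
  fit <- global_fit(ds, sc, start = p, n_starts = 1,
                    share_responses = FALSE)
  p_hat <- rate_params(k1 = fit$coef$estimate[fit$coef$term == "k1"],
                       km1 = fit$coef$estimate[fit$coef$term == "km1"])
  for (i in 1:2) {
    traj <- integrate_scheme(sc, p_hat, attr(ds[[i]], "conc0"), ds[[i]]$time,
                             method = "pfo")
    ssr_fit <- sum((ds[[i]]$signal - fit$fitted[[i]])^2)
    cf <- fit$responses[fit$responses$trace == i, ]
    best_grid <- Inf
    for (off in seq(0.9, 1.1, length.out = 41)) {
      for (r in seq(-1.3, -0.7, length.out = 41)) {
        ssr <- sum((ds[[i]]$signal - off - r * traj$ES)^2)
        best_grid <- min(best_grid, ssr)
      }
    }
    expect_lte(ssr_fit, best_grid + 1e-12)
  }
})

test_that("noiseless ternary data are recovered from perturbed starts", {
  truth <- ternary_truth()
  ds <- gen_ternary_dataset(truth, sigma = 0)
  start <- rate_params(k2 = 30, km2 = 2000, k3 = 300, km3 = 5000,
                       k4 = 20, km4 = 5)
  fit <- global_fit(ds, build_scheme("TERNARY"), start = start,
                    n_starts = 5, seed = 7)
  rel <- abs(fit$coef$estimate - truth[fit$coef$term]) / truth[fit$coef$term]
  expect_lt(max(rel), 5e-5)  # >= 4 significant digits
})

test_that("an under-determined single-trace fit is flagged, not silently reported", {
  truth <- ternary_truth()
  ds <- gen_ternary_dataset(truth, sigma = 0.01, seed = 9)
  expect_warning(
    fit1 <- global_fit(ds[1], build_scheme("TERNARY"), start = truth,
                       n_starts = 1),
    "under-determined")
  expect_gte(sum(fit1$coef$flagged), 1)
})

test_that("bootstrap intervals are deterministic and collapse on noiseless data", {
  truth <- ternary_truth()
  ds <- gen_ternary_dataset(truth, sigma = 0, n_points = 60)
  fit <- global_fit(ds, build_scheme("TERNARY"), start = truth, n_starts = 1)
  suppressWarnings({
    ci_a <- bootstrap_ci(fit, n_boot = 20, seed = 11)
    ci_b <- bootstrap_ci(fit, n_boot = 20, seed = 11)
  })
  expect_equal(ci_a, ci_b)
  expect_lt(max((ci_a$upper - ci_a$lower) / ci_a$estimate), 1e-6)
})

test_that("model discrimination prefers the generating scheme", {
  p_if <- induced_fit_truth()
  ds <- gen_transient_series("INDUCED_FIT", p_if, concs = c(2, 5, 10, 20, 40),
                             E0 = 0.1, sigma = 0.005, seed = 21, n_points = 120)
  fit_if <- global_fit(ds, build_scheme("INDUCED_FIT"), start = p_if,
                       n_starts = 1)
  fit_one <- global_fit(ds, build_scheme("ONE_STEP"),
                        start = rate_params(k1 = 1, km1 = 10), n_starts = 3,
                        seed = 2)
  cmp <- compare_models(fit_if, fit_one)
  expect_equal(cmp$preferred, "A")
  expect_lt(cmp$delta_aicc, -10)

  # one-step data: the one-step description is never beaten by > 2
  p1 <- rate_params(k1 = 0.5, km1 = 5)
  ds1 <- gen_transient_series("ONE_STEP", p1, concs = c(2, 5, 10, 20, 40),
                              E0 = 0.1, sigma = 0.005, seed = 22, n_points = 120)
  f1 <- global_fit(ds1, build_scheme("ONE_STEP"), start = p1, n_starts = 1)
  f2 <- global_fit(ds1, build_scheme("INDUCED_FIT"),
                   start = rate_params(k1 = 0.5, km1 = 5, kconf = 5, kmconf = 1),
                   n_starts = 3, seed = 3)
  cmp2 <- compare_models(f1, f2)
  expect_true(cmp2$preferred %in% c("A", "indistinguishable"))

  # identical fits are indistinguishable with delta exactly 0
  cmp3 <- compare_models(f1, f1)
  expect_equal(cmp3$delta_aicc, 0)
  expect_equal(cmp3$preferred, "indistinguishable")

  expect_error(compare_models(fit_if, f1), "different datasets")
})

test_that("AICc ordering is invariant under common signal rescaling", {
  p1 <- rate_params(k1 = 0.5, km1 = 5)
  ds <- gen_transient_series("ONE_STEP", p1, concs = c(2, 5, 10, 20),
                             E0 = 0.1, sigma = 0.01, seed = 31, n_points = 60)
  scale_ds <- function(ds, c) {
    out <- ds
    for (i in seq_along(out)) out[[i]]$signal <- out[[i]]$signal * c
    out
  }
  fit_a1 <- global_fit(ds, build_scheme("ONE_STEP"), start = p1, n_starts = 1)
  fit_b1 <- global_fit(ds, build_scheme("INDUCED_FIT"),
                       start = rate_params(k1 = 0.5, km1 = 5, kconf = 2, kmconf = 0.5),
                       n_starts = 1)
  ds10 <- scale_ds(ds, 10)
  fit_a2 <- global_fit(ds10, build_scheme("ONE_STEP"), start = p1, n_starts = 1)
  fit_b2 <- global_fit(ds10, build_scheme("INDUCED_FIT"),
                       start = rate_params(k1 = 0.5, km1 = 5, kconf = 2, kmconf = 0.5),
                       n_starts = 1)
  d1 <- fit_a1$aicc - fit_b1$aicc
  d2 <- fit_a2$aicc - fit_b2$aicc
  expect_equal(d1, d2, tolerance = 0.05)
})

test_that("derived equilibrium constants are recomputed from the estimates", {
  truth <- ternary_truth()
  ds <- gen_ternary_dataset(truth, sigma = 0, n_points = 60)
  fit <- global_fit(ds, build_scheme("TERNARY"), start = truth, n_starts = 1)
  d <- derived_constants_fit(fit)
  est <- setNames(fit$coef$estimate, fit$coef$term)
  expect_equal(d$value[d$name == "K4"], est[["k4"]] / est[["km4"]])
  expect_equal(d$value[d$name == "KD2"], est[["km2"]] / est[["k2"]])
})
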