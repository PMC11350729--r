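test_that("no association means no complex", {
  sc <- build_scheme("ONE_STEP")
  tr <- integrate_scheme(sc, rate_params(k1 = 0, km1 = 1), c(E = 1, S = 10),
                         seq(0, 5, 0.1))
  expect_true(all(tr$ES == 0))
})

test_that("one-step pseudo-first-order kinetics match the closed form", {
  sc <- build_scheme("ONE_STEP")
  p <- rate_params(k1 = 0.1, km1 = 1)
  tt <- seq(0, 3, 0.005)
  E0 <- 0.1; S0 <- 10
  kobs <- 0.1 * S0 + 1
  closed <- E0 * S0 / (10 + S0) * (1 - exp(-kobs * tt))
  # clamped-ligand ODE (the PFO approximation integrated numerically)
  ode <- integrate_scheme(sc, p, c(E = E0, S = S0), tt, method = "ode",
                          clamp = "S")
  expect_lt(max(abs(ode$ES - closed)), 1e-6)
  # exact linear path
  lin <- integrate_scheme(sc, p, c(E = E0, S = S0), tt, method = "pfo")
  expect_lt(max(abs(lin$ES - closed)), 1e-12)
})

test_that("conserved totals stay constant through integration", {
  cases <- list(
    list(sc = build_scheme("ONE_STEP"), p = rate_params(k1 = 0.5, km1 = 3),
         init = c(E = 1, S = 4)),
    list(sc = build_scheme("INDUCED_FIT"), p = induced_fit_truth(),
         init = c(E = 0.5, S = 2)),
    list(sc = build_scheme("TERNARY"), p = ternary_truth(),
         init = c(E = 0.5, I = 3, A = 7)))
  for (cs in cases) {
    tr <- integrate_scheme(cs$sc, cs$p, cs$init, seq(0, 1, 0.01), method = "ode")
    M <- cs$sc$moieties
    tot0 <- drop(crossprod(M, init_vector_for_test(cs$sc, cs$init)))
    tots <- as.matrix(tr[cs$sc$species$name]) %*% M
    for (m in seq_along(tot0)) {
      if (tot0[m] > 0) {
        expect_lt(max(abs(tots[, m] - tot0[m])) / tot0[m], 1e-8)
      }
    }
  }
})

test_that("long ternary integrations land on the algebraic equilibrium", {
  sc <- build_scheme("TERNARY")
  p <- ternary_truth()
  t_end <- 1e4 / min(p)
  tr <- integrate_scheme(sc, p, c(E = 0.5, I = 30, A = 70),
                         c(0, t_end / 2, t_end), method = "ode")
  last <- as.list(tr[nrow(tr), ])
  kv <- list(c("E", "I", "EI", 100 / 5000), c("E", "A", "EA", 100 / 20000),
             c("EA", "I", "EIA", 100 / 5000), c("EI", "A", "EIA", 100 / 20000))
  for (q in kv) {
    Keq <- as.numeric(q[4])
    ratio <- last[[q[3]]] / (last[[q[1]]] * last[[q[2]]])
    expect_equal(ratio, Keq, tolerance = 1e-6)
  }
  expect_equal(last$EIA_c / last$EIA, 50 / 12, tolerance = 1e-6)
})

test_that("equilibrium_state solves the binding quadratic and closes cycles", {
  sc <- build_scheme("ONE_STEP")
  eq <- equilibrium_state(sc, rate_params(k1 = 1, km1 = 1), c(E = 1, S = 1))
  expect_equal(eq[["ES"]], (3 - sqrt(5)) / 2, tolerance = 1e-9)

  eq0 <- equilibrium_state(sc, rate_params(k1 = 0, km1 = 1), c(E = 1, S = 1))
  expect_equal(eq0[["ES"]], 0)
  expect_equal(eq0[["S"]], 1)

  tern <- build_scheme("TERNARY")
  eq <- equilibrium_state(tern, ternary_truth(), c(E = 0.05, I = 250, A = 500))
  # shared constants force exact cycle closure E -> EI -> EIA -> EA -> E
  q_cycle <- (eq[["EI"]] / (eq[["E"]] * eq[["I"]])) *
    (eq[["EIA"]] / (eq[["EI"]] * eq[["A"]])) /
    (eq[["EIA"]] / (eq[["EA"]] * eq[["I"]])) /
    (eq[["EA"]] / (eq[["E"]] * eq[["A"]]))
  expect_equal(q_cycle, 1, tolerance = 1e-9)

  # irreversible reactions have no finite equilibrium
  sp <- tibble::tibble(name = c("E", "S", "ES"),
                       role = c("enzyme-state", "ligand", "complex"),
                       E = c(1L, 0L, 1L), S = c(0L, 1L, 1L))
  rx <- tibble::tibble(reactants = list(c("E", "S")), products = list("ES"),
                       kf_name = "k1", kr_name = "")
  irr <- build_scheme(species = sp, reactions = rx)
  expect_error(equilibrium_state(irr, rate_params(k1 = 1), c(E = 1, S = 1)),
               "irreversible")
})

test_that("relaxation rates obey the linearised-system identities", {
  expect_equal(relaxation_rates_pfo("ONE_STEP", rate_params(k1 = 0.1, km1 = 1), 10),
               2.0)
  expect_error(relaxation_rates_pfo("ONE_STEP", rate_params(k1 = 0.1, km1 = 1), -1))

  p <- induced_fit_truth()  # k1 10, km1 100, kconf 40, kmconf 2
  r <- relaxation_rates_pfo("INDUCED_FIT", p, 10)
  expect_length(r, 2)
  expect_gt(r[1], r[2])
  # trace and determinant of the 2x2 rate matrix pin both eigenvalues
  L <- 10
  expect_equal(sum(r), p[["k1"]] * L + p[["km1"]] + p[["kconf"]] + p[["kmconf"]],
               tolerance = 1e-12)
  expect_equal(prod(r),
               (p[["k1"]] * L + p[["km1"]] + p[["kconf"]]) * p[["kmconf"]] -
                 (-p[["k1"]] * L + p[["kmconf"]]) * p[["kconf"]],
               tolerance = 1e-10)

  # zero-ligand limit: rates approach km1 (fast) and kmconf (slow) when
  # dissociation dominates the conformational step
  p2 <- rate_params(k1 = 10, km1 = 1000, kconf = 4, kmconf = 0.5)
  r0 <- relaxation_rates_pfo("INDUCED_FIT", p2, 0)
  expect_equal(r0[1], p2[["km1"]], tolerance = 0.01)
  expect_equal(r0[2], p2[["kmconf"]], tolerance = 0.01)

  # conformational selection, zero ligand: exact rates km1 and kconf + kmconf
  r0c <- relaxation_rates_pfo("CONF_SELECTION", p, 0)
  expect_equal(sort(r0c), sort(c(p[["km1"]], p[["kconf"]] + p[["kmconf"]])),
               tolerance = 1e-12)
})

test_that("hyperbolic kobs agrees with the slow eigenvalue in rapid equilibrium", {
  expect_equal(kobs_hyperbolic(c(KD1 = 10, kconf = 40, kmconf = 2), 0), 2)
  expect_equal(kobs_hyperbolic(c(KD1 = 10, kconf = 40, kmconf = 2), 1e9),
               42, tolerance = 1e-6)
  expect_equal(kobs_hyperbolic(c(KD1 = 10, kconf = 40, kmconf = 2), 10), 22)

  # binding relaxes >= 50x faster than the conformational step
  p <- rate_params(k1 = 100, km1 = 1000, kconf = 10, kmconf = 1)
  for (S in c(0.5, 2, 10, 40)) {
    slow <- relaxation_rates_pfo("INDUCED_FIT", p, S)[2]
    expect_equal(slow, kobs_hyperbolic(c(KD1 = 10, kconf = 10, kmconf = 1), S),
                 tolerance = 0.02)
  }
})

test_that("relaxation rates are monotone in ligand concentration", {
  p <- induced_fit_truth()
  L_grid <- seq(0, 100, 5)
  one <- vapply(L_grid, function(L)
    relaxation_rates_pfo("ONE_STEP", rate_params(k1 = 0.1, km1 = 1), L),
    numeric(1))
  expect_true(all(diff(one) > 0))
  slow <- vapply(L_grid, function(L)
    relaxation_rates_pfo("INDUCED_FIT", p, L)[2], numeric(1))
  expect_true(all(diff(slow) > -1e-10))
  expect_true(all(slow <= p[["kconf"]] + p[["kmconf"]] + 1e-9))
})

test_that("observable projection truncates at the dead time and flags lost phases", {
  sc <- build_scheme("ONE_STEP")
  tt <- seq(0, 0.02, 1e-5)
  # kobs = 1000/s: association essentially complete within the 2 ms dead time
  fast <- integrate_scheme(sc, rate_params(k1 = 1, km1 = 0), c(E = 0.1, S = 1000),
                           tt, method = "pfo")
  tw <- project_observable(fast, c(ES = 1), t_dead = 0.002)
  expect_true(attr(tw, "obscured"))
  expect_equal(attr(tw, "pre_dead_fraction"), 1 - exp(-2), tolerance = 1e-3)
  expect_true(all(tw$time >= 0.002))

  # kobs = 1/s: nothing is lost
  tt2 <- seq(0, 5, 0.01)
  slow <- integrate_scheme(sc, rate_params(k1 = 1e-3, km1 = 0.999),
                           c(E = 0.1, S = 1), tt2, method = "ode")
  tw2 <- project_observable(slow, c(ES = 1), t_dead = 0.002)
  expect_false(attr(tw2, "obscured"))
  expect_lt(attr(tw2, "pre_dead_fraction"), 0.01)

  # t_dead = 0 is the identity sampling
  tw3 <- project_observable(slow, c(ES = 2), c0 = 0.5, t_dead = 0)
  expect_equal(tw3$signal, 0.5 + 2 * slow$ES)

  expect_error(project_observable(slow, c(nope = 1)), "unknown species")
})
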