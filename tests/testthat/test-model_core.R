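test_that("weekly schedule reproduces the regimen arithmetic", {
  s <- build_schedule(25, 20)
  expect_equal(nrow(s), 100)
  expect_equal(sum(s$amount), 2500)
  expect_equal(max(s$time), 138) # 7*19 + 5
  expect_true(all(diff(s$time) > 0))
  s1 <- build_schedule(25, 1)
  expect_equal(s1$time, 1:5)
  expect_error(build_schedule(25, 20, pattern = integer(0)), "empty")
  expect_error(build_schedule(-1, 20), "dose_mg_per_kg")
})

test_that("cumulative dose sums events up to t", {
  s <- build_schedule(25, 20)
  expect_equal(cumulative_dose(s, 98.1), 1750) # 14 weeks * 5 * 25
  expect_equal(cumulative_dose(s, 0.5), 0)
  expect_equal(cumulative_dose(s, 7), 125)
  expect_true(all(diff(cumulative_dose(s, 0:140)) >= 0))
})

test_that("rhs matches hand arithmetic and the mass-balance identity", {
  m <- base_model()
  d <- rhs(c(1, 0), 0, m)
  expect_equal(d, c(-(0.033 + 0.183), 0.183), tolerance = 1e-12)
  expect_equal(rhs(c(0, 0), 10, m), c(0, 0))
  # sum of derivatives = -K(t) * A1 for arbitrary states
  mh <- truth_model()
  for (st in list(c(1, 0), c(0.3, 7), c(5, 2))) {
    for (t in c(0, 30, 90)) {
      f <- fx_eval(mh$expansion, t)
      expect_equal(sum(rhs(st, t, mh)), -(0.3 / f) * st[1],
                   tolerance = 1e-12)
    }
  }
  expect_error(rhs(c(1, 0, 0), 0, m), "compartments")
})

test_that("scaling convention switches division by f(t)", {
  f <- truth_expansion()
  p <- truth_params()
  t <- 90
  ft <- fx_eval(f, t)
  m_def <- structural_model(p, f)
  m_none <- structural_model(p, f, scaling_convention("none", "none"))
  a <- c(2, 3)
  d_def <- rhs(a, t, m_def)
  d_none <- rhs(a, t, m_none)
  expect_equal(d_none[2], 0.3 * a[1] - 6 * a[2], tolerance = 1e-12)
  expect_equal(d_def[2], 0.3 * a[1] - 6 / ft * a[2], tolerance = 1e-12)
})

test_that("ODE integration matches the analytic bi-exponential oracle", {
  p <- base_params()
  # t = 0 is excluded: an output at a dose time is a pre-dose trough
  ts <- seq(2.5, 140, by = 2.5)
  sim <- simulate_profile(base_model(), bolus_schedule(25), ts)
  an <- analytic_two_compartment(p, 25, ts)
  c1 <- conc_stream(sim, "serum")
  c2 <- conc_stream(sim, "spleen")
  expect_equal(an$C1[1] > 0 && an$C2[1] > 0, TRUE)
  expect_lt(max(abs(c1 - an$C1) / an$C1), 1e-6)
  expect_lt(max(abs(c2 - an$C2) / an$C2), 1e-6)
  # analytic initial condition: C1(0) = D/V1, C2(0) = 0
  an0 <- analytic_two_compartment(p, 25, 0)
  expect_equal(an0$C1, 25 / 2.43, tolerance = 1e-12)
  expect_equal(an0$C2, 0)
})

test_that("one-compartment degenerate case is mono-exponential", {
  p <- pk_parameters(V1 = 2, V2 = 1, K = 0.4, K12 = 0, K21 = 0)
  ts <- seq(0.5, 20, by = 0.5)
  sim <- simulate_profile(structural_model(p), bolus_schedule(10), ts)
  expect_equal(conc_stream(sim, "serum"), (10 / 2) * exp(-0.4 * ts),
               tolerance = 1e-8)
  an <- analytic_two_compartment(p, 10, ts)
  expect_equal(an$C1, (10 / 2) * exp(-0.4 * ts), tolerance = 1e-12)
})

test_that("repeated eigenvalues fall back to the Jordan limit form", {
  # K12 = 0 with K = K21 gives a double eigenvalue -K
  p <- pk_parameters(V1 = 1, V2 = 1, K = 0.2, K12 = 0, K21 = 0.2)
  an <- analytic_two_compartment(p, 5, c(0, 1, 10))
  expect_equal(an$C1, 5 * exp(-0.2 * c(0, 1, 10)), tolerance = 1e-9)
})

test_that("simulation is linear in the dose", {
  m <- truth_model()
  s1 <- study_schedule()
  s2 <- build_schedule(50, 20)
  ts <- c(7, 56, 140)
  a <- simulate_profile(m, s1, ts)
  b <- simulate_profile(m, s2, ts)
  expect_equal(b$concentration, 2 * a$concentration, tolerance = 1e-9)
})

test_that("an observation at a dose time is a trough (pre-dose)", {
  p <- pk_parameters(V1 = 1, V2 = 1, K = 0, K12 = 0, K21 = 0)
  s <- build_schedule(10, 1, pattern = c(1, 2))
  sim <- simulate_profile(structural_model(p), s, c(1, 1.5, 2, 3))
  a1 <- sim$amount[sim$compartment == "serum"]
  # nothing eliminated or transferred: amounts count doses given *before* t
  expect_equal(a1, c(0, 10, 10, 20))
})

test_that("mass balance holds to 1e-8 across a 20-week regimen", {
  models <- list(
    base = base_model(),
    hill = truth_model(),
    sqrt = structural_model(truth_params(), sqrt_expansion()),
    three = structural_model(
      pk_parameters(V1 = 60, V2 = 0.1, K = 0.3, K12 = 0.3, K21 = 6,
                    V3 = 10, K13 = 0.05, K31 = 0.02),
      truth_expansion()))
  for (nm in names(models)) {
    sim <- simulate_profile(models[[nm]], study_schedule(),
                            c(7, 35, 70, 105, 140))
    mb <- mass_balance(sim)
    expect_lt(max(abs(mb$rel_error)), 1e-8)
    expect_true(all(sim$concentration >= -1e-10),
                label = paste(nm, "non-negative"))
  }
})

test_that("constant f approaches periodic steady state; sigmoid f gives
           strictly increasing spleen troughs", {
  wk <- 7 * (1:20)
  sim_c <- simulate_profile(base_model(), study_schedule(), wk)
  c1 <- conc_stream(sim_c, "serum")
  # weekly increments shrink as the periodic steady state is approached
  inc <- diff(c1)
  expect_lt(inc[19] / inc[1], 0.9)
  sim_s <- simulate_profile(truth_model(), study_schedule(), wk)
  expect_true(all(diff(conc_stream(sim_s, "spleen")) > 0))
})
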