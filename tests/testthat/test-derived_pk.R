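test_that("vd_total is V1 + V2*f(t) and monotone for sigmoids", {
  expect_equal(vd_total(base_model(), 50), 2.43 + 0.00516,
               tolerance = 1e-12)
  m <- truth_model()
  expect_equal(vd_total(m, 0), 60 + 0.1, tolerance = 1e-12)
  v <- vd_total(m, seq(0, 140, by = 1))
  expect_true(all(diff(v) >= 0))
})

test_that("base-row half-life reproduces the 21-day first-order value", {
  hl <- half_life(base_model(), 0)
  expect_equal(hl, 21, tolerance = 0.005) # ln2*(V1+V2)/(K*V1) = 21.05
  # doubling K halves the half-life
  p2 <- pk_parameters(V1 = 2.43, V2 = 0.00516, K = 0.066, K12 = 0.183,
                      K21 = 0.00287)
  expect_equal(half_life(structural_model(p2), 0), hl / 2,
               tolerance = 1e-10)
})

test_that("eigenvalue convention reduces to ln2/K in the 1-compartment
           limit", {
  p <- pk_parameters(V1 = 2, V2 = 1, K = 0.4, K12 = 0, K21 = 0)
  expect_equal(half_life(structural_model(p), 5, convention = "eigen"),
               log(2) / 0.4, tolerance = 1e-10)
  expect_error(half_life(structural_model(
    pk_parameters(V1 = 1, V2 = 1, K = 0, K12 = 0.1, K21 = 0.1)), 1), "K = 0")
})

test_that("half-life and Vd_total rise monotonically for sigmoid models", {
  for (f in all_sigmoids()) {
    m <- structural_model(truth_params(), f)
    t <- seq(0, 140, by = 1)
    expect_true(all(diff(half_life(m, t)) >= 0))
    expect_true(all(diff(vd_total(m, t)) >= 0))
  }
})

test_that("cumulative fraction sequestered follows its defining arithmetic", {
  # toy: constant C2 = 10 mg/L, W = 0.004 L/kg, one week of dosing
  m <- structural_model(pk_parameters(V1 = 1, V2 = 1, K = 0, K12 = 0,
                                      K21 = 0))
  s <- build_schedule(25, 20)
  # oracle route: direct arithmetic on the simulated concentration
  sim <- simulate_profile(m, s, 7)
  c2 <- conc_stream(sim, "spleen")
  got <- cumulative_fraction_sequestered(m, s, function(t) 0.004, 7)
  expect_equal(got, c2 * 0.004 / 125, tolerance = 1e-12)
  # spec toy example: 10 * 0.004 / 125
  expect_equal(10 * 0.004 / 125, 3.2e-4)
  expect_error(cumulative_fraction_sequestered(m, s, function(t) 0.004, 0.5),
               "before the first dose")
})

test_that("fractions are bounded by mass balance across a 20-week run", {
  truth <- truth_model()
  s <- study_schedule()
  design <- study_design()
  wf <- get("spleen_weight_volume_fn", asNamespace("adaptvd"))(
    design, truth$expansion)
  t <- 7 * (1:20)
  frac <- cumulative_fraction_sequestered(truth, s, wf, t)
  sim <- simulate_profile(truth, s, t)
  mb <- mass_balance(sim)
  body_frac <- mb$in_body / mb$administered
  expect_true(all(frac >= 0 & frac <= body_frac + 1e-12))
  expect_true(all(frac <= 1))
})

test_that("interval fractions telescope to the cumulative fraction", {
  truth <- truth_model()
  s <- study_schedule()
  wf <- function(t) 0.002 + 1e-4 * t / 140
  days <- c(7, 14, 28, 56, 84, 114, 140)
  per <- vapply(seq_along(days)[-1], function(i)
    per_dose_fraction_sequestered(truth, s, wf, days[i - 1], days[i]), 0)
  dd <- diff(cumulative_dose(s, days))
  m_first <- cumulative_fraction_sequestered(truth, s, wf, days[1]) *
    cumulative_dose(s, days[1])
  total <- (m_first + sum(per * dd)) / cumulative_dose(s, 140)
  expect_equal(total, cumulative_fraction_sequestered(truth, s, wf, 140),
               tolerance = 1e-9)
  expect_error(per_dose_fraction_sequestered(truth, s, wf, 13, 13.5),
               "no dose")
  expect_error(per_dose_fraction_sequestered(truth, s, wf, 10, 10), "t_prev")
})

test_that("per-dose fraction peaks strictly after week 4 and plateaus", {
  truth <- truth_model()
  s <- study_schedule()
  design <- study_design()
  wf <- get("spleen_weight_volume_fn", asNamespace("adaptvd"))(
    design, truth$expansion)
  tr <- derived_trajectory(truth, s, 7 * (1:20), spleen_weight_fn = wf)
  pd <- tr$per_dose_fraction[-1] # week-over-week
  peak_week <- which.max(pd) + 1
  expect_gt(peak_week, 4)
  # declines or flattens after the peak
  expect_lte(pd[length(pd)], max(pd))
})

test_that("consensus reduces to mean/SD pointwise", {
  truth <- truth_model()
  s <- study_schedule()
  t <- c(7, 70, 140)
  tr1 <- derived_trajectory(truth, s, t)
  expect_s3_class(tr1, "derived_trajectory")
  cons1 <- consensus(list(tr1))
  expect_true(all(cons1$sd == 0))
  expect_equal(cons1$mean[cons1$quantity == "Vd_total"], tr1$Vd_total)

  # three-trajectory oracle: scripted mean/SD
  trs <- lapply(all_sigmoids(), function(f)
    derived_trajectory(structural_model(truth_params(), f), s, t))
  cons <- consensus(unname(trs))
  vd <- vapply(trs, function(x) x$Vd_total, numeric(3))
  expect_equal(cons$mean[cons$quantity == "Vd_total"], rowMeans(vd))
  expect_equal(cons$sd[cons$quantity == "Vd_total"], apply(vd, 1, sd))

  tr_bad <- derived_trajectory(truth, s, c(7, 70))
  expect_error(consensus(list(tr1, tr_bad)), "time grid")
})
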