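# A tiny deterministic dataset for likelihood arithmetic tests.
toy_dataset <- function(seed = 401, n_days = 4) {
  truth <- truth_model()
  days <- c(7, 28, 84, 140)[seq_len(n_days)]
  generate_study(truth, study_design(sampling_days = days,
                                     animals_per_day = 2, day14_n2 = FALSE),
                 error_model(0.2, 0.3), seed = seed)
}

test_that("neg2loglik matches a direct normal-density oracle", {
  ds <- toy_dataset()
  m <- truth_model()
  err <- error_model(0.17, 0.31)
  ofv <- neg2loglik(ds, m, err)
  # oracle: -2 * sum log N(obs; pred, sigma*pred)
  pred <- get("predict_observations", asNamespace("adaptvd"))(
    m, ds$schedule, ds$observations)
  sigma <- ifelse(ds$observations$stream == "serum", 0.17, 0.31)
  oracle <- -2 * sum(dnorm(ds$observations$conc, pred, sigma * pred,
                           log = TRUE))
  expect_equal(ofv, oracle, tolerance = 1e-10)
  # scaling both sigmas by c adds 2*N*log(c) + rescales residual terms
  c_ <- 2.5
  ofv2 <- neg2loglik(ds, m, error_model(0.17 * c_, 0.31 * c_))
  resid <- sum((ds$observations$conc - pred)^2 / (sigma * pred)^2)
  expect_equal(ofv2, ofv + 2 * nrow(ds$observations) * log(c_) +
                 resid / c_^2 - resid, tolerance = 1e-8)
})

test_that("a perfect single observation contributes log(2*pi)", {
  s <- bolus_schedule(10)
  m <- structural_model(pk_parameters(V1 = 10, V2 = 1, K = 0, K12 = 0,
                                      K21 = 0))
  # C1 = 1 for all t > 0; obs = pred = 1 with sigma = 1
  obs <- data.frame(id = "a", time = 5, stream = "serum", conc = 1)
  ds <- study_dataset(obs, s)
  expect_equal(neg2loglik(ds, m, error_model(1, 1)), log(2 * pi),
               tolerance = 1e-10)
})

test_that("aic and r_squared follow their definitions", {
  expect_identical(aic(100, 5), 110)
  expect_identical(aic(0, 0), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 27 / 28,
               tolerance = 1e-12)
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_error(r_squared(1:3, c(2, 2, 2)), "zero variance")
  expect_error(r_squared(1, 1), ">= 2")
})

test_that("weighted residuals are standardised prediction errors", {
  ds <- toy_dataset()
  m <- truth_model()
  err <- error_model(0.2, 0.3)
  wr <- weighted_residuals(ds, m, err)
  expect_identical(nrow(wr), nrow(ds$observations))
  # hand-check: obs = pred * (1 + sigma) gives wres = 1
  obs2 <- ds$observations
  pred <- wr$pred
  obs2$conc <- pred * (1 + ifelse(obs2$stream == "serum", 0.2, 0.3))
  wr2 <- weighted_residuals(study_dataset(obs2, ds$schedule), m, err)
  expect_equal(wr2$wres, rep(1, nrow(obs2)), tolerance = 1e-10)
})

test_that("fixing every parameter returns the initial values and their OFV", {
  ds <- toy_dataset()
  m <- truth_model()
  err <- error_model(0.2, 0.3)
  all_names <- names(get("param_template", asNamespace("adaptvd"))(m, err))
  fit <- fit_model(ds, m, err, fixed = all_names)
  expect_identical(fit$p, 0L)
  expect_equal(fit$ofv, neg2loglik(ds, m, err, rtol = 1e-8, atol = 1e-11),
               tolerance = 1e-10)
  expect_equal(unname(fit$estimates["K"]), 0.3)
  expect_identical(fit$aic, fit$ofv)
})

test_that("noise-free data recovers generating parameters within 1%", {
  truth <- truth_model()
  des <- study_design(sampling_days = c(7, 14, 28, 56, 84, 114, 140),
                      animals_per_day = 1, day14_n2 = FALSE)
  ds <- generate_study(truth, des, error_model(1e-12, 1e-12), seed = 5)
  # estimate a well-identified subset from perturbed inits
  fit <- fit_model(ds, truth, error_model(0.05, 0.05),
                   init = c(K = 0.2, Emax = 4, T50 = 80),
                   fixed = c("V1", "V2", "K12", "K21", "Hill",
                             "sigma_serum", "sigma_spleen"),
                   n_multistart = 2, seed = 9)
  expect_lt(abs(fit$estimates[["K"]] / 0.3 - 1), 0.01)
  expect_lt(abs(fit$estimates[["Emax"]] / 5 - 1), 0.01)
  expect_lt(abs(fit$estimates[["T50"]] / 60 - 1), 0.01)
})

test_that("releasing a fixed parameter never increases the OFV", {
  ds <- toy_dataset()
  m <- truth_model()
  err <- error_model(0.2, 0.3)
  fit_fixed <- fit_model(ds, m, err,
                         fixed = c("V1", "V2", "K12", "K21", "Hill", "T50",
                                   "Emax"),
                         n_multistart = 2, seed = 3)
  fit_free <- fit_model(ds, m, err,
                        init = fit_fixed$estimates[fit_fixed$estimated],
                        fixed = setdiff(fit_fixed$fixed, "T50"),
                        n_multistart = 2, seed = 3)
  expect_lte(fit_free$ofv, fit_fixed$ofv + 1e-6)
  expect_identical(fit_free$p, fit_fixed$p + 1L)
})

test_that("bootstrap is seed-deterministic and validates n_reps", {
  ds <- toy_dataset()
  m <- truth_model()
  expect_error(bootstrap(ds, m, n_reps = 0), "n_reps")
  b1 <- bootstrap(ds, m, n_reps = 10, seed = 21,
                  fixed = c("V1", "K12", "Hill", "V2", "K21",
                            "sigma_serum", "sigma_spleen"),
                  control = list(rel.tol = 1e-6))
  b2 <- bootstrap(ds, m, n_reps = 10, seed = 21,
                  fixed = c("V1", "K12", "Hill", "V2", "K21",
                            "sigma_serum", "sigma_spleen"),
                  control = list(rel.tol = 1e-6))
  expect_identical(b1$summary, b2$summary)
  expect_identical(dim(b1$estimates), c(10L, 3L))
  # resampling preserves the per-day design
  expect_identical(sort(unique(b1$summary$parameter)),
                   sort(c("K", "Emax", "T50")))
})

test_that("compare_models sorts by AIC with stable ties", {
  ds <- toy_dataset()
  m <- truth_model()
  all_names <- names(get("param_template", asNamespace("adaptvd"))(
    m, error_model()))
  tab <- compare_models(ds, list(a = m, b = m), fixed = all_names,
                        n_multistart = 1, seed = 1)
  expect_identical(tab$model, c("a", "b")) # tie keeps input order
  expect_equal(tab$aic[1], tab$aic[2])
  expect_error(compare_models(ds, list(m)), "2 structural models")
})
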