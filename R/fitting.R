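#' Proportional (multiplicative) residual error model
#'
#' Observations are modelled as `obs = pred * (1 + eps)` with
#' `eps ~ N(0, sigma^2)`, i.e. a normal density with mean `pred` and SD
#' `sigma * pred`. Serum and spleen streams carry separate magnitudes since
#' their concentrations differ by orders of magnitude.
#'
#' @param sigma_serum,sigma_spleen Proportional error SDs (dimensionless).
#' @return An object of class `error_model`.
#' @export
error_model <- function(sigma_serum = 0.2, sigma_spleen = 0.2) {
  check_scalar(sigma_serum, "sigma_serum", 0, strict = TRUE)
  check_scalar(sigma_spleen, "sigma_spleen", 0, strict = TRUE)
  structure(list(sigma_serum = sigma_serum, sigma_spleen = sigma_spleen),
            class = "error_model")
}

# Population predictions for each observation row (naive-pooled: one
# simulation serves all animals since dosing is shared and ETAs are not
# estimated). Bypasses the tidy simulate_profile() output: this sits in the
# optimiser's inner loop.
predict_observations <- function(model, schedule, observations,
                                 rtol = 1e-9, atol = 1e-12) {
  ut <- sort(unique(observations$time))
  n <- model$n_compartments
  p <- model$parameters
  A <- .ode_simulate_cpp(ut, schedule$time, schedule$amount, n,
                         p$K, p$K12, p$K21,
                         if (n == 3L) p$K13 else 0,
                         if (n == 3L) p$K31 else 0,
                         model$scaling$scale_K == "inverse_f",
                         model$scaling$scale_K21 == "inverse_f",
                         expansion_kind_code(model$expansion$kind),
                         as.numeric(model$expansion$params), rtol, atol)
  c1 <- A[, 1] / p$V1
  c2 <- A[, 2] / (p$V2 * fx_eval(model$expansion, ut))
  idx <- match(observations$time, ut)
  ifelse(observations$stream == "serum", c1[idx], c2[idx])
}

#' Extended-least-squares objective (-2 log-likelihood)
#'
#' Under the proportional error model the contribution of each observation
#' is `log(2*pi) + log(sigma^2 * pred^2) + (obs - pred)^2 / (sigma^2 *
#' pred^2)`, summed over both streams with stream-specific `sigma`. Animals
#' are pooled (see [fit_model()]).
#'
#' @param dataset A [study_dataset()].
#' @param model A [structural_model()].
#' @param error An [error_model()].
#' @param rtol,atol Integrator tolerances passed to the simulator.
#' @return The objective function value (OFV).
#' @export
neg2loglik <- function(dataset, model, error, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(error, "error_model"))
  obs <- dataset$observations
  pred <- predict_observations(model, dataset$schedule, obs, rtol, atol)
  bad <- which(pred <= 0)
  if (length(bad))
    stopf("non-positive prediction at record %d (id %s, t = %g, %s)",
          bad[1], obs$id[bad[1]], obs$time[bad[1]], obs$stream[bad[1]])
  sigma <- ifelse(obs$stream == "serum", error$sigma_serum,
                  error$sigma_spleen)
  v <- (sigma * pred)^2
  sum(log(2 * pi) + log(v) + (obs$conc - pred)^2 / v)
}

#' Akaike information criterion
#'
#' @param ofv Objective function value (-2 log-likelihood).
#' @param p Number of estimated parameters (structural + expansion +
#'   estimated error SDs; fixed parameters are excluded).
#' @return `ofv + 2 * p`.
#' @export
aic <- function(ofv, p) {
  check_scalar(ofv, "ofv")
  check_scalar(p, "p", 0)
  ofv + 2 * p
}

#' Squared correlation of observed vs predicted concentrations
#'
#' @param observed,predicted Numeric vectors (pooled across streams).
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stopf("need >= 2 paired observations")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stopf("undefined statistic: zero variance in observed or predicted")
  cor(observed, predicted)^2
}

#' Weighted residuals under the proportional error model
#'
#' Population-prediction weighted residuals `(obs - pred) / (sigma * pred)`,
#' an approximation to conditional weighted residuals appropriate for the
#' pooled likelihood used here.
#'
#' @inheritParams neg2loglik
#' @return Data frame with `id`, `time`, `stream`, `obs`, `pred`, `wres`.
#' @export
weighted_residuals <- function(dataset, model, error,
                               rtol = 1e-9, atol = 1e-12) {
  obs <- dataset$observations
  pred <- predict_observations(model, dataset$schedule, obs, rtol, atol)
  if (any(pred <= 0)) stopf("non-positive prediction in residual computation")
  sigma <- ifelse(obs$stream == "serum", error$sigma_serum,
                  error$sigma_spleen)
  data.frame(id = obs$id, time = obs$time, stream = obs$stream,
             obs = obs$conc, pred = pred,
             wres = (obs$conc - pred) / (sigma * pred))
}

# Full parameter vector (structural + expansion + error SDs) for a model.
param_template <- function(model, error) {
  c(unlist(model$parameters), model$expansion$params,
    sigma_serum = error$sigma_serum, sigma_spleen = error$sigma_spleen)
}

# Lean objective used inside the optimiser loop: identical arithmetic to
# neg2loglik() but without rebuilding the S3 model objects per evaluation.
make_objective <- function(dataset, model, rtol, atol) {
  obs <- dataset$observations
  sched <- dataset$schedule
  ut <- sort(unique(obs$time))
  idx <- match(obs$time, ut)
  serum <- obs$stream == "serum"
  conc <- obs$conc
  n <- model$n_compartments
  ekind <- expansion_kind_code(model$expansion$kind)
  ep <- expansion_param_names(model$expansion$kind)
  scK <- model$scaling$scale_K == "inverse_f"
  scK21 <- model$scaling$scale_K21 == "inverse_f"
  function(th) {
    A <- .ode_simulate_cpp(ut, sched$time, sched$amount, n,
                           th[["K"]], th[["K12"]], th[["K21"]],
                           if (n == 3L) th[["K13"]] else 0,
                           if (n == 3L) th[["K31"]] else 0,
                           scK, scK21, ekind, unname(th[ep]), rtol, atol)
    f <- .fx_eval_cpp(ekind, unname(th[ep]), ut)
    c1 <- A[, 1] / th[["V1"]]
    c2 <- A[, 2] / (th[["V2"]] * f)
    pred <- ifelse(serum, c1[idx], c2[idx])
    if (any(pred <= 0)) return(Inf)
    v <- (ifelse(serum, th[["sigma_serum"]], th[["sigma_spleen"]]) *
            pred)^2
    sum(log(2 * pi) + log(v) + (conc - pred)^2 / v)
  }
}

# Rebuild model and error objects from a full parameter vector.
realize_theta <- function(model, theta) {
  sp <- c("V1", "V2", "K", "K12", "K21",
          if (model$n_compartments == 3L) c("V3", "K13", "K31"))
  params <- do.call(pk_parameters, as.list(theta[sp]))
  ep <- expansion_param_names(model$expansion$kind)
  expansion <- if (length(ep))
    expansion_fn(model$expansion$kind, as.list(theta[ep]))
  else model$expansion
  list(model = structural_model(params, expansion, model$scaling),
       error = error_model(theta[["sigma_serum"]], theta[["sigma_spleen"]]))
}

#' Fit a structural model by maximum likelihood
#'
#' Minimises [neg2loglik()] over the estimated parameters, working in
#' log-parameter space (positivity by construction) with a quasi-Newton
#' local search from multiple jittered starts. Coefficients of variation
#' come from the inverse Hessian of the objective at the optimum (delta
#' method on the log scale); when the Hessian is ill-conditioned they are
#' `NA` and a bootstrap is the recommended fallback.
#'
#' @param dataset A [study_dataset()].
#' @param model A [structural_model()] supplying the structure and the
#'   initial parameter values.
#' @param error An [error_model()] with initial error SDs.
#' @param init Optional named vector overriding initial values (structural,
#'   expansion, `sigma_serum`, `sigma_spleen`).
#' @param fixed Character vector of parameter names held at their initial
#'   values. Everything else is estimated; with every parameter fixed the
#'   initial values are returned with their OFV.
#' @param bounds Optional list with named numeric vectors `lower` and/or
#'   `upper` (natural scale) constraining estimated parameters. By default
#'   each estimated parameter is boxed to `init/50 .. init*50`: wide enough
#'   for any plausible optimum when initial values are study-anchored, and
#'   it keeps the optimiser out of ultra-stiff rate regimes where the
#'   likelihood is flat along compensation ridges.
#' @param n_multistart Number of optimisation starts (first unjittered,
#'   the rest multiplied by Uniform(0.5, 1.5) draws).
#' @param seed Seed controlling the start jitter.
#' @param control List: `rtol`, `atol` (integrator tolerances used during
#'   fitting), `rel.tol` (optimiser convergence tolerance on the OFV,
#'   default 1e-8), `iter.max`, `eval.max`.
#' @return An object of class `pk_fit`: estimates, CV%, OFV, AIC, R-squared,
#'   residual table, updated model/error, and per-start convergence info.
#' @export
fit_model <- function(dataset, model, error = error_model(),
                      init = NULL, fixed = character(), bounds = NULL,
                      n_multistart = 8, seed = 1L, control = list()) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(model, "structural_model"))
  # fitting uses slightly looser integrator tolerances than reporting
  # simulations: 1e-8/1e-11 is far below the measurement noise and ~35%
  # cheaper inside the optimiser loop
  # `hessian = FALSE` skips the CV% Hessian (bootstrap refits don't use it)
  ctl <- modifyList(list(rtol = 1e-8, atol = 1e-11, rel.tol = 1e-8,
                         iter.max = 500, eval.max = 2000, hessian = TRUE),
                    control)
  theta0 <- param_template(model, error)
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(theta0))
    if (length(unknown))
      stopf("unknown parameter(s) in `init`: %s",
            paste(unknown, collapse = ", "))
    theta0[names(init)] <- init
  }
  unknown <- setdiff(fixed, names(theta0))
  if (length(unknown))
    stopf("unknown parameter(s) in `fixed`: %s",
          paste(unknown, collapse = ", "))
  est <- setdiff(names(theta0), fixed)

  objective <- make_objective(dataset, model, ctl$rtol, ctl$atol)

  if (length(est) == 0L) {
    ofv <- objective(theta0)
    return(finish_fit(dataset, model, theta0, est, fixed, ofv,
                      cv = numeric(0), ctl,
                      convergence = data.frame(start = 1, ofv = ofv,
                                               code = 0)))
  }
  if (any(theta0[est] <= 0))
    stopf("initial values of estimated parameters must be > 0 (log scale)")
  lower <- theta0[est] / 50
  upper <- theta0[est] * 50
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower))
      lower[intersect(names(bounds$lower), est)] <-
        bounds$lower[intersect(names(bounds$lower), est)]
    if (!is.null(bounds$upper))
      upper[intersect(names(bounds$upper), est)] <-
        bounds$upper[intersect(names(bounds$upper), est)]
  }
  if (any(theta0[est] < lower | theta0[est] > upper))
    stopf("initial values must lie within the bounds")

  obj_log <- function(lp) {
    th <- theta0
    th[est] <- exp(lp)
    v <- tryCatch(objective(th), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, n_multistart)), function(i) {
      jit <- if (i == 1L) rep(1, length(est))
             else runif(length(est), 0.5, 1.5)
      log(theta0[est] * jit)
    })
  })
  runs <- lapply(seq_along(starts), function(i) {
    r <- tryCatch(
      nlminb(starts[[i]], obj_log,
             lower = log(lower), upper = log(upper),
             control = list(rel.tol = ctl$rel.tol, iter.max = ctl$iter.max,
                            eval.max = ctl$eval.max)),
      error = function(e) list(objective = Inf, convergence = 99L,
                               message = conditionMessage(e)))
    list(start = i, par = r$par, ofv = r$objective,
         code = r$convergence %||% 99L)
  })
  ofvs <- vapply(runs, `[[`, 0, "ofv")
  if (all(!is.finite(ofvs) | ofvs >= 1e10)) {
    stopf("all %d optimisation starts failed; per-start OFVs: %s",
          length(runs), paste(signif(ofvs, 6), collapse = ", "))
  }
  best <- runs[[which.min(ofvs)]]
  theta <- theta0
  theta[est] <- exp(best$par)

  cv <- rep(NA_real_, length(est))
  names(cv) <- est
  H <- if (isFALSE(ctl$hessian)) NULL
       else tryCatch(optimHess(best$par, obj_log), error = function(e) NULL)
  if (!is.null(H)) {
    cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_log)) {
      d <- diag(cov_log)
      ok <- is.finite(d) & d >= 0
      cv[ok] <- 100 * sqrt(d[ok]) # SD on log scale ~ CV of the parameter
    }
  }
  convergence <- data.frame(start = vapply(runs, `[[`, 0, "start"),
                            ofv = ofvs,
                            code = vapply(runs, `[[`, 0, "code"))
  finish_fit(dataset, model, theta, est, fixed, min(ofvs), cv, ctl,
             convergence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_fit <- function(dataset, model, theta, est, fixed, ofv, cv, ctl,
                       convergence) {
  r <- realize_theta(model, theta)
  res <- weighted_residuals(dataset, r$model, r$error,
                            rtol = ctl$rtol, atol = ctl$atol)
  p <- length(est)
  structure(list(
    estimates = theta, estimated = est, fixed = fixed, cv_pct = cv,
    ofv = ofv, p = p, aic = aic(ofv, p),
    r_squared = r_squared(res$obs, res$pred),
    residuals = res, model = r$model, error = r$error,
    convergence = convergence, n_obs = nrow(res)), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %s expansion, %d obs, p = %d\n",
              x$model$expansion$kind, x$n_obs, x$p))
  cat(sprintf("  OFV = %.3f, AIC = %.3f, R^2 = %.4f\n", x$ofv, x$aic,
              x$r_squared))
  est <- x$estimates[x$estimated]
  if (length(est)) {
    cvs <- ifelse(is.na(x$cv_pct), "NA", sprintf("%.1f%%", x$cv_pct))
    cat("  estimates:",
        paste(sprintf("%s = %.4g (%s)", names(est), est, cvs),
              collapse = ", "), "\n")
  }
  if (length(x$fixed))
    cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified nonparametric bootstrap
#'
#' Resamples *animals* with replacement within each sampling day (preserving
#' the destructive design: each animal contributes a single timepoint) and
#' refits the model to each resample. Refits start from the supplied initial
#' values, typically the point estimates of a converged fit.
#'
#' @param dataset A [study_dataset()].
#' @param model A [structural_model()] providing structure and initial
#'   values (e.g. `fit$model` from a converged [fit_model()]).
#' @param n_reps Number of bootstrap replicates (>= 10).
#' @param seed RNG seed; identical seeds give identical summaries.
#' @param error,init,fixed,bounds,n_multistart,control Passed to
#'   [fit_model()] (default one start per refit).
#' @return A `pk_bootstrap`: per-parameter mean, SD, CV% and percentile 95%
#'   CI across successful refits, the replicate estimates matrix, and the
#'   failure count (a warning is recorded when > 20% of refits fail).
#' @export
bootstrap <- function(dataset, model, n_reps = 1000, seed = 1L,
                      error = error_model(), init = NULL,
                      fixed = character(), bounds = NULL, n_multistart = 1,
                      control = list()) {
  stopifnot(inherits(dataset, "study_dataset"))
  check_scalar(n_reps, "n_reps", 10)
  obs <- dataset$observations
  days <- sort(unique(obs$time))
  ids_by_day <- lapply(days, function(d) unique(obs$id[obs$time == d]))

  draws <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i)
      lapply(ids_by_day, function(ids)
        sample(ids, length(ids), replace = TRUE)))
  })
  refit_seeds <- with_seed(seed, sample.int(2^31 - 1, n_reps))

  est_names <- NULL
  rows <- vector("list", n_reps)
  n_fail <- 0L
  for (i in seq_len(n_reps)) {
    res_obs <- do.call(rbind, lapply(seq_along(days), function(j) {
      picked <- draws[[i]][[j]]
      do.call(rbind, lapply(seq_along(picked), function(k) {
        o <- obs[obs$id == picked[k] & obs$time == days[j], , drop = FALSE]
        o$id <- sprintf("boot%03d_d%g_%d", i, days[j], k)
        o
      }))
    }))
    bdat <- study_dataset(res_obs, dataset$schedule, design = dataset$design)
    fit <- tryCatch(
      fit_model(bdat, model, error = error, init = init, fixed = fixed,
                bounds = bounds, n_multistart = n_multistart,
                seed = refit_seeds[i],
                control = modifyList(list(hessian = FALSE), control)),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_fail <- n_fail + 1L
    } else {
      est_names <- fit$estimated
      rows[[i]] <- fit$estimates[fit$estimated]
    }
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) == 0L)
    stopf("all %d bootstrap refits failed", n_reps)
  summary <- data.frame(
    parameter = est_names,
    mean = colMeans(est),
    sd = apply(est, 2, sd),
    cv_pct = 100 * apply(est, 2, sd) / colMeans(est),
    ci_lower = apply(est, 2, quantile, 0.025, names = FALSE),
    ci_upper = apply(est, 2, quantile, 0.975, names = FALSE),
    row.names = NULL)
  warn <- if (n_fail > 0.2 * n_reps)
    sprintf("%d of %d bootstrap refits failed (> 20%%)", n_fail, n_reps)
  else NULL
  structure(list(summary = summary, estimates = est, n_reps = n_reps,
                 n_failed = n_fail, seed = seed, warning = warn),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("<pk_bootstrap> %d replicates (%d failed), seed %s\n",
              x$n_reps, x$n_failed, format(x$seed)))
  print(x$summary, digits = 4)
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Fit and compare a set of candidate models
#'
#' Fits each model to the same dataset and tabulates parameter count, OFV,
#' AIC and R-squared, sorted ascending by AIC (stable: ties keep input
#' order). A failed fit yields an `NA` row rather than aborting the
#' comparison.
#'
#' @param dataset A [study_dataset()].
#' @param models Named list of [structural_model()] objects.
#' @param error,fixed,n_multistart,seed,control Passed to [fit_model()];
#'   `fixed` may be a single character vector applied to every model or a
#'   named list keyed by model name.
#' @return A data frame (one row per model: `model`, `p`, `ofv`, `aic`,
#'   `r_squared`, `converged`, `message`) with the fit objects in attribute
#'   `fits`.
#' @export
compare_models <- function(dataset, models, error = error_model(),
                           fixed = character(), n_multistart = 8,
                           seed = 1L, control = list()) {
  if (!is.list(models) || length(models) < 2L)
    stopf("`models` must be a named list of >= 2 structural models")
  if (is.null(names(models)) || any(names(models) == ""))
    stopf("`models` must be named")
  fixed_for <- function(nm) {
    fx <- if (is.list(fixed)) fixed[[nm]] %||% character() else fixed
    # a shared mask may name parameters some candidates lack (e.g. `Hill`
    # for the base model): apply only what exists in each model
    intersect(fx, names(param_template(models[[nm]], error)))
  }
  fits <- lapply(names(models), function(nm) {
    tryCatch(fit_model(dataset, models[[nm]], error = error,
                       fixed = fixed_for(nm), n_multistart = n_multistart,
                       seed = seed, control = control),
             error = function(e) e)
  })
  names(fits) <- names(models)
  rows <- lapply(names(models), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "pk_fit"))
      data.frame(model = nm, p = f$p, ofv = f$ofv, aic = f$aic,
                 r_squared = f$r_squared, converged = TRUE, message = "")
    else
      data.frame(model = nm, p = NA_integer_, ofv = NA_real_,
                 aic = NA_real_, r_squared = NA_real_, converged = FALSE,
                 message = conditionMessage(f))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
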