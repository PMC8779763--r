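#' Study design for a destructive trough-sampling experiment
#'
#' Encodes the sampling structure of a chronic-dosing mouse study: cohorts
#' of animals are euthanised at discrete sampling days (each animal
#' contributes exactly one timepoint), serum and spleen concentrations are
#' measured at trough, and each spleen is weighed.
#'
#' @param sampling_days Days at which cohorts are sampled (default the
#'   study's `7, 14, 28, 56, 84, 114, 140`).
#' @param animals_per_day Animals per sampling day (default 3).
#' @param day14_n2 Drop one animal at day 14 (default `TRUE`, matching the
#'   `n = 2` cohort of the emulated study).
#' @param streams Sampled concentration streams.
#' @param body_weight_kg Nominal body weight (default 0.02 kg, typical for
#'   an adult BALB/c mouse).
#' @param spleen_w0_g,spleen_wmax_g Baseline and plateau spleen mass for
#'   the expansion-linked spleen weight model (defaults 0.1 g and 0.5 g).
#' @return An object of class `study_design`.
#' @export
study_design <- function(sampling_days = c(7, 14, 28, 56, 84, 114, 140),
                         animals_per_day = 3, day14_n2 = TRUE,
                         streams = c("serum", "spleen"),
                         body_weight_kg = 0.02,
                         spleen_w0_g = 0.1, spleen_wmax_g = 0.5) {
  if (!length(sampling_days) || any(sampling_days <= 0))
    stopf("`sampling_days` must be positive")
  check_scalar(animals_per_day, "animals_per_day", 1)
  animals_per_day <- as.integer(animals_per_day)
  check_scalar(body_weight_kg, "body_weight_kg", 0, strict = TRUE)
  check_scalar(spleen_w0_g, "spleen_w0_g", 0, strict = TRUE)
  if (spleen_wmax_g < spleen_w0_g)
    stopf("`spleen_wmax_g` must be >= `spleen_w0_g`")
  streams <- match.arg(streams, c("serum", "spleen"), several.ok = TRUE)
  structure(list(sampling_days = sort(unique(sampling_days)),
                 animals_per_day = animals_per_day, day14_n2 = day14_n2,
                 streams = streams, body_weight_kg = body_weight_kg,
                 spleen_w0_g = spleen_w0_g, spleen_wmax_g = spleen_wmax_g),
            class = "study_design")
}

#' Between-subject variability on expansion parameters
#'
#' Log-normal random effects (ETA) applied multiplicatively to the
#' expansion parameters governing the rate and the ceiling of spleen
#' expansion: `param_i = param * exp(eta)`, `eta ~ N(0, omega2)`. The
#' affected parameters per kind are: `linear` rate `X`; `hill_exp` rate
#' `Hill`, ceiling `Emax`; `logistic` rate `M2`, ceiling `M1`;
#' `sqrt_sigmoid` rate `B3`, ceiling `B1`.
#'
#' @param omega2_rate,omega2_ceiling Variances (>= 0) of the log-scale
#'   random effects.
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(omega2_rate = 0, omega2_ceiling = 0) {
  check_scalar(omega2_rate, "omega2_rate", 0)
  check_scalar(omega2_ceiling, "omega2_ceiling", 0)
  structure(list(omega2_rate = omega2_rate,
                 omega2_ceiling = omega2_ceiling),
            class = "random_effects")
}

eta_param_map <- function(kind) {
  switch(kind,
    linear = c(rate = "X"),
    hill_exp = c(rate = "Hill", ceiling = "Emax"),
    logistic = c(rate = "M2", ceiling = "M1"),
    sqrt_sigmoid = c(rate = "B3", ceiling = "B1"),
    character(0))
}

#' Expansion-linked spleen weight model
#'
#' Spleen mass tracks the expansion function's approach to its plateau:
#' `W(t) = W0 + (Wmax - W0) * (f(t) - 1) / (f(Inf) - 1)` for sigmoid
#' expansions, so the mass rises steeply over the same weeks in which the
#' sequestered fraction accelerates; for constant/linear expansions the
#' mass stays at `W0`.
#'
#' @param t Time(s) in days.
#' @param design A [study_design()] carrying `spleen_w0_g`/`spleen_wmax_g`.
#' @param expansion An [expansion_fn()].
#' @return Spleen mass in grams.
#' @export
spleen_weight <- function(t, design, expansion) {
  stopifnot(inherits(design, "study_design"),
            inherits(expansion, "expansion_fn"))
  check_expansion_time(t)
  w0 <- design$spleen_w0_g
  wmax <- design$spleen_wmax_g
  if (!is_sigmoid(expansion)) return(rep(w0, length(t)))
  plateau <- fx_plateau(expansion)
  w0 + (wmax - w0) * (fx_eval(expansion, t) - 1) / (plateau - 1)
}

# Spleen weight as volume (L) per kg body weight, density 1 g/mL.
spleen_weight_volume_fn <- function(design, expansion) {
  function(t) spleen_weight(t, design, expansion) / 1000 /
    design$body_weight_kg
}

#' Study dataset container
#'
#' @param observations Data frame with columns `id`, `time` (days),
#'   `stream` (`"serum"`/`"spleen"`), `conc` (mg/L).
#' @param schedule A [build_schedule()] dose schedule covering all
#'   observation times.
#' @param spleen_weights Optional data frame `id`, `day`, `weight_g`.
#' @param design Optional [study_design()] echo.
#' @param provenance Optional list recording generator parameters and seed.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(observations, schedule, spleen_weights = NULL,
                          design = NULL, provenance = NULL) {
  need <- c("id", "time", "stream", "conc")
  missing <- setdiff(need, names(observations))
  if (length(missing))
    stopf("observations lack column(s): %s", paste(missing, collapse = ", "))
  stopifnot(inherits(schedule, "dose_schedule"))
  if (nrow(observations) == 0L) stopf("empty dataset: no observations")
  if (!all(observations$stream %in% c("serum", "spleen")))
    stopf("`stream` must be 'serum' or 'spleen'")
  if (any(observations$conc <= 0))
    stopf("observed concentrations must be > 0")
  if (max(observations$time) > schedule_horizon(schedule))
    stopf("observation time %g beyond the dosing horizon %g",
          max(observations$time), schedule_horizon(schedule))
  rownames(observations) <- NULL
  structure(list(observations = observations, schedule = schedule,
                 spleen_weights = spleen_weights, design = design,
                 provenance = provenance),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  o <- x$observations
  cat(sprintf(
    "<study_dataset> %d observations, %d animals, days {%s}, %d doses\n",
    nrow(o), length(unique(o$id)),
    paste(sort(unique(o$time)), collapse = ", "), nrow(x$schedule)))
  if (!is.null(x$provenance))
    cat("  synthetic (seed", format(x$provenance$seed), ")\n")
  invisible(x)
}

#' Generate a synthetic chronic-dosing study
#'
#' Simulates the destructive-sampling experiment: for each animal, draws
#' its log-normal ETAs on the designated expansion parameters, simulates
#' its concentration trajectory under the schedule, reads the trough
#' serum/spleen concentrations at the animal's single sampling day,
#' applies multiplicative noise `obs = pred * (1 + eps)` with
#' `eps ~ N(0, sigma^2)` (redrawn, not clipped, while `obs <= 0`), and
#' attaches the spleen mass from the weight model. Fully reproducible from
#' the seed.
#'
#' @param model A [structural_model()] (the generating truth).
#' @param design A [study_design()].
#' @param error An [error_model()] (noise magnitudes; may differ by
#'   stream).
#' @param random_effects A [random_effects()] object; defaults to none.
#' @param seed RNG seed (required for provenance).
#' @param schedule Optional dose schedule; defaults to 25 mg/kg
#'   Monday-Friday for 20 weeks.
#' @return A [study_dataset()] with generator provenance attached.
#' @examples
#' truth <- structural_model(
#'   pk_parameters(V1 = 2.43, V2 = 0.00708, K = 0.229, K12 = 0.183,
#'                 K21 = 3.36),
#'   expansion_fn("hill_exp", Emax = 6.99, T50 = 49, Hill = 3.71))
#' ds <- generate_study(truth, study_design(), error_model(0.2, 0.2),
#'                      seed = 42)
#' @export
generate_study <- function(model, design = study_design(),
                           error = error_model(),
                           random_effects = NULL, seed,
                           schedule = build_schedule(25, 20)) {
  stopifnot(inherits(model, "structural_model"),
            inherits(design, "study_design"),
            inherits(error, "error_model"))
  if (missing(seed)) stopf("`seed` is required")
  re <- random_effects %||% random_effects()
  horizon <- schedule_horizon(schedule)
  if (any(design$sampling_days > horizon))
    stopf("design sampling day %g outside the dosing horizon %g",
          max(design$sampling_days), horizon)

  cohorts <- data.frame(day = rep(design$sampling_days,
                                  times = vapply(design$sampling_days,
                                                 function(d)
                                                   if (design$day14_n2 && d == 14)
                                                     max(1L, design$animals_per_day - 1L)
                                                   else design$animals_per_day,
                                                 0L)))
  cohorts$id <- sprintf("M%02d", seq_len(nrow(cohorts)))

  emap <- eta_param_map(model$expansion$kind)
  has_eta <- length(emap) > 0 &&
    (re$omega2_rate > 0 || re$omega2_ceiling > 0)

  with_seed(seed, {
    etas <- if (has_eta)
      data.frame(rate = rnorm(nrow(cohorts), 0, sqrt(re$omega2_rate)),
                 ceiling = rnorm(nrow(cohorts), 0, sqrt(re$omega2_ceiling)))
    else NULL

    # without ETAs every animal shares one population trajectory
    pred_for <- function(i) {
      m <- model
      if (has_eta) {
        pars <- as.list(m$expansion$params)
        for (role in names(emap))
          if (emap[[role]] %in% names(pars))
            pars[[emap[[role]]]] <- pars[[emap[[role]]]] * exp(etas[i, role])
        m <- structural_model(m$parameters,
                              expansion_fn(m$expansion$kind, pars),
                              m$scaling)
      }
      sim <- simulate_profile(m, schedule, cohorts$day[i])
      setNames(sim$concentration[sim$compartment %in% c("serum", "spleen")],
               c("serum", "spleen")[seq_len(min(2, m$n_compartments))])
    }
    preds <- if (has_eta) {
      lapply(seq_len(nrow(cohorts)), pred_for)
    } else {
      sim <- simulate_profile(model, schedule, design$sampling_days)
      lk <- lapply(design$sampling_days, function(d) {
        sel <- sim$time == d & sim$compartment %in% c("serum", "spleen")
        setNames(sim$concentration[sel],
                 as.character(sim$compartment[sel]))
      })
      names(lk) <- as.character(design$sampling_days)
      lapply(seq_len(nrow(cohorts)), function(i)
        lk[[as.character(cohorts$day[i])]])
    }

    draw_obs <- function(pred, sigma) {
      repeat {
        o <- pred * (1 + rnorm(1, 0, sigma))
        if (o > 0) return(o)
      }
    }
    obs <- do.call(rbind, lapply(seq_len(nrow(cohorts)), function(i) {
      do.call(rbind, lapply(design$streams, function(s) {
        sigma <- if (s == "serum") error$sigma_serum else error$sigma_spleen
        data.frame(id = cohorts$id[i], time = cohorts$day[i], stream = s,
                   conc = if (sigma > 0) draw_obs(preds[[i]][[s]], sigma)
                          else preds[[i]][[s]])
      }))
    }))
    weights <- data.frame(
      id = cohorts$id, day = cohorts$day,
      weight_g = spleen_weight(cohorts$day, design, model$expansion))

    study_dataset(obs, schedule, spleen_weights = weights, design = design,
                  provenance = list(
                    seed = seed,
                    expansion = model$expansion$kind,
                    parameters = unlist(model$parameters),
                    expansion_params = model$expansion$params,
                    sigma = c(serum = error$sigma_serum,
                              spleen = error$sigma_spleen),
                    omega2 = c(rate = re$omega2_rate,
                               ceiling = re$omega2_ceiling)))
  })
}

#' Truncate a study to an early-phase window
#'
#' Retains observations and dose events at or before `t_max` — the
#' "soluble phase" workflow fits the first four weeks (before appreciable
#' precipitation) to anchor `V1` and `K12`.
#'
#' @param dataset A [study_dataset()].
#' @param t_max Cutoff time in days.
#' @return A truncated [study_dataset()].
#' @export
truncate_study <- function(dataset, t_max) {
  stopifnot(inherits(dataset, "study_dataset"))
  check_scalar(t_max, "t_max", 0, strict = TRUE)
  obs <- dataset$observations[dataset$observations$time <= t_max, ,
                              drop = FALSE]
  if (nrow(obs) == 0L)
    stopf("no observations at or before t = %g", t_max)
  sched <- dataset$schedule[dataset$schedule$time <= t_max, , drop = FALSE]
  sched <- as_schedule(sched$time, sched$amount)
  attr(sched, "horizon") <- min(schedule_horizon(dataset$schedule), t_max)
  w <- dataset$spleen_weights
  if (!is.null(w)) w <- w[w$day <= t_max, , drop = FALSE]
  study_dataset(obs, sched, spleen_weights = w, design = dataset$design,
                provenance = dataset$provenance)
}
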