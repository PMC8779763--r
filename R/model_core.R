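#' Compartmental model parameters
#'
#' Rate constants and volumes for the two- or three-compartment model.
#' Compartment 1 is serum (receives doses, eliminates), compartment 2 is
#' spleen, and the optional compartment 3 is a peripheral compartment
#' exchanging with serum. Volumes are apparent volumes per kg body weight.
#'
#' @param V1 Serum compartment volume (L/kg).
#' @param V2 Baseline spleen compartment volume (L/kg); the effective volume
#'   at time `t` is `V2 * f(t)`.
#' @param K Elimination rate constant from serum (1/day).
#' @param K12,K21 Serum<->spleen intercompartmental rate constants (1/day).
#' @param V3,K13,K31 Peripheral compartment volume and rate constants; all
#'   three must be given together for a three-compartment model.
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(V1, V2, K, K12, K21,
                          V3 = NULL, K13 = NULL, K31 = NULL) {
  core <- c(V1 = V1, V2 = V2, K = K, K12 = K12, K21 = K21)
  for (nm in names(core)) check_scalar(core[[nm]], nm, 0, strict = nm %in% c("V1", "V2"))
  per <- c(V3 = V3, K13 = K13, K31 = K31)
  if (length(per) %in% c(1L, 2L))
    stopf("V3, K13, K31 must be supplied together for a 3-compartment model")
  if (length(per) == 3L)
    for (nm in names(per)) check_scalar(per[[nm]], nm, 0)
  structure(as.list(c(core, per)), class = "pk_parameters")
}

n_compartments <- function(params) if (is.null(params$V3)) 2L else 3L

#' Scaling convention for expansion-modulated rate constants
#'
#' The expansion function enlarges the spleen compartment volume. Under the
#' default convention, the spleen-to-serum rate constant `K21` and the
#' elimination constant `K` are divided by `f(t)` (sequestered drug returns
#' and clears more slowly as the compartment expands); either can be switched
#' off for sensitivity analysis.
#'
#' @param scale_K21,scale_K `"inverse_f"` (default) or `"none"`.
#' @return An object of class `scaling_convention`.
#' @export
scaling_convention <- function(scale_K21 = c("inverse_f", "none"),
                               scale_K = c("inverse_f", "none")) {
  structure(list(scale_K21 = match.arg(scale_K21),
                 scale_K = match.arg(scale_K)),
            class = "scaling_convention")
}

#' Structural pharmacokinetic model
#'
#' Binds parameters, an expansion function, and the rate-constant scaling
#' convention into a simulatable model. Serum observations map to
#' compartment 1 and spleen observations to compartment 2; elimination is
#' from compartment 1 only.
#'
#' @param parameters A [pk_parameters()] object.
#' @param expansion An [expansion_fn()]; defaults to the constant (base
#'   model) expansion.
#' @param scaling A [scaling_convention()].
#' @return An object of class `structural_model`.
#' @examples
#' m <- structural_model(
#'   pk_parameters(V1 = 2.43, V2 = 0.00516, K = 0.033, K12 = 0.183,
#'                 K21 = 0.00287))
#' @export
structural_model <- function(parameters,
                             expansion = expansion_fn("constant"),
                             scaling = scaling_convention()) {
  stopifnot(inherits(parameters, "pk_parameters"),
            inherits(expansion, "expansion_fn"),
            inherits(scaling, "scaling_convention"))
  structure(list(parameters = parameters, expansion = expansion,
                 scaling = scaling,
                 n_compartments = n_compartments(parameters)),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat(sprintf("<structural_model> %d-compartment, expansion = %s\n",
              x$n_compartments, x$expansion$kind))
  p <- unlist(x$parameters)
  cat("  ", paste(names(p), signif(p, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Build a weekly oral dosing schedule
#'
#' Doses are modelled as instantaneous boluses into the serum compartment
#' (trough-only sampling precludes estimating absorption). The first dose is
#' given on day 1 and in-week days 1-5 correspond to Monday-Friday, so week
#' `w` doses fall on days `7*(w-1) + {1..5}`.
#'
#' @param dose_mg_per_kg Dose per administration (mg/kg body weight).
#' @param weeks Number of dosing weeks.
#' @param pattern In-week dosing days as integers in 1..7 (default `1:5`,
#'   Monday through Friday).
#' @return A `dose_schedule`: data frame with columns `time` (days) and
#'   `amount` (mg/kg), plus regimen metadata attributes.
#' @examples
#' sched <- build_schedule(25, 20)       # 100 doses, 2500 mg/kg total
#' cumulative_dose(sched, 98.1)          # 1750 mg/kg = 1.75 g/kg
#' @export
build_schedule <- function(dose_mg_per_kg, weeks, pattern = 1:5) {
  check_scalar(dose_mg_per_kg, "dose_mg_per_kg", 0, strict = TRUE)
  check_scalar(weeks, "weeks", 1)
  pattern <- sort(unique(as.integer(pattern)))
  if (length(pattern) == 0L) stopf("dosing `pattern` must not be empty")
  if (any(pattern < 1L | pattern > 7L))
    stopf("dosing `pattern` entries must be in-week days 1..7")
  times <- as.numeric(outer(pattern, 7 * (seq_len(weeks) - 1), `+`))
  times <- sort(times)
  structure(data.frame(time = times, amount = dose_mg_per_kg),
            class = c("dose_schedule", "data.frame"),
            regimen = list(dose_mg_per_kg = dose_mg_per_kg, weeks = weeks,
                           pattern = pattern),
            horizon = 7 * weeks)
}

as_schedule <- function(times, amounts) {
  o <- order(times)
  structure(data.frame(time = times[o], amount = amounts[o]),
            class = c("dose_schedule", "data.frame"),
            horizon = max(times) + 7)
}

schedule_horizon <- function(schedule) {
  h <- attr(schedule, "horizon")
  if (is.null(h)) max(schedule$time) + 7 else h
}

#' Cumulative administered dose
#'
#' @param schedule A [build_schedule()] result.
#' @param t Time in days.
#' @return Total dose administered up to and including time `t` (mg/kg).
#' @export
cumulative_dose <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (any(t < 0)) stopf("`t` must be non-negative")
  vapply(t, function(ti) sum(schedule$amount[schedule$time <= ti]), 0)
}

#' Right-hand side of the compartmental ODE system
#'
#' State is drug *amount* per kg body weight in each compartment (the
#' time-varying volume never enters the state); concentrations are derived
#' at output. Under the default scaling convention `K21(t) = K21 / f(t)` and
#' `K(t) = K / f(t)`:
#' `dA1/dt = -(K(t) + K12) A1 + K21(t) A2` and
#' `dA2/dt = K12 A1 - K21(t) A2`, with a symmetric `K13`/`K31` exchange for
#' the three-compartment model. The mass-balance identity
#' `sum(dA) = -K(t) A1` holds for every state.
#'
#' @param amounts Numeric state vector (mg/kg), length = n compartments.
#' @param t Time in days.
#' @param model A [structural_model()].
#' @return `d(amounts)/dt` (mg/kg/day).
#' @export
rhs <- function(amounts, t, model) {
  stopifnot(inherits(model, "structural_model"))
  n <- model$n_compartments
  if (length(amounts) != n)
    stopf("state has length %d but model has %d compartments",
          length(amounts), n)
  if (any(!is.finite(amounts)))
    stopf("non-finite state at t = %g", t)
  p <- model$parameters
  f <- fx_eval(model$expansion, t)
  Ke <- if (model$scaling$scale_K == "inverse_f") p$K / f else p$K
  K21e <- if (model$scaling$scale_K21 == "inverse_f") p$K21 / f else p$K21
  d1 <- -(Ke + p$K12) * amounts[1] + K21e * amounts[2]
  d2 <- p$K12 * amounts[1] - K21e * amounts[2]
  if (n == 3L) {
    d1 <- d1 - p$K13 * amounts[1] + p$K31 * amounts[3]
    d3 <- p$K13 * amounts[1] - p$K31 * amounts[3]
    c(d1, d2, d3)
  } else {
    c(d1, d2)
  }
}

#' Simulate concentration-time profiles under a dosing schedule
#'
#' Integrates the model with an adaptive Dormand-Prince 5(4) method,
#' applying bolus jumps `A1 <- A1 + amount` at each dose event. An output
#' time coinciding with a dose time is evaluated *before* the dose (trough
#' convention). Concentrations are `C1 = A1/V1` and `C2 = A2/(V2 * f(t))`.
#'
#' @param model A [structural_model()].
#' @param schedule A [build_schedule()] dose schedule.
#' @param times Output time grid (days, non-negative).
#' @param rtol,atol Integrator tolerances (defaults 1e-9 / 1e-12; the rate
#'   constants span several orders of magnitude).
#' @return A tidy data frame with columns `time`, `compartment`
#'   (`serum`/`spleen`/`peripheral`), `amount` (mg/kg) and `concentration`
#'   (mg/L). Attribute `mass_balance` holds per-time administered, in-body
#'   and eliminated amounts.
#' @export
simulate_profile <- function(model, schedule, times,
                             rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(model, "structural_model"),
            inherits(schedule, "dose_schedule"))
  if (any(!is.finite(times)) || any(times < 0))
    stopf("`times` must be finite and non-negative")
  o <- order(times)
  ts <- times[o]
  n <- model$n_compartments
  p <- model$parameters
  amounts <- tryCatch(
    .ode_simulate_cpp(ts, schedule$time, schedule$amount, n,
                      p$K, p$K12, p$K21,
                      if (n == 3L) p$K13 else 0, if (n == 3L) p$K31 else 0,
                      model$scaling$scale_K == "inverse_f",
                      model$scaling$scale_K21 == "inverse_f",
                      expansion_kind_code(model$expansion$kind),
                      as.numeric(model$expansion$params), rtol, atol),
    error = function(e)
      stopf("simulation failed (%d-compartment, expansion '%s') on [0, %g]: %s",
            n, model$expansion$kind, max(ts), conditionMessage(e)))
  # undo the sort
  inv <- order(o)
  amounts <- amounts[inv, , drop = FALSE]
  f <- fx_eval(model$expansion, times)
  vols <- cbind(p$V1, p$V2 * f, if (n == 3L) p$V3)
  cmt_names <- c("serum", "spleen", if (n == 3L) "peripheral")
  out <- data.frame(
    time = rep(times, times = n),
    compartment = factor(rep(cmt_names, each = length(times)),
                         levels = cmt_names),
    amount = as.numeric(amounts[, seq_len(n)]),
    concentration = as.numeric(amounts[, seq_len(n)] / vols))
  attr(out, "mass_balance") <- data.frame(
    time = times,
    administered = cumulative_dose(schedule, times) -
      # a dose exactly at an output time is applied after evaluation
      vapply(times, function(ti)
        sum(schedule$amount[abs(schedule$time - ti) <= 1e-9]), 0),
    in_body = rowSums(amounts[, seq_len(n), drop = FALSE]),
    eliminated = amounts[, n + 1L])
  out
}

#' Mass-balance check for a simulation
#'
#' @param sim Output of [simulate_profile()].
#' @return Data frame with the per-time relative mass-balance error
#'   `(administered - in_body - eliminated) / administered` (0 where nothing
#'   has been administered).
#' @export
mass_balance <- function(sim) {
  mb <- attr(sim, "mass_balance")
  if (is.null(mb)) stopf("`sim` carries no mass-balance attribute")
  mb$rel_error <- ifelse(mb$administered > 0,
                         (mb$administered - mb$in_body - mb$eliminated) /
                           mb$administered, 0)
  mb
}

#' Analytic two-compartment solution for a single bolus (constant volumes)
#'
#' Closed-form bi-exponential solution used as an independent oracle for the
#' numerical integrator when `f(t) = 1`. The rate matrix
#' `M = [[-(K+K12), K21], [K12, -K21]]` has eigenvalues solving
#' `lambda^2 + (K + K12 + K21) lambda + K*K21 = 0`; the state is propagated
#' with the exact matrix exponential (Lagrange form for distinct
#' eigenvalues, the Jordan limit form when they coincide).
#'
#' @param params A [pk_parameters()] object (two-compartment).
#' @param bolus Bolus amount into compartment 1 at `t = 0` (mg/kg).
#' @param times Output times (days).
#' @return Data frame `time`, `C1`, `C2` (mg/L).
#' @export
analytic_two_compartment <- function(params, bolus, times) {
  stopifnot(inherits(params, "pk_parameters"))
  if (n_compartments(params) != 2L)
    stopf("analytic solution is for the two-compartment model")
  K <- params$K; K12 <- params$K12; K21 <- params$K21
  b <- K + K12 + K21
  disc <- b^2 - 4 * K * K21
  M <- matrix(c(-(K + K12), K12, K21, -K21), 2, 2)
  A <- vapply(times, function(t) {
    if (disc > 1e-12 * b^2) {
      l1 <- (-b + sqrt(disc)) / 2
      l2 <- (-b - sqrt(disc)) / 2
      E <- (exp(l1 * t) * (M - l2 * diag(2)) -
              exp(l2 * t) * (M - l1 * diag(2))) / (l1 - l2)
    } else {
      l <- -b / 2
      E <- exp(l * t) * (diag(2) + t * (M - l * diag(2)))
    }
    E %*% c(bolus, 0)
  }, numeric(2))
  data.frame(time = times, C1 = A[1, ] / params$V1, C2 = A[2, ] / params$V2)
}
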