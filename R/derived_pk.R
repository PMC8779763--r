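#' Total volume of distribution at a timepoint
#'
#' Sum of the serum compartment volume and the expanded spleen compartment
#' volume: `V1 + V2 * f(t)`.
#'
#' @param model A [structural_model()].
#' @param t Time(s) in days.
#' @return Total Vd (L/kg), non-decreasing in `t` for non-negative
#'   expansion parameters.
#' @export
vd_total <- function(model, t) {
  stopifnot(inherits(model, "structural_model"))
  p <- model$parameters
  p$V1 + p$V2 * fx_eval(model$expansion, t)
}

#' Time-varying elimination half-life
#'
#' Default (`"algebraic"`) convention: first-order elimination from the
#' total distribution volume,
#' `t_half(t) = ln(2) * (V1 + V2 * f(t)) / (K(t) * V1)` with `K(t)` scaled
#' per the model's convention (`K / f(t)` by default). With constant
#' expansion and the Table-style base parameters this reduces to the
#' familiar `ln(2) * Vd / CL`. The `"eigen"` convention instead freezes the
#' rate-constant matrix at time `t` and returns `ln(2) / |lambda_slow|`
#' from its slowest eigenvalue, as a sensitivity alternative.
#'
#' @param model A [structural_model()].
#' @param t Time(s) in days.
#' @param convention `"algebraic"` (default) or `"eigen"`.
#' @return Half-life in days.
#' @export
half_life <- function(model, t, convention = c("algebraic", "eigen")) {
  stopifnot(inherits(model, "structural_model"))
  convention <- match.arg(convention)
  p <- model$parameters
  if (p$K <= 0) stopf("half-life undefined for K = 0")
  f <- fx_eval(model$expansion, t)
  Ke <- if (model$scaling$scale_K == "inverse_f") p$K / f else rep(p$K, length(f))
  if (convention == "algebraic")
    return(log(2) * (p$V1 + p$V2 * f) / (Ke * p$V1))
  K21e <- if (model$scaling$scale_K21 == "inverse_f") p$K21 / f
          else rep(p$K21, length(f))
  vapply(seq_along(f), function(i) {
    M <- if (model$n_compartments == 3L)
      matrix(c(-(Ke[i] + p$K12 + p$K13), p$K12, p$K13,
               K21e[i], -K21e[i], 0,
               p$K31, 0, -p$K31), 3, 3)
    else
      matrix(c(-(Ke[i] + p$K12), p$K12, K21e[i], -K21e[i]), 2, 2)
    ev <- eigen(M, only.values = TRUE)$values
    ev <- Re(ev[abs(Im(ev)) < 1e-12])
    # slowest *eliminating* mode: zero eigenvalues belong to decoupled
    # compartments (e.g. K12 = K21 = 0) and carry no drug
    ev <- ev[ev < -1e-300]
    if (!length(ev)) stopf("degenerate rate matrix at t = %g", t[i])
    log(2) / abs(max(ev))
  }, 0)
}

# Spleen drug mass per kg body weight (mg/kg) at the requested times:
# C2(t) [mg/L] * W_spleen(t) [L per kg body weight].
spleen_mass_per_kg <- function(model, schedule, spleen_weight_fn, t,
                               rtol = 1e-9, atol = 1e-12) {
  sim <- simulate_profile(model, schedule, t, rtol = rtol, atol = atol)
  c2 <- sim$concentration[sim$compartment == "spleen"]
  w <- vapply(t, spleen_weight_fn, 0)
  if (any(w < 0)) stopf("spleen_weight_fn returned a negative volume")
  c2 * w
}

#' Cumulative fraction of administered dose sequestered in the spleen
#'
#' Spleen drug mass (predicted spleen concentration times spleen volume,
#' both per kg body weight) divided by the cumulative dose administered up
#' to `t`.
#'
#' @param model A [structural_model()].
#' @param schedule A [build_schedule()] dose schedule.
#' @param spleen_weight_fn Function of time returning spleen volume in L
#'   per kg body weight (tissue density 1 g/mL, so grams/1000/body-kg).
#' @param t Time(s) in days, after the first dose.
#' @return Fraction(s) in `[0, 1]`.
#' @export
cumulative_fraction_sequestered <- function(model, schedule,
                                            spleen_weight_fn, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (any(t < min(schedule$time)))
    stopf("cumulative fraction undefined before the first dose (day %g)",
          min(schedule$time))
  m <- spleen_mass_per_kg(model, schedule, spleen_weight_fn, t)
  m / cumulative_dose(schedule, t)
}

#' Per-dose (interval) fraction sequestered in the spleen
#'
#' Change in spleen drug mass across `(t_prev, t_now]` divided by the dose
#' administered in that interval.
#'
#' @inheritParams cumulative_fraction_sequestered
#' @param t_prev,t_now Interval endpoints in days, `t_prev < t_now`, with
#'   at least one dose in `(t_prev, t_now]`.
#' @return A single fraction (can be negative if spleen mass declined).
#' @export
per_dose_fraction_sequestered <- function(model, schedule, spleen_weight_fn,
                                          t_prev, t_now) {
  stopifnot(inherits(schedule, "dose_schedule"))
  check_scalar(t_prev, "t_prev", 0)
  check_scalar(t_now, "t_now", 0)
  if (t_prev >= t_now) stopf("`t_prev` must be < `t_now`")
  d <- cumulative_dose(schedule, t_now) - cumulative_dose(schedule, t_prev)
  if (d <= 0)
    stopf("no dose administered in (%g, %g]", t_prev, t_now)
  m <- spleen_mass_per_kg(model, schedule, spleen_weight_fn,
                          c(t_prev, t_now))
  (m[2] - m[1]) / d
}

#' Derived pharmacokinetic trajectory
#'
#' Evaluates the time-varying derived quantities on a shared grid: serum,
#' spleen and total distribution volumes, half-life, spleen drug mass and
#' (when a spleen weight function is supplied) cumulative and per-interval
#' sequestered dose fractions.
#'
#' @param model A [structural_model()].
#' @param schedule A [build_schedule()] dose schedule.
#' @param times Time grid (days).
#' @param spleen_weight_fn Optional function of time returning spleen
#'   volume (L per kg body weight); without it the sequestration columns
#'   are `NA`.
#' @param convention Half-life convention, see [half_life()].
#' @return A `derived_trajectory` data frame with columns `time`,
#'   `Vd_serum`, `Vd_spleen`, `Vd_total`, `half_life`, `spleen_mass`,
#'   `cumulative_fraction`, `per_dose_fraction` (the interval ending at
#'   each grid point; `NA` where the interval contains no dose).
#' @export
derived_trajectory <- function(model, schedule, times,
                               spleen_weight_fn = NULL,
                               convention = "algebraic") {
  stopifnot(inherits(model, "structural_model"))
  times <- sort(unique(times))
  p <- model$parameters
  f <- fx_eval(model$expansion, times)
  out <- data.frame(
    time = times,
    Vd_serum = rep(p$V1, length(times)),
    Vd_spleen = p$V2 * f,
    Vd_total = p$V1 + p$V2 * f,
    half_life = half_life(model, times, convention),
    spleen_mass = NA_real_, cumulative_fraction = NA_real_,
    per_dose_fraction = NA_real_)
  if (!is.null(spleen_weight_fn)) {
    m <- spleen_mass_per_kg(model, schedule, spleen_weight_fn, times)
    cum <- cumulative_dose(schedule, times)
    out$spleen_mass <- m
    out$cumulative_fraction <- ifelse(cum > 0, m / cum, NA_real_)
    if (length(times) > 1L) {
      dd <- diff(cum)
      out$per_dose_fraction[-1L] <- ifelse(dd > 0, diff(m) / dd, NA_real_)
    }
  }
  class(out) <- c("derived_trajectory", "data.frame")
  out
}

#' Consensus (mean and SD) of derived trajectories across models
#'
#' Pointwise mean and sample standard deviation of each derived quantity
#' across a set of trajectories on an identical time grid — the composite
#' view across the sigmoidal expansion families.
#'
#' @param trajectories List of [derived_trajectory()] objects sharing one
#'   time grid.
#' @return A long data frame `time`, `quantity`, `mean`, `sd` (SD is 0 for
#'   a single trajectory).
#' @export
consensus <- function(trajectories) {
  if (!is.list(trajectories) || length(trajectories) < 1L)
    stopf("`trajectories` must be a non-empty list")
  if (!all(vapply(trajectories, inherits, TRUE, "derived_trajectory")))
    stopf("all elements must be derived_trajectory objects")
  grid <- trajectories[[1L]]$time
  for (tr in trajectories)
    if (length(tr$time) != length(grid) || any(tr$time != grid))
      stopf("trajectories must share an identical time grid")
  qty <- setdiff(names(trajectories[[1L]]), "time")
  out <- do.call(rbind, lapply(qty, function(q) {
    vals <- vapply(trajectories, function(tr) as.numeric(tr[[q]]),
                   numeric(length(grid)))
    vals <- matrix(vals, nrow = length(grid))
    data.frame(time = grid, quantity = q,
               mean = rowMeans(vals),
               sd = if (ncol(vals) > 1L) apply(vals, 1, sd) else
                 rep(0, length(grid)))
  }))
  rownames(out) <- NULL
  out
}
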