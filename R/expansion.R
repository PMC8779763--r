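#' Volume-expansion functions f(t)
#'
#' An expansion function is a dimensionless, non-decreasing multiplier on the
#' baseline volume of the tissue (spleen) compartment, normalised so that
#' `f(0) = 1`. It models the apparent growth of the compartment as insoluble
#' drug accumulates. Five families are supported:
#'
#' * `constant`: `f(t) = 1` (the base, fixed-volume model);
#' * `linear`: `f(t) = 1 + X * t`, with `X` the expansion rate (1/day);
#' * `hill_exp` (exponentiated Hill): `f(t) = exp(Emax * t^Hill /
#'   (T50^Hill + t^Hill))`, plateau `exp(Emax)`, `T50` in days;
#' * `logistic`: baseline-normalised logistic with fold ceiling `M1`,
#'   steepness `M2` (1/day) and inflection location `M3` (days);
#' * `sqrt_sigmoid` (rational square-root sigmoid): baseline-normalised,
#'   fold ceiling `B1`, inflection time `B2` (days), width `B3` (days^2).
#'
#' The logistic and square-root families are shifted/rescaled so that
#' `f(0) = 1` exactly while preserving the family's plateau parameter and
#' inflection location: with `L(t) = 1/(1 + exp(-M2*(t - M3)))` the logistic
#' form is `f(t) = 1 + (M1 - 1) * (L(t) - L(0)) / (1 - L(0))`, and with
#' `S(t) = (1 + (t - B2)/sqrt((t - B2)^2 + B3))/2` the square-root form is
#' `f(t) = 1 + (B1 - 1) * (S(t) - S(0)) / (1 - S(0))`.
#'
#' @param kind One of `"constant"`, `"linear"`, `"hill_exp"`, `"logistic"`,
#'   `"sqrt_sigmoid"`.
#' @param ... Named numeric parameters for the chosen kind (see Details).
#' @return An object of class `expansion_fn`.
#' @examples
#' f <- expansion_fn("hill_exp", Emax = 6.99, T50 = 49, Hill = 3.71)
#' fx_eval(f, c(0, 49, 140))
#' @export
expansion_fn <- function(kind = c("constant", "linear", "hill_exp",
                                  "logistic", "sqrt_sigmoid"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) &&
      is.list(params[[1L]]))
    params <- params[[1L]]
  params <- unlist(params)
  need <- expansion_param_names(kind)
  if (length(need)) {
    missing <- setdiff(need, names(params))
    if (length(missing))
      stopf("expansion kind '%s' requires parameter(s): %s", kind,
            paste(missing, collapse = ", "))
    params <- params[need]
    for (nm in need) {
      if (!is.finite(params[[nm]]))
        stopf("expansion parameter `%s` must be finite", nm)
      if (params[[nm]] < 0)
        stopf("expansion parameter `%s` must be non-negative (got %g)",
              nm, params[[nm]])
    }
    # ceilings are fold-expansions (>= 1); scale/width parameters must be
    # strictly positive to keep the form well defined
    strict_pos <- c(hill_exp = "T50", logistic = "M2", sqrt_sigmoid = "B3")
    if (kind %in% names(strict_pos)) {
      sp <- strict_pos[[kind]]
      if (params[[sp]] <= 0) stopf("expansion parameter `%s` must be > 0", sp)
    }
    ceil <- c(logistic = "M1", sqrt_sigmoid = "B1")
    if (kind %in% names(ceil) && params[[ceil[[kind]]]] < 1)
      stopf("fold ceiling `%s` must be >= 1", ceil[[kind]])
    if (kind == "hill_exp" && params[["Hill"]] <= 0)
      stopf("expansion parameter `Hill` must be > 0")
  } else {
    params <- numeric(0)
  }
  structure(list(kind = kind, params = params), class = "expansion_fn")
}

expansion_param_names <- function(kind) {
  switch(kind,
    constant = character(0),
    linear = "X",
    hill_exp = c("Emax", "T50", "Hill"),
    logistic = c("M1", "M2", "M3"),
    sqrt_sigmoid = c("B1", "B2", "B3"))
}

expansion_kind_code <- function(kind) {
  match(kind, c("constant", "linear", "hill_exp", "logistic",
                "sqrt_sigmoid")) - 1L
}

is_sigmoid <- function(f) f$kind %in% c("hill_exp", "logistic", "sqrt_sigmoid")

#' @export
print.expansion_fn <- function(x, ...) {
  cat("<expansion_fn>", x$kind)
  if (length(x$params))
    cat(":", paste(names(x$params), signif(x$params, 4), sep = " = ",
                   collapse = ", "))
  cat("\n")
  invisible(x)
}

check_expansion_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stopf("`t` must be finite numeric")
  if (any(t < 0)) stopf("`t` must be non-negative (time in days)")
  t
}

#' Evaluate an expansion function
#'
#' @param f An [expansion_fn()].
#' @param t Time(s) in days, `t >= 0`.
#' @return Fold-expansion value(s), `>= 1` for non-negative parameters;
#'   `fx_eval(f, 0)` is exactly 1 for every kind.
#' @export
fx_eval <- function(f, t) {
  stopifnot(inherits(f, "expansion_fn"))
  t <- check_expansion_time(t)
  .fx_eval_cpp(expansion_kind_code(f$kind), as.numeric(f$params),
               as.numeric(t))
}

#' Analytic derivative of an expansion function
#'
#' @inheritParams fx_eval
#' @return `d f / d t` in 1/day; non-negative for non-negative parameters.
#' @export
fx_deriv <- function(f, t) {
  stopifnot(inherits(f, "expansion_fn"))
  t <- check_expansion_time(t)
  p <- f$params
  switch(f$kind,
    constant = rep(0, length(t)),
    linear = rep(p[["X"]], length(t)),
    hill_exp = {
      H <- p[["Hill"]]; T50 <- p[["T50"]]; Emax <- p[["Emax"]]
      th <- t^H
      d <- fx_eval(f, t) * Emax * H * T50^H * t^(H - 1) / (T50^H + th)^2
      # limit at t = 0: 0 for Hill > 1, Emax/T50 at Hill = 1, Inf below
      d[t == 0] <- if (H > 1) 0 else if (H == 1) Emax / T50 else Inf
      d
    },
    logistic = {
      M1 <- p[["M1"]]; M2 <- p[["M2"]]; M3 <- p[["M3"]]
      L <- 1 / (1 + exp(-M2 * (t - M3)))
      L0 <- 1 / (1 + exp(M2 * M3))
      (M1 - 1) / (1 - L0) * M2 * L * (1 - L)
    },
    sqrt_sigmoid = {
      B1 <- p[["B1"]]; B2 <- p[["B2"]]; B3 <- p[["B3"]]
      S0 <- 0.5 * (1 - B2 / sqrt(B2^2 + B3))
      (B1 - 1) / (1 - S0) * 0.5 * B3 / ((t - B2)^2 + B3)^1.5
    })
}

#' Plateau (t -> Inf limit) of an expansion function
#'
#' @param f An [expansion_fn()].
#' @return The finite limit for sigmoid kinds (`exp(Emax)`, `M1`, `B1`),
#'   1 for `constant`, `Inf` for `linear`.
#' @export
fx_plateau <- function(f) {
  stopifnot(inherits(f, "expansion_fn"))
  switch(f$kind,
    constant = 1,
    linear = Inf,
    hill_exp = exp(f$params[["Emax"]]),
    logistic = f$params[["M1"]],
    sqrt_sigmoid = f$params[["B1"]])
}

expansion_time_scale <- function(f) {
  switch(f$kind,
    hill_exp = f$params[["T50"]],
    logistic = f$params[["M3"]],
    sqrt_sigmoid = f$params[["B2"]],
    stopf("expansion kind '%s' has no sigmoid time scale", f$kind))
}

check_sigmoid <- function(f) {
  if (!is_sigmoid(f))
    stopf("operation requires a sigmoid expansion kind, not '%s'", f$kind)
  invisible(f)
}

#' Time of maximum expansion rate
#'
#' Locates the argmax of the analytic derivative of `f` on
#' `[0, 10 * time-scale]` by golden-section search (tolerance 1e-6 days).
#' For the symmetric square-root sigmoid this equals `B2`; for the
#' normalised logistic it equals `M3` (when `M3 >= 0`).
#'
#' @param f A sigmoid [expansion_fn()].
#' @return Inflection time in days.
#' @export
inflection_time <- function(f) {
  check_sigmoid(f)
  upper <- 10 * max(expansion_time_scale(f), 1)
  opt <- optimize(function(t) fx_deriv(f, t), c(0, upper), maximum = TRUE,
                  tol = 1e-6)
  opt$maximum
}

#' Time to reach a fraction of the plateau expansion
#'
#' Smallest `t` with `f(t) - 1 = q * (f(Inf) - 1)`, found by root bisection
#' to 1e-6-day tolerance (the expansion is monotone, so the root is unique).
#'
#' @param f A sigmoid [expansion_fn()].
#' @param q Fraction of the plateau expansion, in (0, 1).
#' @return Time in days.
#' @export
time_to_fraction_of_plateau <- function(f, q) {
  check_sigmoid(f)
  check_scalar(q, "q")
  if (q <= 0 || q >= 1) stopf("`q` must be in (0, 1)")
  target <- q * (fx_plateau(f) - 1)
  g <- function(t) (fx_eval(f, t) - 1) - target
  upper <- 10 * max(expansion_time_scale(f), 1)
  while (g(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e9) stopf("failed to bracket the %g-plateau time", q)
  }
  uniroot(g, c(0, upper), tol = 1e-6)$root
}
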