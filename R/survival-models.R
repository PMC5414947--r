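#' Survival curve: probability of survival vs burial time
#'
#' A monotone non-increasing piecewise-linear curve through knots
#' (time in minutes, survival probability). Piecewise-linear interpolation is
#' used deliberately: it preserves monotonicity, which smooth splines through
#' sparse digitized knots can violate. Beyond the last knot the last
#' probability is held constant.
#'
#' @param times_min strictly increasing knot times in minutes, starting at 0.
#' @param survival non-increasing survival probabilities in [0, 1].
#' @param version character label identifying the knot set.
#' @return an object of class `survival_curve`.
#' @export
survival_curve <- function(times_min, survival, version = "custom") {
  times_min <- as.numeric(times_min); survival <- as.numeric(survival)
  if (length(times_min) < 1 || length(times_min) != length(survival))
    stop("knot times and probabilities must be non-empty and equal length")
  if (times_min[1] != 0) stop("survival curve must start at time 0")
  if (any(diff(times_min) <= 0)) stop("knot times must be strictly increasing")
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]")
  if (any(diff(survival) > 0)) stop("survival must be non-increasing in time")
  structure(list(times_min = times_min, survival = survival,
                 version = version),
            class = "survival_curve")
}

#' Evaluate a survival curve
#'
#' @param curve a [survival_curve()].
#' @param t_min burial duration(s) in minutes, all `>= 0`.
#' @return survival probabilities, clamped to [0, 1]; constant beyond the
#'   last knot.
#' @export
survival_at <- function(curve, t_min) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t_min < 0)) stop("burial time must be non-negative")
  p <- stats::approx(curve$times_min, curve$survival, xout = t_min,
                     method = "linear", rule = 2)$y
  pmin(1, pmax(0, p))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve '%s': %d knots, %g min -> %g min, S(0) = %.2f\n",
              x$version, length(x$times_min), x$times_min[1],
              max(x$times_min), x$survival[1]))
  invisible(x)
}

#' Load a survival curve from a knot config file
#'
#' @param path YAML file with fields `version` and `knots`
#'   (list of `{time_min, survival}` pairs).
#' @return a `survival_curve`.
#' @export
read_survival_curve <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$knots)) stop("no 'knots' entry in curve config: ", path)
  survival_curve(vapply(cfg$knots, `[[`, numeric(1), "time_min"),
                 vapply(cfg$knots, `[[`, numeric(1), "survival"),
                 version = as.character(cfg$version %||% "unversioned"))
}

#' Write a survival curve to a knot config file
#' @param curve a `survival_curve`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  yaml::write_yaml(list(
    version = curve$version,
    knots = Map(function(t, s) list(time_min = t, survival = s),
                curve$times_min, curve$survival)), path)
  invisible(path)
}

#' The package's default avalanche survival curve
#'
#' Returns the shipped digitization of the Swiss accident-data survival curve
#' (see `inst/extdata/survival_curve_default.yaml`): survival near 0.9 during
#' the first ~10 minutes, a steep asphyxiation decline to about one third by
#' 35 minutes, and a low slowly-decaying tail. The knot set is an approximate
#' digitization of a published figure and is versioned so results can record
#' which curve they used; substitute your own knots via [read_survival_curve()]
#' for quantitative work.
#'
#' @return a `survival_curve`.
#' @export
default_survival_curve <- function() {
  read_survival_curve(system.file("extdata", "survival_curve_default.yaml",
                                  package = "avrescue", mustWork = TRUE))
}

#' Resuscitation-success (ROSC) model
#'
#' Probability of return of spontaneous circulation after `t` minutes of CPR:
#' `p1(t) = a * (1 - exp(-0.07 * t^1.3))`, a saturating curve rising from 0
#' towards the ceiling `a`, which encodes how long the patient was buried
#' before the arrest (see [default_triage_table()]).
#'
#' @param a success ceiling in [0, 1].
#' @param rate rate constant, default 0.07 per min^1.3.
#' @param exponent time exponent, default 1.3.
#' @return an object of class `rosc_model`.
#' @export
rosc_model <- function(a, rate = 0.07, exponent = 1.3) {
  stopifnot(length(a) == 1, a >= 0, a <= 1, rate > 0, exponent > 0)
  structure(list(a = a, rate = rate, exponent = exponent),
            class = "rosc_model")
}

#' Evaluate the ROSC model
#'
#' @param model a [rosc_model()].
#' @param t_cpr CPR duration(s) in minutes, all `>= 0`.
#' @return probabilities `a * (1 - exp(-rate * t^exponent))`.
#' @export
rosc_probability <- function(model, t_cpr) {
  stopifnot(inherits(model, "rosc_model"))
  if (any(t_cpr < 0)) stop("CPR duration must be non-negative")
  model$a * (1 - exp(-model$rate * t_cpr^model$exponent))
}

#' Mean ROSC probability over a CPR-duration grid
#'
#' The per-patient "average probability of survival" reported for the
#' resuscitation scenario: the arithmetic mean of [rosc_probability()] over
#' the tested CPR durations.
#'
#' @param model a [rosc_model()].
#' @param grid_min CPR durations in minutes, non-empty.
#' @return a single probability.
#' @export
mean_rosc_over_grid <- function(model, grid_min = 0:30) {
  if (length(grid_min) == 0) stop("grid must be non-empty")
  mean(rosc_probability(model, grid_min))
}

#' Triage parameter table: ROSC ceiling vs initial burial time
#'
#' @param t_burial_min burial times in minutes, strictly increasing.
#' @param a matching ROSC ceilings, non-increasing, in [0, 1].
#' @return an object of class `triage_table`.
#' @export
triage_table <- function(t_burial_min, a) {
  stopifnot(length(t_burial_min) >= 1, length(t_burial_min) == length(a),
            all(diff(t_burial_min) > 0), all(a >= 0 & a <= 1))
  if (any(diff(a) > 0))
    stop("the ROSC ceiling must be non-increasing in burial time")
  structure(list(t_burial_min = as.numeric(t_burial_min), a = as.numeric(a)),
            class = "triage_table")
}

#' The shipped triage table
#'
#' Ceilings `a` = 0.62, 0.25 and 0 for initial burial times of 12, 20 and 35
#' minutes (see `inst/extdata/triage_table_default.yaml`); other burial times
#' require a user-supplied ceiling.
#'
#' @return a `triage_table`.
#' @export
default_triage_table <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "triage_table_default.yaml",
                                     package = "avrescue", mustWork = TRUE))
  triage_table(vapply(cfg$entries, `[[`, numeric(1), "t_burial_min"),
               vapply(cfg$entries, `[[`, numeric(1), "a"))
}

#' Look up the ROSC ceiling for a burial time
#'
#' Exact-match lookup: the table is sparse clinical data, so no interpolation
#' is attempted between entries.
#'
#' @param table a [triage_table()].
#' @param t_burial_min initial burial time in minutes.
#' @return the ceiling `a`.
#' @export
triage_a <- function(table, t_burial_min) {
  stopifnot(inherits(table, "triage_table"))
  i <- match(t_burial_min, table$t_burial_min)
  if (is.na(i))
    stop("no triage entry for burial time ", t_burial_min, " min (have: ",
         paste(table$t_burial_min, collapse = ", "),
         "); supply the ceiling 'a' explicitly")
  table$a[i]
}
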