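#' Configuration for the resuscitation-triage scenario
#'
#' One rescuer, two subjects. Patient 1 has just been extricated after
#' `t_burial1_min` minutes of burial, is normothermic and pulseless; patient 2
#' is still buried. The rescuer performs CPR on patient 1 for `t_cpr` minutes
#' and then searches for and excavates patient 2. Patient 1's survival is the
#' ROSC probability after `t_cpr` minutes of CPR with ceiling `a`; patient 2's
#' burial lasts `t_burial1 + t_cpr + t_search + d_burial / v_dig` minutes,
#' where the search time is a Gaussian (mean 2 min, sd 1 min, negatives set
#' to zero) and the burial depth is resampled from the empirical distribution.
#' The two survival probabilities are independent, so the expected number of
#' survivors is `p1 + p2`.
#'
#' @param t_burial1_min initial burial time of patient 1, minutes.
#' @param depth_source an `empirical_distribution` of burial depths (metres).
#' @param a ROSC ceiling; by default looked up in `table` for `t_burial1_min`.
#' @param table a [triage_table()], default [default_triage_table()].
#' @param t_cpr_grid_min CPR durations to evaluate, default 0:30 minutes.
#' @param search_time_mean_min,search_time_sd_min Gaussian search-time
#'   parameters, defaults 2 and 1 minutes.
#' @param v_dig_m_per_min digging speed, default 0.15 m/min.
#' @param curve a [survival_curve()], default [default_survival_curve()].
#' @param n_runs Monte Carlo repetitions, default 10000.
#' @param seed integer seed.
#' @return a list of class `cpr_config`.
#' @export
cpr_config <- function(t_burial1_min, depth_source, a = NULL,
                       table = default_triage_table(),
                       t_cpr_grid_min = 0:30,
                       search_time_mean_min = 2, search_time_sd_min = 1,
                       v_dig_m_per_min = 0.15,
                       curve = default_survival_curve(),
                       n_runs = 10000, seed = 1L) {
  if (is.null(a)) a <- triage_a(table, t_burial1_min)
  stopifnot(t_burial1_min >= 0, a >= 0, a <= 1,
            inherits(depth_source, "empirical_distribution"),
            inherits(curve, "survival_curve"),
            length(t_cpr_grid_min) >= 1, all(t_cpr_grid_min >= 0),
            !is.unsorted(t_cpr_grid_min, strictly = TRUE),
            search_time_mean_min >= 0, search_time_sd_min >= 0,
            v_dig_m_per_min > 0, n_runs > 0)
  structure(list(t_burial1_min = t_burial1_min, a = a,
                 t_cpr_grid_min = as.numeric(t_cpr_grid_min),
                 search_time_mean_min = search_time_mean_min,
                 search_time_sd_min = search_time_sd_min,
                 v_dig_m_per_min = v_dig_m_per_min,
                 depth_source = depth_source, curve = curve,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "cpr_config")
}

#' Sample search times for patient 2
#'
#' Gaussian with the configured mean and standard deviation; negative draws
#' are set to zero (a censored normal).
#'
#' @param n number of draws.
#' @param mean_min,sd_min Gaussian parameters in minutes.
#' @return non-negative search times, minutes.
#' @export
sample_search_time <- function(n, mean_min = 2, sd_min = 1) {
  pmax(0, stats::rnorm(n, mean_min, sd_min))
}

# one batch of scenario draws shared across the whole CPR grid
cpr_draws <- function(config, n = config$n_runs) {
  list(t_search_min = sample_search_time(n, config$search_time_mean_min,
                                         config$search_time_sd_min),
       d_burial_m = dist_sample(config$depth_source, n))
}

#' Simulate patient 2's survival probabilities for one CPR duration
#'
#' @param config a [cpr_config()].
#' @param t_cpr_min CPR duration spent on patient 1, minutes.
#' @param draws optional precomputed draws (internal); by default `n_runs`
#'   fresh draws under the config seed.
#' @return survival probabilities of patient 2, one per run.
#' @export
simulate_patient2_survival <- function(config, t_cpr_min, draws = NULL) {
  stopifnot(inherits(config, "cpr_config"), t_cpr_min >= 0)
  if (is.null(draws))
    draws <- with_seed(derive_seed(config$seed, "cpr", config$t_burial1_min),
                       cpr_draws(config))
  total <- config$t_burial1_min + t_cpr_min + draws$t_search_min +
    draws$d_burial_m / config$v_dig_m_per_min
  survival_at(config$curve, total)
}

#' Evaluate the resuscitation scenario over the CPR-duration grid
#'
#' Patient 1's survival `p1` is deterministic given `t_cpr` (the ROSC formula
#' has no random inputs); patient 2's mean survival `mean_p2` is a Monte Carlo
#' average. One draw set (search time, burial depth) is shared across the
#' grid (common random numbers), so `mean_p2` is exactly non-increasing in
#' `t_cpr`: every extra CPR minute adds a minute to every sampled burial.
#' Combined statistics use the independence of the two patients:
#' `expected_survivors = p1 + mean_p2`, `p_both = p1 * mean_p2`,
#' `p_at_least_one = 1 - (1 - p1)(1 - mean_p2)`.
#'
#' @param config a [cpr_config()].
#' @return a `cpr_result`: a data frame with one row per CPR duration
#'   (`t_cpr_min`, `p1`, `mean_p2`, `se_p2`, `expected_survivors`, `p_both`,
#'   `p_at_least_one`, `half_sample_delta`) with attributes
#'   `optimal_t_cpr_min` (argmax of expected survivors, earliest on ties),
#'   `config`, and `curve_version`.
#' @export
run_cpr_grid <- function(config) {
  stopifnot(inherits(config, "cpr_config"))
  draws <- with_seed(derive_seed(config$seed, "cpr", config$t_burial1_min),
                     cpr_draws(config))
  model <- rosc_model(config$a)
  half <- seq_len(config$n_runs %/% 2)
  rows <- lapply(config$t_cpr_grid_min, function(t_cpr) {
    p2 <- simulate_patient2_survival(config, t_cpr, draws = draws)
    p1 <- rosc_probability(model, t_cpr)
    m2 <- mean(p2)
    data.frame(t_cpr_min = t_cpr, p1 = p1, mean_p2 = m2,
               se_p2 = stats::sd(p2) / sqrt(length(p2)),
               expected_survivors = p1 + m2,
               p_both = p1 * m2,
               p_at_least_one = 1 - (1 - p1) * (1 - m2),
               half_sample_delta = mean(p2[half]) - m2)
  })
  res <- do.call(rbind, rows)
  structure(res,
            optimal_t_cpr_min =
              res$t_cpr_min[which.max(res$expected_survivors)],
            config = config, curve_version = config$curve$version,
            class = c("cpr_result", "data.frame"))
}

#' Survival-optimal CPR duration
#'
#' @param result a `cpr_result` from [run_cpr_grid()].
#' @return the grid CPR duration maximizing the expected number of survivors;
#'   ties are broken toward the shortest duration (favouring the still-buried
#'   patient when indifferent).
#' @export
optimal_cpr_duration <- function(result) {
  stopifnot(inherits(result, "cpr_result"))
  result$t_cpr_min[which.max(result$expected_survivors)]
}

#' Sweep the resuscitation scenario over initial burial times
#'
#' Runs [run_cpr_grid()] for each (burial time, ceiling) pair of the triage
#' table under one root seed, sharing the victim draw set across cases so the
#' cases are directly comparable.
#'
#' @param depth_source an `empirical_distribution` of burial depths.
#' @param table a [triage_table()], default the shipped three-entry table.
#' @param n_runs,seed,... passed to [cpr_config()].
#' @return a list of class `cpr_sweep`: one `cpr_result` per burial time,
#'   named by the time in minutes, plus an `optima` data frame.
#' @export
run_burial_time_sweep <- function(depth_source,
                                  table = default_triage_table(),
                                  n_runs = 10000, seed = 1L, ...) {
  stopifnot(inherits(table, "triage_table"))
  results <- lapply(seq_along(table$t_burial_min), function(i) {
    cfg <- cpr_config(t_burial1_min = table$t_burial_min[i],
                      a = table$a[i], depth_source = depth_source,
                      table = table, n_runs = n_runs, seed = seed, ...)
    draws <- with_seed(derive_seed(seed, "cpr-sweep"), cpr_draws(cfg))
    model <- rosc_model(cfg$a)
    half <- seq_len(cfg$n_runs %/% 2)
    rows <- lapply(cfg$t_cpr_grid_min, function(t_cpr) {
      p2 <- simulate_patient2_survival(cfg, t_cpr, draws = draws)
      p1 <- rosc_probability(model, t_cpr)
      m2 <- mean(p2)
      data.frame(t_cpr_min = t_cpr, p1 = p1, mean_p2 = m2,
                 se_p2 = stats::sd(p2) / sqrt(length(p2)),
                 expected_survivors = p1 + m2, p_both = p1 * m2,
                 p_at_least_one = 1 - (1 - p1) * (1 - m2),
                 half_sample_delta = mean(p2[half]) - m2)
    })
    res <- do.call(rbind, rows)
    structure(res,
              optimal_t_cpr_min =
                res$t_cpr_min[which.max(res$expected_survivors)],
              config = cfg, curve_version = cfg$curve$version,
              class = c("cpr_result", "data.frame"))
  })
  names(results) <- as.character(table$t_burial_min)
  optima <- data.frame(
    t_burial1_min = table$t_burial_min, a = table$a,
    optimal_t_cpr_min = vapply(results, optimal_cpr_duration, numeric(1)))
  structure(list(results = results, optima = optima), class = "cpr_sweep")
}

#' @export
print.cpr_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Resuscitation scenario: burial %g min, a = %.2f, %d runs, curve '%s'\n",
              cfg$t_burial1_min, cfg$a, cfg$n_runs, attr(x, "curve_version")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Optimal CPR duration: %g min\n", attr(x, "optimal_t_cpr_min")))
  invisible(x)
}
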