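test_that("the probing-speed power law passes through the published endpoints", {
  expect_equal(search_speed(0.5), 13)
  expect_equal(search_speed(2.5), 1.5)
  expect_equal(search_speed(1.0), 13 * 0.5^(log(13 / 1.5) / log(5)))
  expect_equal(round(search_speed(1.0), 2), 5.13)
  grid <- seq(0.5, 2.5, by = 0.01)
  expect_true(all(diff(search_speed(grid)) < 0))
  expect_error(search_speed(0), "positive")
  expect_warning(v <- search_speed(3), "clamped")
  expect_equal(v, 1.5)
})

test_that("tabulated speed curves can replace the power law", {
  tab <- list(depth_m = c(0.5, 1.5, 2.5), speed_m_per_min = c(13, 6, 1.5),
              range_m = c(0.5, 2.5))
  expect_equal(search_speed(1.0, tab), 9.5)
  expect_equal(search_speed(2.5, tab), 1.5)
})

test_that("a subject buried deeper than the probing depth is missed; equality finds", {
  cfg <- probe_config(area_m2 = 1000, n_rescuers = 5,
                      depth_source = point_dist(1.0), n_runs = 200, seed = 2)
  missed <- simulate_probe_run(cfg, 0.9)
  expect_true(all(!missed$found))
  expect_true(all(missed$p_survival == 0))
  tie <- simulate_probe_run(cfg, 1.0)
  expect_true(all(tie$found))
  expect_true(all(tie$p_survival > 0))
  expect_equal(tie$t_total_min, tie$t_search_min + tie$t_dig_min)
})

test_that("with a vanishing search area survival collapses to the dig-time closed form", {
  d0 <- 0.9
  cfg <- probe_config(area_m2 = 1e-9, n_rescuers = 5,
                      depth_source = point_dist(d0), n_runs = 100, seed = 2)
  s <- simulate_probe_run(cfg, 1.0)
  expect_equal(s$p_survival,
               rep(survival_at(cfg$curve, d0 / 0.15), 100),
               tolerance = 1e-7)
})

test_that("Monte Carlo mean matches the quadrature oracle for a degenerate depth", {
  d0 <- 1.2
  cfg <- probe_config(area_m2 = 5000, n_rescuers = 20,
                      depth_source = point_dist(d0), n_runs = 20000, seed = 31)
  probing <- 1.5
  s <- simulate_probe_run(cfg, probing)
  # independent 1-D quadrature over the uniform position
  L <- cfg$area_m2 / cfg$strip_width_m
  v <- search_speed(probing) * cfg$n_rescuers
  oracle <- stats::integrate(function(x)
    survival_at(cfg$curve, x / v + d0 / cfg$v_dig_m_per_min),
    0, L, subdivisions = 2000L, rel.tol = 1e-9)$value / L
  se <- stats::sd(s$p_survival) / sqrt(nrow(s))
  expect_lt(abs(mean(s$p_survival) - oracle), 3 * se)
})

test_that("miss fraction equals the depth distribution's tail mass within 3 SE", {
  d <- s1_depths()
  cfg <- probe_config(area_m2 = 5000, n_rescuers = 20, depth_source = d,
                      n_runs = 10000, seed = 42)
  res <- run_probe_grid(cfg)
  for (i in c(1, 6, 11, 21)) {
    p_tail <- mean(d$values > res$depth_m[i])
    se <- sqrt(max(p_tail * (1 - p_tail), 1e-6) / cfg$n_runs)
    expect_lt(abs(res$miss_fraction[i] - p_tail), 3 * se + 1e-12)
  }
})

test_that("grid results satisfy the scenario's structural invariants", {
  cfg <- probe_config(area_m2 = 5000, n_rescuers = 20,
                      depth_source = s1_depths(), n_runs = 10000, seed = 42)
  res <- run_probe_grid(cfg)
  expect_true(all(diff(res$miss_fraction) <= 0))
  expect_true(all(res$mean_survival >= 0 & res$mean_survival <= 1))
  # mean survival cannot exceed the find rate times the best possible survival
  expect_true(all(res$mean_survival <=
                    (1 - res$miss_fraction) * max(cfg$curve$survival) + 1e-12))
  expect_true(attr(res, "optimal_depth_m") %in% cfg$depth_grid_m)
  # identical seed reproduces the result bit-for-bit
  expect_identical(as.data.frame(run_probe_grid(cfg)), as.data.frame(res))
})

test_that("run-doubling leaves grid means within pooled Monte Carlo error", {
  d <- s1_depths()
  mk <- function(n, seed) run_probe_grid(
    probe_config(area_m2 = 5000, n_rescuers = 20, depth_source = d,
                 n_runs = n, seed = seed))
  a <- mk(5000, 1); b <- mk(10000, 2)
  pooled <- sqrt(a$se_mean^2 + b$se_mean^2)
  expect_true(all(abs(a$mean_survival - b$mean_survival) < 3 * pooled))
  # the recorded half-vs-full diagnostic is itself small
  expect_true(all(abs(b$half_sample_delta) < 4 * b$se_mean))
})

test_that("the optimal depth is the grid argmax with ties toward shallow", {
  res <- structure(data.frame(depth_m = c(1.8, 1.9, 2.0),
                              mean_survival = c(0.5, 0.5, 0.4)),
                   class = c("probe_result", "data.frame"))
  expect_equal(optimal_probing_depth(res), 1.8)
  res$mean_survival <- c(0.3, 0.6, 0.4)
  expect_equal(optimal_probing_depth(res), 1.9)
})

test_that("a tiny area with a shallow point-mass burial pins the optimum", {
  # with no meaningful search time, the best grid depth is the smallest one
  # that still finds the subject
  cfg <- probe_config(area_m2 = 0.01, n_rescuers = 5,
                      depth_source = point_dist(0.83), n_runs = 500, seed = 6)
  res <- run_probe_grid(cfg)
  expect_equal(optimal_probing_depth(res), 0.9)
})

test_that("the area sweep is reproducible and its optimum shrinks with area", {
  d <- s1_depths()
  areas <- c(50, 500, 5000)
  sw <- run_area_sweep(areas, d, rescuer_policy = function(a) 5,
                       n_runs = 4000, seed = 11)
  sw2 <- run_area_sweep(areas, d, rescuer_policy = function(a) 5,
                        n_runs = 4000, seed = 11)
  expect_identical(sw$optima, sw2$optima)
  expect_true(all(diff(sw$optima$optimal_depth_m) <= 0))
  # default policy: companion-scale crews on small deposits, organized on large
  sw3 <- run_area_sweep(c(1000, 5000), d, n_runs = 100, seed = 1)
  expect_equal(sw3$optima$n_rescuers, c(5, 20))
})
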