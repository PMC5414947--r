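test_that("CSV ingest converts centimetres to metres and keeps absent fields absent", {
  f <- write_toy_table(c("A,100,", "B,,5000", "C,150,200"))
  rec <- read_avalanche_table(f)
  expect_s3_class(rec, "avalanche_records")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$burial_depth_m, c(1.0, NA, 1.5))
  expect_equal(rec$deposit_area_m2, c(NA, 5000, 200))
  expect_equal(attr(rec, "n_rejected"), 0L)
})

test_that("rows with neither measurement are dropped with a warning and counted", {
  f <- write_toy_table(c("A,100,", "B,,", "C,not-a-number,", "D,150,200"))
  expect_warning(rec <- read_avalanche_table(f), "dropped")
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "n_rejected"), 2L)
  s <- summarize_records(rec)
  expect_equal(s$n_total, 4)       # source rows, including the rejected ones
})

test_that("read errors are informative", {
  expect_error(read_avalanche_table(tempfile()), "not found")
  f <- write_toy_table("A,100,5", header = "foo,bar,baz")
  expect_error(read_avalanche_table(f), "column")
})

test_that("delimiter override and re-read stability", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id;depth_cm;area_m2", "A;70;1200", "B;210;"), f)
  rec <- read_avalanche_table(f, delim = ";")
  expect_equal(rec$burial_depth_m, c(0.7, 2.1))
  expect_identical(rec, read_avalanche_table(f, delim = ";"))
})

test_that("summary counts and quartiles follow the stated conventions", {
  f <- write_toy_table(c("A,100,", "B,,5000", "C,150,200", "D,50,300"))
  s <- summarize_records(read_avalanche_table(f))
  expect_equal(s$n_total, 4)
  expect_equal(s$n_depth, 3)
  expect_equal(s$n_area, 3)
  expect_equal(s$n_both, 2)
  expect_equal(s$n_depth + s$n_area - s$n_both, s$n_total)
  # type-7 quantiles of {0.5, 1.0, 1.5}
  expect_equal(s$quartiles_depth_m, c(0.75, 1.0, 1.25))
  expect_true(all(diff(s$quartiles_depth_m) >= 0))
  expect_true(all(diff(s$quartiles_area_m2) >= 0))
  # degenerate case: a single record pins all three quartiles
  one <- summarize_records(read_avalanche_table(write_toy_table("A,100,")))
  expect_equal(one$quartiles_depth_m, c(1, 1, 1))
  expect_error(summarize_records(read_avalanche_table(write_toy_table("A,100,"))[0, ]),
               "empty")
})

test_that("summary serializes to JSON and CSV", {
  s <- summarize_records(read_avalanche_table(write_toy_table(c("A,100,50", "B,200,75"))))
  j <- tempfile(fileext = ".json"); write_summary(s, j)
  expect_equal(jsonlite::read_json(j)$n_total, 2)
  csv <- tempfile(fileext = ".csv"); write_summary(s, csv)
  expect_equal(utils::read.csv(csv)$depth_median_m, 1.5)
})

test_that("to_distribution keeps only present values in file order", {
  f <- write_toy_table(c("A,100,", "B,,5000", "C,150,200"))
  rec <- read_avalanche_table(f)
  d <- to_distribution(rec, "burial_depth")
  expect_equal(d$values, c(1.0, 1.5))
  expect_equal(d$n, 2)
  expect_equal(to_distribution(rec, "deposit_area")$values, c(5000, 200))
  rec$deposit_area_m2 <- NA_real_
  expect_error(to_distribution(rec, "deposit_area"), "no records")
  expect_error(empirical_distribution(numeric(0)), "at least one")
  expect_error(empirical_distribution(c(1, -2)), "positive")
})

test_that("resampling is uniform over the stored values", {
  d <- empirical_distribution(c(1, 2))
  set.seed(11)
  draws <- dist_sample(d, 1e5)
  p_hat <- mean(draws == 1)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(p_hat - 0.5), 3 * se)
  expect_true(all(draws %in% c(1, 2)))
  # point mass
  expect_equal(dist_sample(point_dist(1.0), 50), rep(1.0, 50))
  # same seed, same sequence
  set.seed(3); a <- dist_sample(d, 100)
  set.seed(3); b <- dist_sample(d, 100)
  expect_identical(a, b)
})

test_that("empirical frequency of each distinct value converges to multiplicity/n", {
  d <- empirical_distribution(c(0.5, 0.5, 1.5, 2.0))   # multiplicities 2,1,1
  set.seed(21)
  draws <- dist_sample(d, 4e4)
  for (spec in list(c(0.5, 0.5), c(1.5, 0.25), c(2.0, 0.25))) {
    p <- spec[2]
    expect_lt(abs(mean(draws == spec[1]) - p), 3 * sqrt(p * (1 - p) / 4e4))
  }
})

test_that("distribution quantiles interpolate linearly and the median is interior", {
  d <- empirical_distribution(c(4, 1, 3, 2))
  expect_equal(quantile(d, 0.5), 2.5)
  expect_gte(quantile(d, 0.5), min(d$values))
  expect_lte(quantile(d, 0.5), max(d$values))
})
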