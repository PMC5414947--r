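# Shared fixtures for the test suite. Everything is generated in code; the
# synthetic registry stand-in is built once per test run and reused.

point_dist <- function(value, unit = "m") {
  empirical_distribution(rep(value, 1), unit = unit)
}

write_toy_table <- function(lines,
                            header = "avalanche_id,burial_depth_cm,deposit_area_m2") {
  f <- tempfile(fileext = ".csv")
  writeLines(c(header, lines), f)
  f
}

# flat survival curve: isolates found/missed logic from burial-time effects
flat_curve <- function(p = 1) survival_curve(c(0, 1000), c(p, p), "flat-test")

s1_records <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) cache <<- synthetic_s1_table(seed = seed)
    cache
  }
})

s1_depths <- function() to_distribution(s1_records(), "burial_depth")
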