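#' Configuration for the synthetic avalanche-record generator
#'
#' Burial depths and deposit areas in avalanche registries are positive and
#' strongly right-skewed, so the generator draws both from log-normal laws
#' parameterized by their median and log-scale spread. Measurement fields are
#' then masked independently at the configured missing rates, with the
#' guarantee that every record keeps at least one field.
#'
#' Defaults: depth median 1.0 m with log-sd 0.6 (a typical full-burial depth
#' scale), area median 7200 m2 (the registry's median deposit size) with
#' log-sd 1.2 reflecting the several-decade span of deposit sizes.
#'
#' @param n_records number of records.
#' @param depth_median_m median burial depth, metres.
#' @param depth_log_sd log-scale standard deviation of depth.
#' @param area_median_m2 median deposit area, square metres.
#' @param area_log_sd log-scale standard deviation of area.
#' @param missing_depth_frac probability a record lacks the depth field.
#' @param missing_area_frac probability a record lacks the area field.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 1555,
                             depth_median_m = 1.0, depth_log_sd = 0.6,
                             area_median_m2 = 7200, area_log_sd = 1.2,
                             missing_depth_frac = 0, missing_area_frac = 0,
                             seed = 1L) {
  stopifnot(n_records >= 0,
            depth_median_m > 0, area_median_m2 > 0,
            depth_log_sd >= 0, area_log_sd >= 0,
            missing_depth_frac >= 0, missing_depth_frac < 1,
            missing_area_frac >= 0, missing_area_frac < 1)
  structure(list(n_records = as.integer(n_records),
                 depth_median_m = depth_median_m, depth_log_sd = depth_log_sd,
                 area_median_m2 = area_median_m2, area_log_sd = area_log_sd,
                 missing_depth_frac = missing_depth_frac,
                 missing_area_frac = missing_area_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate synthetic avalanche records
#'
#' @param config a [synthetic_config()].
#' @return an `avalanche_records` data frame (see [read_avalanche_table()]).
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_records
  with_seed(config$seed, {
    depth <- stats::rlnorm(n, meanlog = log(config$depth_median_m),
                           sdlog = config$depth_log_sd)
    area <- stats::rlnorm(n, meanlog = log(config$area_median_m2),
                          sdlog = config$area_log_sd)
    miss_d <- stats::runif(n) < config$missing_depth_frac
    miss_a <- stats::runif(n) < config$missing_area_frac
    both <- miss_d & miss_a
    # every record keeps at least one field: break double-masks at random
    keep_depth <- stats::runif(n) < 0.5
    miss_d[both] <- !keep_depth[both]
    miss_a[both] <- keep_depth[both]
    depth[miss_d] <- NA_real_
    area[miss_a] <- NA_real_
    structure(data.frame(avalanche_id = sprintf("SYN%05d", seq_len(max(n, 0))),
                         burial_depth_m = depth, deposit_area_m2 = area,
                         stringsAsFactors = FALSE),
              n_rejected = 0L, source = "synthetic",
              class = c("avalanche_records", "data.frame"))
  })
}

#' Write avalanche records in the registry CSV layout
#'
#' Depths are re-expressed in centimetres and rounded to the nearest
#' centimetre (a bounded 0.005 m perturbation); absent fields become empty
#' cells. The file round-trips through [read_avalanche_table()].
#'
#' @param records an `avalanche_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_avalanche_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt <- function(x, scale = 1) {
    out <- ifelse(is.na(x), "", format(round(x * scale),
                                       scientific = FALSE, trim = TRUE))
    out
  }
  lines <- c("avalanche_id,burial_depth_cm,deposit_area_m2",
             paste(records$avalanche_id,
                   fmt(records$burial_depth_m, 100),
                   fmt(records$deposit_area_m2), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Synthetic stand-in for the Swiss avalanche registry snapshot
#'
#' Builds a 1555-row synthetic table emulating the published structure of the
#' SLF registry snapshot of fully buried subjects (1973/74 to 2012/13): 1490
#' rows carry a burial depth, 541 a deposit area, 477 both, and one anomalous
#' row carries neither (the registry's own counts do not add up by exactly one
#' row; the reader drops and reports such rows). The synthetic marginals are
#' log-normal, deterministically rescaled so that the published summary facts
#' hold exactly: the sample median deposit area is 7200 m2 and exactly
#' 1043/1490 depths (70.0%) exceed 0.5 m. It is a calibrated stand-in, not
#' the real registry data.
#'
#' @param path optional path; when given the table is also written as CSV in
#'   the registry layout (including the anomalous empty row).
#' @param seed integer seed; the calibration facts hold for every seed.
#' @return an `avalanche_records` data frame with `n_rejected = 1`,
#'   mirroring what [read_avalanche_table()] returns for the written file.
#' @export
synthetic_s1_table <- function(path = NULL, seed = 1L) {
  n_depth <- 1490L; n_area <- 541L; n_both <- 477L
  n_exceed <- 1043L                      # depths > 0.5 m: 70.0% of 1490
  with_seed(derive_seed(seed, "synthetic-s1"), {
    # depths, in whole centimetres; pin the count above the 50 cm threshold
    d_cm <- pmax(1, round(100 * stats::rlnorm(n_depth, log(0.7), 0.6)))
    ord <- order(d_cm)
    k <- n_depth - n_exceed
    scale <- 50.5 / ((d_cm[ord][k] + d_cm[ord][k + 1]) / 2)
    d_cm <- pmax(1, round(d_cm * scale))
    d_sorted <- sort(d_cm)
    d_sorted[seq_len(k)] <- pmin(d_sorted[seq_len(k)], 50)
    d_sorted[(k + 1):n_depth] <- pmax(d_sorted[(k + 1):n_depth], 51)
    d_cm <- d_sorted[rank(d_cm, ties.method = "first")]

    # areas, whole square metres; pin the sample median at 7200
    a <- stats::rlnorm(n_area, log(7200), 1.2)
    a <- round(a * 7200 / stats::median(a))

    n_total <- n_depth + n_area - n_both + 1L        # 1555 incl. anomalous row
    depth_m <- rep(NA_real_, n_total)
    area_m2 <- rep(NA_real_, n_total)
    # rows 1..477 both, then depth-only, then area-only, last row neither
    depth_m[seq_len(n_depth)] <- d_cm / 100
    area_m2[c(seq_len(n_both), n_depth + seq_len(n_area - n_both))] <- a
    perm <- sample.int(n_total)
    rec <- data.frame(avalanche_id = sprintf("SLF%04d", seq_len(n_total)),
                      burial_depth_m = depth_m[perm],
                      deposit_area_m2 = area_m2[perm],
                      stringsAsFactors = FALSE)
    if (!is.null(path)) {
      write_avalanche_table(
        structure(rec, class = c("avalanche_records", "data.frame")), path)
    }
    keep <- !(is.na(rec$burial_depth_m) & is.na(rec$deposit_area_m2))
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
    structure(rec, n_rejected = 1L, source = "synthetic-s1",
              class = c("avalanche_records", "data.frame"))
  })
}
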