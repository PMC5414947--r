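#' Read an avalanche burial table
#'
#' Reads a CSV in the layout of the Swiss (SLF) avalanche registry snapshot:
#' one row per fully buried subject with an avalanche identifier, the burial
#' depth in centimetres, and the deposit (debris) area in square metres.
#' Depths are converted to metres on ingest; all downstream computation is in
#' metres and minutes. Blank or non-numeric measurement cells become `NA`
#' (absent), never zero. Rows where both measurements are absent cannot feed
#' any distribution: they are dropped with a warning and counted in the
#' `n_rejected` attribute so summaries can still report the full row count.
#'
#' Columns are located by name: the identifier column must contain "id", the
#' depth column "depth", and the area column "area" or "size"
#' (case-insensitive).
#'
#' @param path path to the CSV file.
#' @param delim field delimiter, default ",".
#' @return a data frame of class `avalanche_records` with columns
#'   `avalanche_id` (character), `burial_depth_m`, `deposit_area_m2`;
#'   attributes `n_rejected` (count of dropped rows) and `source`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("avalanche_id,burial_depth_cm,deposit_area_m2",
#'              "A,100,", "B,,5000", "C,150,200"), f)
#' read_avalanche_table(f)
read_avalanche_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("avalanche table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", strip.white = TRUE,
                           fill = TRUE, blank.lines.skip = TRUE,
                           fileEncoding = "UTF-8", check.names = FALSE)
  nm <- tolower(names(raw))
  find_col <- function(patterns, what) {
    hit <- which(Reduce(`|`, lapply(patterns, grepl, x = nm)))
    if (length(hit) == 0)
      stop("cannot identify the ", what, " column in header: ",
           paste(names(raw), collapse = ", "))
    hit[1]
  }
  id_col <- find_col("id", "id")
  depth_col <- find_col("depth", "burial depth")
  area_col <- find_col(c("area", "size"), "deposit area")

  as_num <- function(x) {
    x[!nzchar(x)] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  depth_cm <- as_num(raw[[depth_col]])
  area_m2 <- as_num(raw[[area_col]])
  depth_cm[!is.na(depth_cm) & depth_cm <= 0] <- NA_real_
  area_m2[!is.na(area_m2) & area_m2 <= 0] <- NA_real_

  rec <- data.frame(avalanche_id = as.character(raw[[id_col]]),
                    burial_depth_m = depth_cm / 100,
                    deposit_area_m2 = area_m2,
                    stringsAsFactors = FALSE)
  bad <- is.na(rec$burial_depth_m) & is.na(rec$deposit_area_m2)
  if (any(bad)) {
    warning(sum(bad), " row(s) with neither burial depth nor deposit area ",
            "were dropped (ids: ",
            paste(utils::head(rec$avalanche_id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")")
    rec <- rec[!bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  structure(rec, n_rejected = sum(bad), source = path,
            class = c("avalanche_records", "data.frame"))
}

#' Summarize an avalanche record table
#'
#' Counts records carrying each measurement and computes quartiles of the
#' present values. Quantiles use linear interpolation between order statistics
#' (R's default type 7). `n_total` includes any rows that were rejected at
#' read time for carrying neither measurement, so it reports the size of the
#' source table, not only of the usable records.
#'
#' @param records an `avalanche_records` data frame.
#' @return an object of class `avalanche_summary`: a list with counts
#'   `n_total`, `n_depth`, `n_area`, `n_both`, `n_rejected` and quartile
#'   triples `quartiles_depth_m`, `quartiles_area_m2`.
#' @export
summarize_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("cannot summarize an empty record collection")
  has_d <- !is.na(records$burial_depth_m)
  has_a <- !is.na(records$deposit_area_m2)
  n_rej <- attr(records, "n_rejected") %||% 0L
  q3 <- function(x) {
    if (!any(!is.na(x))) return(rep(NA_real_, 3))
    stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                    type = 7)
  }
  structure(list(
    n_total = nrow(records) + n_rej,
    n_depth = sum(has_d),
    n_area = sum(has_a),
    n_both = sum(has_d & has_a),
    n_rejected = n_rej,
    quartiles_depth_m = q3(records$burial_depth_m),
    quartiles_area_m2 = q3(records$deposit_area_m2)
  ), class = "avalanche_summary")
}

#' @export
print.avalanche_summary <- function(x, ...) {
  cat("Avalanche record summary\n")
  cat(sprintf("  rows in source table : %d\n", x$n_total))
  cat(sprintf("  with burial depth    : %d\n", x$n_depth))
  cat(sprintf("  with deposit area    : %d\n", x$n_area))
  cat(sprintf("  with both            : %d\n", x$n_both))
  if (x$n_rejected > 0)
    cat(sprintf("  rejected (no fields) : %d\n", x$n_rejected))
  if (!anyNA(x$quartiles_depth_m))
    cat(sprintf("  depth quartiles [m]  : %.2f / %.2f / %.2f\n",
                x$quartiles_depth_m[1], x$quartiles_depth_m[2],
                x$quartiles_depth_m[3]))
  if (!anyNA(x$quartiles_area_m2))
    cat(sprintf("  area quartiles [m2]  : %.0f / %.0f / %.0f\n",
                x$quartiles_area_m2[1], x$quartiles_area_m2[2],
                x$quartiles_area_m2[3]))
  invisible(x)
}

#' Empirical distribution of positive values
#'
#' A thin container for an ordered multiset of positive measurements that the
#' simulations resample uniformly (each stored value with probability 1/n),
#' i.e. bootstrap-style resampling of the raw data rather than a fitted law.
#'
#' @param values numeric vector of positive values; order is preserved.
#' @param unit unit label, e.g. "m" or "m2".
#' @return an object of class `empirical_distribution`.
#' @export
empirical_distribution <- function(values, unit = "") {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("empirical distribution needs at least one non-missing value")
  if (any(values <= 0)) stop("empirical distribution values must be positive")
  structure(list(values = values, n = length(values), unit = unit),
            class = "empirical_distribution")
}

#' Extract an empirical distribution from avalanche records
#'
#' @param records an `avalanche_records` data frame.
#' @param field `"burial_depth"` or `"deposit_area"`.
#' @return an `empirical_distribution` of the present values of that field,
#'   in file order.
#' @export
to_distribution <- function(records,
                            field = c("burial_depth", "deposit_area")) {
  field <- match.arg(field)
  col <- switch(field, burial_depth = "burial_depth_m",
                deposit_area = "deposit_area_m2")
  v <- records[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no records carry the field '", field, "'")
  empirical_distribution(v, unit = if (field == "burial_depth") "m" else "m2")
}

#' Resample an empirical distribution
#'
#' Draws values uniformly with replacement from the stored multiset, using
#' R's global random stream (seed it with [set.seed()] or run inside a seeded
#' driver for reproducibility).
#'
#' @param dist an `empirical_distribution`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
dist_sample <- function(dist, n = 1) {
  stopifnot(inherits(dist, "empirical_distribution"), n >= 0)
  dist$values[sample.int(dist$n, n, replace = TRUE)]
}

#' @export
quantile.empirical_distribution <- function(x, probs = c(0.25, 0.5, 0.75),
                                            ...) {
  stats::quantile(x$values, probs = probs, names = FALSE, type = 7)
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat(sprintf("Empirical distribution: n = %d [%s], median = %g, range = [%g, %g]\n",
              x$n, x$unit, stats::median(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Serialize an avalanche summary
#'
#' @param x an `avalanche_summary`.
#' @param path output path; extension ".json" writes JSON, anything else a
#'   one-row CSV.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "avalanche_summary"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    write_json_file(unclass(x), path)
  } else {
    flat <- data.frame(n_total = x$n_total, n_depth = x$n_depth,
                       n_area = x$n_area, n_both = x$n_both,
                       n_rejected = x$n_rejected,
                       depth_q1_m = x$quartiles_depth_m[1],
                       depth_median_m = x$quartiles_depth_m[2],
                       depth_q3_m = x$quartiles_depth_m[3],
                       area_q1_m2 = x$quartiles_area_m2[1],
                       area_median_m2 = x$quartiles_area_m2[2],
                       area_q3_m2 = x$quartiles_area_m2[3])
    utils::write.csv(flat, path, row.names = FALSE)
  }
  invisible(path)
}
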