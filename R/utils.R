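#' Derive a reproducible sub-stream seed
#'
#' Hashes an integer root seed together with any number of string/numeric
#' labels into a new seed below 2^31, so that each scenario cell of a sweep
#' gets its own reproducible random stream while remaining a pure function of
#' the root seed.
#'
#' @param seed integer root seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return a single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                         character(1)), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- as.double(seed) %% 2147483647
  # 31-bit multiplicative hash; doubles hold intermediate products exactly
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' library functions do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a list as pretty JSON
#' @keywords internal
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
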