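# Internal helpers: error conditions and seeded evaluation.

#' @keywords internal
#' @noRd
abort_validation <- function(msg, class = "smartddpcr_validation_error") {
  stop(structure(
    class = c(class, "smartddpcr_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
abort_saturation <- function(msg) {
  abort_validation(msg, class = "smartddpcr_saturation_error")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` substream seeds (< 2^31) from one seed.
#' @keywords internal
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
check_columns <- function(df, required, file = "input") {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s", file,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
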