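## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded generators do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Round half away from zero, the convention used for all printed
## percentages. base::round() rounds half to even, which prints 48.2 from
## 48.25 differently; the trials literature prints 48.3.
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny epsilon guards against representation error in x * scale + 0.5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

## stop() with a classed condition so callers and the CLI can map error
## families to exit codes.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "crtadhere_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_validation <- function(msg) abort(msg, "crtadhere_validation_error")
abort_computation <- function(msg) abort(msg, "crtadhere_computation_error")

## Assert a data.frame has the given columns; used by every table-facing
## entry point.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s contains value(s) outside {%s}: %s", what,
      paste(levels, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}
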