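# Internal helpers shared across the package.

dd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dwidistort_error")))
}

dd_warn <- function(msg, class = "dwidistort_warning") {
  warning(warningCondition(msg, class = c(class, "dwidistort_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

deg2rad <- function(d) d * pi / 180

#' @useDynLib dwidistort, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
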