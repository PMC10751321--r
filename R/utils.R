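#' Unit conversion: mmHg to kPa
#'
#' Lumen pressures are specified in mmHg (the clinical unit) and converted to
#' kPa once, here, before they reach the solver. 1 mmHg = 0.1333224 kPa.
#'
#' @param p pressure in mmHg.
#' @return pressure in kPa.
#' @export
mmHg_to_kPa <- function(p) p * 0.1333224

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(p) p / 0.1333224

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "atheroIFEM_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
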