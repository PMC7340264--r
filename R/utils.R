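## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' `.Random.seed` afterwards, so seeded operations never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child-seed derivation: master seed plus a stream index give
## an independent, reproducible seed below 2^31. Documented rule: child =
## (master * 48271 + 1000003 * index) mod (2^31 - 1), the Lehmer modulus.
childSeed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + 1000003 * as.numeric(index)) %% m)
}

## Numeric formatting used by all CSV writers: full precision, locale-free,
## so reruns at a fixed seed are byte-identical.
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
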