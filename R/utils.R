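# internal input-validation helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric with no missing values", name), call. = FALSE)
  }
  bad <- which(x < lo | x > hi)
  if (length(bad)) {
    stop(sprintf("'%s' out of bounds [%g, %g]: value %g at position %d",
                 name, lo, hi, x[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(x)
}

.check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric with no missing values", name), call. = FALSE)
  }
  bad <- if (strict) which(x <= 0) else which(x < 0)
  if (length(bad)) {
    stop(sprintf("'%s' must be %s: value %g at position %d",
                 name, if (strict) "> 0" else ">= 0", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  invisible(x)
}

.check_prob <- function(x, name) .check_range(x, 0, 1, name)

# seeded evaluation that restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
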