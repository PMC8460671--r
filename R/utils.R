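# internal helpers shared across modules

# trapezoidal integral of y over x (x sorted, length >= 2)
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's global RNG stream is left untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = TRUE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  bad <- if (strict) (x <= lower || x >= upper) else (x < lower || x > upper)
  stop_if(bad, sprintf("'%s' = %g is outside the admissible range (%g, %g)",
                       name, x, lower, upper))
  invisible(x)
}
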