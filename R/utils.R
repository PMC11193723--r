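#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef fft rnorm runif sd dist hclust t.test median
#' @importFrom utils head tail
NULL

# Validation helpers ---------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_count <- function(x, field, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_field(field, "must be a single integer")
  if (x < lower) stop_field(field, sprintf("must be >= %d", lower))
  invisible(as.integer(x))
}

# Seeded generation ----------------------------------------------------------

# Runs `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so generators never touch global RNG state.
with_private_seed <- function(seed, expr) {
  check_count(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
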