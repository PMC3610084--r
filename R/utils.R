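# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators can be
#' deterministic per seed without clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a base seed and an index, kept within 32-bit range
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483399 + 1
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# next integer >= n whose prime factors are all in {2, 3, 5}; keeps FFT
# lengths cheap for R's mixed-radix transform
next_fast_len <- function(n) {
  n <- as.integer(ceiling(n))
  if (n <= 1L) return(1L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# truncated normal draws by inverse-CDF; vectorized over n
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu <= pl) stop("empty truncation interval", call. = FALSE)
  u <- stats::runif(n, pl, pu)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}
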