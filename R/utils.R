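#' @keywords internal
"_PACKAGE"

#' @importFrom stats rexp rweibull rlnorm rnorm rpois rnbinom runif
#'   fisher.test chisq.test cor.test pchisq pnorm sd
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under `seed` without clobbering the caller's RNG state.
# All generators route their randomness through this, so seeds stay explicit.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed))
  force(code)
}

# Smallest census-grid value t with ecdf(t) >= q; step-function quantile,
# no interpolation (grid times only).
grid_quantile <- function(x, q) {
  n <- length(x)
  k <- ceiling(q * n - 1e-9)
  k <- min(max(k, 1L), n)
  sort(x)[k]
}

# Round up to the next multiple of the census interval (a death seen at a
# census is only known to have happened since the previous one).
snap_up <- function(x, interval) {
  ceiling(x / interval - 1e-12) * interval
}

is_grid_multiple <- function(x, interval) {
  r <- x / interval
  abs(r - round(r)) < 1e-8 & x > 0
}

# GCD of a numeric vector of grid times (used to infer a census interval).
# Times are scaled to integer microunits first, so floating drift is moot.
vec_gcd <- function(x) {
  xi <- round(x * 1e6)
  gcd2 <- function(a, b) {
    while (b != 0) {
      t <- b
      b <- a %% b
      a <- t
    }
    a
  }
  Reduce(gcd2, xi) / 1e6
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
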