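#' @useDynLib lcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the R random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded helpers do not perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

# Deterministic 31-bit sub-seed from (seed, index); exact in double
# arithmetic because all intermediates stay below 2^53.
hash_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  i <- as.numeric(index)
  h <- (s * 2654435761) %% 2147483647
  h <- (h + (i + 1) * 40503) %% 2147483647
  h <- (h * 48271) %% 2147483647
  as.integer(h %% 2147483641 + 1)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("'%s' must be a single finite number", name)
  }
  if (integer && x != round(x)) {
    stop_config("'%s' must be an integer (got %g)", name, x)
  }
  if (x < min || x > max) {
    stop_config("'%s' must be in [%g, %g] (got %g)", name, min, max, x)
  }
  invisible(x)
}

check_range <- function(x, name, min = -Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
    stop_config("'%s' must be a numeric interval c(lo, hi)", name)
  }
  if (integer && any(x != round(x))) {
    stop_config("'%s' must contain integers", name)
  }
  if (x[1] > x[2]) stop_config("'%s' must satisfy lo <= hi", name)
  if (any(x < min)) stop_config("'%s' must be >= %g", name, min)
  invisible(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
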