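#' @useDynLib neuromod, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom median setNames
#' @importFrom utils head tail str
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All generators in the package route their
# randomness through this so no function touches global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Column-wise softmax for a matrix of logits (units x batch).
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# sign() with sign(0) = +1; the tie-break used by the polarity rules.
sign1 <- function(x) ifelse(x >= 0, 1, -1)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    stop(sprintf("`%s` must be a single finite number %s %g", name,
                 if (strict) ">" else ">=", min), call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
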