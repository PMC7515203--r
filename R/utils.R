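#' @keywords internal
"_PACKAGE"

#' @useDynLib adipomr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rgamma rpois runif pnorm qnorm pchisq pt plogis
#'   qlogis sd var cor lm coef residuals p.adjust setNames cor.test t.test
#'   quantile median
#' @importFrom utils read.delim write.table head
NULL

# -- small argument checkers used across modules ------------------------------

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop_bad("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_bad("`%s` must be a single number in [%g, %g]", name, lo, hi)
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_bad("`%s` must be a single nonnegative number", name)
  }
  as.numeric(x)
}

# Seed handling: every generator seeds a local RNG and restores the caller's
# RNG state on exit, so calls are bit-reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
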