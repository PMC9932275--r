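#' @useDynLib idex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median plogis qlogis rnorm runif rbinom sd var
#'   complete.cases setNames aggregate kmeans uniroot pbinom weighted.mean
#'   dnorm
#' @importFrom utils write.csv read.csv head modifyList
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route through this so global RNG state is never consumed or clobbered.
with_seed <- function(seed, expr) {
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

# Derive a child seed from a master seed and a stream index, kept within the
# 32-bit signed integer range R requires.
derive_seed <- function(master_seed, stream) {
  as.integer((as.double(master_seed) * 1103L + as.double(stream) * 7919) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_idex <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_idex("`%s` must be a single number in [%g, %g]", name, lo, hi)
  invisible(x)
}
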