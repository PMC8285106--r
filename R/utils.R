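#' @useDynLib calspike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif rlnorm rbeta rexp quantile median sd
#'   kmeans cov setNames plogis filter runmed cor coef convolve
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + 104729 * as.numeric(i)) %% 2147483629
}

abort_calspike <- function(msg, class) {
  stop(structure(class = c(class, "calspike_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
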