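#' @keywords internal
"_PACKAGE"

## Seed-substream helpers.
##
## Every stochastic stage of the pipeline (dataset generation per location,
## strategy draws, replicate draws per step, fixture construction) derives its
## own 31-bit seed from a master seed, a stage name and a counter.  Stages are
## therefore locally reproducible: adding a location or an iteration never
## reshuffles the draws of earlier ones.

# Stable small integer hash of a stage label.
.stage_hash <- function(stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  h
}

#' Derive a substream seed
#'
#' Deterministically maps (master seed, stage label, counter) to a seed in
#' `[0, 2^31 - 2]`.  Used internally so that each pipeline stage and each
#' index within a stage (location, step, iteration, record) has its own
#' reproducible random stream.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"dataset"`.
#' @param index Nonnegative integer counter within the stage.
#' @return A single integer seed.
#' @export
substream_seed <- function(master, stage = "default", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- abs(as.numeric(master)) %% 2147483647
  h <- .stage_hash(stage)
  ## All intermediates stay far below 2^53, so double arithmetic is exact.
  s <- (m * 48271 + h * 69621 + as.numeric(index) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under seed `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Draw from a truncated normal distribution
#'
#' Samples `n` independent values from a normal distribution with the given
#' mean and standard deviation, truncated to the symmetric window
#' `[mean - bound, mean + bound]`.  Sampling is by inversion of the truncated
#' CDF rather than rejection, so exactly `n` uniform variates are consumed
#' per call and draw counts are deterministic for a fixed seed.
#'
#' @param n Number of draws (positive integer).
#' @param mean Location of the untruncated normal.
#' @param sd Standard deviation of the untruncated normal (> 0).
#' @param bound Truncation half-width about the mean (> 0).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (and advanced).
#' @return Numeric vector of length `n`, all values in
#'   `[mean - bound, mean + bound]`.
#' @examples
#' x <- sample_truncated_normal(1000, mean = 0, sd = 2, bound = 2, seed = 1)
#' range(x)   # within [-2, 2]
#' @export
sample_truncated_normal <- function(n, mean = 0, sd = 1, bound, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("`sd` must be a positive number", call. = FALSE)
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0)
    stop("`bound` must be a positive number", call. = FALSE)
  draw <- function() {
    u <- stats::runif(n)
    z <- bound / sd
    p_lo <- stats::pnorm(-z)
    p_hi <- stats::pnorm(z)
    q <- stats::qnorm(p_lo + u * (p_hi - p_lo))
    ## qnorm can return +/-Inf only at u = 0/1, excluded by runif; clamp for
    ## floating-point safety at the window edges.
    mean + pmin(pmax(q * sd, -bound), bound)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
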