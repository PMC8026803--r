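# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive algorithms (rejection sampling, double loops,
# exhaustive enumeration) and never call the code paths they verify.

# Rejection sampler for the truncated normal: the textbook definition.
oracle_rtruncnorm <- function(n, mean, sd, bound) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[abs(x - mean) <= bound])
  }
  out[seq_len(n)]
}

# Brute-force piecewise fit: loop over every candidate breakpoint, compute
# the branch parameters and the RMSE by direct summation.
oracle_fit_piecewise <- function(x, y, candidates) {
  best <- list(rmse = Inf)
  n <- length(x)
  for (b in candidates) {
    below <- x < b
    k <- if (any(below) && sum(x[below]^2) > 0)
      sum(x[below] * y[below]) / sum(x[below]^2) else 0
    a <- if (any(!below)) mean(y[!below]) else mean(y)
    pred <- ifelse(below, k * x, a)
    rmse <- sqrt(sum((y - pred)^2) / n)
    if (rmse < best$rmse) best <- list(k = k, a = a, b = b, rmse = rmse)
  }
  best
}

# Exhaustive search for the minimum interval variance achievable by any
# placement of n_loc distinct integer sites on 1..grid_n that includes the
# endpoints (uniform spread anchors the transect ends).
oracle_min_interval_variance <- function(grid_n, n_loc) {
  inner <- utils::combn(2:(grid_n - 1L), n_loc - 2L)
  best <- Inf
  for (j in seq_len(ncol(inner))) {
    v <- stats::var(diff(c(1L, inner[, j], grid_n)))
    if (v < best) best <- v
  }
  best
}

# Small default datasets shared across tests, built once per run.
.fixture_env <- new.env()
fixture_dataset <- function(hypothesis = "given", seed = 101L) {
  key <- paste(hypothesis, seed, sep = "-")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(gradient_model(hypothesis),
                                            seed = seed)
  .fixture_env[[key]]
}
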