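#' Piecewise-linear hypothesis model prediction
#'
#' The two-branch saturation model: strength `k * x` below the saturation
#' moisture `b`, constant stabilized strength `a` at or above it.
#' Continuity at the breakpoint is not imposed.
#'
#' @param k Pre-saturation slope (strength per \% moisture).
#' @param a Stabilized strength.
#' @param b Saturation moisture (\%).
#' @param x Numeric vector of moistures.
#' @return Numeric vector of predicted strengths.
#' @examples
#' piecewise_predict(2, 7, 3, c(0, 2, 3, 5))  # 0 4 7 7
#' @export
piecewise_predict <- function(k, a, b, x) {
  ifelse(x < b, k * x, a)
}

#' Fit the piecewise-linear saturation model
#'
#' Grid search over candidate breakpoints `b` spanning the observed moisture
#' range.  For each candidate, the pre-saturation slope `k` is the
#' least-squares through-origin slope of the points with `x < b` and the
#' stabilized strength `a` is the mean strength of the points with
#' `x >= b`; the returned fit minimizes the RMSE over all candidates.
#' Degenerate branches (no points on one side, or no moisture spread below
#' `b`) default `k` to 0 and `a` to the global strength mean so the search
#' is total.  Ties in RMSE resolve to the smallest candidate `b`.
#'
#' @param moisture Numeric vector of observed moistures, or a data frame
#'   with `moisture` and `strength` columns (e.g. a `ground_truth`
#'   dataset).
#' @param strength Numeric vector of observed strengths (ignored when
#'   `moisture` is a data frame).
#' @param n_grid Number of equally spaced breakpoint candidates across the
#'   observed moisture range (default 200).
#' @param breakpoints `"grid"` (default) or `"observed"` (restrict
#'   candidates to the observed moisture values).
#' @param continuous Logical; constrain `a = k * b` (continuous variant,
#'   default `FALSE`).
#' @return An object of class `piecewise_fit`: a list with `k`, `a`, `b`,
#'   `rmse`, `n_points` and the breakpoint `grid_step` used.
#' @examples
#' x <- seq(0.2, 6, length.out = 20)
#' y <- piecewise_predict(1.5, 6, 4, x)
#' fit_piecewise(x, y)
#' @export
fit_piecewise <- function(moisture, strength = NULL, n_grid = 200L,
                          breakpoints = c("grid", "observed"),
                          continuous = FALSE) {
  if (is.data.frame(moisture)) {
    strength <- moisture$strength
    moisture <- moisture$moisture
  }
  breakpoints <- match.arg(breakpoints)
  x <- as.numeric(moisture); y <- as.numeric(strength)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("insufficient data: need at least 2 distinct moisture values",
         call. = FALSE)

  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cs_xx <- cumsum(xs * xs)
  cs_xy <- cumsum(xs * ys)
  cs_y  <- cumsum(ys)
  cs_yy <- cumsum(ys * ys)
  tot_y <- cs_y[n]; tot_yy <- cs_yy[n]
  ybar <- tot_y / n

  cand <- if (breakpoints == "observed") sort(unique(xs))
          else seq(xs[1L], xs[n], length.out = n_grid)
  grid_step <- if (length(cand) > 1L) cand[2L] - cand[1L] else 0

  ## nb = number of points strictly below each candidate b
  nb <- findInterval(cand, xs, left.open = TRUE)
  sxx <- ifelse(nb > 0L, cs_xx[pmax(nb, 1L)], 0)
  sxy <- ifelse(nb > 0L, cs_xy[pmax(nb, 1L)], 0)
  sy_below  <- ifelse(nb > 0L, cs_y[pmax(nb, 1L)], 0)
  syy_below <- ifelse(nb > 0L, cs_yy[pmax(nb, 1L)], 0)
  n_above <- n - nb
  sy_above  <- tot_y - sy_below
  syy_above <- tot_yy - syy_below

  if (continuous) {
    denom <- sxx + n_above * cand^2
    k <- ifelse(denom > 0, (sxy + cand * sy_above) / denom, 0)
    a <- k * cand
  } else {
    k <- ifelse(sxx > 0, sxy / sxx, 0)
    a <- ifelse(n_above > 0L, sy_above / n_above, ybar)
  }
  rss <- (syy_below - 2 * k * sxy + k^2 * sxx) +
         (syy_above - 2 * a * sy_above + n_above * a^2)
  best <- which.min(pmax(rss, 0))
  ## the cumulative-sum form above is used only to rank candidates; the
  ## returned error is recomputed by direct residual summation, which is
  ## immune to the cancellation the difference-of-sums form suffers when
  ## the fit is near-perfect
  res <- ys - piecewise_predict(k[best], a[best], cand[best], xs)
  structure(
    list(k = k[best], a = a[best], b = cand[best],
         rmse = sqrt(mean(res^2)),
         n_points = n, grid_step = grid_step, continuous = continuous),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "Piecewise fit: k = %.4g, a = %.4g, b = %.4g%%; RMSE = %.4g (n = %d)\n",
    x$k, x$a, x$b, x$rmse, x$n_points))
  invisible(x)
}

#' Fitting error of a model against observed points
#'
#' Root mean squared error of observed strengths against the piecewise
#' model's predictions.
#'
#' @param moisture Numeric vector of moistures, or a data frame with
#'   `moisture` and `strength` columns.
#' @param strength Numeric vector of strengths.
#' @param fit A `piecewise_fit`, or a list with `k`, `a`, `b`.
#' @return Nonnegative scalar RMSE (strength units).
#' @export
fitting_error <- function(moisture, strength = NULL, fit) {
  if (is.data.frame(moisture)) {
    strength <- moisture$strength
    moisture <- moisture$moisture
  }
  if (length(moisture) < 1L)
    stop("insufficient data: no points", call. = FALSE)
  res <- strength - piecewise_predict(fit$k, fit$a, fit$b, moisture)
  sqrt(mean(res^2))
}

#' Representative fitting error of a dataset
#'
#' The fitting error obtained when every available measurement in the
#' dataset is used: `fit_piecewise` on all records, returning its RMSE.
#' This is the convergence reference against which partial-sampling
#' trajectories and final-error distributions are judged.
#'
#' @param dataset A `ground_truth` data frame.
#' @param ... Passed to [fit_piecewise()].
#' @return Nonnegative scalar RMSE.
#' @export
representative_fitting_error <- function(dataset, ...) {
  grid <- attr(dataset, "grid")
  n_rep <- attr(dataset, "n_replicates")
  if (!is.null(grid) && !is.null(n_rep) &&
      nrow(dataset) < grid$n_locations * n_rep)
    warning("dataset is incomplete; representative error computed on available records",
            call. = FALSE)
  fit_piecewise(dataset$moisture, dataset$strength, ...)$rmse
}

#' Coverage binning specification
#'
#' @param n_intervals Number of equal-width bins partitioning the full
#'   dataset's moisture range (default 10, so coverage reads in 10\%
#'   steps).
#' @return An object of class `coverage_spec`.
#' @export
coverage_spec <- function(n_intervals = 10L) {
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 2L) stop("`n_intervals` must be >= 2", call. = FALSE)
  structure(list(n_intervals = n_intervals), class = "coverage_spec")
}

#' Effective coverage of the moisture variable-space
#'
#' Partition the full dataset's moisture range into equal-width bins and
#' return the fraction of bins containing at least one observed moisture.
#' An empty observation set has coverage 0.
#'
#' @param observed Numeric vector of observed moistures, or a data frame
#'   with a `moisture` column.
#' @param dataset The full `ground_truth` dataset defining the moisture
#'   range, or a length-2 numeric range.
#' @param spec A [coverage_spec()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' effective_coverage(c(0.1, 3.05, 5.9), c(0, 6))  # 3 of 10 bins
#' @export
effective_coverage <- function(observed, dataset, spec = coverage_spec()) {
  if (is.data.frame(observed)) observed <- observed$moisture
  rng <- if (is.numeric(dataset) && length(dataset) == 2L) dataset
         else moisture_range(dataset)
  if (length(observed) == 0L) return(0)
  nb <- spec$n_intervals
  width <- (rng[2L] - rng[1L]) / nb
  if (width <= 0) return(1)
  idx <- pmin(pmax(floor((observed - rng[1L]) / width), 0), nb - 1L)
  length(unique(idx)) / nb
}
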