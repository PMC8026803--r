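#' Ground-truth gradient model for one hypothesis
#'
#' Describes the mean structure underlying a stimulus dataset: a monotone
#' moisture gradient along the transect (dry crest at location 1, wet
#' interdune at the last location) and a mean strength-versus-moisture curve
#' for one of the two competing hypotheses.
#'
#' Under the *given* hypothesis, mean shear strength rises linearly with
#' moisture (slope `k_true`) until the saturation moisture `b_true`, beyond
#' which it is constant at the stabilized strength `a_true`.  Under the
#' *alternative* hypothesis the curve rises the same way, then decreases by
#' `dip_depth` strength units over a moisture span of `dip_width` beyond
#' saturation, and finally levels off at `a_true - dip_depth`.  Setting
#' `dip_depth = 0` reduces the alternative curve to the given one.
#'
#' Defaults place saturation at 3\% moisture with the transect spanning
#' 0--6\% moisture, and make the given curve continuous at the breakpoint
#' (`a_true = k_true * b_true`).
#'
#' @param hypothesis `"given"` or `"alternative"`.
#' @param k_true Pre-saturation slope, strength units per \% moisture
#'   (>= 0).
#' @param a_true Stabilized strength, strength units (> 0).
#' @param b_true Saturation moisture, \% (inside `moisture_range`).
#' @param dip_depth Post-saturation decrease, strength units (alternative
#'   hypothesis; >= 0, default 1.5 for `"alternative"`, 0 for `"given"`).
#' @param dip_width Moisture span (\%) over which the decrease unfolds.
#' @param moisture_range Length-2 numeric, the mean-moisture span of the
#'   transect from crest to interdune.
#' @return An object of class `gradient_model`.
#' @examples
#' m <- gradient_model("given")
#' mean_strength_of_moisture(m, c(0, 1.5, 3, 6))
#' @export
gradient_model <- function(hypothesis = c("given", "alternative"),
                           k_true = 3, a_true = 9, b_true = 3,
                           dip_depth = NULL, dip_width = 1.5,
                           moisture_range = c(0, 6)) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(dip_depth)) dip_depth <- if (hypothesis == "alternative") 1.5 else 0
  if (!is.numeric(k_true) || k_true < 0)
    stop("`k_true` must be nonnegative", call. = FALSE)
  if (!is.numeric(a_true) || a_true <= 0)
    stop("`a_true` must be positive", call. = FALSE)
  if (length(moisture_range) != 2L || diff(moisture_range) <= 0)
    stop("`moisture_range` must be an increasing length-2 numeric", call. = FALSE)
  if (b_true <= moisture_range[1L] || b_true >= moisture_range[2L])
    stop("`b_true` must lie strictly inside `moisture_range`", call. = FALSE)
  if (dip_depth < 0)
    stop("`dip_depth` must be nonnegative", call. = FALSE)
  if (hypothesis == "given" && dip_depth != 0)
    stop("the given hypothesis has no post-saturation dip; use hypothesis = \"alternative\"",
         call. = FALSE)
  if (dip_width <= 0)
    stop("`dip_width` must be positive", call. = FALSE)
  ## shape constraints: rising branch never exceeds the plateau, and the
  ## post-dip plateau stays positive
  if (a_true < k_true * b_true - 1e-9)
    stop("`a_true` must be >= k_true * b_true (mean curve nondecreasing up to saturation)",
         call. = FALSE)
  if (a_true - dip_depth <= 0)
    stop("`dip_depth` produces a nonpositive plateau strength", call. = FALSE)
  structure(
    list(hypothesis = hypothesis, k_true = k_true, a_true = a_true,
         b_true = b_true, dip_depth = dip_depth, dip_width = dip_width,
         moisture_range = as.numeric(moisture_range)),
    class = "gradient_model"
  )
}

#' Mean moisture at each transect location
#'
#' Linear moisture gradient along the transect: the first grid position (dune
#' crest) sits at the dry end of the model's moisture range and the last
#' (interdune) at the wet end.
#'
#' @param model A [gradient_model()].
#' @param grid A [transect_grid()], or a numeric vector of positions.
#' @return Numeric vector of mean moistures (\%), one per location,
#'   monotone nondecreasing from crest to interdune.
#' @export
moisture_of_location <- function(model, grid = transect_grid()) {
  stopifnot(inherits(model, "gradient_model"))
  pos <- if (inherits(grid, "transect_grid")) grid$positions else as.numeric(grid)
  lo <- model$moisture_range[1L]
  hi <- model$moisture_range[2L]
  if (length(pos) == 1L) return(lo)
  span <- pos[length(pos)] - pos[1L]
  lo + (pos - pos[1L]) / span * (hi - lo)
}

#' Mean strength at a given moisture
#'
#' Evaluates the model's mean strength-versus-moisture curve.
#'
#' @param model A [gradient_model()].
#' @param moisture Numeric vector of moistures (\%).
#' @return Numeric vector of mean strengths (strength units).
#' @export
mean_strength_of_moisture <- function(model, moisture) {
  stopifnot(inherits(model, "gradient_model"))
  k <- model$k_true; a <- model$a_true; b <- model$b_true
  d <- model$dip_depth; w <- model$dip_width
  out <- ifelse(moisture < b, k * moisture, a)
  if (d > 0) {
    in_dip <- moisture >= b & moisture < b + w
    out[in_dip] <- a - d * (moisture[in_dip] - b) / w
    out[moisture >= b + w] <- a - d
  }
  out
}

#' @export
print.gradient_model <- function(x, ...) {
  cat(sprintf(
    "Gradient model (%s hypothesis): k = %g, a = %g, b = %g%%",
    x$hypothesis, x$k_true, x$a_true, x$b_true))
  if (x$dip_depth > 0)
    cat(sprintf(", dip %g over %g%%", x$dip_depth, x$dip_width))
  cat(sprintf("; moisture range [%g, %g]%%\n",
              x$moisture_range[1L], x$moisture_range[2L]))
  invisible(x)
}
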