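#' Sampling strategy
#'
#' An ordered plan of (location, number-of-measurements) steps.  Each step
#' carries a phase tag: `"initial"` for the plan reported before any data
#' were seen, `"added"` for mid-run or post-plan amendments.
#'
#' @param location Integer vector of 1-based location indices on the grid.
#' @param n Integer vector of measurement counts per step.
#' @param phase Character vector, `"initial"` or `"added"` per step
#'   (default all `"initial"`).
#' @param grid The [transect_grid()] the locations refer to.
#' @param max_measurements Per-location cap on counts (default 10; the
#'   bounded task's limit).
#' @return An object of class `sampling_strategy`: a data frame with
#'   columns `location`, `n`, `phase` and attribute `grid`.
#' @examples
#' sampling_strategy(c(1, 8, 15, 22), n = 3)
#' @export
sampling_strategy <- function(location, n, phase = "initial",
                              grid = transect_grid(),
                              max_measurements = 10L) {
  location <- as.integer(location)
  n <- as.integer(rep(n, length.out = length(location)))
  phase <- rep(as.character(phase), length.out = length(location))
  if (!all(phase %in% c("initial", "added")))
    stop("`phase` must be \"initial\" or \"added\"", call. = FALSE)
  if (any(location < 1L) || any(location > grid$n_locations))
    stop("step locations must be indices on the grid", call. = FALSE)
  if (any(n < 1L) || any(n > max_measurements))
    stop("per-step measurement counts must be in [1, ", max_measurements, "]",
         call. = FALSE)
  ## initial steps must precede amendments at the same location
  for (loc in unique(location)) {
    ph <- phase[location == loc]
    if (any(ph == "initial") && any(ph == "added") &&
        max(which(ph == "initial")) > min(which(ph == "added")))
      stop("initial-phase steps must precede added steps at the same location",
           call. = FALSE)
  }
  structure(data.frame(location = location, n = n, phase = phase,
                       stringsAsFactors = FALSE),
            grid = grid, class = c("sampling_strategy", "data.frame"))
}

initial_steps <- function(strategy) {
  strategy[strategy$phase == "initial", , drop = FALSE]
}

#' Evenly spaced heuristic strategy
#'
#' The equal-spacing + magic-number heuristic: `n_locations` sites spread
#' as uniformly as the integer grid allows, each assigned `magic_number`
#' measurements, visited in ascending spatial order.  Ideal real-valued
#' equispaced coordinates over the grid span are snapped to the nearest grid
#' sites; collisions are resolved deterministically by shifting outward.
#'
#' @param grid A [transect_grid()].
#' @param n_locations Number of sites (2..grid size).
#' @param magic_number Measurements per site (>= 1).
#' @return A [sampling_strategy()].
#' @examples
#' evenly_spaced_strategy(transect_grid(), 8, 3)
#' @export
evenly_spaced_strategy <- function(grid = transect_grid(), n_locations,
                                   magic_number) {
  stopifnot(inherits(grid, "transect_grid"))
  if (n_locations > grid$n_locations)
    stop("`n_locations` exceeds the grid size", call. = FALSE)
  if (n_locations < 2L) stop("`n_locations` must be >= 2", call. = FALSE)
  if (magic_number < 1L) stop("`magic_number` must be >= 1", call. = FALSE)
  pos <- grid$positions
  ideal <- seq(pos[1L], pos[length(pos)], length.out = n_locations)
  ## snap each ideal coordinate to the nearest grid index, then enforce
  ## strictly increasing indices (shift later collisions outward) while
  ## keeping the tail feasible
  idx <- integer(n_locations)
  prev <- 0L
  for (i in seq_len(n_locations)) {
    cand <- which.min(abs(pos - ideal[i]))
    cand <- max(cand, prev + 1L)
    cand <- min(cand, grid$n_locations - (n_locations - i))
    idx[i] <- cand
    prev <- cand
  }
  sampling_strategy(idx, n = magic_number, phase = "initial", grid = grid)
}

#' Random sampling strategy
#'
#' The random counterpart of the evenly spaced heuristic: `n_locations`
#' distinct sites drawn uniformly without replacement, visited in ascending
#' spatial order, `magic_number` measurements each.
#'
#' @inheritParams evenly_spaced_strategy
#' @param seed Integer seed for the location draw.
#' @return A [sampling_strategy()].
#' @export
random_strategy <- function(grid = transect_grid(), n_locations, magic_number,
                            seed) {
  stopifnot(inherits(grid, "transect_grid"))
  if (n_locations > grid$n_locations)
    stop("`n_locations` exceeds the grid size", call. = FALSE)
  if (n_locations < 2L) stop("`n_locations` must be >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  idx <- with_seed(seed, sort(sample.int(grid$n_locations, n_locations)))
  sampling_strategy(idx, n = magic_number, phase = "initial", grid = grid)
}

#' Average interval discrepancy of a strategy
#'
#' Spread statistic over the between-location interval sizes of the initial
#' plan: compute intervals between consecutive distinct planned locations,
#' order the interval sizes smallest to largest, and take the mean
#' difference of successive intervals.  Zero means perfectly uniform
#' spacing; with fewer than two intervals the discrepancy is 0 by
#' convention.  Equivalently (for the successive-difference reading) this is
#' `(max interval - min interval) / (number of intervals - 1)`.
#'
#' @param strategy A [sampling_strategy()].
#' @param method `"successive"` (default; mean of successive differences of
#'   the sorted interval list) or `"pairwise"` (mean absolute pairwise
#'   difference of intervals, a Gini-type alternative).
#' @return Nonnegative scalar, in grid-step units.
#' @examples
#' s <- sampling_strategy(c(1, 2, 10, 12), n = 2)
#' average_interval_discrepancy(s)  # intervals 1,8,2 -> sorted 1,2,8 -> mean(1,6) = 3.5
#' @export
average_interval_discrepancy <- function(strategy,
                                         method = c("successive", "pairwise")) {
  method <- match.arg(method)
  grid <- attr(strategy, "grid")
  locs <- sort(unique(initial_steps(strategy)$location))
  if (length(locs) < 2L)
    stop("degenerate strategy: fewer than 2 initial locations", call. = FALSE)
  pos <- grid$positions[locs]
  intervals <- diff(pos)
  if (length(intervals) < 2L) return(0)
  if (method == "successive") {
    mean(diff(sort(intervals)))
  } else {
    d <- abs(outer(intervals, intervals, "-"))
    mean(d[upper.tri(d)])
  }
}

#' Detect the magic number of a strategy
#'
#' Returns the common per-location measurement count of the initial plan if
#' all initial-phase counts are identical, otherwise `NA`.
#'
#' @param strategy A [sampling_strategy()].
#' @return A positive integer, or `NA_integer_` when the initial counts
#'   differ.
#' @export
detect_magic_number <- function(strategy) {
  counts <- initial_steps(strategy)$n
  if (length(counts) < 1L)
    stop("strategy has no initial-phase steps", call. = FALSE)
  if (length(unique(counts)) == 1L) counts[1L] else NA_integer_
}

#' Classify a strategy by the two sampling heuristics
#'
#' Computes the average interval discrepancy and the magic number of the
#' initial plan and applies the equal-spacing threshold (discrepancy <= 1
#' grid step by default).
#'
#' @param strategy A [sampling_strategy()].
#' @param threshold Equal-spacing threshold on the discrepancy (default 1).
#' @param method Discrepancy method, see [average_interval_discrepancy()].
#' @return An object of class `strategy_classification`: a list with
#'   `avg_interval_discrepancy`, `is_equal_spacing`, `magic_number`,
#'   `n_locations` (distinct initial sites) and `total_measurements`.
#' @export
classify_strategy <- function(strategy, threshold = 1,
                              method = c("successive", "pairwise")) {
  method <- match.arg(method)
  disc <- average_interval_discrepancy(strategy, method = method)
  structure(
    list(avg_interval_discrepancy = disc,
         is_equal_spacing = disc <= threshold,
         magic_number = detect_magic_number(strategy),
         n_locations = length(unique(initial_steps(strategy)$location)),
         total_measurements = sum(strategy$n)),
    class = "strategy_classification"
  )
}

#' @export
print.strategy_classification <- function(x, ...) {
  cat(sprintf(
    "Strategy: %d locations, %d measurements; interval discrepancy %.3g (%s); magic number %s\n",
    x$n_locations, x$total_measurements, x$avg_interval_discrepancy,
    if (x$is_equal_spacing) "equal spacing" else "non-uniform",
    if (is.na(x$magic_number)) "none" else x$magic_number))
  invisible(x)
}

#' Strategy JSON / CSV round trip
#'
#' JSON schema: `{"grid_size": int, "steps": [{"location": int, "n": int,
#' "phase": "initial"|"added"}, ...]}`.  CSV columns:
#' `order,location,n,phase`.
#'
#' @param strategy A [sampling_strategy()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a
#'   [sampling_strategy()].
#' @export
write_strategy_json <- function(strategy, path) {
  grid <- attr(strategy, "grid")
  obj <- list(grid_size = grid$n_locations,
              steps = lapply(seq_len(nrow(strategy)), function(i)
                list(location = strategy$location[i], n = strategy$n[i],
                     phase = strategy$phase[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_strategy_json
#' @export
read_strategy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sampling_strategy(obj$steps$location, obj$steps$n, obj$steps$phase,
                    grid = transect_grid(obj$grid_size))
}

#' @rdname write_strategy_json
#' @export
write_strategy_csv <- function(strategy, path) {
  df <- data.frame(order = seq_len(nrow(strategy)),
                   location = strategy$location, n = strategy$n,
                   phase = strategy$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_strategy_json
#' @param grid Grid for the CSV reader (the CSV carries no grid size).
#' @export
read_strategy_csv <- function(path, grid = transect_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$order), , drop = FALSE]
  sampling_strategy(df$location, df$n, df$phase, grid = grid)
}
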