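#' Transect sampling grid
#'
#' The labelled sampling sites along a single dune transect.  The default grid
#' mirrors the survey task: 22 integer-labelled locations, location 1 at the
#' dry dune crest and location 22 in the wet interdune.
#'
#' @param n_locations Number of labelled sites (positive integer, default 22).
#' @param positions Strictly increasing numeric coordinates of the sites
#'   (default `1:n_locations`, unit = one grid step).
#' @return An object of class `transect_grid`.
#' @examples
#' transect_grid()
#' @export
transect_grid <- function(n_locations = 22L, positions = seq_len(n_locations)) {
  if (!is.numeric(n_locations) || length(n_locations) != 1L ||
      n_locations < 1 || n_locations != floor(n_locations))
    stop("`n_locations` must be a positive integer", call. = FALSE)
  n_locations <- as.integer(n_locations)
  positions <- as.numeric(positions)
  if (length(positions) != n_locations)
    stop("`positions` must have length `n_locations`", call. = FALSE)
  if (n_locations > 1L && any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing", call. = FALSE)
  structure(list(n_locations = n_locations, positions = positions),
            class = "transect_grid")
}

#' @export
print.transect_grid <- function(x, ...) {
  cat("Transect grid:", x$n_locations, "locations, positions",
      x$positions[1L], "..", x$positions[x$n_locations], "\n")
  invisible(x)
}
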