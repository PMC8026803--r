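#' Measurement noise model
#'
#' Truncated-normal noise applied independently to strength and moisture
#' about each location's mean.  Defaults follow the survey task's stimulus
#' construction: strength noise with standard deviation 2 truncated at
#' +/- 2 strength units, moisture noise with standard deviation 0.5
#' truncated at +/- 1 \% moisture.
#'
#' @param strength_sd Standard deviation of strength noise (> 0).
#' @param strength_bound Truncation half-width of strength noise (> 0).
#' @param moisture_sd Standard deviation of moisture noise (> 0).
#' @param moisture_bound Truncation half-width of moisture noise (> 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(strength_sd = 2, strength_bound = 2,
                        moisture_sd = 0.5, moisture_bound = 1) {
  vals <- c(strength_sd, strength_bound, moisture_sd, moisture_bound)
  if (!is.numeric(vals) || any(vals <= 0))
    stop("all noise parameters must be positive", call. = FALSE)
  structure(list(strength_sd = strength_sd, strength_bound = strength_bound,
                 moisture_sd = moisture_sd, moisture_bound = moisture_bound),
            class = "noise_model")
}

#' Generate a ground-truth dataset
#'
#' Builds the full replicate table for one hypothesis: at every transect
#' location, `n_replicates` (moisture, strength) pairs drawn from truncated
#' normal distributions about the location's mean moisture and the mean
#' strength curve.  By default strength noise is applied about the mean
#' curve evaluated at the location's *mean* moisture, so the two noise
#' sources are independent; set `couple_strength = TRUE` to evaluate the
#' curve at each record's noisy moisture draw instead.
#'
#' Each location uses its own seed substream derived from `seed`, so the
#' records of location *i* do not depend on how many other locations exist.
#'
#' @param model A [gradient_model()].
#' @param noise A [noise_model()].
#' @param grid A [transect_grid()].
#' @param n_replicates Replicates per location (default 10).
#' @param seed Integer master seed.
#' @param couple_strength Logical; couple strength noise to the noisy
#'   moisture draw (default `FALSE`).
#' @return A `data.frame` of class `ground_truth` with columns
#'   `hypothesis`, `location_index`, `replicate_index`, `moisture`,
#'   `strength`, and attributes `model`, `noise`, `grid`, `seed`.
#' @examples
#' d <- generate_dataset(gradient_model("given"), seed = 1)
#' nrow(d)  # 22 locations x 10 replicates = 220
#' @export
generate_dataset <- function(model, noise = noise_model(),
                             grid = transect_grid(), n_replicates = 10L,
                             seed, couple_strength = FALSE) {
  stopifnot(inherits(model, "gradient_model"), inherits(noise, "noise_model"),
            inherits(grid, "transect_grid"))
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)

  mean_m <- moisture_of_location(model, grid)
  nloc <- grid$n_locations
  moisture <- strength <- numeric(nloc * n_replicates)
  for (i in seq_len(nloc)) {
    idx <- (i - 1L) * n_replicates + seq_len(n_replicates)
    m_i <- sample_truncated_normal(
      n_replicates, mean = mean_m[i], sd = noise$moisture_sd,
      bound = noise$moisture_bound,
      seed = substream_seed(seed, "dataset-moisture", i))
    centre <- if (couple_strength) mean_strength_of_moisture(model, m_i)
              else rep(mean_strength_of_moisture(model, mean_m[i]), n_replicates)
    s_i <- centre + sample_truncated_normal(
      n_replicates, mean = 0, sd = noise$strength_sd,
      bound = noise$strength_bound,
      seed = substream_seed(seed, "dataset-strength", i))
    moisture[idx] <- m_i
    strength[idx] <- s_i
  }
  out <- data.frame(
    hypothesis = model$hypothesis,
    location_index = rep(seq_len(nloc), each = n_replicates),
    replicate_index = rep(seq_len(n_replicates), times = nloc),
    moisture = moisture,
    strength = strength,
    stringsAsFactors = FALSE
  )
  structure(out, model = model, noise = noise, grid = grid, seed = seed,
            n_replicates = n_replicates,
            class = c("ground_truth", "data.frame"))
}

#' Moisture range of a dataset
#'
#' The observed span of moisture values in a full dataset; this defines the
#' variable-space over which effective coverage is binned.
#'
#' @param dataset A `ground_truth` data frame (or any data frame with a
#'   `moisture` column).
#' @return Length-2 numeric `c(min, max)`.
#' @export
moisture_range <- function(dataset) {
  range(dataset$moisture)
}

#' Write / read a ground-truth dataset as CSV
#'
#' Plain-text round trip of the replicate table with 12 significant digits,
#' header `hypothesis,location_index,replicate_index,moisture,strength`.
#'
#' @param dataset A `ground_truth` data frame.
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns the data frame (without generation attributes).
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$moisture <- signif(df$moisture, 12)
  df$strength <- signif(df$strength, 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hypothesis", "location_index", "replicate_index",
            "moisture", "strength")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  class(df) <- c("ground_truth", "data.frame")
  df
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground-truth dataset (%s hypothesis): %d records at %d locations\n",
              x$hypothesis[1L], nrow(x), length(unique(x$location_index))))
  NextMethod()
}
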