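#' Execute a sampling strategy against a dataset
#'
#' Replays the survey-task interface: one step at a time, in plan order,
#' the requested number of that location's replicates is drawn uniformly
#' without replacement from the replicates not yet shown for that location.
#' After each step the cumulative number of observations, effective
#' coverage and fitting error are recorded (the fitting error is defined
#' once at least 3 observations with 2 distinct moistures are available;
#' before that it is `NA`).
#'
#' Requesting more replicates than remain at a location yields a warning
#' and a partial (capped) draw.
#'
#' @param dataset A `ground_truth` data frame.
#' @param strategy A [sampling_strategy()] on the dataset's grid.
#' @param seed Integer seed; each step draws from its own substream.
#' @param spec A [coverage_spec()] for the cumulative coverage.
#' @param compute_cumulative Logical; compute per-step coverage and fitting
#'   error (default `TRUE`).  Disable when only the final state matters.
#' @param ... Passed to [fit_piecewise()] for the cumulative fits.
#' @return An object of class `observation_log`: a list with `steps`
#'   (step, location, n_requested, n_drawn, phase), `observations`
#'   (step, location, replicate_index, moisture, strength) and
#'   `cumulative` (step, n_obs, coverage, rmse) data frames.
#' @export
execute_strategy <- function(dataset, strategy, seed, spec = coverage_spec(),
                             compute_cumulative = TRUE, ...) {
  stopifnot(inherits(strategy, "sampling_strategy"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_rep <- attr(dataset, "n_replicates")
  if (is.null(n_rep)) n_rep <- max(dataset$replicate_index)
  rng <- moisture_range(dataset)
  remaining <- lapply(seq_len(max(dataset$location_index)), function(loc)
    sort(unique(dataset$replicate_index[dataset$location_index == loc])))

  n_steps <- nrow(strategy)
  obs <- vector("list", n_steps)
  n_drawn <- integer(n_steps)
  cum_n <- integer(n_steps)
  cum_cov <- rep(NA_real_, n_steps)
  cum_rmse <- rep(NA_real_, n_steps)
  all_m <- numeric(0); all_s <- numeric(0)

  for (i in seq_len(n_steps)) {
    loc <- strategy$location[i]
    req <- strategy$n[i]
    avail <- remaining[[loc]]
    take <- min(req, length(avail))
    if (take < req)
      warning(sprintf(
        "step %d requests %d measurements at location %d but only %d remain; drawing %d",
        i, req, loc, length(avail), take), call. = FALSE)
    drawn <- if (take == 0L) integer(0)
             else with_seed(substream_seed(seed, "replicates", i),
                            avail[sample.int(length(avail), take)])
    remaining[[loc]] <- setdiff(avail, drawn)
    rows <- dataset[dataset$location_index == loc &
                    dataset$replicate_index %in% drawn, , drop = FALSE]
    ## preserve the random draw order
    rows <- rows[match(drawn, rows$replicate_index), , drop = FALSE]
    n_drawn[i] <- take
    obs[[i]] <- data.frame(step = i, location = loc,
                           replicate_index = rows$replicate_index,
                           moisture = rows$moisture, strength = rows$strength)
    all_m <- c(all_m, rows$moisture)
    all_s <- c(all_s, rows$strength)
    cum_n[i] <- length(all_m)
    if (compute_cumulative) {
      cum_cov[i] <- effective_coverage(all_m, rng, spec)
      if (length(all_m) >= 3L && length(unique(all_m)) >= 2L)
        cum_rmse[i] <- fit_piecewise(all_m, all_s, ...)$rmse
    }
  }
  structure(
    list(steps = data.frame(step = seq_len(n_steps),
                            location = strategy$location,
                            n_requested = strategy$n,
                            n_drawn = n_drawn,
                            phase = strategy$phase),
         observations = do.call(rbind, obs),
         cumulative = data.frame(step = seq_len(n_steps), n_obs = cum_n,
                                 coverage = cum_cov, rmse = cum_rmse),
         seed = seed, spec = spec),
    class = "observation_log"
  )
}

#' @export
print.observation_log <- function(x, ...) {
  cat(sprintf("Observation log: %d steps, %d observations\n",
              nrow(x$steps), sum(x$steps$n_drawn)))
  invisible(x)
}

#' Fitting-error trajectory of an observation log
#'
#' Recomputes, from the raw observations alone, the effective coverage and
#' fitting error after each completed step.  The trajectory starts at the
#' first step with a defined fit (at least 3 observations, 2 distinct
#' moistures); when the log contains the full dataset the final fitting
#' error equals [representative_fitting_error()].
#'
#' @param log An [execute_strategy()] observation log.
#' @param dataset The `ground_truth` dataset the log was produced on.
#' @param spec A [coverage_spec()].
#' @param ... Passed to [fit_piecewise()].
#' @return Data frame with columns `step`, `n_obs`, `coverage`, `rmse`,
#'   one row per step with a defined fit.
#' @export
fitting_trajectory <- function(log, dataset, spec = coverage_spec(), ...) {
  stopifnot(inherits(log, "observation_log"))
  rng <- moisture_range(dataset)
  obs <- log$observations
  steps <- sort(unique(obs$step))
  out <- lapply(steps, function(s) {
    sub <- obs[obs$step <= s, , drop = FALSE]
    if (nrow(sub) < 3L || length(unique(sub$moisture)) < 2L) return(NULL)
    data.frame(step = s, n_obs = nrow(sub),
               coverage = effective_coverage(sub$moisture, rng, spec),
               rmse = fit_piecewise(sub$moisture, sub$strength, ...)$rmse)
  })
  do.call(rbind, out)
}

#' Strategy specification for Monte-Carlo runs
#'
#' A compact description of a strategy family: `"even"` (equal spacing,
#' fixed locations across iterations) or `"random"` (locations redrawn
#' each iteration).  The label mirrors the shell notation, e.g.
#' `"even:8x3"` is 3 measurements at 8 evenly spaced locations.
#'
#' @param type `"even"` or `"random"`.
#' @param n_locations Number of sites.
#' @param magic_number Measurements per site.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(type = c("even", "random"), n_locations,
                          magic_number) {
  type <- match.arg(type)
  structure(list(type = type, n_locations = as.integer(n_locations),
                 magic_number = as.integer(magic_number),
                 label = sprintf("%s:%dx%d", type, n_locations, magic_number)),
            class = "strategy_spec")
}

#' Parse a strategy label
#'
#' Converts `"even:8x3"` / `"random:11x3"` notation into a
#' [strategy_spec()].
#'
#' @param label Character label.
#' @return A [strategy_spec()].
#' @export
parse_strategy_spec <- function(label) {
  m <- regmatches(label, regexec("^(even|random):([0-9]+)x([0-9]+)$", label))[[1L]]
  if (length(m) != 4L)
    stop("strategy label must look like \"even:8x3\" or \"random:11x3\"",
         call. = FALSE)
  strategy_spec(m[2L], as.integer(m[3L]), as.integer(m[4L]))
}

#' Monte-Carlo distribution of final fitting errors
#'
#' Runs `n_iter` independent executions of a strategy family against one
#' dataset and records the final fitting error of each run.  Evenly spaced
#' (heuristic) strategies keep their locations fixed and only resample
#' which replicates are shown; random strategies redraw their locations
#' each iteration.
#'
#' @param spec A [strategy_spec()], a label string, or a function
#'   `function(seed)` returning a [sampling_strategy()].
#' @param dataset A `ground_truth` data frame.
#' @param n_iter Number of iterations (default 100).
#' @param seed Integer master seed; each iteration derives its own
#'   substreams.
#' @param ... Passed to [fit_piecewise()].
#' @return An object of class `error_distribution`: a list with
#'   `strategy_label`, `hypothesis`, `final_errors` (length `n_iter`) and
#'   `representative_error`.
#' @export
strategy_error_distribution <- function(spec, dataset, n_iter = 100L, seed,
                                        ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.character(spec)) spec <- parse_strategy_spec(spec)
  grid <- attr(dataset, "grid")
  if (is.null(grid)) grid <- transect_grid(max(dataset$location_index))
  maker <- if (is.function(spec)) {
    label <- "custom"
    spec
  } else {
    label <- spec$label
    if (spec$type == "even") {
      fixed <- evenly_spaced_strategy(grid, spec$n_locations, spec$magic_number)
      function(s) fixed
    } else {
      function(s) random_strategy(grid, spec$n_locations, spec$magic_number,
                                  seed = s)
    }
  }
  errs <- vapply(seq_len(n_iter), function(it) {
    strat <- maker(substream_seed(seed, "iter-strategy", it))
    log <- execute_strategy(dataset, strat,
                            seed = substream_seed(seed, "iter-replicates", it),
                            compute_cumulative = FALSE)
    fit_piecewise(log$observations$moisture, log$observations$strength, ...)$rmse
  }, numeric(1))
  structure(
    list(strategy_label = label,
         hypothesis = dataset$hypothesis[1L],
         final_errors = errs,
         representative_error = representative_fitting_error(dataset, ...)),
    class = "error_distribution"
  )
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "Final fitting-error distribution (%s, %s hypothesis): %d iterations\n",
    x$strategy_label, x$hypothesis, length(x$final_errors)))
  cat(sprintf("  mean %.4g, sd %.4g; representative error %.4g\n",
              mean(x$final_errors), stats::sd(x$final_errors),
              x$representative_error))
  invisible(x)
}

#' Write an error distribution to CSV + JSON sidecar
#'
#' CSV columns `iteration,final_rmse`; the JSON sidecar records the
#' representative error and the strategy label.
#'
#' @param dist An [strategy_error_distribution()] result.
#' @param path CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_error_distribution <- function(dist, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(dist$final_errors),
               final_rmse = signif(dist$final_errors, 12)),
    path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(
    list(strategy = dist$strategy_label, hypothesis = dist$hypothesis,
         representative_error = dist$representative_error,
         n_iter = length(dist$final_errors)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
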