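#' Build a synthetic participant cohort with known composition
#'
#' Generates participant records whose cohort-level summary is analytically
#' predictable: exact numbers of records (rounded from the requested
#' fractions) are given each property, so counting identities can be
#' verified against [cohort_summary()] output.  The defaults mirror an
#' expert-like cohort: everyone uses a magic number, most use equal
#' spacing, most anchor to their plan.
#'
#' Equal-spacing records use an evenly spaced 8-location plan; non-uniform
#' records use a clustered plan whose interval discrepancy exceeds the
#' threshold.  Adjusted (non-anchored) records append one added step at an
#' unplanned location, either after the plan is complete or (for the
#' deviating fraction) mid-plan; magic-number-changing records give that
#' added location a count different from their magic number.
#'
#' @param n_records Cohort size (>= 1).
#' @param seed Integer seed (controls magic-number draws and the
#'   non-uniform location sets).
#' @param frac_equal_spacing Fraction with equal-spacing plans.
#' @param frac_magic_number Fraction whose initial counts are constant.
#' @param magic_numbers Integer support of the magic-number distribution.
#' @param magic_weights Sampling weights over `magic_numbers`.
#' @param frac_anchored Fraction (of records, all of which get logs) that
#'   execute exactly their plan.
#' @param frac_deviated_of_adjusted Among adjusted records, the fraction
#'   whose added step comes before plan completion.
#' @param frac_magic_change_of_adjusted Among adjusted records with a
#'   magic number, the fraction whose addition changes the magic number.
#' @param accuracy_given,accuracy_alternative Fraction of records assigned
#'   each hypothesis that reach the correct conclusion.
#' @return List of [participant_record()]s.
#' @export
make_fixture_cohort <- function(n_records, seed,
                                frac_equal_spacing = 1,
                                frac_magic_number = 1,
                                magic_numbers = 3:5,
                                magic_weights = NULL,
                                frac_anchored = 1,
                                frac_deviated_of_adjusted = 0,
                                frac_magic_change_of_adjusted = 0,
                                accuracy_given = 1,
                                accuracy_alternative = 1) {
  stopifnot(n_records >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  grid <- transect_grid()
  n <- as.integer(n_records)
  n_eq <- round(frac_equal_spacing * n)
  n_magic <- round(frac_magic_number * n)
  n_anch <- round(frac_anchored * n)
  n_adj <- n - n_anch
  n_dev <- round(frac_deviated_of_adjusted * n_adj)

  magics <- with_seed(substream_seed(seed, "fixture-magic"), {
    sample(magic_numbers, n, replace = TRUE, prob = magic_weights)
  })

  hyp <- rep(c("given", "alternative"), length.out = n)
  ## exact per-hypothesis accuracy counts
  correct <- logical(n)
  for (h in c("given", "alternative")) {
    idx <- which(hyp == h)
    acc <- if (h == "given") accuracy_given else accuracy_alternative
    correct[idx[seq_len(round(acc * length(idx)))]] <- TRUE
  }

  ## adjusted records with a magic-number change, counted among adjusted
  ## records that have a magic number (the first n_magic records)
  adj_idx <- if (n_adj > 0L) (n_anch + 1L):n else integer(0)
  adj_with_magic <- adj_idx[adj_idx <= n_magic]
  n_chg <- round(frac_magic_change_of_adjusted * length(adj_with_magic))
  chg_set <- adj_with_magic[seq_len(n_chg)]

  records <- vector("list", n)
  for (i in seq_len(n)) {
    magic <- magics[i]
    if (i <= n_eq) {
      plan_loc <- evenly_spaced_strategy(grid, 8L, 1L)$location
    } else {
      ## clustered, non-uniform plan: intervals {1, 1, 8, 7} style,
      ## discrepancy well above 1
      plan_loc <- c(1L, 2L, 3L, 11L, 18L)
    }
    counts <- if (i <= n_magic) rep(magic, length(plan_loc))
              else magic + (seq_along(plan_loc) %% 2L)  # alternating, non-constant
    plan <- sampling_strategy(plan_loc, counts, grid = grid)

    anchored <- i <= n_anch
    if (anchored) {
      exec <- data.frame(location = plan$location, n = plan$n,
                         phase = "initial")
    } else {
      extra_loc <- setdiff(seq_len(grid$n_locations), plan_loc)[1L]
      extra_n <- if (i %in% chg_set) magic + 1L else magic
      deviates <- match(i, adj_idx) <= n_dev
      init <- data.frame(location = plan$location, n = plan$n,
                         phase = "initial")
      add <- data.frame(location = extra_loc, n = extra_n, phase = "added")
      exec <- if (deviates)
        rbind(init[1L, ], add, init[-1L, ])  # mid-plan deviation
      else
        rbind(init, add)                     # waited until completion
    }
    conclusion <- if (hyp[i] == "given") {
      if (correct[i]) "accept" else "reject"
    } else {
      if (correct[i]) "reject" else "accept"
    }
    records[[i]] <- participant_record(
      participant_id = sprintf("S%03d", i), expertise = "expert",
      initial_strategy = plan, assigned_hypothesis = hyp[i],
      executed_log = exec, conclusion = conclusion)
  }
  records
}

#' Participant-record JSON round trip
#'
#' Versioned plain-text schema for cohorts of participant records:
#' `{"schema_version": 1, "records": [{"participant_id":, "expertise":,
#' "assigned_hypothesis":, "conclusion":, "confidence":, "grid_size":,
#' "initial_strategy": [{"location":, "n":}], "executed_steps":
#' [{"location":, "n":, "phase":}]}]}`.
#'
#' @param records List of [participant_record()]s.
#' @param path File path.
#' @return The writer returns `path` invisibly; the reader returns a list
#'   of records.
#' @export
write_participant_records <- function(records, path) {
  enc <- lapply(records, function(r) {
    grid <- attr(r$initial_strategy, "grid")
    exec <- executed_steps(r$executed_log)
    list(participant_id = r$participant_id, expertise = r$expertise,
         assigned_hypothesis = r$assigned_hypothesis,
         conclusion = r$conclusion, confidence = r$confidence,
         grid_size = grid$n_locations,
         initial_strategy = lapply(seq_len(nrow(r$initial_strategy)),
           function(i) list(location = r$initial_strategy$location[i],
                            n = r$initial_strategy$n[i])),
         executed_steps = if (is.null(exec)) NULL else
           lapply(seq_len(nrow(exec)),
             function(i) list(location = exec$location[i], n = exec$n[i],
                              phase = exec$phase[i])))
  })
  jsonlite::write_json(list(schema_version = 1L, records = enc), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_participant_records
#' @export
read_participant_records <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported participant-record schema; expected schema_version 1. ",
         "Externally digitized logs must first be converted to this schema ",
         "(see ?write_participant_records for the field layout).",
         call. = FALSE)
  lapply(obj$records, function(r) {
    grid <- transect_grid(r$grid_size)
    plan <- sampling_strategy(
      vapply(r$initial_strategy, `[[`, numeric(1), "location"),
      vapply(r$initial_strategy, `[[`, numeric(1), "n"),
      grid = grid)
    exec <- if (is.null(r$executed_steps) || length(r$executed_steps) == 0L) NULL
            else data.frame(
              location = vapply(r$executed_steps, `[[`, numeric(1), "location"),
              n = vapply(r$executed_steps, `[[`, numeric(1), "n"),
              phase = vapply(r$executed_steps, `[[`, character(1), "phase"))
    na_if_null <- function(x) if (is.null(x)) NA_character_ else x
    participant_record(r$participant_id, r$expertise, plan,
                       na_if_null(r$assigned_hypothesis), exec,
                       na_if_null(r$conclusion), na_if_null(r$confidence))
  })
}
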