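#' Participant record
#'
#' One subject's assigned dataset, initial plan, executed sampling sequence
#' and conclusion about the given hypothesis.  Experts carry an assigned
#' hypothesis and a conclusion; novices may have only an initial strategy.
#'
#' @param participant_id Identifier string.
#' @param expertise `"expert"` or `"novice"`.
#' @param initial_strategy A [sampling_strategy()] whose steps are all
#'   phase `"initial"`.
#' @param assigned_hypothesis `"given"`, `"alternative"` or `NA`.
#' @param executed_log Executed steps: an [execute_strategy()] observation
#'   log, a data frame with columns `location`, `n`, `phase` in execution
#'   order, or `NULL`.
#' @param conclusion `"accept"`, `"reject"` or `NA`.
#' @param confidence `"very"`, `"moderately"`, `"slightly"`,
#'   `"not_at_all"` or `NA`.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, expertise = c("expert", "novice"),
                               initial_strategy,
                               assigned_hypothesis = NA_character_,
                               executed_log = NULL,
                               conclusion = NA_character_,
                               confidence = NA_character_) {
  expertise <- match.arg(expertise)
  stopifnot(inherits(initial_strategy, "sampling_strategy"))
  if (!is.na(assigned_hypothesis) &&
      !assigned_hypothesis %in% c("given", "alternative"))
    stop("`assigned_hypothesis` must be \"given\" or \"alternative\"", call. = FALSE)
  if (!is.na(conclusion) && !conclusion %in% c("accept", "reject"))
    stop("`conclusion` must be \"accept\" or \"reject\"", call. = FALSE)
  if (expertise == "expert" && (is.na(assigned_hypothesis) || is.na(conclusion)))
    stop("expert records require `assigned_hypothesis` and `conclusion`",
         call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id), expertise = expertise,
         assigned_hypothesis = assigned_hypothesis,
         initial_strategy = initial_strategy,
         executed_log = executed_log,
         conclusion = conclusion, confidence = confidence),
    class = "participant_record"
  )
}

# Normalize an executed log to a data.frame(location, n, phase) in
# execution order.
executed_steps <- function(log) {
  if (is.null(log)) return(NULL)
  if (inherits(log, "observation_log"))
    return(data.frame(location = log$steps$location,
                      n = log$steps$n_requested,
                      phase = log$steps$phase))
  stopifnot(all(c("location", "n", "phase") %in% names(log)))
  data.frame(location = as.integer(log$location), n = as.integer(log$n),
             phase = as.character(log$phase))
}

# Earliest executed-step index at which the initial plan is fully covered
# (per-location executed initial-phase counts >= planned counts); NA if the
# plan is never completed.
.plan_completion_index <- function(plan, exec) {
  need <- tapply(plan$n, plan$location, sum)
  got <- stats::setNames(rep(0L, length(need)), names(need))
  for (i in seq_len(nrow(exec))) {
    loc <- as.character(exec$location[i])
    if (exec$phase[i] == "initial" && loc %in% names(got))
      got[loc] <- got[loc] + exec$n[i]
    if (all(got >= need)) return(i)
  }
  NA_integer_
}

#' Classify a participant's adaptation behavior
#'
#' Compares the executed sampling sequence against the initial plan and
#' flags the anchoring/adaptation patterns of interest:
#' \describe{
#'   \item{anchored_no_adjustment}{the executed steps exactly equal the
#'     initial plan — same locations, same counts, no additions.}
#'   \item{deviated_before_completion}{some added step occurred before the
#'     initial plan was complete (encounter-conditional / area-restricted
#'     search).}
#'   \item{completed_initial_then_added}{additions exist but all came after
#'     the initial plan was complete.}
#'   \item{eventually_visited_all_initial}{every planned location was
#'     visited at some point.}
#'   \item{changed_magic_number}{some sampled location's final total count
#'     differs from the initial magic number; `n_magic_number_changes`
#'     counts such locations.  `NA` when the initial plan has no magic
#'     number.}
#' }
#'
#' @param record A [participant_record()] with an executed log.
#' @return An object of class `behavior_summary` (a list of the flags
#'   above plus `n_locations_sampled` and `conclusion_outcome`).
#' @export
classify_adaptation <- function(record) {
  stopifnot(inherits(record, "participant_record"))
  exec <- executed_steps(record$executed_log)
  if (is.null(exec))
    stop("classification unavailable: record has no executed log", call. = FALSE)
  plan <- initial_steps(record$initial_strategy)

  added <- which(exec$phase == "added")
  done_at <- .plan_completion_index(plan, exec)
  anchored <- length(added) == 0L &&
    nrow(exec) == nrow(plan) &&
    all(exec$location == plan$location) && all(exec$n == plan$n)

  deviated <- length(added) > 0L &&
    (is.na(done_at) || any(added < done_at))
  completed_then_added <- length(added) > 0L && !deviated

  eventually_all <- all(plan$location %in% exec$location)

  magic <- detect_magic_number(record$initial_strategy)
  locs_sampled <- unique(exec$location)
  if (is.na(magic)) {
    changed <- NA
    n_changes <- NA_integer_
  } else {
    totals <- tapply(exec$n, exec$location, sum)
    n_changes <- sum(totals[as.character(locs_sampled)] != magic)
    changed <- n_changes > 0L
  }
  structure(
    list(anchored_no_adjustment = anchored,
         deviated_before_completion = if (anchored) FALSE else deviated,
         completed_initial_then_added = if (anchored) FALSE else completed_then_added,
         eventually_visited_all_initial = eventually_all,
         changed_magic_number = if (isTRUE(anchored) && !is.na(magic)) FALSE else changed,
         n_magic_number_changes = n_changes,
         n_locations_sampled = length(locs_sampled),
         conclusion_outcome = conclusion_outcome(record)),
    class = "behavior_summary"
  )
}

#' Conclusion outcome of a participant
#'
#' A conclusion is correct when it matches the assigned ground truth:
#' accepting the given hypothesis when its dataset was assigned, or
#' rejecting it when the alternative dataset was assigned.  Rejecting the
#' given hypothesis on its own dataset is a Type 1 error; accepting it on
#' the alternative dataset is a Type 2 error.
#'
#' @param record A [participant_record()].
#' @return `"correct"`, `"type1_error"`, `"type2_error"` or `"none"`
#'   (missing hypothesis or conclusion).
#' @export
conclusion_outcome <- function(record) {
  h <- record$assigned_hypothesis
  c_ <- record$conclusion
  if (is.na(h) || is.na(c_)) return("none")
  if (h == "given" && c_ == "accept") "correct"
  else if (h == "given" && c_ == "reject") "type1_error"
  else if (h == "alternative" && c_ == "accept") "type2_error"
  else "correct"
}

#' Summarize a cohort of participant records
#'
#' Computes the cohort-level fractions and counts used in the behavioral
#' analyses: equal-spacing and magic-number adherence, the magic-number
#' histogram, anchoring/adaptation subgroups (by assigned hypothesis),
#' conclusion outcomes, and the per-location magic-number change rate
#' (changed locations / all locations sampled, over records with a magic
#' number).
#'
#' @param records List of [participant_record()]s.
#' @param threshold Equal-spacing threshold (default 1 grid step).
#' @return An object of class `cohort_summary` (a named list).
#' @export
cohort_summary <- function(records, threshold = 1) {
  stopifnot(length(records) >= 1L)
  n <- length(records)
  cls <- lapply(records, function(r) classify_strategy(r$initial_strategy,
                                                       threshold = threshold))
  eq <- vapply(cls, `[[`, logical(1), "is_equal_spacing")
  magic <- vapply(cls, `[[`, integer(1), "magic_number")
  has_log <- vapply(records, function(r) !is.null(r$executed_log), logical(1))
  beh <- vector("list", n)
  beh[has_log] <- lapply(records[has_log], classify_adaptation)
  hyp <- vapply(records, function(r) as.character(r$assigned_hypothesis),
                character(1))
  outcome <- vapply(records, conclusion_outcome, character(1))

  flag <- function(name) vapply(beh, function(b)
    if (is.null(b)) NA else isTRUE(b[[name]]), logical(1))
  anchored <- flag("anchored_no_adjustment")
  deviated <- flag("deviated_before_completion")
  completed_added <- flag("completed_initial_then_added")
  eventually <- flag("eventually_visited_all_initial")

  n_changes <- vapply(beh, function(b)
    if (is.null(b)) NA_integer_ else b$n_magic_number_changes, integer(1))
  n_sampled <- vapply(beh, function(b)
    if (is.null(b)) NA_integer_ else b$n_locations_sampled, integer(1))
  with_magic <- has_log & !is.na(magic)

  adjusted <- has_log & !anchored
  structure(list(
    n_records = n,
    n_equal_spacing = sum(eq), frac_equal_spacing = mean(eq),
    n_magic_number = sum(!is.na(magic)), frac_magic_number = mean(!is.na(magic)),
    magic_number_histogram = table(magic[!is.na(magic)]),
    n_with_log = sum(has_log),
    n_anchored = sum(anchored, na.rm = TRUE),
    frac_anchored = if (any(has_log)) sum(anchored, na.rm = TRUE) / sum(has_log) else NA_real_,
    anchored_by_hypothesis = table(hyp[which(anchored)]),
    n_adjusted = sum(adjusted, na.rm = TRUE),
    n_completed_then_added = sum(completed_added, na.rm = TRUE),
    n_deviated_before_completion = sum(deviated, na.rm = TRUE),
    n_deviated_eventually_all = sum(deviated & eventually, na.rm = TRUE),
    n_conclusions = sum(outcome != "none"),
    conclusion_outcomes = table(factor(outcome[outcome != "none"],
                                       levels = c("correct", "type1_error",
                                                  "type2_error"))),
    n_magic_number_changes = sum(n_changes[with_magic]),
    n_locations_sampled = sum(n_sampled[with_magic]),
    magic_number_change_rate =
      if (sum(n_sampled[with_magic]) > 0)
        sum(n_changes[with_magic]) / sum(n_sampled[with_magic])
      else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d records\n", x$n_records))
  cat(sprintf("  equal spacing: %d (%.1f%%); magic number: %d (%.1f%%)\n",
              x$n_equal_spacing, 100 * x$frac_equal_spacing,
              x$n_magic_number, 100 * x$frac_magic_number))
  if (x$n_with_log > 0)
    cat(sprintf("  anchored: %d of %d with logs (%.1f%%); adjusted: %d (%d waited, %d deviated)\n",
                x$n_anchored, x$n_with_log, 100 * x$frac_anchored,
                x$n_adjusted, x$n_completed_then_added,
                x$n_deviated_before_completion))
  if (x$n_conclusions > 0) {
    oc <- x$conclusion_outcomes
    cat(sprintf("  conclusions: %d correct, %d Type 1, %d Type 2\n",
                oc[["correct"]], oc[["type1_error"]], oc[["type2_error"]]))
  }
  if (!is.na(x$magic_number_change_rate))
    cat(sprintf("  magic-number changes: %d of %d locations sampled (%.1f%%)\n",
                x$n_magic_number_changes, x$n_locations_sampled,
                100 * x$magic_number_change_rate))
  invisible(x)
}
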