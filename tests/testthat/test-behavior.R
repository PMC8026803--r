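make_record <- function(plan_loc = c(1, 4, 7, 10, 13, 16, 19, 22),
                        plan_n = 3, exec = NULL, hypothesis = "given",
                        conclusion = "accept") {
  plan <- sampling_strategy(plan_loc, plan_n)
  if (is.null(exec))
    exec <- data.frame(location = plan$location, n = plan$n, phase = "initial")
  participant_record("P1", "expert", plan, hypothesis, exec, conclusion)
}

test_that("a log identical to the plan is classified as anchored", {
  b <- classify_adaptation(make_record())
  expect_true(b$anchored_no_adjustment)
  expect_false(b$deviated_before_completion)
  expect_false(b$completed_initial_then_added)
  expect_false(b$changed_magic_number)
  expect_equal(b$n_magic_number_changes, 0L)
  expect_true(b$eventually_visited_all_initial)
})

test_that("mid-plan additions are deviations; post-plan additions are not", {
  plan_loc <- c(1, 4, 7, 10, 13, 16, 19, 22)
  init <- data.frame(location = plan_loc, n = 3, phase = "initial")
  # added step after step 4, then the remaining plan completed
  exec_dev <- rbind(init[1:4, ],
                    data.frame(location = 5, n = 3, phase = "added"),
                    init[5:8, ])
  b <- classify_adaptation(make_record(exec = exec_dev))
  expect_false(b$anchored_no_adjustment)
  expect_true(b$deviated_before_completion)
  expect_false(b$completed_initial_then_added)
  expect_true(b$eventually_visited_all_initial)

  # the same addition after the full plan: waited until completion
  exec_wait <- rbind(init, data.frame(location = 5, n = 3, phase = "added"))
  b2 <- classify_adaptation(make_record(exec = exec_wait))
  expect_false(b2$deviated_before_completion)
  expect_true(b2$completed_initial_then_added)

  # abandoning the plan part-way (with an addition) is a deviation and
  # leaves initial locations unvisited
  exec_quit <- rbind(init[1:3, ], data.frame(location = 9, n = 3, phase = "added"))
  b3 <- classify_adaptation(make_record(exec = exec_quit))
  expect_true(b3$deviated_before_completion)
  expect_false(b3$eventually_visited_all_initial)
})

test_that("magic-number changes are counted per sampled location", {
  plan_loc <- c(1, 6, 11, 16, 21)
  init <- data.frame(location = plan_loc, n = 3, phase = "initial")
  # one location topped up to 5 total: one change
  exec <- rbind(init, data.frame(location = 11, n = 2, phase = "added"))
  b <- classify_adaptation(make_record(plan_loc = plan_loc, exec = exec))
  expect_true(b$changed_magic_number)
  expect_equal(b$n_magic_number_changes, 1L)
  expect_equal(b$n_locations_sampled, 5L)
  # a new location sampled with the same magic number: no change
  exec2 <- rbind(init, data.frame(location = 3, n = 3, phase = "added"))
  b2 <- classify_adaptation(make_record(plan_loc = plan_loc, exec = exec2))
  expect_false(b2$changed_magic_number)
  # no magic number in the plan -> change undefined
  plan <- sampling_strategy(plan_loc, c(3, 3, 4, 3, 3))
  r <- participant_record("P2", "expert", plan, "given",
                          data.frame(location = plan_loc, n = c(3, 3, 4, 3, 3),
                                     phase = "initial"), "accept")
  expect_true(is.na(classify_adaptation(r)$changed_magic_number))
})

test_that("classification is a pure function of log content", {
  exec <- data.frame(location = c(1, 4, 7, 10, 13, 16, 19, 22), n = 3,
                     phase = "initial")
  r1 <- make_record(exec = exec)
  path <- withr::local_tempfile(fileext = ".json")
  write_participant_records(list(r1), path)
  r2 <- read_participant_records(path)[[1]]
  expect_equal(classify_adaptation(r2), classify_adaptation(r1))
  expect_equal(r2$conclusion, r1$conclusion)
})

test_that("conclusion outcomes follow the assigned ground truth", {
  expect_equal(conclusion_outcome(make_record(hypothesis = "given",
                                              conclusion = "accept")), "correct")
  expect_equal(conclusion_outcome(make_record(hypothesis = "given",
                                              conclusion = "reject")), "type1_error")
  expect_equal(conclusion_outcome(make_record(hypothesis = "alternative",
                                              conclusion = "accept")), "type2_error")
  expect_equal(conclusion_outcome(make_record(hypothesis = "alternative",
                                              conclusion = "reject")), "correct")
  novice <- participant_record("N1", "novice",
                               sampling_strategy(c(1, 11, 21), 3))
  expect_equal(conclusion_outcome(novice), "none")
})

test_that("cohort summaries reproduce counting identities on constructed fixtures", {
  # 4 records: 3 uniform plans, 1 non-uniform
  recs <- c(lapply(1:3, function(i) make_record()),
            list(make_record(plan_loc = c(1, 2, 10, 12), plan_n = 2)))
  cs <- cohort_summary(recs)
  expect_equal(cs$frac_equal_spacing, 0.75)
  expect_equal(cs$n_records, 4L)
  # all anchored -> adjusted fraction 0
  expect_equal(cs$n_anchored, 4L)
  expect_equal(cs$n_adjusted, 0L)
  expect_equal(cs$frac_anchored, 1)

  # 2 records each sampling 5 locations, one with 1 magic-number change
  plan_loc <- c(1, 6, 11, 16, 21)
  init <- data.frame(location = plan_loc, n = 3, phase = "initial")
  r_plain <- make_record(plan_loc = plan_loc, exec = init)
  r_change <- make_record(plan_loc = plan_loc,
                          exec = rbind(init[-5, ],
                                       data.frame(location = 21, n = 5,
                                                  phase = "initial")))
  cs2 <- cohort_summary(list(r_plain, r_change))
  expect_equal(cs2$n_magic_number_changes, 1L)
  expect_equal(cs2$n_locations_sampled, 10L)
  expect_equal(cs2$magic_number_change_rate, 1 / 10)
})

test_that("subgroup counts sum to the cohort size and fractions stay in [0, 1]", {
  recs <- make_fixture_cohort(20, seed = 7, frac_equal_spacing = 0.7,
                              frac_anchored = 0.5,
                              frac_deviated_of_adjusted = 0.4,
                              accuracy_given = 0.8, accuracy_alternative = 0.6)
  cs <- cohort_summary(recs)
  expect_equal(cs$n_anchored + cs$n_adjusted, cs$n_with_log)
  expect_equal(cs$n_completed_then_added + cs$n_deviated_before_completion,
               cs$n_adjusted)
  expect_equal(sum(cs$conclusion_outcomes), cs$n_conclusions)
  fr <- c(cs$frac_equal_spacing, cs$frac_magic_number, cs$frac_anchored,
          cs$magic_number_change_rate)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("fixture cohorts reproduce their requested mixture weights exactly", {
  # all equal-spacing, all anchored -> fractions exactly 1
  r1 <- make_fixture_cohort(10, seed = 1)
  cs1 <- cohort_summary(r1)
  expect_equal(cs1$frac_equal_spacing, 1)
  expect_equal(cs1$frac_anchored, 1)
  expect_equal(cs1$frac_magic_number, 1)

  # magic numbers concentrated on 3..5 -> histogram mode within 3..5
  hist <- cs1$magic_number_histogram
  expect_true(all(as.integer(names(hist)) %in% 3:5))

  # a mixed cohort hits its counts exactly
  r2 <- make_fixture_cohort(40, seed = 2, frac_equal_spacing = 0.6,
                            frac_magic_number = 0.9, frac_anchored = 0.25,
                            frac_deviated_of_adjusted = 0.5,
                            frac_magic_change_of_adjusted = 0.5,
                            accuracy_given = 0.75, accuracy_alternative = 0.5)
  cs2 <- cohort_summary(r2)
  expect_equal(cs2$n_equal_spacing, 24L)
  expect_equal(cs2$n_magic_number, 36L)
  expect_equal(cs2$n_anchored, 10L)
  expect_equal(cs2$n_deviated_before_completion, 15L)
  expect_equal(cs2$n_completed_then_added, 15L)
  # hypotheses alternate 20/20; accuracies 0.75 and 0.5
  oc <- cs2$conclusion_outcomes
  expect_equal(oc[["correct"]], 15L + 10L)
  expect_equal(oc[["type1_error"]], 5L)
  expect_equal(oc[["type2_error"]], 10L)
})

test_that("expert records require a hypothesis and conclusion", {
  plan <- sampling_strategy(c(1, 11, 21), 3)
  expect_error(participant_record("X", "expert", plan), "require")
  expect_s3_class(participant_record("X", "novice", plan),
                  "participant_record")
  expect_error(read_participant_records(
    withr::local_tempfile(lines = '{"schema_version": 2, "records": []}',
                          fileext = ".json")), "schema")
})
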