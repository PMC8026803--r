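test_that("average interval discrepancy follows the sorted-interval definition", {
  # perfectly uniform intervals score zero
  expect_equal(average_interval_discrepancy(
    sampling_strategy(c(1, 4, 7, 10), 3)), 0)
  # two locations (a single interval) score zero by convention
  expect_equal(average_interval_discrepancy(
    sampling_strategy(c(3, 17), 2)), 0)
  # hand enumeration: intervals {1, 8, 2} -> sorted {1, 2, 8} ->
  # successive differences {1, 6} -> mean 3.5
  expect_equal(average_interval_discrepancy(
    sampling_strategy(c(1, 2, 10, 12), 2)), 3.5)
  # equivalently (max - min) / (n_intervals - 1)
  expect_equal(average_interval_discrepancy(
    sampling_strategy(c(1, 2, 10, 12), 2)), (8 - 1) / 2)
  # the Gini-type pairwise alternative on the same intervals:
  # |1-8|, |1-2|, |8-2| -> mean 14/3
  expect_equal(average_interval_discrepancy(
    sampling_strategy(c(1, 2, 10, 12), 2), method = "pairwise"), 14 / 3)
  # degenerate strategy
  expect_error(average_interval_discrepancy(sampling_strategy(5, 2)),
               "degenerate")
})

test_that("discrepancy is translation-invariant and scales with dilation", {
  base <- c(2, 5, 11, 19)
  d0 <- average_interval_discrepancy(sampling_strategy(base, 1))
  shifted <- average_interval_discrepancy(sampling_strategy(base + 3, 1))
  expect_equal(shifted, d0)
  # uniform dilation of the grid positions scales the statistic linearly
  g2 <- transect_grid(22, positions = 2 * (1:22))
  d2 <- average_interval_discrepancy(sampling_strategy(base, 1, grid = g2))
  expect_equal(d2, 2 * d0)
})

test_that("magic-number detection requires constant initial counts", {
  expect_equal(detect_magic_number(sampling_strategy(c(1, 5, 9, 13), 4)), 4L)
  expect_true(is.na(detect_magic_number(
    sampling_strategy(c(1, 5, 9), c(3, 3, 4)))))
  # single location: vacuous constancy
  expect_equal(detect_magic_number(sampling_strategy(7, 5)), 5L)
  # added-phase steps do not affect the initial magic number
  s <- sampling_strategy(c(1, 5, 9, 14), c(3, 3, 3, 7),
                         phase = c("initial", "initial", "initial", "added"))
  expect_equal(detect_magic_number(s), 3L)
  # exhaustively: any two differing counts among three steps -> none
  for (counts in asplit(as.matrix(expand.grid(1:3, 1:3, 1:3)), 1)) {
    got <- detect_magic_number(sampling_strategy(c(1, 8, 15), counts))
    if (length(unique(counts)) == 1L) expect_equal(got, counts[[1]])
    else expect_true(is.na(got))
  }
})

test_that("evenly spaced strategies match the survey's heuristic strategies", {
  grid <- transect_grid()
  # full grid: all 22 locations, intervals exactly 1
  full <- evenly_spaced_strategy(grid, 22, 3)
  expect_equal(full$location, 1:22)
  expect_equal(average_interval_discrepancy(full), 0)
  # 3 measurements at 8 evenly spaced locations: 24 planned measurements
  s8 <- evenly_spaced_strategy(grid, 8, 3)
  cls <- classify_strategy(s8)
  expect_equal(sum(s8$n), 24)
  expect_true(cls$is_equal_spacing)
  expect_equal(cls$magic_number, 3L)
  expect_equal(cls$n_locations, 8L)
  expect_error(evenly_spaced_strategy(grid, 23, 3), "grid")
})

test_that("integer placement achieves the minimum interval variance (brute force)", {
  grid <- transect_grid()
  for (n_loc in c(8, 11, 15)) {
    s <- evenly_spaced_strategy(grid, n_loc, 3)
    expect_equal(length(unique(s$location)), n_loc)
    expect_true(all(diff(s$location) >= 1))
    got <- var(diff(s$location))
    best <- oracle_min_interval_variance(22L, n_loc)
    expect_equal(got, best, tolerance = 1e-12,
                 label = sprintf("interval variance for %d locations", n_loc))
  }
})

test_that("random strategies draw distinct locations uniformly", {
  grid <- transect_grid()
  # exhaustive draw: all 22 locations regardless of seed
  expect_equal(random_strategy(grid, 22, 3, seed = 5)$location, 1:22)
  # counting and distinctness for any seed
  s <- random_strategy(grid, 8, 3, seed = 42)
  expect_equal(length(unique(s$location)), 8L)
  expect_equal(sum(s$n), 24)
  expect_true(all(diff(s$location) > 0))  # ascending visit order
  # inclusion frequencies match the hypergeometric probability 8/22
  draws <- 4000L
  counts <- integer(22)
  for (i in seq_len(draws)) {
    loc <- random_strategy(grid, 8, 3, seed = i)$location
    counts[loc] <- counts[loc] + 1L
  }
  expect_gt(chisq.test(counts, p = rep(1 / 22, 22))$p.value, 1e-3)
})

test_that("classification applies the threshold and is orthogonal in its two heuristics", {
  # non-uniform, magic number present
  c1 <- classify_strategy(sampling_strategy(c(1, 2, 10, 12), 2))
  expect_false(c1$is_equal_spacing)
  expect_equal(c1$avg_interval_discrepancy, 3.5)
  expect_equal(c1$magic_number, 2L)
  # uniform, no magic number
  c2 <- classify_strategy(sampling_strategy(c(1, 11, 21), c(3, 5, 3)))
  expect_true(c2$is_equal_spacing)
  expect_equal(c2$avg_interval_discrepancy, 0)
  expect_true(is.na(c2$magic_number))
  # threshold is a parameter
  expect_true(classify_strategy(sampling_strategy(c(1, 2, 10, 12), 2),
                                threshold = 4)$is_equal_spacing)
})

test_that("strategy JSON and CSV round trips preserve steps, counts and phases", {
  s <- sampling_strategy(c(1, 5, 9, 14, 7), c(3, 3, 3, 3, 2),
                         phase = c(rep("initial", 4), "added"))
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_strategy_json(s, pj)
  write_strategy_csv(s, pc)
  for (s2 in list(read_strategy_json(pj), read_strategy_csv(pc))) {
    expect_equal(s2$location, s$location)
    expect_equal(s2$n, s$n)
    expect_equal(s2$phase, s$phase)
  }
})

test_that("strategy validation rejects off-grid and over-cap steps", {
  expect_error(sampling_strategy(c(1, 30), 3), "grid")
  expect_error(sampling_strategy(c(1, 5), 11), "\\[1, 10\\]")
  # an amendment at a location cannot precede that location's initial step
  expect_error(sampling_strategy(c(5, 5), c(3, 3),
                                 phase = c("added", "initial")),
               "precede")
  # but added steps at other locations may interleave with the plan
  expect_s3_class(sampling_strategy(c(1, 7, 5), c(3, 2, 3),
                                    phase = c("initial", "added", "initial")),
                  "sampling_strategy")
})
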