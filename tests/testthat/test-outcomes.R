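test_that("the transformation enumeration has the published structure", {
  specs <- enumerate_outcomes()
  expect_equal(nrow(specs), 10)
  expect_equal(anyDuplicated(specs$label), 0)
  expect_equal(as.vector(table(specs$family)), c(1, 3, 3, 3))
  f4 <- specs[specs$family == 4, ]
  expect_equal(f4$label, c("4a", "4b", "4c"))
  expect_equal(paste(f4$x, f4$y),
               c("pulp predentine", "pulp hard", "predentine hard"))
})

test_that("outcome values follow their defining ratios", {
  eq <- tooth_volumes(18, 0.1, 0.1, 0.1)
  expect_equal(compute_outcome(eq, "3a"), 1 / 3)
  expect_equal(compute_outcome(eq, "3b"), 1 / 3)
  expect_equal(compute_outcome(eq, "3c"), 1 / 3)
  expect_equal(compute_outcome(eq, "1"), 0.3)
  expect_equal(compute_outcome(eq, "2a"), 0.5)
  # female median volumes: (pulp + predentine)/total = 0.068/0.780
  fm <- tooth_volumes(28, 0.052, 0.016, 0.712)
  expect_equal(compute_outcome(fm, "4a"), 0.068 / 0.780)
  expect_equal(compute_outcome(fm, "4a"), 0.0872, tolerance = 1e-3)
})

test_that("algebraic identities hold on random volumes", {
  set.seed(42)
  for (i in 1:25) {
    tv <- tooth_volumes(38, runif(1, 0.01, 0.2), runif(1, 0.01, 0.1),
                        runif(1, 0.3, 1))
    o <- sapply(setNames(nm = enumerate_outcomes()$label),
                function(l) compute_outcome(tv, l))
    expect_equal(o[["3a"]] + o[["3b"]] + o[["3c"]], 1)
    expect_equal(o[["4a"]], 1 - o[["3c"]])
    expect_equal(o[["4b"]], 1 - o[["3b"]])
    expect_equal(o[["4c"]], 1 - o[["3a"]])
    expect_equal(o[["2c"]], (1 - o[["4a"]]) / o[["4a"]])
  }
})

test_that("non-positive volumes are rejected before the ln transform", {
  expect_error(compute_outcome(list(pulp_ml = 0, predentine_ml = 0.1,
                                    hard_ml = 0.5), "4a"), "positive")
  expect_error(tooth_volumes(18, -0.1, 0.1, 0.1))
})

test_that("a singleton tooth set is the ln outcome with no averaging", {
  co <- toy_cohort()
  s <- outcome_series(co, "4a", 28L)
  manual <- log((co$pulp_ml_28 + co$predentine_ml_28) /
                  (co$pulp_ml_28 + co$predentine_ml_28 + co$hard_ml_28))
  expect_equal(s$y, manual)
  expect_equal(s$participant_id, co$participant_id)
})

test_that("participants missing a member tooth are dropped with a count", {
  co <- toy_cohort()
  co$pulp_ml_18[2] <- NA
  s <- outcome_series(co, "4a", c(18L, 28L))
  expect_false("T02" %in% s$participant_id)
  expect_equal(nrow(s), 5)
  expect_equal(attr(s, "n_dropped"), 1)
  expect_error(outcome_series(co[2, ], "4a", c(18L, 28L)), "empty")
})

test_that("tooth-set averaging is mean of ratios then ln (brute force)", {
  co <- generate_cohort(generator_config(n_participants = 40, seed = 13))
  s <- outcome_series(co, "4a", c(18L, 28L, 38L, 48L))
  for (i in seq_len(nrow(s))) {
    row <- co[co$participant_id == s$participant_id[i], ]
    vals <- sapply(c(18, 28, 38, 48), function(t) {
      p <- row[[paste0("pulp_ml_", t)]]
      d <- row[[paste0("predentine_ml_", t)]]
      h <- row[[paste0("hard_ml_", t)]]
      (p + d) / (p + d + h)
    })
    expect_equal(s$y[i], log(mean(vals)))
  }
  # the log-mean variant averages the ln ratios instead
  s2 <- outcome_series(co, "4a", c(18L, 28L), average = "log")
  row1 <- co[co$participant_id == s2$participant_id[1], ]
  v <- sapply(c(18, 28), function(t) {
    p <- row1[[paste0("pulp_ml_", t)]]
    d <- row1[[paste0("predentine_ml_", t)]]
    h <- row1[[paste0("hard_ml_", t)]]
    log((p + d) / (p + d + h))
  })
  expect_equal(s2$y[1], mean(v))
})

test_that("redundancy filtering drops the odds-family duplicates", {
  co <- generate_cohort(generator_config(n_participants = 200, seed = 1))
  filt <- redundancy_filter(co)
  expect_equal(filt$retained$label, c("1", "3a", "3b", "3c", "4a", "4b", "4c"))
  expect_equal(sort(filt$dropped$label), c("2a", "2b", "2c"))
  expect_setequal(filt$dropped$overlaps_with, c("3a", "3b", "4a"))
  expect_true(all(filt$dropped$r >= 0.999))
})

test_that("the correlation matrix matches the textbook Pearson oracle", {
  co <- generate_cohort(generator_config(n_participants = 60, seed = 9))
  filt <- redundancy_filter(co)
  specs <- enumerate_outcomes()
  y4a <- unlist(lapply(third_molars(), function(t)
    outcome_series(co, "4a", t)$y))
  y3c <- unlist(lapply(third_molars(), function(t)
    outcome_series(co, "3c", t)$y))
  expect_equal(filt$correlation["4a", "3c"], abs(pearson_oracle(y4a, y3c)),
               tolerance = 1e-12)
  expect_equal(diag(filt$correlation), setNames(rep(1, 10), specs$label))
})

test_that("a duplicated spec is recognised as perfectly redundant", {
  co <- generate_cohort(generator_config(n_participants = 50, seed = 5))
  specs <- enumerate_outcomes()
  dup <- rbind(specs[specs$label == "4a", ], specs[specs$label == "4a", ])
  dup$label <- c("4a", "4a_copy")
  filt <- redundancy_filter(co, dup)
  expect_equal(nrow(filt$retained), 1)
  expect_equal(filt$dropped$r, 1)
})

test_that("the filter is idempotent on its own retained set", {
  co <- generate_cohort(generator_config(n_participants = 200, seed = 1))
  first <- redundancy_filter(co)
  second <- redundancy_filter(co, first$retained)
  expect_equal(second$retained$label, first$retained$label)
  expect_equal(nrow(second$dropped), 0)
})

test_that("constant series are flagged and skipped rather than compared", {
  co <- toy_cohort()
  # family-1 total constant across participants for tooth 18 only
  co$hard_ml_18 <- 0.8 - co$pulp_ml_18 - co$predentine_ml_18
  filt <- redundancy_filter(co, teeth = 18L)
  expect_true("1" %in% filt$flagged)
  expect_true(all(is.na(filt$correlation["1", ])))
})

test_that("small-ratio cohorts reproduce the three published removals", {
  # push pulp + predentine well below total: overlap of the odds family
  # with the share family tightens
  cfg <- generator_config(n_participants = 150, intercept_f = -2.4,
                          intercept_m = -2.3, seed = 17)
  co <- generate_cohort(cfg)
  s2a <- outcome_series(co, "2a", 18L)$y
  s3a <- outcome_series(co, "3a", 18L)$y
  expect_gt(abs(cor(s2a, s3a)), 0.999)
  filt <- redundancy_filter(co)
  expect_equal(sort(filt$dropped$label), c("2a", "2b", "2c"))
})
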