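# synthetic cohort generation, stage bookkeeping, and control matching

test_that("cohort generator handles empty input and is seed-deterministic", {
  empty <- simulate_cohort(c(control = 0, `1` = 0), seed = 1)
  expect_equal(nrow(empty), 0L)

  a <- simulate_cohort(seed = 42)
  b <- simulate_cohort(seed = 42)
  expect_identical(a, b)
  c2 <- simulate_cohort(seed = 43)
  expect_false(identical(a, c2))

  expect_error(simulate_cohort(c(control = -1)), "nonnegative")
  expect_error(simulate_cohort(c(control = 5, bogus = 2)), "unknown group")

  # invariants: controls unstage; ranges respected
  expect_true(all(is.na(a$hy_stage[a$group == "control"])))
  expect_true(all(a$age > 0))
  expect_true(all(a$icv > 0))
  expect_true(all(a$moca >= 0 & a$moca <= 30, na.rm = TRUE))
})

test_that("clinical scores follow the monotone stage gradient", {
  big <- simulate_cohort(c(`1` = 500, `2` = 500, `3` = 500, `4` = 250,
                           `5` = 250),
                         n_cohorts = 5, seed = 9)
  g <- group_stages(big$hy_stage, "HY45")
  moca_means <- tapply(big$moca, g, mean, na.rm = TRUE)
  dur_means <- tapply(big$time_since_diagnosis, g, mean, na.rm = TRUE)
  up3_means <- tapply(big$updrs3, g, mean, na.rm = TRUE)
  ord <- c("HY1", "HY2", "HY3", "HY45")
  expect_true(all(diff(moca_means[ord]) < 0))   # cognition declines
  expect_true(all(diff(dur_means[ord]) > 0))    # duration lengthens
  expect_true(all(diff(up3_means[ord]) > 0))    # motor score worsens
})

test_that("modified stages regroup and merge per scheme", {
  expect_equal(regroup_stage(c(1, 1.5, 2, 2.5, 3, 4, 5)),
               c(1, 2, 2, 2, 3, 4, 5))
  expect_error(regroup_stage(3.5), "invalid")

  expect_equal(group_stages(c(1, 1.5, 3, 4, 5), "HY45"),
               c("HY1", "HY2", "HY3", "HY45", "HY45"))
  expect_equal(group_stages(c(1, 2.5, 3, 4, 5), "HY345"),
               c("HY1", "HY2", "HY345", "HY345", "HY345"))
  expect_equal(group_stages(1, "HY45"), "HY1")
  expect_equal(group_stages(1, "HY345"), "HY1")
  expect_equal(group_stages(NA, "HY45"), NA_character_)
})

test_that("matching selects the identical-covariate control and respects ratio order", {
  mk <- function(age, sex) data.frame(subject_id = paste0("s", seq_along(age)),
                                      age = age, sex = sex)
  cases <- mk(60, 1)
  controls <- mk(c(60, 70, 50), c(1, 1, 1))
  sel <- match_controls(cases, controls, covariates = "age", exact = "sex")
  expect_equal(sel$age, 60)

  # ratio 2 with one case: the two nearest controls by age
  controls5 <- mk(c(61, 75, 59, 80, 66), rep(1, 5))
  sel2 <- match_controls(cases, controls5, covariates = "age",
                         exact = "sex", ratio = 2)
  expect_setequal(sel2$age, c(61, 59))

  # cross-sex controls are never selected under exact sex matching
  mixed <- mk(c(60, 60), c(0, 1))
  sel3 <- match_controls(cases, mixed, covariates = "age", exact = "sex")
  expect_equal(sel3$sex, 1)
})

test_that("small-instance greedy matching agrees with exhaustive minimum-cost assignment", {
  # instance chosen so that hardest-first greedy attains the optimum
  cases <- data.frame(subject_id = c("c1", "c2"), age = c(50, 80),
                      sex = c(1, 1))
  controls <- data.frame(subject_id = paste0("k", 1:3),
                         age = c(49, 60, 78), sex = c(1, 1, 1))
  sel <- match_controls(cases, controls, covariates = "age", exact = "sex")
  # exhaustive oracle over all one-to-one assignments
  allv <- c(cases$age, controls$age)
  z <- (allv - mean(allv)) / sd(allv)
  zc <- z[1:2]; zk <- z[3:5]
  combs <- expand.grid(a = 1:3, b = 1:3)
  combs <- combs[combs$a != combs$b, ]
  cost <- abs(zc[1] - zk[combs$a]) + abs(zc[2] - zk[combs$b])
  best <- combs[which.min(cost), ]
  expect_setequal(sel$subject_id,
                  controls$subject_id[c(best$a, best$b)])
})

test_that("matching shrinks the case-control age gap on age-shifted pools", {
  set.seed(3)
  cases <- data.frame(subject_id = paste0("c", 1:40),
                      age = rnorm(40, 70, 5), sex = rbinom(40, 1, 0.5))
  controls <- data.frame(subject_id = paste0("k", 1:200),
                         age = rnorm(200, 58, 10),
                         sex = rbinom(200, 1, 0.5))
  sel <- match_controls(cases, controls, covariates = "age", exact = "sex",
                        ratio = 1)
  gap_matched <- abs(mean(sel$age) - mean(cases$age))
  gap_pool <- abs(mean(controls$age) - mean(cases$age))
  expect_lt(gap_matched, gap_pool)
  expect_error(match_controls(cases, controls[0, ], covariates = "age"),
               "empty control pool")
})
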