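test_that("baseline accuracy is the modal level share", {
  expect_equal(baseline_accuracy(rep(3, 10)), 1)
  expect_equal(baseline_accuracy(rep(1:5, 4)), 0.2)
  expect_equal(baseline_accuracy(c(1, 1, 2)), 2 / 3)
  expect_error(baseline_accuracy(integer(0)), "empty")
})

test_that("crude accuracy and its bootstrap interval behave at the extremes", {
  a <- crude_accuracy(1:10, 1:10, B = 300, seed = 1)
  expect_equal(a$accuracy, 1)
  expect_equal(c(a$ci_low, a$ci_high), c(1, 1))
  b <- crude_accuracy(rep(1, 10), rep(2, 10), B = 300, seed = 1)
  expect_equal(b$accuracy, 0)
  h <- crude_accuracy(c(rep(1, 50), rep(2, 50)), rep(1, 100), B = 500,
                      seed = 2)
  expect_equal(h$accuracy, 0.5)
  expect_lt(h$ci_low, 0.5)
  expect_gt(h$ci_high, 0.5)
  expect_error(crude_accuracy(1:3, 1:4), "equal length")
})

test_that("profiles assemble from aligned domain predictions", {
  expect_equal(assemble_profiles(list(1, 1, 1, 1, 1)), "11111")
  expect_equal(assemble_profiles(list(5, 5, 5, 5, 5)), "55555")
  expect_equal(assemble_profiles(list(1, 2, 3, 4, 5)), "12345")
  expect_equal(assemble_profiles(list(c(1, 2), c(1, 2), c(1, 2), c(1, 2),
                                      c(1, 2))), c("11111", "22222"))
  expect_error(assemble_profiles(list(1, 1, 1, 1, c(1, 2))), "misaligned")
})

test_that("utility errors reduce to hand arithmetic on fixed fixtures", {
  vs <- toy_value_set("additive")
  prof <- c("11111", "21111", "31111", "41111")
  same <- utility_errors(prof, prof, vs, boot_B = 200, seed = 1)
  expect_equal(same$mae, 0)
  expect_equal(same$mse, 0)
  expect_equal(same$mae_ci, c(0, 0))
  # errors 0.1 and 0.3 by construction under uniform decrements
  path <- write_additive_vs(uniform_decrements(0.1))
  u <- read_value_set(path, "additive")
  rep2 <- utility_errors(c("11111", "11114"), c("21111", "11111"), u,
                         boot_B = 200, seed = 1)
  expect_equal(rep2$mae, 0.2)
  expect_equal(rep2$mse, mean(c(0.01, 0.09)))
  expect_error(utility_errors(character(0), character(0), u), "empty")
})

test_that("MAE and MSE are invariant to a constant utility shift", {
  base <- uniform_decrements(0.08)
  vs1 <- read_value_set(write_additive_vs(base, constant = 1), "additive")
  vs2 <- read_value_set(write_additive_vs(base, constant = 1.5), "additive")
  set.seed(5)
  act <- profile_code(matrix(sample(1:5, 200 * 5, replace = TRUE), 200))
  prd <- profile_code(matrix(sample(1:5, 200 * 5, replace = TRUE), 200))
  r1 <- utility_errors(act, prd, vs1, boot_B = 200, seed = 3)
  r2 <- utility_errors(act, prd, vs2, boot_B = 200, seed = 3)
  expect_equal(r1$mae, r2$mae)
  expect_equal(r1$mse, r2$mse)
})

test_that("bootstrap intervals are seeded and contain the point estimate", {
  set.seed(6)
  act <- profile_code(matrix(sample(1:5, 150 * 5, replace = TRUE), 150))
  prd <- profile_code(matrix(sample(1:5, 150 * 5, replace = TRUE), 150))
  vs <- toy_value_set("additive")
  r <- utility_errors(act, prd, vs, boot_B = 200, seed = 11)
  expect_lte(r$mae_ci[1], r$mae)
  expect_gte(r$mae_ci[2], r$mae)
  expect_lte(r$mse_ci[1], r$mse)
  expect_gte(r$mse_ci[2], r$mse)
  r2 <- utility_errors(act, prd, vs, boot_B = 200, seed = 11)
  expect_identical(r$mae_ci, r2$mae_ci)
  # median split covers both strata
  expect_equal(r$n_above + r$n_below, 150L)
})

test_that("value-set summaries aggregate like the printed bottom rows", {
  vs <- toy_value_set("additive")
  set.seed(7)
  act <- profile_code(matrix(sample(1:5, 100 * 5, replace = TRUE), 100))
  prd <- profile_code(matrix(sample(1:5, 100 * 5, replace = TRUE), 100))
  r1 <- utility_errors(act, prd, vs, boot_B = 100, seed = 1)
  one <- multi_valueset_summary(list(r1))
  s1 <- attr(one, "summary")
  expect_equal(s1$mae[s1$statistic == "mean"],
               s1$mae[s1$statistic == "min"])
  expect_equal(s1$mae[s1$statistic == "sd"], 0)
  r2 <- utility_errors(act, prd, toy_value_set("lookup"), boot_B = 100,
                       seed = 1)
  two <- attr(multi_valueset_summary(list(r1, r2)), "summary")
  expect_equal(two$mae[two$statistic == "mean"], mean(c(r1$mae, r2$mae)))
  expect_equal(two$mse[two$statistic == "max"], max(c(r1$mse, r2$mse)))
  expect_error(multi_valueset_summary(list()), "at least one")
})

test_that("conceptual overlap recovers exact and null relationships", {
  co <- calibrated_cohort(1000L)
  total <- oks_total(co$oks_items)
  exact <- conceptual_overlap(co$oks_items, co$eq_levels,
                              0.02 * total - 0.3)
  expect_equal(exact$ols$r_squared, 1)
  expect_equal(exact$ols$slope, 0.02)
  expect_true(all(exact$correlations < 0))
  # independent noise: correlations concentrate near zero
  set.seed(8)
  Xn <- matrix(sample(0:4, 1000 * 12, replace = TRUE), 1000, 12,
               dimnames = list(NULL, sprintf("oks_q%02d", 1:12)))
  En <- matrix(sample(1:5, 1000 * 5, replace = TRUE), 1000, 5,
               dimnames = list(NULL, paste0("eq_", c("mo", "sc", "ua",
                                                     "pd", "ad"))))
  null <- conceptual_overlap(Xn, En, rnorm(1000))
  expect_lt(max(abs(null$correlations)), 0.12)
  # constant columns are flagged, not fatal
  Xc <- Xn
  Xc[, 3] <- 2L
  flagged <- conceptual_overlap(Xc, En, rnorm(1000))
  expect_true("oks_q03" %in% flagged$constant_columns)
})
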