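test_that("the full grid enumerates 133 structures and 532 trials", {
  g <- enumerate_grid(seed = 1)
  fams <- vapply(g$structures, `[[`, character(1), "family")
  expect_equal(sum(fams == "cumulative"), 10L)
  expect_equal(sum(fams == "penalized"), 16L)
  expect_equal(sum(fams == "ocart"), 80L)
  expect_equal(sum(fams == "oforest"), 27L)
  expect_length(g$structures, 133L)
  expect_equal(nrow(g$trials), 532L)
  # cp values: 20 random draws inside the documented range, seed-stable
  cps <- vapply(Filter(function(s) s$family == "ocart", g$structures),
                `[[`, numeric(1), "cp")
  expect_length(unique(cps), 20L)
  expect_true(all(cps >= 1e-4 & cps <= 1e-1))
  g2 <- enumerate_grid(seed = 1)
  expect_identical(g$structures, g2$structures)
})

test_that("the reduced grid shrinks cp and forest cells as documented", {
  g <- enumerate_grid(seed = 1, options = grid_options(reduced = TRUE))
  fams <- vapply(g$structures, `[[`, character(1), "family")
  expect_equal(sum(fams == "ocart"), 20L)   # 5 cp x 2 x 2
  expect_equal(sum(fams == "oforest"), 27L) # halved sizes, same cells
  expect_length(g$structures, 73L)
  nts <- vapply(Filter(function(s) s$family == "oforest", g$structures),
                `[[`, numeric(1), "ntreefinal")
  expect_setequal(unique(nts), c(100, 200, 300))
})

test_that("cross-validation bookkeeping matches its definition", {
  co <- calibrated_cohort(456L)
  y <- co$eq_levels[, "eq_pd"]
  st <- list(family = "ocart", cp = 0.02, split_cost = "absolute",
             prune_rule = "misclassification_rate")
  res <- cross_validate(st, all_items_set(), co$oks_items, y,
                        folds = 5, repeats = 3, seed = 9)
  expect_equal(res$n_folds, 15L)
  expect_length(res$fold_accuracies[[1]], 15L)
  expect_equal(res$cv_accuracy_mean, mean(res$fold_accuracies[[1]]),
               tolerance = 1e-12)
  expect_equal(res$cv_cv, res$cv_accuracy_sd / res$cv_accuracy_mean)
  res2 <- cross_validate(st, all_items_set(), co$oks_items, y,
                         folds = 5, repeats = 3, seed = 9)
  expect_equal(res$fold_accuracies, res2$fold_accuracies)
})

test_that("a modal-level model cross-validates at the baseline accuracy", {
  co <- calibrated_cohort(456L)
  y <- co$eq_levels[, "eq_mo"]
  trivial <- list(family = "ocart", cp = 2, split_cost = "absolute",
                  prune_rule = "misclassification_rate")
  res <- cross_validate(trivial, all_items_set(), co$oks_items, y,
                        folds = 5, repeats = 3, seed = 10)
  expect_equal(res$cv_accuracy_mean, baseline_accuracy(y),
               tolerance = 0.02)
})

test_that("selection takes the accuracy argmax with documented tie-breaks", {
  co <- calibrated_cohort(200L)
  y <- co$eq_levels[, "eq_mo"]
  sets <- list(all = all_items_set())
  structures <- list(
    list(family = "ocart", cp = 2, split_cost = "absolute",
         prune_rule = "misclassification_rate", structure_id = 1L),
    list(family = "cumulative", parallel = TRUE, link = "logit",
         structure_id = 2L))
  grid <- list(structures = structures,
               trials = data.frame(structure_id = 1:2,
                                   predictor_set = "all",
                                   stringsAsFactors = FALSE))
  fake <- data.frame(structure_id = 1:2,
                     label = c("a", "b"), family = c("ocart", "cumulative"),
                     predictor_set = "all",
                     cv_accuracy_mean = c(0.60, 0.65),
                     cv_accuracy_sd = 0.01, cv_cv = 0.02,
                     n_folds = 15L, note = "", merged_folds = FALSE,
                     stringsAsFactors = FALSE)
  sel <- select_and_refit(fake, grid, sets, co$oks_items, y, seed = 1)
  expect_equal(sel$winner$cv_accuracy_mean, 0.65)
  # exact tie: simpler family (cumulative) wins
  fake$cv_accuracy_mean <- c(0.65, 0.65)
  sel2 <- select_and_refit(fake, grid, sets, co$oks_items, y, seed = 1)
  expect_equal(sel2$winner$family, "cumulative")
  # all trials flagged: hard error
  fake$note <- "fit_error"
  expect_error(select_and_refit(fake, grid, sets, co$oks_items, y),
               "no trial converged")
})

test_that("a small tournament returns a refitted winner beating the baseline", {
  co <- calibrated_cohort(250L)
  X <- co$oks_items
  y <- co$eq_levels[, "eq_ua"]
  grid <- enumerate_grid(seed = 2, options = grid_options(
    cp_n = 2, oforest_nsets = 5L, oforest_ntreeperdiv = 20L,
    oforest_ntreefinal = 50L))
  keep <- vapply(grid$structures, function(s)
    s$family %in% c("cumulative", "ocart", "oforest") &&
      (s$family != "cumulative" || s$parallel), logical(1))
  grid$structures <- grid$structures[keep]
  for (i in seq_along(grid$structures)) {
    grid$structures[[i]]$structure_id <- i
  }
  grid$trials <- expand.grid(structure_id = seq_along(grid$structures),
                             predictor_set = c("all", "pca"),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  sets <- list(all = all_items_set(), pca = pca_preprocess(X))
  res <- run_tournament(X, y, grid, sets, folds = 3, repeats = 1, seed = 6)
  expect_equal(nrow(res), nrow(grid$trials))
  sel <- select_and_refit(res, grid, sets, X, y, seed = 6)
  expect_gte(sel$winner$cv_accuracy_mean, baseline_accuracy(y) - 0.02)
  # refitted training accuracy within the sanity band of its CV accuracy
  Xw <- apply_predictor_set(sel$predictor_set, X)
  train_acc <- mean(predict_levels(sel$fit, Xw) == y)
  expect_gte(train_acc, sel$winner$cv_accuracy_mean - 0.05)
})
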