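test_that("a 2-level parallel logit fit coincides with binary logistic regression", {
  set.seed(12)
  n <- 500
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- as.integer(drop(X %*% c(1, -0.5, 0.8)) + rlogis(n) > 0) + 1L
  fit <- fit_cumulative(X, y, parallel = TRUE, link = "logit")
  oracle <- glm(I(y == 2) ~ X, family = binomial())
  expect_lt(max(abs(fit$beta - coef(oracle)[-1])), 1e-4)
  expect_lt(abs(fit$theta[1] - (-coef(oracle)[1])), 1e-4)
})

test_that("parallel fits agree with an independent cumulative-link fitter", {
  skip_if_not_installed("MASS")
  d <- make_ordinal_data(n = 400, seed = 7)
  mine <- fit_cumulative(d$X, d$y, parallel = TRUE, link = "probit")
  ref <- MASS::polr(factor(d$y) ~ d$X, method = "probit")
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_lt(max(abs(mine$beta - coef(ref))), 1e-3)
  # cauchit: score the estimates under a test-local likelihood (the
  # reference fitter's reported cauchit deviance is not consistent with
  # its own parameters under the standard cumulative likelihood)
  mc <- fit_cumulative(d$X, d$y, parallel = TRUE, link = "cauchit")
  rc <- MASS::polr(factor(d$y) ~ d$X, method = "cauchit")
  ll_at <- function(theta, beta) {
    gam <- cbind(pcauchy(outer(-drop(d$X %*% beta), theta, "+")), 1)
    pk <- gam[cbind(seq_along(d$y), d$y)] -
      cbind(0, gam)[cbind(seq_along(d$y), d$y)]
    sum(log(pk))
  }
  expect_equal(mc$logLik, ll_at(mc$theta, mc$beta), tolerance = 1e-8)
  expect_gte(mc$logLik, ll_at(rc$zeta, coef(rc)) - 1e-8)
  expect_lt(max(abs(mc$beta - coef(rc))), 0.05)
})

test_that("parallel probit/logit models recover generating parameters at n = 5000", {
  skip_if_not_installed("MASS")
  for (lk in c("probit", "logit")) {
    d <- make_ordinal_data(n = 5000, p = 3, K = 4,
                           seed = if (lk == "probit") 101 else 202,
                           link = lk)
    fit <- fit_cumulative(d$X, d$y, parallel = TRUE, link = lk)
    ref <- MASS::polr(factor(d$y) ~ d$X,
                      method = if (lk == "logit") "logistic" else lk,
                      Hess = TRUE)
    se <- sqrt(diag(vcov(ref)))
    est <- c(fit$beta, fit$theta)
    truth <- c(d$beta, d$thresholds)
    expect_true(all(abs(est - truth) < 3 * se),
                info = paste(lk, paste(round(abs(est - truth) / se, 2),
                                       collapse = " ")))
  }
})

test_that("predicted probabilities are simplex-valid and cumulative in k", {
  d <- make_ordinal_data(n = 250, seed = 5)
  for (lk in ordinal_links()) {
    for (par in c(TRUE, FALSE)) {
      fit <- fit_cumulative(d$X, d$y, parallel = par, link = lk)
      P <- predict(fit, d$X, type = "prob")
      expect_true(all(P >= 0), info = paste(lk, par))
      expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-8)
      gam <- t(apply(P, 1, cumsum))
      expect_true(all(diff(t(gam)) >= -1e-8), info = paste(lk, par))
      expect_true(all(predict_levels(fit, d$X) %in% sort(unique(d$y))))
    }
  }
})

test_that("the likelihood optimum matches a brute-force optimizer on a 30-row fixture", {
  set.seed(30)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- findInterval(drop(X %*% c(1, -1)) + rlogis(n), c(-0.5, 0.8)) + 1L
  K <- 3L
  fit <- fit_cumulative(X, y, parallel = TRUE, link = "logit")
  par0 <- c(-0.5, 0.8, 0, 0)
  bf <- optim(par0, oracle_nll_parallel_logit, X = X, y = y, K = K,
              method = "Nelder-Mead",
              control = list(maxit = 20000, reltol = 1e-14))
  bf <- optim(bf$par, oracle_nll_parallel_logit, X = X, y = y, K = K,
              method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$logLik, -bf$value, tolerance = 1e-6)
})

test_that("single-level outcomes are rejected, degenerate slopes predict the mode", {
  d <- make_ordinal_data(n = 100, seed = 3)
  expect_error(fit_cumulative(d$X, rep(2L, 100)), "single level")
  # independent outcome: slopes ~ 0, prediction = marginal modal level
  set.seed(4)
  y_noise <- sample(1:3, 200, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  X <- matrix(rnorm(400), 200, 2)
  fit <- fit_cumulative(X, y_noise, parallel = TRUE, link = "logit")
  modal <- as.integer(names(which.max(table(y_noise))))
  expect_true(mean(predict_levels(fit, X) == modal) > 0.95)
})

test_that("the penalty path touches the unpenalized optimum as lambda -> 0", {
  d <- make_ordinal_data(n = 400, seed = 21)
  free <- fit_cumulative(d$X, d$y, parallel = TRUE, link = "logit")
  pen <- fit_penalized(d$X, d$y, alpha = "lasso", criterion = "AIC",
                       link = "logit", nlambda = 30,
                       lambda_min_ratio = 1e-7)
  # informative predictors: the information criterion selects a tiny
  # penalty, whose slopes match the unpenalized fit
  expect_lt(max(abs(pen$beta - free$beta)), 1e-3)
})

test_that("an overwhelming lasso penalty zeroes every slope", {
  d <- make_ordinal_data(n = 300, seed = 22)
  po <- oksmap:::penalized_path(d$X, d$y, alpha = "lasso", link = "logit",
                                nlambda = 3, lambda_min_ratio = 0.9)
  top <- po$path[[1]]  # lambda_max: all slopes shrunk away
  expect_true(all(top$par[-(1:3)] == 0))
  # and the resulting predictions are the marginal modal level
  fit <- oksmap:::penalized_select(po, "AIC")
  if (all(fit$beta == 0)) {
    modal <- as.integer(names(which.max(table(d$y))))
    expect_true(all(predict_levels(fit, d$X) == modal))
  }
})

test_that("lasso at the selected penalty keeps the informative slopes", {
  set.seed(23)
  n <- 2000
  X <- matrix(sample(0:4, n * 12, replace = TRUE), n, 12,
              dimnames = list(NULL, sprintf("q%02d", 1:12)))
  eta <- 0.9 * X[, 3] - 0.8 * X[, 8]
  y <- findInterval(eta + rlogis(n), quantile(eta, c(0.3, 0.7))) + 1L
  for (crit in c("AIC", "BIC")) {
    fit <- fit_penalized(X, y, alpha = "lasso", criterion = crit,
                         link = "logit")
    expect_true(all(c("q03", "q08") %in% fit$nonzero), info = crit)
  }
})

test_that("ridge effective df shrinks along the penalty path", {
  d <- make_ordinal_data(n = 300, seed = 24)
  po <- oksmap:::penalized_path(d$X, d$y, alpha = "ridge", link = "probit",
                                nlambda = 10)
  dfs <- vapply(po$path, `[[`, numeric(1), "df")
  expect_true(all(diff(dfs) >= 0))  # lambda decreasing -> df increasing
  expect_true(all(dfs >= 3 & dfs <= 3 + ncol(d$X)))  # K-1 thresholds + p
})

test_that("generalized Gini impurity equals the brute-force pairwise cost sum", {
  set.seed(31)
  for (rep in 1:10) {
    K <- sample(3:5, 1)
    p <- as.vector(rmultinom(1, 50, runif(K))) / 50
    s <- sort(runif(K))
    for (cost in c("absolute", "quadratic")) {
      bf <- 0
      for (i in seq_len(K)) {
        for (j in seq_len(K)) {
          d <- s[i] - s[j]
          bf <- bf + (if (cost == "absolute") abs(d) else d^2) * p[i] * p[j]
        }
      }
      expect_equal(gini_impurity(p, s, cost), bf, tolerance = 1e-12)
    }
  }
})

test_that("quadratic cost weighs a two-level miss four times an adjacent one", {
  C <- oksmap:::cost_matrix(1:3, "quadratic")
  expect_equal(C[1, 3] / C[1, 2], 4)
  Ca <- oksmap:::cost_matrix(1:3, "absolute")
  expect_equal(Ca[1, 3] / Ca[1, 2], 2)
})

test_that("a prohibitive cp yields the root-only modal tree", {
  set.seed(32)
  X <- matrix(sample(0:4, 456 * 12, replace = TRUE), 456, 12)
  y <- findInterval(0.7 * X[, 2] + rnorm(456), c(1, 2.5)) + 1L
  fit <- fit_ocart(X, y, cp = 2, split_cost = "absolute",
                   prune_rule = "misclassification_rate")
  expect_equal(oksmap:::n_leaves(fit$tree), 1L)
  modal <- as.integer(names(which.max(table(y))))
  pred <- predict(fit, X)
  expect_true(all(pred == modal))
  expect_equal(mean(pred == y), baseline_accuracy(y))
  expect_error(fit_ocart(X, y, cp = -1), "cp")
})

test_that("a perfectly separating predictor gives one split and accuracy 1", {
  X <- matrix(c(rep(0, 60), rep(1, 60)), ncol = 1)
  y <- rep(c(1L, 3L), each = 60)
  fit <- fit_ocart(X, y, cp = 0.01, minsplit = 10, minbucket = 5)
  expect_equal(oksmap:::n_leaves(fit$tree), 2L)
  expect_equal(mean(predict(fit, X) == y), 1)
})

test_that("the root split maximizes brute-force impurity gain on tiny data", {
  set.seed(33)
  x <- sample(0:4, 40, replace = TRUE)
  y <- findInterval(x + rnorm(40, 0, 0.8), c(1.5, 3.2)) + 1L
  if (length(unique(y)) < 2) y[1:5] <- 1:3
  C <- oksmap:::cost_matrix(1:3, "quadratic")
  n <- length(y)
  cand <- sort(unique(x))
  cand <- (cand[-1] + cand[-length(cand)]) / 2
  gains <- vapply(cand, function(ct) {
    l <- y[x <= ct]; r <- y[x > ct]
    n * gini_impurity(tabulate(y, 3), 1:3, "quadratic") -
      length(l) * gini_impurity(tabulate(l, 3), 1:3, "quadratic") -
      length(r) * gini_impurity(tabulate(r, 3), 1:3, "quadratic")
  }, numeric(1))
  best <- oksmap:::best_split(matrix(x, ncol = 1), y, 3L, C, minbucket = 1L)
  expect_equal(best$point, cand[which.max(gains)])
  expect_equal(best$gain_abs, max(gains), tolerance = 1e-10)
})

test_that("ordinal forests are seeded-deterministic and select sensibly", {
  co <- calibrated_cohort(456L)
  X <- co$oks_items
  y <- co$eq_levels[, "eq_sc"]
  f1 <- fit_oforest(X, y, nsets = 20, ntreeperdiv = 25, ntreefinal = 100,
                    seed = 77)
  f2 <- fit_oforest(X, y, nsets = 20, ntreeperdiv = 25, ntreefinal = 100,
                    seed = 77)
  expect_identical(predict(f1, X), predict(f2, X))
  # self-care-like domain: out-of-bag accuracy at least the baseline
  expect_gte(f1$oob_accuracy, baseline_accuracy(y))
  # degenerate selection: one candidate set is used as-is
  f3 <- fit_oforest(X, y, nsets = 1, ntreeperdiv = 25, ntreefinal = 50,
                    seed = 3)
  expect_length(f3$score_perf, 1L)
  expect_equal(f3$scores[c(1, length(f3$scores))], c(0, 1))
  expect_true(all(predict(f3, X) %in% sort(unique(y))))
})

test_that("the batched forest evaluation matches the standalone contract", {
  co <- calibrated_cohort(456L)
  X <- co$oks_items[1:300, ]
  y <- co$eq_levels[1:300, "eq_mo"]
  specs <- list(list(nsets = 5, ntreeperdiv = 25, ntreefinal = 50),
                list(nsets = 10, ntreeperdiv = 50, ntreefinal = 100))
  fits <- oksmap:::oforest_batch_fit(X, y, specs, seed = 4)
  expect_length(fits, 2L)
  for (f in fits) {
    expect_s3_class(f, "oksmap_oforest")
    expect_true(all(predict(f, X) %in% sort(unique(y))))
    expect_equal(f$scores[1], 0)
  }
  expect_length(fits[[1]]$score_perf, 5L)
  expect_length(fits[[2]]$score_perf, 10L)
  # same seed, same grid: deterministic
  fits2 <- oksmap:::oforest_batch_fit(X, y, specs, seed = 4)
  expect_identical(predict(fits[[2]], X), predict(fits2[[2]], X))
})

test_that("prediction rejects schema mismatches by column name", {
  d <- make_ordinal_data(n = 120, seed = 8)
  fit <- fit_cumulative(d$X, d$y)
  bad <- d$X[, 1:2]
  expect_error(predict_levels(fit, bad), "x3")
})
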