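## Penalized cumulative (parallel) regression: ridge (alpha = 0) or lasso
## (alpha = 1) penalty on the slopes, thresholds unpenalized, fitted by
## proximal gradient descent over a decreasing lambda path with warm starts,
## the penalty magnitude selected by AIC or BIC.

# Smooth part of the objective: mean NLL (+ ridge term if alpha = 0).
penalized_smooth <- function(par, X, y, K, link, lambda, ridge) {
  val <- cumulative_nll(par, X, y, K, link, parallel = TRUE) / nrow(X)
  if (ridge) {
    beta <- par[-seq_len(K - 1L)]
    val <- val + lambda / 2 * sum(beta^2)
  }
  val
}

penalized_smooth_grad <- function(par, X, y, K, link, lambda, ridge) {
  g <- cumulative_grad(par, X, y, K, link, parallel = TRUE) / nrow(X)
  if (ridge) {
    idx <- -seq_len(K - 1L)
    g[idx] <- g[idx] + lambda * par[idx]
  }
  g
}

# One FISTA run at fixed lambda with backtracking line search and adaptive
# restart. Soft-thresholding is applied to slope coordinates only (lasso);
# thresholds always take plain gradient steps.
fista_fit <- function(par0, X, y, K, link, lambda, alpha,
                      maxit = 300L, tol = 1e-7, L0 = 1) {
  ridge <- alpha == 0
  slope_idx <- K:length(par0)
  L <- L0
  par <- par0
  z <- par
  tacc <- 1
  penval <- function(p) if (ridge) 0 else lambda * sum(abs(p[slope_idx]))
  f_old <- penalized_smooth(par, X, y, K, link, lambda, ridge) + penval(par)
  for (it in seq_len(maxit)) {
    g <- penalized_smooth_grad(z, X, y, K, link, lambda, ridge)
    fz <- penalized_smooth(z, X, y, K, link, lambda, ridge)
    repeat {
      cand <- z - g / L
      if (!ridge) {  # lasso prox: soft threshold the slopes
        s <- cand[slope_idx]
        cand[slope_idx] <- sign(s) * pmax(abs(s) - lambda / L, 0)
      }
      fc <- penalized_smooth(cand, X, y, K, link, lambda, ridge)
      dd <- cand - z
      if (fc <= fz + sum(g * dd) + L / 2 * sum(dd^2) + 1e-12 || L > 1e8) break
      L <- L * 2
    }
    f_new <- fc + penval(cand)
    if (f_new > f_old) {      # adaptive restart of the momentum
      z <- par
      tacc <- 1
      if (it > 1L) next
    }
    t_new <- (1 + sqrt(1 + 4 * tacc^2)) / 2
    z <- cand + ((tacc - 1) / t_new) * (cand - par)
    par <- cand
    tacc <- t_new
    if (abs(f_old - f_new) < tol * (abs(f_old) + tol)) break
    f_old <- min(f_old, f_new)
  }
  list(par = par, iters = it, L = L)
}

#' Fit a penalized cumulative regression with AIC/BIC penalty selection
#'
#' Fits the parallel cumulative model under a penalty on the slope
#' coefficients -- the sum of squared coefficients for ridge (`alpha =
#' "ridge"`, i.e. \eqn{\alpha = 0}) or of absolute coefficients for lasso
#' (`alpha = "lasso"`, \eqn{\alpha = 1}) -- over a decreasing path of
#' penalty magnitudes, then selects the magnitude minimizing AIC or BIC.
#' Predictors are standardized internally; reported slopes are on the
#' original scale. Model degrees of freedom count the unpenalized thresholds
#' plus, for lasso, the nonzero slopes, and for ridge, the standard ridge
#' effective-df trace computed on the standardized design.
#'
#' @inheritParams fit_cumulative
#' @param alpha `"ridge"` or `"lasso"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param link one of logit, probit, cauchit, cloglog (logc is only admitted
#'   for the plain cumulative family).
#' @param nlambda,lambda_min_ratio path geometry.
#' @return object of class `oksmap_penalized` (also `oksmap_fit`) with the
#'   selected penalty magnitude, slope path summary and criterion values.
#' @export
fit_penalized <- function(X, y, alpha = c("ridge", "lasso"),
                          criterion = c("AIC", "BIC"), link = "logit",
                          nlambda = 20L, lambda_min_ratio = 1e-3) {
  criterion <- match.arg(criterion)
  po <- penalized_path(X, y, alpha = alpha, link = link, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio)
  penalized_select(po, criterion)
}

# Fit the whole penalty path once (shared by the AIC and BIC selections).
penalized_path <- function(X, y, alpha = c("ridge", "lasso"),
                           link = "logit", nlambda = 20L,
                           lambda_min_ratio = 1e-3) {
  alpha <- match.arg(alpha)
  link <- match.arg(link, c("logit", "probit", "cauchit", "cloglog"))
  X <- as.matrix(X)
  prep <- encode_outcome(y)
  y_idx <- prep$idx; K <- prep$K
  if (K < 2L) stop("outcome has a single level; nothing to model",
                   call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  theta0 <- start_thresholds(y_idx, K, link)
  par <- c(theta0, numeric(p))
  # lambda_max: smallest lambda with all-zero lasso slopes = max |score| at
  # the null model (thresholds refitted, slopes zero); reused for ridge.
  null_fit <- stats::optim(theta0, function(th)
    cumulative_nll(c(th, numeric(p)), Xs, y_idx, K, link, TRUE),
    method = "BFGS")
  par[seq_len(K - 1L)] <- null_fit$par
  g0 <- cumulative_grad(par, Xs, y_idx, K, link, TRUE) / n
  lambda_max <- max(abs(g0[-seq_len(K - 1L)])) * 1.05 + 1e-8
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = nlambda))

  d2 <- svd(Xs, nu = 0, nv = 0)$d^2  # for ridge effective df
  path <- vector("list", nlambda)
  L_carry <- 1
  for (i in seq_len(nlambda)) {
    res <- fista_fit(par, Xs, y_idx, K, link, lambdas[i],
                     alpha = if (alpha == "ridge") 0 else 1, L0 = L_carry)
    par <- res$par
    L_carry <- max(res$L / 2, 1e-2)  # warm Lipschitz estimate
    beta_s <- par[-seq_len(K - 1L)]
    nll <- cumulative_nll(par, Xs, y_idx, K, link, TRUE)
    df <- if (alpha == "lasso") (K - 1L) + sum(beta_s != 0) else
      (K - 1L) + sum(d2 / (d2 + n * lambdas[i]))
    path[[i]] <- list(lambda = lambdas[i], par = par, nll = nll, df = df)
  }
  list(path = path, lambdas = lambdas, alpha = alpha, link = link,
       K = K, n = n, p = p, ctr = ctr, scl = scl, levels = prep$levels,
       xnames = colnames(X))
}

# Select the path point minimizing AIC or BIC and package the fit.
penalized_select <- function(po, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  K <- po$K; n <- po$n
  crit_vals <- vapply(po$path, function(pt)
    2 * pt$nll + (if (criterion == "AIC") 2 else log(n)) * pt$df,
    numeric(1))
  best <- po$path[[which.min(crit_vals)]]
  theta_s <- best$par[seq_len(K - 1L)]
  beta_s <- best$par[-seq_len(K - 1L)]
  beta <- beta_s / po$scl
  theta <- theta_s + sum(beta * po$ctr)  # undo centering on original scale
  names(beta) <- po$xnames

  structure(list(family = "penalized", parallel = TRUE, link = po$link,
                 alpha = po$alpha, criterion = criterion,
                 theta = theta, beta = beta, lambda = best$lambda,
                 lambda_path = po$lambdas, criterion_path = crit_vals,
                 df = best$df, logLik = -best$nll,
                 nonzero = names(beta)[beta != 0],
                 levels = po$levels, converged = TRUE,
                 crossing_detected = FALSE, n = n, p = po$p,
                 xnames = po$xnames),
            class = c("oksmap_penalized", "oksmap_cumulative", "oksmap_fit"))
}
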