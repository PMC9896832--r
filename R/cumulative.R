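## Cumulative link (ordinal) models, parallel and non-parallel, fitted by
## maximum likelihood with analytic gradients. The parallel model with a
## logit link is the proportional-odds model; the non-parallel variant
## allows per-threshold slopes, in which case fitted cumulative curves can
## cross -- category probabilities are clipped at a small epsilon inside the
## likelihood and a `crossing_detected` flag is reported.

.prob_eps <- 1e-10

# Internal: build the n x K matrix of category probabilities.
# theta: K-1 thresholds; beta: p vector (parallel) or (K-1) x p matrix.
cumulative_probs <- function(X, theta, beta, link, parallel) {
  n <- nrow(X)
  K <- length(theta) + 1L
  if (parallel) {
    eta <- drop(X %*% beta)
    Z <- outer(eta, theta, function(e, t) t - e)  # n x (K-1)
  } else {
    Z <- vapply(seq_len(K - 1L),
                function(k) theta[k] - drop(X %*% beta[k, ]),
                numeric(n))
    Z <- matrix(Z, nrow = n)
  }
  G <- matrix(link_inverse(link, Z), nrow = n)
  Gam <- cbind(G, 1)  # n x K cumulative probabilities, top fixed at 1
  P <- Gam - cbind(0, Gam[, -K, drop = FALSE])
  list(P = P, Gam = Gam, Z = Z)
}

cumulative_nll <- function(par, X, y, K, link, parallel) {
  p <- ncol(X)
  theta <- par[seq_len(K - 1L)]
  beta <- if (parallel) par[K - 1L + seq_len(p)] else
    matrix(par[-seq_len(K - 1L)], nrow = K - 1L, byrow = TRUE)
  pr <- cumulative_probs(X, theta, beta, link, parallel)
  pk <- pr$P[cbind(seq_along(y), y)]
  -sum(log(pmax(pk, .prob_eps)))
}

cumulative_grad <- function(par, X, y, K, link, parallel) {
  n <- nrow(X); p <- ncol(X)
  theta <- par[seq_len(K - 1L)]
  beta <- if (parallel) par[K - 1L + seq_len(p)] else
    matrix(par[-seq_len(K - 1L)], nrow = K - 1L, byrow = TRUE)
  pr <- cumulative_probs(X, theta, beta, link, parallel)
  pk <- pmax(pr$P[cbind(seq_len(n), y)], .prob_eps)
  live <- pr$P[cbind(seq_len(n), y)] > .prob_eps  # zero gradient where clipped
  g <- matrix(link_density(link, pr$Z), nrow = n)  # n x (K-1)
  w <- ifelse(live, 1 / pk, 0)
  # d pk / d gamma_k = [k == y] - [k == y-1]
  gtheta <- numeric(K - 1L)
  if (parallel) gbeta <- numeric(p) else gbeta <- matrix(0, K - 1L, p)
  for (k in seq_len(K - 1L)) {
    dk <- (y == k) - (y == k + 1L)       # d pk_i / d gamma_ik
    common <- -w * dk * g[, k]           # d NLL / d z_ik, z = theta_k - eta_k
    gtheta[k] <- sum(common)
    contrib <- -common                   # d z / d beta = -x
    if (parallel) {
      gbeta <- gbeta + drop(crossprod(X, contrib))
    } else {
      gbeta[k, ] <- drop(crossprod(X, contrib))
    }
  }
  if (parallel) c(gtheta, gbeta) else c(gtheta, as.vector(t(gbeta)))
}

# Starting thresholds from marginal cumulative frequencies through the link.
start_thresholds <- function(y, K, link) {
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
  cum <- pmin(pmax(cum, 0.02), 0.98)
  cum <- cummax(cum + seq_len(K - 1L) * 1e-6)
  link_forward(link, cum)
}

#' Fit a cumulative link ordinal model
#'
#' Models the cumulative probability of being at or below each outcome level
#' through one of five link functions, assuming the ordered ratings arise
#' from categorizing a latent continuous variable. With `parallel = TRUE`
#' one slope vector is shared across thresholds; with `parallel = FALSE`
#' each threshold gets its own slopes and fitted cumulative curves are kept
#' usable by clipping negative category probabilities inside the likelihood
#' (reported through `crossing_detected`).
#'
#' @param X numeric predictor matrix (no intercept column).
#' @param y ordinal outcome: integer or factor; at least two levels present.
#' @param parallel share slopes across thresholds?
#' @param link one of [ordinal_links()].
#' @param maxit,reltol optimizer control.
#' @param starts number of jittered restarts tried on non-convergence.
#' @return object of class `oksmap_cumulative` (also `oksmap_fit`) with
#'   thresholds, slopes, log-likelihood, convergence and crossing flags.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 100, 2)
#' y <- cut(X %*% c(1, -1) + rnorm(100), c(-Inf, -1, 1, Inf), labels = FALSE)
#' fit <- fit_cumulative(X, y, parallel = TRUE, link = "logit")
#' table(predict_levels(fit, X), y)
#' @export
fit_cumulative <- function(X, y, parallel = TRUE, link = "logit",
                           maxit = 300L, reltol = 1e-10, starts = 3L) {
  link <- match.arg(link, ordinal_links())
  X <- as.matrix(X)
  prep <- encode_outcome(y)
  y_idx <- prep$idx; K <- prep$K
  if (K < 2L) stop("outcome has a single level; nothing to model",
                   call. = FALSE)
  stopifnot(all(is.finite(X)), nrow(X) == length(y_idx))
  p <- ncol(X)
  theta0 <- start_thresholds(y_idx, K, link)
  par0 <- if (parallel) c(theta0, numeric(p)) else
    c(theta0, numeric((K - 1L) * p))

  best <- NULL
  for (s in seq_len(starts)) {
    par_try <- if (s == 1L) par0 else par0 + stats::rnorm(length(par0), sd = 0.2)
    opt <- try(stats::optim(par_try, cumulative_nll, gr = cumulative_grad,
                            X = X, y = y_idx, K = K, link = link,
                            parallel = parallel, method = "BFGS",
                            control = list(maxit = maxit, reltol = reltol)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0L) break
  }
  if (is.null(best)) stop("cumulative model failed to optimize", call. = FALSE)

  theta <- best$par[seq_len(K - 1L)]
  beta <- if (parallel) best$par[K - 1L + seq_len(p)] else
    matrix(best$par[-seq_len(K - 1L)], nrow = K - 1L, byrow = TRUE)
  if (parallel) names(beta) <- colnames(X) else colnames(beta) <- colnames(X)
  pr <- cumulative_probs(X, theta, beta, link, parallel)
  crossing <- !parallel && any(pr$P < -1e-8)

  structure(list(family = "cumulative", parallel = parallel, link = link,
                 theta = theta, beta = beta, levels = prep$levels,
                 logLik = -best$value, converged = best$convergence == 0L,
                 crossing_detected = crossing, n = nrow(X), p = p,
                 xnames = colnames(X)),
            class = c("oksmap_cumulative", "oksmap_fit"))
}

# Map an outcome vector to consecutive indices 1..K, remembering labels.
encode_outcome <- function(y) {
  if (is.factor(y)) {
    levels_present <- levels(droplevels(y))
    idx <- as.integer(droplevels(y))
  } else {
    levels_present <- sort(unique(y))
    idx <- match(y, levels_present)
  }
  list(idx = idx, K = length(levels_present), levels = levels_present)
}

decode_levels <- function(idx, levels) {
  if (is.character(levels)) factor(levels[idx], levels = levels)
  else levels[idx]
}

#' Predicted category probabilities / levels for fitted ordinal models
#'
#' @param object a fitted model from [fit_cumulative()], [fit_penalized()],
#'   [fit_ocart()] or [fit_oforest()].
#' @param X predictor matrix with the columns the model was fitted with.
#' @param type `"class"` for levels, `"prob"` for per-level probabilities
#'   (probabilistic families only).
#' @param ... unused.
#' @return level predictions (ties broken toward the lower, healthier level)
#'   or an n x K probability matrix.
#' @export
predict.oksmap_cumulative <- function(object, X, type = c("class", "prob"),
                                      ...) {
  type <- match.arg(type)
  X <- check_newdata(object, X)
  pr <- cumulative_probs(X, object$theta, object$beta, object$link,
                         object$parallel)
  P <- pmax(pr$P, 0)
  P <- P / rowSums(P)
  colnames(P) <- as.character(object$levels)
  if (type == "prob") return(P)
  decode_levels(max.col(P, ties.method = "first"), object$levels)
}

check_newdata <- function(object, X) {
  X <- as.matrix(X)
  if (!is.null(object$xnames)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(object$xnames)) {
        stop("newdata has ", ncol(X), " columns; model needs ",
             length(object$xnames), call. = FALSE)
      }
      colnames(X) <- object$xnames
    } else {
      miss <- setdiff(object$xnames, colnames(X))
      if (length(miss)) {
        stop("newdata is missing columns: ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      X <- X[, object$xnames, drop = FALSE]
    }
  }
  X
}

#' @rdname predict.oksmap_cumulative
#' @param model a fitted ordinal model.
#' @export
predict_levels <- function(model, X) {
  stats::predict(model, X, type = "class")
}

#' @export
print.oksmap_fit <- function(x, ...) {
  extra <- switch(x$family,
    cumulative = sprintf("link=%s parallel=%s", x$link, x$parallel),
    penalized = sprintf("link=%s alpha=%s criterion=%s lambda=%.4g",
                        x$link, x$alpha, x$criterion, x$lambda),
    ocart = sprintf("cp=%.4g split=%s prune=%s leaves=%d", x$cp,
                    x$split_cost, x$prune_rule, n_leaves(x$tree)),
    oforest = sprintf("nsets=%d ntreeperdiv=%d ntreefinal=%d",
                      x$nsets, x$ntreeperdiv, x$ntreefinal))
  cat(sprintf("oksmap %s model (%s); %d obs, levels: %s\n", x$family, extra,
              x$n, paste(x$levels, collapse = " ")))
  invisible(x)
}
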