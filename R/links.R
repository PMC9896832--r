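#' Link functions for cumulative ordinal models
#'
#' Five links transform a cumulative probability onto an unbounded (or, for
#' `logc`, half-open) scale: `logit(p) = log(p/(1-p))`, `probit(p)` the
#' standard-normal quantile, `cauchit(p) = tan(pi*(p - 0.5))`,
#' `cloglog(p) = log(-log(1-p))` and `logc(p) = -log(1-p)`.
#'
#' `logc` maps \eqn{[0,1)} onto \eqn{[0,\infty)}; it is only admitted for the
#' plain cumulative family, where the top cumulative probability is fixed at 1
#' and never transformed.
#'
#' @param name one of `"logit"`, `"probit"`, `"cauchit"`, `"cloglog"`, `"logc"`.
#' @param p probabilities; must lie strictly inside (0,1) (for `logc`, in
#'   `[0,1)`).
#' @param q values on the transformed scale.
#' @return `link_forward` returns transformed values; `link_inverse` maps them
#'   back to probabilities; `link_density` gives the derivative of the inverse
#'   (used for analytic likelihood gradients).
#' @examples
#' link_forward("logit", 0.5)              # 0
#' link_forward("cauchit", 0.75)           # tan(pi/4) = 1
#' link_inverse("cloglog", 0)              # 1 - exp(-1)
#' @export
link_forward <- function(name, p) {
  name <- match.arg(name, ordinal_links())
  if (name == "logc") {
    if (any(p < 0 | p >= 1)) stop("logc is defined on [0, 1)", call. = FALSE)
    return(-log(1 - p))
  }
  if (any(p <= 0 | p >= 1)) {
    stop(sprintf("%s is defined on the open interval (0, 1)", name),
         call. = FALSE)
  }
  switch(name,
    logit   = stats::qlogis(p),
    probit  = stats::qnorm(p),
    cauchit = stats::qcauchy(p),
    cloglog = log(-log(1 - p))
  )
}

#' @rdname link_forward
#' @export
link_inverse <- function(name, q) {
  name <- match.arg(name, ordinal_links())
  switch(name,
    logit   = stats::plogis(q),
    probit  = stats::pnorm(q),
    cauchit = stats::pcauchy(q),
    cloglog = 1 - exp(-exp(q)),
    logc    = ifelse(q < 0, 0, 1 - exp(-q))
  )
}

#' @rdname link_forward
#' @export
link_density <- function(name, q) {
  name <- match.arg(name, ordinal_links())
  switch(name,
    logit   = stats::dlogis(q),
    probit  = stats::dnorm(q),
    cauchit = stats::dcauchy(q),
    cloglog = exp(q - exp(q)),
    logc    = ifelse(q < 0, 0, exp(-q))
  )
}

#' @rdname link_forward
#' @export
ordinal_links <- function() c("logit", "probit", "cauchit", "cloglog", "logc")
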