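# Shared fixtures built in code at test time.

# Small deterministic ordinal regression data set.
make_ordinal_data <- function(n = 300L, p = 3L, K = 4L, seed = 42L,
                              link = "logit") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- seq(1, -1, length.out = p)
  eta <- drop(X %*% beta)
  noise <- switch(link, logit = rlogis(n), probit = rnorm(n))
  y <- findInterval(eta + noise, seq(-1, 1, length.out = K - 1L)) + 1L
  list(X = X, y = y, beta = beta,
       thresholds = seq(-1, 1, length.out = K - 1L))
}

# Calibrated synthetic cohort, cached per session.
calibrated_cohort <- local({
  cache <- new.env()
  function(n = 5000L, seed = 20230202L) {
    key <- paste0("n", n, "_", seed)
    if (is.null(cache[[key]])) {
      sp <- default_cohort_spec("estimation", seed = seed)
      sp$n_patients <- as.integer(n)
      cache[[key]] <- generate_cohort(sp)
    }
    cache[[key]]
  }
})

# Independent plain-R negative log-likelihood for the parallel-logit
# cumulative model (oracle path: no shared code with the package internals).
oracle_nll_parallel_logit <- function(par, X, y, K) {
  theta <- par[1:(K - 1)]
  beta <- par[K:length(par)]
  total <- 0
  for (i in seq_along(y)) {
    eta <- sum(X[i, ] * beta)
    gam <- c(plogis(theta - eta), 1)
    pk <- if (y[i] == 1) gam[1] else gam[y[i]] - gam[y[i] - 1]
    total <- total - log(max(pk, 1e-12))
  }
  total
}

# Write a temporary additive value-set CSV from a coefficient matrix.
write_additive_vs <- function(coef, constant = 1, path = tempfile(fileext = ".csv")) {
  rows <- data.frame(domain = "constant", level = "", decrement = constant)
  for (d in rownames(coef)) {
    rows <- rbind(rows, data.frame(domain = d, level = 2:5,
                                   decrement = coef[d, ]))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

uniform_decrements <- function(value = 0.1) {
  m <- matrix(rep(value * (1:4), each = 5), nrow = 5, byrow = FALSE)
  dimnames(m) <- list(c("mo", "sc", "ua", "pd", "ad"), paste0("L", 2:5))
  m
}
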