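#' Specify a synthetic OKS / EQ-5D-5L cohort
#'
#' The generator follows a single-factor graded-response-style threshold
#' model: each patient has one latent standard-normal health score; every
#' observed OKS item and EQ-5D domain is the binned value of
#' `loading * latent + noise` under its own strictly increasing threshold
#' vector. OKS loadings are positive (higher item value = better knee) and
#' EQ loadings negative (higher level = worse health), so item-by-domain
#' correlations come out negative, as observed in knee-osteoarthritis
#' cohorts.
#'
#' @param n_patients cohort size.
#' @param latent_loadings_oks 12 positive loadings.
#' @param latent_loadings_eq 5 negative loadings (mobility, self-care, usual
#'   activities, pain/discomfort, anxiety/depression).
#' @param noise_sd standard deviation of the per-item independent noise.
#' @param oks_thresholds 12 x 4 matrix, each row strictly increasing; bins
#'   the latent item value into the 5 response levels 0..4.
#' @param eq_thresholds 5 x 4 matrix, each row strictly increasing; bins
#'   into levels 1..5.
#' @param seed integer seed; the seed is an explicit field, never global
#'   state shared between cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, latent_loadings_oks, latent_loadings_eq,
                        noise_sd, oks_thresholds, eq_thresholds, seed) {
  oks_thresholds <- as.matrix(oks_thresholds)
  eq_thresholds <- as.matrix(eq_thresholds)
  stopifnot(n_patients >= 1, noise_sd >= 0,  # 0 = deterministic degenerate case
            length(latent_loadings_oks) == 12L,
            length(latent_loadings_eq) == 5L,
            all(dim(oks_thresholds) == c(12L, 4L)),
            all(dim(eq_thresholds) == c(5L, 4L)))
  if (any(apply(oks_thresholds, 1L, diff) <= 0) ||
      any(apply(eq_thresholds, 1L, diff) <= 0)) {
    stop("threshold vectors must be strictly increasing", call. = FALSE)
  }
  ok_dir <- all(latent_loadings_oks > 0) && all(latent_loadings_eq < 0)
  rev_dir <- all(latent_loadings_oks < 0) && all(latent_loadings_eq > 0)
  if (!ok_dir && !rev_dir) {
    stop("OKS and EQ loadings must have uniform, opposite signs",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 latent_loadings_oks = latent_loadings_oks,
                 latent_loadings_eq = latent_loadings_eq,
                 noise_sd = noise_sd,
                 oks_thresholds = oks_thresholds,
                 eq_thresholds = eq_thresholds,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Bin continuous values by a strictly increasing threshold vector into
# 0-based levels 0..length(thr).
bin_by_thresholds <- function(x, thr) {
  findInterval(x, thr)
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return object of class `sim_cohort`: list with `oks_items` (n x 12,
#'   levels 0..4), `eq_levels` (n x 5, levels 1..5) and the hidden
#'   `latent_health` draw kept for diagnostics. Identical spec (including
#'   seed) gives a bit-identical cohort.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  u <- stats::rnorm(n)
  oks <- matrix(0L, n, 12L,
                dimnames = list(NULL, sprintf("oks_q%02d", 1:12)))
  for (j in 1:12) {
    lat <- spec$latent_loadings_oks[j] * u + stats::rnorm(n, sd = spec$noise_sd)
    oks[, j] <- bin_by_thresholds(lat, spec$oks_thresholds[j, ])
  }
  eq <- matrix(1L, n, 5L, dimnames = list(NULL, paste0("eq_", eq_domains())))
  for (d in 1:5) {
    lat <- spec$latent_loadings_eq[d] * u + stats::rnorm(n, sd = spec$noise_sd)
    eq[, d] <- 1L + bin_by_thresholds(lat, spec$eq_thresholds[d, ])
  }
  structure(list(oks_items = oks, eq_levels = eq, latent_health = u,
                 spec = spec),
            class = "sim_cohort")
}

# Printed reference marginals used to calibrate the default specification:
# per-item OKS means/SDs and EQ-5D level counts of a knee-osteoarthritis
# estimation cohort (n = 456). The EQ counts ship as a CSV fixture so the
# evaluation module can recompute baseline accuracies from them.
oks_item_moments <- function() {
  list(mean = c(1.11, 3.06, 2.39, 2.70, 2.16, 2.38, 2.11, 2.16, 2.12, 2.44,
                2.66, 1.98),
       sd   = c(1.11, 1.28, 1.33, 1.23, 1.19, 1.47, 1.42, 1.45, 1.36, 1.43,
                1.53, 1.25))
}

#' Reference EQ-5D-5L level counts
#'
#' Marginal level counts of the reference knee-osteoarthritis estimation
#' cohort (n = 456) bundled with the package. They anchor the default
#' generator thresholds and let baseline accuracies be recomputed exactly.
#'
#' @return data.frame with columns `domain`, `level`, `count`.
#' @export
reference_level_counts <- function() {
  utils::read.csv(system.file("extdata", "eq5d_level_counts_estimation.csv",
                              package = "oksmap"))
}

# Cumulative marginal probabilities -> latent thresholds for a N(0, s) item.
thresholds_from_cum <- function(cum, s) s * stats::qnorm(cum)

#' Default calibrated cohort specification
#'
#' Returns the specification used throughout the package's studies:
#' estimation cohorts of 456 patients and external-validation cohorts of 115,
#' sharing one calibrated population model. EQ thresholds are set so the
#' expected marginal level frequencies match the bundled reference counts;
#' OKS thresholds approximate the reference per-item means and SDs through a
#' discretized-normal fit. Loadings are calibrated so that (i) the first
#' principal component of the 12 standardized items carries roughly two
#' thirds of their variance and (ii) item-by-domain Spearman correlations
#' fall in the negative band seen in knee-osteoarthritis samples
#' (about -0.8 to -0.3), with anxiety/depression the weakest-coupled domain.
#'
#' @param role `"estimation"` (n = 456) or `"validation"` (n = 115).
#' @param seed integer master seed; the two roles derive distinct stream
#'   seeds from it.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(role = c("estimation", "validation"),
                                seed = 20230202L) {
  role <- match.arg(role)
  n <- if (role == "estimation") 456L else 115L
  load_oks <- c(1.25, 1.55, 1.65, 1.55, 1.45, 1.65, 1.35, 1.45, 1.55, 1.65,
                1.55, 1.45)
  load_eq <- -c(1.8, 1.7, 1.8, 1.3, 0.75)
  noise_sd <- 1

  mom <- oks_item_moments()
  oks_thr <- t(vapply(1:12, function(j) {
    cum <- stats::pnorm(((0:3) + 0.5 - mom$mean[j]) / mom$sd[j])
    cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
    cum <- cummax(cum + (0:3) * 1e-6)  # guard strict monotonicity
    thresholds_from_cum(cum, sqrt(load_oks[j]^2 + noise_sd^2))
  }, numeric(4)))

  counts <- reference_level_counts()
  eq_thr <- t(vapply(seq_along(eq_domains()), function(d) {
    ct <- counts$count[counts$domain == eq_domains()[d]]
    cum <- cumsum(ct)[1:4] / sum(ct)
    thresholds_from_cum(cum, sqrt(load_eq[d]^2 + noise_sd^2))
  }, numeric(4)))

  cohort_spec(n_patients = n,
              latent_loadings_oks = load_oks,
              latent_loadings_eq = load_eq,
              noise_sd = noise_sd,
              oks_thresholds = oks_thr,
              eq_thresholds = eq_thr,
              seed = derive_seed(seed, paste0("cohort_", role)))
}

#' Write / read a cohort as delimited text
#'
#' Schema: header `oks_q01..oks_q12, eq_mo, eq_sc, eq_ua, eq_pd, eq_ad`;
#' the reader accepts the same schema for real data.
#'
#' @param cohort a `sim_cohort` or a data frame in the cohort schema.
#' @param path CSV file path.
#' @return `read_cohort` returns a list with `oks_items` and `eq_levels`
#'   integer matrices.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  need <- c(sprintf("oks_q%02d", 1:12), paste0("eq_", eq_domains()))
  if (!all(need %in% names(df))) {
    stop("cohort file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  oks <- as.matrix(df[, sprintf("oks_q%02d", 1:12)])
  eq <- as.matrix(df[, paste0("eq_", eq_domains())])
  check_range(oks, 0L, 4L, "OKS items")
  check_range(eq, 1L, 5L, "EQ-5D levels")
  storage.mode(oks) <- "integer"
  storage.mode(eq) <- "integer"
  list(oks_items = oks, eq_levels = eq)
}

#' @export
as.data.frame.sim_cohort <- function(x, ...) {
  cbind(as.data.frame(x$oks_items), as.data.frame(x$eq_levels))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic OKS/EQ-5D-5L cohort: %d patients (seed %d)\n",
              nrow(x$oks_items), x$spec$seed))
  invisible(x)
}
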