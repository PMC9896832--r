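## Model evaluation: baseline vs crude accuracy per domain, assembly of
## predicted five-digit profiles, utility conversion through value sets,
## MAE/MSE with percentile bootstrap confidence intervals, and the
## median-split error comparison.

#' Baseline accuracy of a domain
#'
#' The accuracy of "no model": the proportion of the most common level.
#'
#' @param y nonempty ordinal vector.
#' @return proportion in (0, 1].
#' @examples
#' baseline_accuracy(c(1, 1, 2, 3))  # 0.5
#' @export
baseline_accuracy <- function(y) {
  if (!length(y)) stop("empty outcome", call. = FALSE)
  max(table(y)) / length(y)
}

#' Crude accuracy with bootstrap confidence interval
#'
#' The proportion of exact level matches, with a percentile bootstrap CI
#' over patients.
#'
#' @param pred,actual aligned level vectors.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `accuracy`, `ci_low`, `ci_high`, `n`.
#' @export
crude_accuracy <- function(pred, actual, B = 2000L, seed = 1L,
                           level = 0.95) {
  if (length(pred) != length(actual)) {
    stop("pred and actual must have equal length", call. = FALSE)
  }
  hit <- as.numeric(as.character(pred) == as.character(actual))
  ci <- boot_ci(hit, mean, B = B, level = level, seed = seed)
  list(accuracy = mean(hit), ci_low = ci[1L], ci_high = ci[2L],
       n = length(hit))
}

#' Assemble five-digit profiles from per-domain predictions
#'
#' @param domain_predictions list (or data frame) of five aligned level
#'   vectors in the order mobility, self-care, usual activities,
#'   pain/discomfort, anxiety/depression.
#' @return character vector of profile codes.
#' @examples
#' assemble_profiles(list(1, 1, 1, 1, 1))  # "11111"
#' @export
assemble_profiles <- function(domain_predictions) {
  if (length(domain_predictions) != 5L) {
    stop("need five domain vectors", call. = FALSE)
  }
  lens <- lengths(domain_predictions)
  if (length(unique(lens)) != 1L) {
    stop("domain prediction vectors are misaligned: lengths ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  m <- vapply(domain_predictions, function(v) as.integer(as.character(v)),
              integer(lens[[1L]]))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  profile_code(m)
}

#' Utility errors between actual and predicted profiles
#'
#' Converts both profile vectors to utilities under one value set and
#' reports MAE and MSE with percentile bootstrap confidence intervals
#' (resampling patients, so the five domains stay coupled), plus the MAE in
#' the strata above and below the median utility. The stratifying variable
#' defaults to the observed utilities; the predicted ones can be chosen
#' instead.
#'
#' @param actual_profiles,predicted_profiles aligned profile code vectors.
#' @param vs an `eq_value_set`.
#' @param boot_B bootstrap replicates.
#' @param seed integer seed.
#' @param split_on `"observed"` or `"predicted"` utilities for the median
#'   split.
#' @return list of class `utility_error_report`.
#' @export
utility_errors <- function(actual_profiles, predicted_profiles, vs,
                           boot_B = 2000L, seed = 1L,
                           split_on = c("observed", "predicted")) {
  split_on <- match.arg(split_on)
  if (!length(actual_profiles)) stop("empty input", call. = FALSE)
  if (length(actual_profiles) != length(predicted_profiles)) {
    stop("profile vectors are misaligned", call. = FALSE)
  }
  u_act <- eq_utility(actual_profiles, vs)
  u_pred <- eq_utility(predicted_profiles, vs)
  err <- u_act - u_pred
  mae_ci <- boot_ci(abs(err), mean, B = boot_B, seed = derive_seed(seed, "mae"))
  mse_ci <- boot_ci(err^2, mean, B = boot_B, seed = derive_seed(seed, "mse"))
  base <- if (split_on == "observed") u_act else u_pred
  med <- stats::median(base)
  hi <- base >= med
  structure(list(
    value_set_id = vs$country,
    mae = mean(abs(err)), mae_ci = mae_ci,
    mse = mean(err^2), mse_ci = mse_ci,
    mae_above_median = mean(abs(err[hi])),
    mae_below_median = mean(abs(err[!hi])),
    n = length(err), n_above = sum(hi), n_below = sum(!hi),
    split_on = split_on),
    class = "utility_error_report")
}

#' @export
print.utility_error_report <- function(x, ...) {
  cat(sprintf(
    "Utility errors under '%s': MAE %.3f (%.3f-%.3f), MSE %.3f (%.3f-%.3f)\n",
    x$value_set_id, x$mae, x$mae_ci[1L], x$mae_ci[2L],
    x$mse, x$mse_ci[1L], x$mse_ci[2L]))
  cat(sprintf("  MAE above/below median utility: %.3f / %.3f (n = %d/%d)\n",
              x$mae_above_median, x$mae_below_median, x$n_above, x$n_below))
  invisible(x)
}

#' Aggregate utility-error reports across value sets
#'
#' @param reports list of `utility_error_report`s.
#' @return data.frame with one row per report plus attribute-free summary
#'   columns accessible via `attr(, "summary")`: mean, sd, min, max of MAE
#'   and MSE across value sets.
#' @export
multi_valueset_summary <- function(reports) {
  if (!length(reports)) stop("need at least one report", call. = FALSE)
  tab <- data.frame(
    value_set = vapply(reports, `[[`, character(1), "value_set_id"),
    mae = vapply(reports, `[[`, numeric(1), "mae"),
    mse = vapply(reports, `[[`, numeric(1), "mse"),
    mae_above_median = vapply(reports, `[[`, numeric(1),
                              "mae_above_median"),
    mae_below_median = vapply(reports, `[[`, numeric(1),
                              "mae_below_median"),
    stringsAsFactors = FALSE)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  summ <- data.frame(
    statistic = c("mean", "sd", "min", "max"),
    mae = c(mean(tab$mae), sd0(tab$mae), min(tab$mae), max(tab$mae)),
    mse = c(mean(tab$mse), sd0(tab$mse), min(tab$mse), max(tab$mse)))
  attr(tab, "summary") <- summ
  tab
}

#' Conceptual overlap between OKS items and EQ-5D-5L
#'
#' Spearman rank correlations between every item and every domain, and an
#' exploratory ordinary-least-squares regression of the utility index on
#' the total OKS score.
#'
#' @param oks_items n x 12 item matrix.
#' @param eq_levels n x 5 domain level matrix.
#' @param utilities n utilities.
#' @return list with the 12 x 5 Spearman `correlations` (constant columns
#'   give NA entries, flagged in `constant_columns`) and `ols` (slope,
#'   intercept, r_squared).
#' @export
conceptual_overlap <- function(oks_items, eq_levels, utilities) {
  stopifnot(nrow(oks_items) == nrow(eq_levels),
            nrow(oks_items) == length(utilities))
  const <- c(colnames(oks_items)[apply(oks_items, 2L, stats::sd) == 0],
             colnames(eq_levels)[apply(eq_levels, 2L, stats::sd) == 0])
  suppressWarnings(
    rho <- stats::cor(oks_items, eq_levels, method = "spearman"))
  total <- oks_total(oks_items)
  fit <- stats::lm(utilities ~ total)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(correlations = rho,
       constant_columns = const,
       ols = list(slope = unname(stats::coef(fit)[2L]),
                  intercept = unname(stats::coef(fit)[1L]),
                  r_squared = r2))
}
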