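## Pipeline orchestration: simulate -> predictor sets -> tournament ->
## refit -> evaluate, as a configured, logged, reproducible run. A run is
## reproducible from the config alone; one master seed fans out
## deterministically per stage.

#' Build a run configuration
#'
#' @param output_dir directory for all artifacts.
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_estimation,n_validation cohort sizes (reference study: 456 and
#'   115).
#' @param folds,repeats tournament cross-validation geometry.
#' @param reduced_grid use the reduced grid profile: 5 random cp values,
#'   halved ordinal-forest sizes, 3 x 1 cross-validation; the full profile
#'   is 20 cp values, full forest sizes, 5 x 3.
#' @param boot_B bootstrap replicates for evaluation CIs.
#' @param domains EQ domains to fit (default all five).
#' @param predictor_sets predictor set ids to include.
#' @param rfe_folds,rfe_repeats RFE geometry.
#' @param value_sets named list of `eq_value_set`s for run_evaluate; default
#'   the bundled toy sets.
#' @param grid optional explicit [grid_options()] override.
#' @return list of class `oksmap_config`.
#' @export
run_config <- function(output_dir = tempfile("oksmap_run_"),
                       seed = 20230202L,
                       n_estimation = 456L, n_validation = 115L,
                       folds = if (reduced_grid) 3L else 5L,
                       repeats = if (reduced_grid) 1L else 3L,
                       reduced_grid = FALSE,
                       boot_B = 2000L,
                       domains = eq_domains(),
                       predictor_sets = c("all", "rfe", "model_based",
                                          "pca"),
                       rfe_folds = if (reduced_grid) 3L else 5L,
                       rfe_repeats = if (reduced_grid) 1L else 5L,
                       value_sets = NULL,
                       grid = NULL) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 n_estimation = as.integer(n_estimation),
                 n_validation = as.integer(n_validation),
                 folds = folds, repeats = repeats,
                 reduced_grid = reduced_grid, boot_B = boot_B,
                 domains = domains, predictor_sets = predictor_sets,
                 rfe_folds = rfe_folds, rfe_repeats = rfe_repeats,
                 value_sets = value_sets,
                 grid = grid %||% grid_options(reduced = reduced_grid)),
            class = "oksmap_config")
}

cohort_path <- function(config, role) {
  file.path(config$output_dir, paste0("cohort_", role, ".csv"))
}

#' Simulate and persist the estimation and validation cohorts
#'
#' Writes both cohorts as delimited text plus a manifest recording the
#' specification, seeds and file checksums. Rerunning with the same config
#' reproduces identical files.
#'
#' @param config an [run_config()] list.
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$output_dir)) {
    stop("cannot create output directory ", config$output_dir,
         call. = FALSE)
  }
  manifest <- list(seed = config$seed, files = list())
  for (role in c("estimation", "validation")) {
    spec <- default_cohort_spec(role, seed = config$seed)
    spec$n_patients <- if (role == "estimation") config$n_estimation else
      config$n_validation
    cohort <- generate_cohort(spec)
    path <- cohort_path(config, role)
    write_cohort(cohort, path)
    manifest$files[[role]] <- list(
      path = path, n = spec$n_patients, seed = spec$seed,
      md5 = unname(tools::md5sum(path)))
  }
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the mapping tournament and refit the winners
#'
#' For every requested domain: builds the four predictor sets on the
#' estimation cohort, cross-validates the full structure grid, selects the
#' winner and refits it on the whole estimation sample. Streams a
#' leaderboard file and serializes the winners (RDS plus a JSON sidecar of
#' structure, hyperparameters and predictor set).
#'
#' @param config an [run_config()] list; run_simulate must have run (or
#'   cohort files in the same schema be present).
#' @return invisibly, a list with per-domain winners and the leaderboard.
#' @export
run_map <- function(config) {
  est_path <- cohort_path(config, "estimation")
  if (!file.exists(est_path)) {
    stop("missing estimation cohort ", est_path,
         "; run run_simulate(config) first", call. = FALSE)
  }
  est <- read_cohort(est_path)
  grid <- enumerate_grid(seed = config$seed, options = config$grid,
                         predictor_sets = config$predictor_sets)
  log_path <- file.path(config$output_dir, "map_log.txt")
  cat(sprintf("[%s] tournament start: %d structures, %d trials/domain\n",
              format(Sys.time()), length(grid$structures),
              nrow(grid$trials)),
      file = log_path)
  winners <- list()
  leaderboard <- NULL
  for (dom in config$domains) {
    t0 <- Sys.time()
    y <- est$eq_levels[, paste0("eq_", dom)]
    sets <- build_tournament_sets(
      est$oks_items, y, seed = derive_seed(config$seed, paste0("sets_", dom)),
      rfe_folds = config$rfe_folds, rfe_repeats = config$rfe_repeats)
    res <- run_tournament(est$oks_items, y, grid, sets,
                          folds = config$folds, repeats = config$repeats,
                          seed = derive_seed(config$seed, paste0("cv_", dom)))
    sel <- select_and_refit(res, grid, sets, est$oks_items, y,
                            seed = derive_seed(config$seed,
                                               paste0("refit_", dom)))
    res$domain <- dom
    leaderboard <- rbind(leaderboard,
                         res[, c("domain", "structure_id", "label",
                                 "family", "predictor_set",
                                 "cv_accuracy_mean", "cv_accuracy_sd",
                                 "cv_cv", "n_folds", "note")])
    winners[[dom]] <- list(domain = dom, winner = sel$winner,
                           fit = sel$fit, predictor_set = sel$predictor_set,
                           baseline = baseline_accuracy(y))
    saveRDS(winners[[dom]],
            file.path(config$output_dir, paste0("winner_", dom, ".rds")))
    jsonlite::write_json(
      list(domain = dom, label = sel$winner$label,
           predictor_set = sel$winner$predictor_set,
           cv_accuracy_mean = sel$winner$cv_accuracy_mean,
           cv_accuracy_sd = sel$winner$cv_accuracy_sd,
           cv_cv = sel$winner$cv_cv,
           baseline = baseline_accuracy(y)),
      file.path(config$output_dir, paste0("winner_", dom, ".json")),
      auto_unbox = TRUE, digits = NA)
    n_bad <- sum(res$note != "")
    cat(sprintf(
      "[%s] %s: winner %s / %s (cv acc %.3f); %d flagged trials; %.1fs\n",
      format(Sys.time()), dom, sel$winner$label,
      sel$winner$predictor_set, sel$winner$cv_accuracy_mean, n_bad,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = log_path, append = TRUE)
  }
  utils::write.csv(leaderboard,
                   file.path(config$output_dir, "leaderboard.csv"),
                   row.names = FALSE)
  invisible(list(winners = winners, leaderboard = leaderboard))
}

#' Evaluate the refitted winners
#'
#' Computes baseline and crude accuracy per domain on the estimation and
#' external-validation cohorts, assembles actual and predicted profiles,
#' converts them to utilities under every configured value set and writes
#' accuracy and utility-error tables.
#'
#' @param config an [run_config()] list; run_map must have run.
#' @return invisibly, list with `accuracy` (data.frame) and
#'   `utility_errors` (per-value-set table with summary attribute).
#' @export
run_evaluate <- function(config) {
  value_sets <- config$value_sets %||%
    list(toy_additive = toy_value_set("additive"),
         toy_lookup = toy_value_set("lookup"))
  samples <- list(estimation = read_cohort(cohort_path(config, "estimation")),
                  validation = read_cohort(cohort_path(config, "validation")))
  winners <- lapply(config$domains, function(dom) {
    p <- file.path(config$output_dir, paste0("winner_", dom, ".rds"))
    if (!file.exists(p)) {
      stop("missing winner for domain ", dom, "; run run_map(config)",
           call. = FALSE)
    }
    readRDS(p)
  })
  names(winners) <- config$domains

  acc_tab <- NULL
  pred_levels <- list()
  for (sam in names(samples)) {
    dat <- samples[[sam]]
    pred_levels[[sam]] <- list()
    for (dom in config$domains) {
      w <- winners[[dom]]
      X <- apply_predictor_set(w$predictor_set, dat$oks_items)
      pred <- predict_levels(w$fit, X)
      actual <- dat$eq_levels[, paste0("eq_", dom)]
      ca <- crude_accuracy(pred, actual, B = config$boot_B,
                           seed = derive_seed(config$seed,
                                              paste0("acc_", sam, dom)))
      acc_tab <- rbind(acc_tab, data.frame(
        sample = sam, domain = dom,
        baseline = baseline_accuracy(actual),
        crude = ca$accuracy, ci_low = ca$ci_low, ci_high = ca$ci_high,
        n = ca$n, stringsAsFactors = FALSE))
      pred_levels[[sam]][[dom]] <- as.integer(as.character(pred))
    }
  }

  err_reports <- list()
  if (length(config$domains) == 5L) {
    val <- samples$validation
    actual_prof <- profile_code(val$eq_levels)
    pred_prof <- assemble_profiles(pred_levels$validation)
    err_reports <- lapply(names(value_sets), function(id)
      utility_errors(actual_prof, pred_prof, value_sets[[id]],
                     boot_B = config$boot_B,
                     seed = derive_seed(config$seed, paste0("err_", id))))
    names(err_reports) <- names(value_sets)
  }
  err_tab <- if (length(err_reports)) multi_valueset_summary(err_reports)
    else NULL

  utils::write.csv(acc_tab, file.path(config$output_dir, "accuracy.csv"),
                   row.names = FALSE)
  if (!is.null(err_tab)) {
    utils::write.csv(err_tab,
                     file.path(config$output_dir, "utility_errors.csv"),
                     row.names = FALSE)
  }
  invisible(list(accuracy = acc_tab, utility_errors = err_tab,
                 reports = err_reports))
}

#' Run the full pipeline
#'
#' Chains [run_simulate()], [run_map()] and [run_evaluate()] under one
#' master seed.
#'
#' @param config an [run_config()] list.
#' @return list with the mapping and evaluation results.
#' @export
run_full <- function(config) {
  run_simulate(config)
  mapres <- run_map(config)
  evres <- run_evaluate(config)
  list(winners = mapres$winners, leaderboard = mapres$leaderboard,
       accuracy = evres$accuracy, utility_errors = evres$utility_errors,
       reports = evres$reports)
}
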