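## Grid enumeration and the cross-validated model tournament. The full grid
## spans 133 model structures -- cumulative 2x5, penalized 2x2x4, ordinal
## CART 20x2x2 (20 random cp values), ordinal forest 3x3x3 -- each tried
## with 4 predictor sets, i.e. 532 trials per EQ domain. Accuracy is
## averaged over repeated stratified k-fold cross-validation (5 folds x 3
## repeats by default) and the best structure is refitted on the whole
## estimation sample.

#' Grid options
#'
#' @param cp_n number of random ordinal-CART complexity parameters, drawn
#'   log-uniformly on `cp_range` from the run seed (the reference grid uses
#'   20).
#' @param cp_range range of the cp draw.
#' @param oforest_nsets,oforest_ntreeperdiv,oforest_ntreefinal ordinal
#'   forest hyperparameter values.
#' @param reduced if TRUE, use the reduced profile: 5 cp values and halved
#'   forest sizes (the structure counts shrink accordingly).
#' @return a list of grid options for [enumerate_grid()].
#' @export
grid_options <- function(cp_n = 20L, cp_range = c(1e-4, 1e-1),
                         oforest_nsets = c(50L, 100L, 150L),
                         oforest_ntreeperdiv = c(50L, 100L, 150L),
                         oforest_ntreefinal = c(200L, 400L, 600L),
                         reduced = FALSE) {
  if (reduced) {
    cp_n <- 5L
    oforest_nsets <- c(25L, 50L, 75L)
    oforest_ntreeperdiv <- c(25L, 50L, 75L)
    oforest_ntreefinal <- c(100L, 200L, 300L)
  }
  list(cp_n = cp_n, cp_range = cp_range, oforest_nsets = oforest_nsets,
       oforest_ntreeperdiv = oforest_ntreeperdiv,
       oforest_ntreefinal = oforest_ntreefinal)
}

#' Enumerate all model structures and trials
#'
#' @param seed integer seed for the random cp draw.
#' @param options a [grid_options()] list.
#' @param predictor_sets predictor set ids to cross with each structure.
#' @return list with `structures` (list of model specs) and `trials`
#'   (data.frame crossing structure ids with predictor set ids). With the
#'   default options this yields 133 structures and 532 trials.
#' @export
enumerate_grid <- function(seed = 1L,
                           options = grid_options(),
                           predictor_sets = c("all", "rfe", "model_based",
                                              "pca")) {
  set.seed(derive_seed(seed, "cp_grid"))
  cp_vals <- sort(exp(stats::runif(options$cp_n,
                                   log(options$cp_range[1L]),
                                   log(options$cp_range[2L]))))
  structures <- list()
  for (par in c(TRUE, FALSE)) {
    for (lk in ordinal_links()) {
      structures[[length(structures) + 1L]] <-
        list(family = "cumulative", parallel = par, link = lk)
    }
  }
  for (al in c("ridge", "lasso")) {
    for (cr in c("AIC", "BIC")) {
      for (lk in setdiff(ordinal_links(), "logc")) {
        structures[[length(structures) + 1L]] <-
          list(family = "penalized", alpha = al, criterion = cr, link = lk)
      }
    }
  }
  for (cp in cp_vals) {
    for (sc in c("absolute", "quadratic")) {
      for (pr in c("misclassification_rate", "misclassification_cost")) {
        structures[[length(structures) + 1L]] <-
          list(family = "ocart", cp = cp, split_cost = sc, prune_rule = pr)
      }
    }
  }
  for (ns in options$oforest_nsets) {
    for (nt in options$oforest_ntreeperdiv) {
      for (nf in options$oforest_ntreefinal) {
        structures[[length(structures) + 1L]] <-
          list(family = "oforest", nsets = ns, ntreeperdiv = nt,
               ntreefinal = nf)
      }
    }
  }
  for (i in seq_along(structures)) structures[[i]]$structure_id <- i
  trials <- expand.grid(structure_id = seq_along(structures),
                        predictor_set = predictor_sets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  list(structures = structures, trials = trials)
}

spec_label <- function(sp) {
  switch(sp$family,
    cumulative = sprintf("cumulative(parallel=%s,link=%s)", sp$parallel,
                         sp$link),
    penalized = sprintf("penalized(alpha=%s,criterion=%s,link=%s)",
                        sp$alpha, sp$criterion, sp$link),
    ocart = sprintf("ocart(cp=%.5g,split=%s,prune=%s)", sp$cp,
                    sp$split_cost, sp$prune_rule),
    oforest = sprintf("oforest(nsets=%d,ntreeperdiv=%d,ntreefinal=%d)",
                      sp$nsets, sp$ntreeperdiv, sp$ntreefinal))
}

# Fit any structure spec on (X, y). seed feeds the stochastic families.
fit_spec <- function(sp, X, y, seed = 1L) {
  switch(sp$family,
    cumulative = fit_cumulative(X, y, parallel = sp$parallel,
                                link = sp$link),
    penalized = fit_penalized(X, y, alpha = sp$alpha,
                              criterion = sp$criterion, link = sp$link),
    ocart = fit_ocart(X, y, cp = sp$cp, split_cost = sp$split_cost,
                      prune_rule = sp$prune_rule),
    oforest = fit_oforest(X, y, nsets = sp$nsets,
                          ntreeperdiv = sp$ntreeperdiv,
                          ntreefinal = sp$ntreefinal, seed = seed))
}

# Resolve the predictor set for a trial: the model-based set is
# family-specific (each family's own importance measure), so it may be
# supplied as a named list of per-family sets.
get_set <- function(sets, set_id, family) {
  s <- sets[[set_id]]
  if (set_id == "model_based" && !inherits(s, "predictor_set")) {
    s <- s[[family]]
  }
  if (!inherits(s, "predictor_set")) {
    stop("no predictor set '", set_id, "' for family ", family,
         call. = FALSE)
  }
  s
}

# Evaluate every trial on one (training, test) split, sharing work inside
# each family: ordinal CART trees are grown once per split_cost and the cp x
# prune_rule variants derived by snip + prune; ordinal forests share the
# candidate-score-set pool through oforest_batch_fit.
eval_fold <- function(structures, trials, sets, X_items, y, tr_idx, te_idx,
                      seed) {
  acc <- rep(NA_real_, nrow(trials))
  note <- character(nrow(trials))
  y_tr <- y[tr_idx]; y_te <- y[te_idx]
  all_fam <- vapply(structures[trials$structure_id], `[[`, character(1),
                    "family")
  groups <- unique(data.frame(set = trials$predictor_set, fam = all_fam,
                              stringsAsFactors = FALSE))
  for (gi in seq_len(nrow(groups))) {
    set_id <- groups$set[gi]
    fam_g <- groups$fam[gi]
    ps <- get_set(sets, set_id, fam_g)
    Xtr <- apply_predictor_set(ps, X_items[tr_idx, , drop = FALSE])
    Xte <- apply_predictor_set(ps, X_items[te_idx, , drop = FALSE])
    rows <- which(trials$predictor_set == set_id & all_fam == fam_g)
    fam <- all_fam[rows]

    for (r in rows[fam == "cumulative"]) {
      sp <- structures[[trials$structure_id[r]]]
      fit <- try(fit_spec(sp, Xtr, y_tr, seed), silent = TRUE)
      if (inherits(fit, "try-error")) {
        note[r] <- "fit_error"
      } else {
        if (!isTRUE(fit$converged)) note[r] <- "non_convergence"
        acc[r] <- mean(predict_levels(fit, Xte) == y_te)
      }
    }

    # penalized: the AIC and BIC variants share one penalty path
    pen_rows <- rows[fam == "penalized"]
    if (length(pen_rows)) {
      pspecs <- structures[trials$structure_id[pen_rows]]
      key <- paste(vapply(pspecs, `[[`, character(1), "alpha"),
                   vapply(pspecs, `[[`, character(1), "link"))
      for (k in unique(key)) {
        idx <- pen_rows[key == k]
        sp1 <- structures[[trials$structure_id[idx[1L]]]]
        po <- try(penalized_path(Xtr, y_tr, alpha = sp1$alpha,
                                 link = sp1$link), silent = TRUE)
        if (inherits(po, "try-error")) {
          note[idx] <- "fit_error"
          next
        }
        for (r in idx) {
          sp <- structures[[trials$structure_id[r]]]
          fit <- penalized_select(po, sp$criterion)
          acc[r] <- mean(predict_levels(fit, Xte) == y_te)
        }
      }
    }

    oc_rows <- rows[fam == "ocart"]
    if (length(oc_rows)) {
      oc_specs <- structures[trials$structure_id[oc_rows]]
      for (sc in unique(vapply(oc_specs, `[[`, character(1), "split_cost"))) {
        idx_sc <- oc_rows[vapply(oc_specs, `[[`, character(1),
                                 "split_cost") == sc]
        cps <- vapply(structures[trials$structure_id[idx_sc]], `[[`,
                      numeric(1), "cp")
        base <- fit_ocart(Xtr, y_tr, cp = min(cps), split_cost = sc,
                          prune_rule = "misclassification_rate")
        for (i in seq_along(idx_sc)) {
          sp <- structures[[trials$structure_id[idx_sc[i]]]]
          sub <- base
          sub$cp <- sp$cp
          sub$prune_rule <- sp$prune_rule
          sub$tree <- prune_tree(snip_tree(base$tree, sp$cp), base$cost,
                                 sp$prune_rule, sp$cp)
          acc[idx_sc[i]] <- mean(predict(sub, Xte) == y_te)
        }
      }
    }

    of_rows <- rows[fam == "oforest"]
    if (length(of_rows)) {
      of_specs <- structures[trials$structure_id[of_rows]]
      fits <- oforest_batch_fit(Xtr, y_tr, of_specs,
                                seed = derive_seed(seed, paste0("of_", set_id)))
      for (i in seq_along(of_rows)) {
        acc[of_rows[i]] <- mean(predict(fits[[i]], Xte) == y_te)
      }
    }
  }
  list(acc = acc, note = note)
}

#' Cross-validated tournament over a set of trials
#'
#' Runs every (structure, predictor set) trial through repeated stratified
#' k-fold cross-validation on the estimation sample and aggregates held-out
#' accuracies. Fold assignment is outcome-stratified where level counts
#' permit; a training split left with a single outcome level triggers a
#' flagged fold merge, never a silent skip.
#'
#' @param oks_items n x 12 item matrix.
#' @param y the domain's ordinal levels.
#' @param grid result of [enumerate_grid()].
#' @param sets named list of `predictor_set`s (see
#'   [build_predictor_sets()]); the model-based set may be a named list per
#'   family.
#' @param folds,repeats cross-validation geometry (reference analysis:
#'   5 folds x 3 repeats).
#' @param seed integer seed controlling fold assignment and the stochastic
#'   families.
#' @return data.frame of trial results: structure id/label, family,
#'   predictor set, `cv_accuracy_mean`, `cv_accuracy_sd`, `cv_cv`
#'   (coefficient of variation), per-fold accuracies (as a list column) and
#'   convergence notes.
#' @export
run_tournament <- function(oks_items, y, grid, sets, folds = 5L,
                           repeats = 3L, seed = 1L) {
  trials <- grid$trials
  structures <- grid$structures
  n_tr <- nrow(trials)
  fold_acc <- matrix(NA_real_, n_tr, folds * repeats)
  notes <- character(n_tr)
  merged_any <- FALSE
  col <- 0L
  for (rp in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("folds_", rp)))
    fid <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      col <- col + 1L
      tr_idx <- which(fid != f)
      te_idx <- which(fid == f)
      if (length(unique(y[tr_idx])) < 2L) {
        # merge this fold into the next one and flag; the training split
        # then regains at least two levels
        merged_any <- TRUE
        fid[te_idx] <- (f %% folds) + 1L
        next
      }
      ev <- eval_fold(structures, trials, sets, oks_items, y,
                      tr_idx, te_idx,
                      seed = derive_seed(seed, paste0("fold_", rp, "_", f)))
      fold_acc[, col] <- ev$acc
      notes <- ifelse(nzchar(ev$note) & !nzchar(notes), ev$note, notes)
    }
  }
  cvm <- rowMeans(fold_acc, na.rm = TRUE)
  cvs <- apply(fold_acc, 1L, stats::sd, na.rm = TRUE)
  out <- data.frame(
    structure_id = trials$structure_id,
    label = vapply(structures[trials$structure_id], spec_label,
                   character(1)),
    family = vapply(structures[trials$structure_id], `[[`, character(1),
                    "family"),
    predictor_set = trials$predictor_set,
    cv_accuracy_mean = cvm,
    cv_accuracy_sd = cvs,
    cv_cv = cvs / cvm,
    n_folds = rowSums(!is.na(fold_acc)),
    note = notes,
    merged_folds = merged_any,
    stringsAsFactors = FALSE)
  out$fold_accuracies <- lapply(seq_len(n_tr), function(i)
    fold_acc[i, !is.na(fold_acc[i, ])])
  out
}

#' Cross-validate a single trial
#'
#' @param structure one structure spec from [enumerate_grid()].
#' @param predictor_set a `predictor_set`.
#' @inheritParams run_tournament
#' @return one-row trial result data.frame (see [run_tournament()]).
#' @export
cross_validate <- function(structure, predictor_set, oks_items, y,
                           folds = 5L, repeats = 3L, seed = 1L) {
  structure$structure_id <- 1L
  grid <- list(structures = list(structure),
               trials = data.frame(structure_id = 1L,
                                   predictor_set = predictor_set$id,
                                   stringsAsFactors = FALSE))
  sets <- stats::setNames(list(predictor_set), predictor_set$id)
  run_tournament(oks_items, y, grid, sets, folds = folds,
                 repeats = repeats, seed = seed)
}

family_rank <- c(cumulative = 1L, penalized = 2L, ocart = 3L, oforest = 4L)

#' Select the winning trial and refit it on the full estimation sample
#'
#' The winner is the trial with maximal cross-validated accuracy;
#' non-converged trials are excluded from ranking. Ties break toward the
#' simpler family (cumulative < penalized < ocart < oforest) and then
#' toward fewer predictors.
#'
#' @param results data.frame from [run_tournament()].
#' @param grid the [enumerate_grid()] result the tournament ran on.
#' @param sets the predictor sets used.
#' @inheritParams run_tournament
#' @return list with `winner` (result row), `fit` (refitted model),
#'   `predictor_set`, and `ranked` (ranked result table).
#' @export
select_and_refit <- function(results, grid, sets, oks_items, y, seed = 1L) {
  ok <- !(results$note %in% c("fit_error", "non_convergence")) &
    is.finite(results$cv_accuracy_mean)
  if (!any(ok)) stop("no trial converged; cannot select a winner",
                     call. = FALSE)
  res <- results[ok, , drop = FALSE]
  set_size <- vapply(seq_len(nrow(res)), function(i)
    length(get_set(sets, res$predictor_set[i], res$family[i])$columns),
    integer(1))
  ord <- order(-res$cv_accuracy_mean, family_rank[res$family], set_size)
  ranked <- res[ord, , drop = FALSE]
  winner <- ranked[1L, , drop = FALSE]
  sp <- grid$structures[[winner$structure_id]]
  ps <- get_set(sets, winner$predictor_set, winner$family)
  X <- apply_predictor_set(ps, oks_items)
  fit <- fit_spec(sp, X, y, seed = derive_seed(seed, "refit"))
  fit$predictor_set_id <- ps$id
  list(winner = winner, fit = fit, predictor_set = ps, ranked = ranked)
}
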