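## The four predictor-set constructions feeding every model structure:
## (1) all 12 items, (2) recursive feature elimination under a random
## forest with repeated cross-validation, (3) model-based importance using
## each family's built-in measure, (4) principal components explaining 90%
## of the item variance. Sets are built on the estimation sample; their
## transforms (centers/scales/rotation) are reused unchanged on validation
## data.

new_predictor_set <- function(id, columns, transform = NULL, ranking = NULL) {
  structure(list(id = id, columns = columns, transform = transform,
                 ranking = ranking),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("predictor set '%s': %s\n", x$id,
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Apply a predictor set to an item matrix
#'
#' Selects (and for the PCA set, transforms) the source columns. Transforms
#' fitted on the estimation sample are reused as-is, never refitted.
#'
#' @param ps a `predictor_set`.
#' @param X n x 12 OKS item matrix with the original column names.
#' @return numeric matrix ready for model fitting.
#' @export
apply_predictor_set <- function(ps, X) {
  stopifnot(inherits(ps, "predictor_set"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("oks_q%02d", seq_len(ncol(X)))
  if (is.null(ps$transform)) {
    miss <- setdiff(ps$columns, colnames(X))
    if (length(miss)) {
      stop("missing item columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(X[, ps$columns, drop = FALSE])
  }
  tr <- ps$transform
  Z <- scale(X[, tr$source, drop = FALSE], center = tr$center,
             scale = tr$scale)
  PC <- Z %*% tr$rotation[, ps$columns, drop = FALSE]
  colnames(PC) <- ps$columns
  PC
}

#' All-items predictor set
#'
#' @param item_names column names of the 12 items.
#' @return a `predictor_set` containing exactly the 12 items.
#' @export
all_items_set <- function(item_names = sprintf("oks_q%02d", 1:12)) {
  stopifnot(length(item_names) == 12L)
  new_predictor_set("all", item_names)
}

#' Rank items by recursive feature elimination
#'
#' Random-forest RFE under repeated stratified cross-validation: within
#' each training split items are ranked by forest impurity importance and
#' nested subsets of every size are scored by held-out accuracy; the subset
#' size with the best mean accuracy wins (ties toward fewer items), and the
#' returned set contains the top items of the full-sample ranking at that
#' size.
#'
#' @param X n x 12 item matrix.
#' @param y one ordinal EQ domain (integer levels).
#' @param folds,repeats cross-validation geometry (the reference analysis
#'   uses 5 x 5).
#' @param seed integer seed.
#' @param num.trees forest size per evaluation.
#' @return a `predictor_set` with `id = "rfe"`, the selected columns and the
#'   full ranking.
#' @export
rfe_rank <- function(X, y, folds = 5L, repeats = 5L, seed = 1L,
                     num.trees = 200L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("oks_q%02d", seq_len(ncol(X)))
  if (length(unique(y)) < 2L) stop("degenerate outcome", call. = FALSE)
  p <- ncol(X)
  yf <- factor(y)
  set.seed(seed)
  acc <- matrix(NA_real_, folds * repeats, p)
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(as.integer(yf), folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- fold_id != f
      if (length(unique(yf[tr])) < 2L) next
      rank_f <- rf_ranking(X[tr, , drop = FALSE], yf[tr],
                           seed = seed + row, num.trees = num.trees)
      for (s in seq_len(p)) {
        keep <- rank_f[seq_len(s)]
        rf <- ranger::ranger(x = X[tr, keep, drop = FALSE], y = yf[tr],
                             num.trees = num.trees, num.threads = 1L,
                             seed = seed + row, verbose = FALSE)
        pred <- stats::predict(rf, data = X[!tr, keep, drop = FALSE],
                               num.threads = 1L)$predictions
        acc[row, s] <- mean(pred == yf[!tr])
      }
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best_size <- which.max(mean_acc * (1 + 1e-12) - seq_len(p) * 1e-9)
  ranking <- rf_ranking(X, yf, seed = seed, num.trees = num.trees)
  new_predictor_set("rfe", ranking[seq_len(best_size)],
                    ranking = structure(ranking, sizes_accuracy = mean_acc))
}

# Impurity-importance ranking of all items from one classification forest.
rf_ranking <- function(X, yf, seed, num.trees) {
  rf <- ranger::ranger(x = X, y = yf, num.trees = num.trees,
                       importance = "impurity", num.threads = 1L,
                       seed = seed, verbose = FALSE)
  names(sort(rf$variable.importance, decreasing = TRUE))
}

#' Model-based important predictors
#'
#' Retains the items each family's own importance measure singles out:
#' absolute standardized slopes above their mean for the cumulative family,
#' nonzero slopes at the selected penalty for the penalized family, and
#' positive impurity-gain sums for the tree and forest families. When a
#' family marks no item (e.g. a fully shrunk lasso), the set falls back to
#' all items with a warning.
#'
#' @param family one of `"cumulative"`, `"penalized"`, `"ocart"`,
#'   `"oforest"`.
#' @param X n x 12 item matrix.
#' @param y one ordinal EQ domain.
#' @param seed integer seed (tree/forest families).
#' @return a `predictor_set` with `id = "model_based"`.
#' @export
model_based_importance <- function(family = c("cumulative", "penalized",
                                              "ocart", "oforest"),
                                   X, y, seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("oks_q%02d", seq_len(ncol(X)))
  imp <- switch(family,
    cumulative = {
      fit <- fit_cumulative(X, y, parallel = TRUE, link = "logit")
      if (!fit$converged) stop("base cumulative model did not converge",
                               call. = FALSE)
      abs(fit$beta) * apply(X, 2L, stats::sd)
    },
    penalized = {
      # BIC screen: consistent selection gives a sparser importance set
      fit <- fit_penalized(X, y, alpha = "lasso", criterion = "BIC",
                           link = "logit")
      abs(fit$beta)
    },
    ocart = {
      fit <- fit_ocart(X, y, cp = 0.001, split_cost = "quadratic",
                       prune_rule = "misclassification_rate")
      ocart_importance(fit)
    },
    oforest = {
      fit <- fit_oforest(X, y, nsets = 20L, ntreeperdiv = 50L,
                         ntreefinal = 200L, seed = seed)
      oforest_importance(fit)
    })
  keep <- if (family == "cumulative") imp > mean(imp) else imp > 0
  ranking <- names(sort(imp, decreasing = TRUE))
  if (!any(keep)) {
    warning("no item passed the ", family,
            " importance screen; falling back to all items")
    return(new_predictor_set("model_based", colnames(X), ranking = ranking))
  }
  new_predictor_set("model_based", ranking[seq_len(sum(keep))],
                    ranking = structure(ranking, importance = imp))
}

#' Principal-component predictor set
#'
#' Items are centered and scaled, components extracted from the correlation
#' structure, and the smallest number of leading components whose cumulative
#' explained variance reaches 90% is retained. The fitted transform is
#' reusable on validation data without refitting.
#'
#' @param X n x 12 item matrix (n > 12; no constant columns).
#' @param var_target cumulative explained-variance target (default 0.90).
#' @return a `predictor_set` with `id = "pca"` and a transform.
#' @export
pca_preprocess <- function(X, var_target = 0.90) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("oks_q%02d", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) stop("need more rows than items for PCA",
                               call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant item column: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumvar >= var_target)[1L]
  cols <- colnames(pc$rotation)[seq_len(k)]
  new_predictor_set("pca", cols,
                    transform = list(source = colnames(X),
                                     center = pc$center, scale = pc$scale,
                                     rotation = pc$rotation,
                                     explained = cumvar))
}

#' Build the four predictor sets for one EQ domain
#'
#' @param oks_items n x 12 item matrix (estimation sample).
#' @param y the domain's ordinal levels.
#' @param family model family the sets will feed (the model-based set is
#'   family-specific).
#' @param seed integer seed.
#' @param rfe_folds,rfe_repeats RFE cross-validation geometry.
#' @return named list of four `predictor_set`s: `all`, `rfe`,
#'   `model_based`, `pca`.
#' @export
build_predictor_sets <- function(oks_items, y, family = "cumulative",
                                 seed = 1L, rfe_folds = 5L,
                                 rfe_repeats = 5L) {
  list(all = all_items_set(colnames(oks_items)),
       rfe = rfe_rank(oks_items, y, folds = rfe_folds,
                      repeats = rfe_repeats, seed = derive_seed(seed, "rfe")),
       model_based = model_based_importance(family, oks_items, y,
                                            seed = derive_seed(seed, "mbi")),
       pca = pca_preprocess(oks_items))
}

#' Build tournament predictor sets (model-based set per family)
#'
#' Like [build_predictor_sets()] but the `model_based` element is a named
#' list with one set per model family, since each family uses its own
#' built-in importance measure.
#'
#' @inheritParams build_predictor_sets
#' @param families model families to build model-based sets for.
#' @return named list: `all`, `rfe`, `model_based` (list per family),
#'   `pca`.
#' @export
build_tournament_sets <- function(oks_items, y, seed = 1L, rfe_folds = 5L,
                                  rfe_repeats = 5L,
                                  families = c("cumulative", "penalized",
                                               "ocart", "oforest")) {
  mb <- lapply(stats::setNames(families, families), function(fm)
    model_based_importance(fm, oks_items, y,
                           seed = derive_seed(seed, paste0("mbi_", fm))))
  list(all = all_items_set(colnames(oks_items)),
       rfe = rfe_rank(oks_items, y, folds = rfe_folds,
                      repeats = rfe_repeats, seed = derive_seed(seed, "rfe")),
       model_based = mb,
       pca = pca_preprocess(oks_items))
}
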