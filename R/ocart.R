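## Cost-sensitive ordinal classification trees. Scores are assigned to the
## ordered outcome levels and node impurity is the generalized Gini index,
## which weights a misclassification between levels i and j by |s_i - s_j|
## (absolute) or (s_i - s_j)^2 (quadratic). The complexity parameter cp
## follows cost-complexity semantics: it gates the scaled impurity gain of
## every split during growth and sets the weakest-link pruning threshold on
## the pruning risk scale (misclassification rate, or misclassification
## cost under the same generalized costs).

#' Generalized Gini impurity of a node
#'
#' \deqn{i(t) = \sum_i \sum_j C(i,j) \, p_i p_j} with cost
#' `C(i,j) = |s_i - s_j|` (`"absolute"`) or `(s_i - s_j)^2` (`"quadratic"`)
#' over the ordered level scores `s`.
#'
#' @param p vector of level proportions (sums to 1) or counts.
#' @param scores numeric scores of the ordered levels (default 1..K).
#' @param split_cost `"absolute"` or `"quadratic"`.
#' @return the impurity value.
#' @export
gini_impurity <- function(p, scores = seq_along(p),
                          split_cost = c("absolute", "quadratic")) {
  split_cost <- match.arg(split_cost)
  p <- p / sum(p)
  C <- cost_matrix(scores, split_cost)
  drop(p %*% C %*% p)
}

cost_matrix <- function(scores, split_cost) {
  D <- outer(scores, scores, "-")
  if (split_cost == "absolute") abs(D) else D^2
}

# Vectorized impurity for a matrix of count rows (m x K).
impurity_rows <- function(counts, C) {
  n <- rowSums(counts)
  n[n == 0] <- 1
  P <- counts / n
  rowSums((P %*% C) * P)
}

# Best split of one node. counts_total: level counts at the node.
# Returns NULL or list(var, point, gain_abs) where gain_abs is
# n_t * i(t) - n_L * i(L) - n_R * i(R) (unscaled, in count units).
best_split <- function(X, y_idx, K, C, minbucket) {
  n_t <- length(y_idx)
  node_counts <- tabulate(y_idx, K)
  i_t <- gini_counts(node_counts, C)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    Y <- matrix(0L, n_t, K)
    Y[cbind(seq_len(n_t), y_idx[ord])] <- 1L
    cum <- apply(Y, 2L, cumsum)           # cumulative level counts
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
    cut_ok <- which(diff(xs) > 0)         # split between distinct values
    cut_ok <- cut_ok[cut_ok >= minbucket & (n_t - cut_ok) >= minbucket]
    if (!length(cut_ok)) next
    left <- cum[cut_ok, , drop = FALSE]
    right <- rep(node_counts, each = length(cut_ok)) - left
    dim(right) <- dim(left)
    nl <- cut_ok
    nr <- n_t - cut_ok
    gain <- n_t * i_t - nl * impurity_rows(left, C) -
      nr * impurity_rows(right, C)
    k <- which.max(gain)
    if (is.null(best) || gain[k] > best$gain_abs) {
      best <- list(var = j, point = (xs[cut_ok[k]] + xs[cut_ok[k] + 1L]) / 2,
                   gain_abs = gain[k])
    }
  }
  best
}

gini_counts <- function(counts, C) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  drop(p %*% C %*% p)
}

grow_node <- function(X, y_idx, K, C, cp, n_root, i_root, minsplit,
                      minbucket, depth, maxdepth) {
  counts <- tabulate(y_idx, K)
  node <- list(n = length(y_idx), counts = counts)
  if (length(y_idx) < minsplit || depth >= maxdepth ||
      sum(counts > 0) < 2L || i_root <= 0) {
    return(node)
  }
  sp <- best_split(X, y_idx, K, C, minbucket)
  if (is.null(sp)) return(node)
  gain_scaled <- sp$gain_abs / (n_root * i_root)
  if (gain_scaled < cp) return(node)
  go_left <- X[, sp$var] <= sp$point
  node$split <- list(var = sp$var, point = sp$point, gain = gain_scaled)
  node$left <- grow_node(X[go_left, , drop = FALSE], y_idx[go_left], K, C,
                         cp, n_root, i_root, minsplit, minbucket,
                         depth + 1L, maxdepth)
  node$right <- grow_node(X[!go_left, , drop = FALSE], y_idx[!go_left], K, C,
                          cp, n_root, i_root, minsplit, minbucket,
                          depth + 1L, maxdepth)
  node
}

is_leaf <- function(node) is.null(node$split)

n_leaves <- function(node) {
  if (is_leaf(node)) 1L else n_leaves(node$left) + n_leaves(node$right)
}

# Node prediction and risk under the pruning rule. For the rate rule the
# prediction is the modal level (ties toward the lower level) and the risk
# the misclassified count; for the cost rule the prediction minimizes the
# expected generalized cost and the risk is that expected cost times n.
node_pred_risk <- function(counts, C, prune_rule) {
  if (prune_rule == "misclassification_rate") {
    pred <- which.max(counts)
    risk <- sum(counts) - counts[pred]
  } else {
    exp_cost <- drop(C %*% counts)
    pred <- which.min(exp_cost)
    risk <- exp_cost[pred]
  }
  list(pred = pred, risk = risk)
}

subtree_risk <- function(node, C, prune_rule) {
  if (is_leaf(node)) return(node_pred_risk(node$counts, C, prune_rule)$risk)
  subtree_risk(node$left, C, prune_rule) +
    subtree_risk(node$right, C, prune_rule)
}

# Remove subtrees whose own split gain falls below cp (depth-first gate:
# equivalent to having grown the tree with that cp).
snip_tree <- function(node, cp) {
  if (is_leaf(node)) return(node)
  if (node$split$gain < cp) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
    return(node)
  }
  node$left <- snip_tree(node$left, cp)
  node$right <- snip_tree(node$right, cp)
  node
}

# Weakest-link cost-complexity pruning at threshold cp (relative to the
# root risk of the pruning rule).
prune_tree <- function(node, C, prune_rule, cp) {
  r_root <- node_pred_risk(node$counts, C, prune_rule)$risk
  if (r_root <= 0) return(collapse_to_leaf(node))
  repeat {
    links <- weakest_links(node, C, prune_rule)
    if (!length(links$g)) break
    m <- min(links$g)
    if (m / r_root >= cp) break
    node <- collapse_at(node, links$path[links$g <= m + 1e-12])
  }
  node
}

collapse_to_leaf <- function(node) {
  node$split <- NULL; node$left <- NULL; node$right <- NULL
  node
}

# Enumerate internal nodes with their weakest-link statistic
# g = (R(t) - R(T_t)) / (leaves - 1), in risk-count units.
weakest_links <- function(node, C, prune_rule, path = "") {
  if (is_leaf(node)) return(list(g = numeric(0), path = character(0)))
  r_here <- node_pred_risk(node$counts, C, prune_rule)$risk
  r_sub <- subtree_risk(node, C, prune_rule)
  nl <- n_leaves(node)
  g <- (r_here - r_sub) / (nl - 1L)
  l <- weakest_links(node$left, C, prune_rule, paste0(path, "L"))
  r <- weakest_links(node$right, C, prune_rule, paste0(path, "R"))
  list(g = c(g, l$g, r$g), path = c(path, l$path, r$path))
}

collapse_at <- function(node, paths) {
  if ("" %in% paths) return(collapse_to_leaf(node))
  lp <- sub("^L", "", paths[startsWith(paths, "L")])
  rp <- sub("^R", "", paths[startsWith(paths, "R")])
  if (!is_leaf(node)) {
    if (length(lp)) node$left <- collapse_at(node$left, lp)
    if (length(rp)) node$right <- collapse_at(node$right, rp)
  }
  node
}

#' Fit a cost-sensitive ordinal classification tree
#'
#' Recursive binary splitting minimizes the generalized Gini impurity with
#' misclassification costs growing with the distance between ordered levels.
#' A split is kept only when its impurity gain, scaled by the root impurity,
#' reaches `cp`; the grown tree is then pruned back by weakest-link
#' cost-complexity pruning at the same `cp` on the scale of the chosen
#' pruning risk.
#'
#' @inheritParams fit_cumulative
#' @param cp complexity parameter, >= 0.
#' @param split_cost `"absolute"` or `"quadratic"` misclassification cost in
#'   the generalized Gini index.
#' @param prune_rule `"misclassification_rate"` (all errors weighted
#'   equally) or `"misclassification_cost"` (errors weighted by the
#'   generalized costs).
#' @param minsplit,minbucket,maxdepth usual tree controls.
#' @param scores numeric scores for the ordered levels (defaults to 1..K).
#' @return object of class `oksmap_ocart` (also `oksmap_fit`).
#' @export
fit_ocart <- function(X, y, cp = 0.01,
                      split_cost = c("absolute", "quadratic"),
                      prune_rule = c("misclassification_rate",
                                     "misclassification_cost"),
                      minsplit = 20L, minbucket = 7L, maxdepth = 30L,
                      scores = NULL) {
  split_cost <- match.arg(split_cost)
  prune_rule <- match.arg(prune_rule)
  if (cp < 0) stop("cp must be >= 0", call. = FALSE)
  X <- as.matrix(X)
  prep <- encode_outcome(y)
  if (prep$K < 2L) stop("outcome has a single level; nothing to model",
                        call. = FALSE)
  scores <- scores %||% seq_len(prep$K)
  C <- cost_matrix(scores, split_cost)
  i_root <- gini_counts(tabulate(prep$idx, prep$K), C)
  tree <- grow_node(X, prep$idx, prep$K, C, cp, nrow(X), i_root,
                    minsplit, minbucket, 0L, maxdepth)
  tree <- prune_tree(tree, C, prune_rule, cp)
  structure(list(family = "ocart", cp = cp, split_cost = split_cost,
                 prune_rule = prune_rule, tree = tree, cost = C,
                 scores = scores, levels = prep$levels, converged = TRUE,
                 n = nrow(X), p = ncol(X), xnames = colnames(X)),
            class = c("oksmap_ocart", "oksmap_fit"))
}

route_rows <- function(node, X, idx, out, C, prune_rule) {
  if (is_leaf(node)) {
    out[idx] <- node_pred_risk(node$counts, C, prune_rule)$pred
    return(out)
  }
  go_left <- X[idx, node$split$var] <= node$split$point
  out <- route_rows(node$left, X, idx[go_left], out, C, prune_rule)
  route_rows(node$right, X, idx[!go_left], out, C, prune_rule)
}

#' @rdname predict.oksmap_cumulative
#' @export
predict.oksmap_ocart <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- check_newdata(object, X)
  idx <- route_rows(object$tree, X, seq_len(nrow(X)),
                    integer(nrow(X)), object$cost, object$prune_rule)
  if (type == "class") return(decode_levels(idx, object$levels))
  # leaf level proportions as a crude probability surrogate
  P <- matrix(0, nrow(X), length(object$levels))
  for (i in seq_len(nrow(X))) P[i, idx[i]] <- 1
  colnames(P) <- as.character(object$levels)
  P
}

# Summed scaled split gains per predictor (importance for the model-based
# predictor set).
ocart_importance <- function(fit) {
  imp <- numeric(fit$p)
  rec <- function(node) {
    if (is_leaf(node)) return(invisible())
    imp[node$split$var] <<- imp[node$split$var] + node$split$gain
    rec(node$left); rec(node$right)
  }
  rec(fit$tree)
  names(imp) <- fit$xnames %||% paste0("x", seq_len(fit$p))
  imp
}
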