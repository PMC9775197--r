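## Interpretable activity rules: depth-capped decision tree on descriptors,
## anchor-style conjunctive rule extraction with greedy pruning, rule
## metrics, and Friedman one-vs-all interaction scores.

#' Train the activity decision tree
#'
#' Gini-impurity binary classification tree over the descriptor matrix with
#' a capped depth (default 10) and otherwise memorization-friendly settings
#' (no complexity pruning, minimum split size 2). The tree is a pattern
#' extraction device for [extract_rules()], not a predictive model: it is
#' deliberately fit to the full dataset and reports its training accuracy.
#'
#' @param descriptors data.frame of numeric descriptors.
#' @param classes factor/character of `active` / `inactive` labels.
#' @param max_depth depth cap (default 10).
#' @param seed RNG seed (rpart's fit is deterministic; the seed is fixed for
#'   reproducibility of any surrogate randomness).
#' @return object of class `urea_tree`: list with `fit` (the rpart tree),
#'   `training_accuracy`, `feature_names`, `classes`.
#' @export
train_activity_tree <- function(descriptors, classes, max_depth = 10,
                                seed = 17) {
  classes <- factor(as.character(classes), levels = c("active", "inactive"))
  if (length(unique(classes)) < 2)
    stop("need both activity classes to train", call. = FALSE)
  stopifnot(nrow(descriptors) == length(classes))
  df <- cbind(descriptors, .class = classes)
  set.seed(seed)
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = 0, minsplit = 2,
                        minbucket = 1, xval = 0, maxcompete = 0,
                        maxsurrogate = 0, usesurrogate = 0))
  pred <- stats::predict(fit, df, type = "class")
  structure(list(fit = fit, training_accuracy = mean(pred == classes),
                 feature_names = names(descriptors), classes = classes),
            class = "urea_tree")
}

#' @export
print.urea_tree <- function(x, ...) {
  cat(sprintf("Activity decision tree (%d leaves, training accuracy %.3f)\n",
              sum(x$fit$frame$var == "<leaf>"), x$training_accuracy))
  invisible(x)
}

# root-to-leaf condition lists: every path as (feature, op in {"<", ">="},
# threshold). rpart node numbering: children of node k are 2k, 2k+1.
.tree_paths <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  splits <- fit$splits
  # with maxcompete = maxsurrogate = 0 there is one splits row per non-leaf,
  # in frame order
  split_row <- integer(nrow(frame)); split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  leaf_paths <- list()
  for (li in which(is_leaf)) {
    node <- nodes[li]
    conds <- list()
    k <- node
    while (k > 1) {
      parent <- k %/% 2
      pi <- which(nodes == parent)
      sr <- split_row[pi]
      var <- as.character(frame$var[pi])
      cut <- splits[sr, "index"]
      ncat <- splits[sr, "ncat"]
      left <- (k %% 2 == 0)
      # ncat = -1: left child is var < cut; ncat = +1: left child is var >= cut
      op <- if ((ncat < 0) == left) "<" else ">="
      conds[[length(conds) + 1]] <- list(feature = var, op = op,
                                         threshold = unname(cut))
      k <- parent
    }
    pred_class <- c("active", "inactive")[frame$yval[li]]
    leaf_paths[[length(leaf_paths) + 1]] <-
      list(node = node, conditions = rev(conds), predicted_class = pred_class)
  }
  leaf_paths
}

# rows of `data` satisfying a conjunctive condition list
.rule_cover <- function(conditions, data) {
  keep <- rep(TRUE, nrow(data))
  for (cond in conditions) {
    x <- data[[cond$feature]]
    keep <- keep & if (cond$op == "<") x < cond$threshold else x >= cond$threshold
  }
  keep
}

# human-readable condition rendering; integer count descriptors get the
# "= 0" / "> 0" style (a cut at 0.5 separates 0 from >= 1)
.render_condition <- function(cond, integer_feature) {
  thr <- cond$threshold
  if (integer_feature) {
    if (cond$op == "<") {
      hi <- ceiling(thr) - 1
      if (hi == 0) sprintf("%s = 0", cond$feature)
      else sprintf("%s <= %d", cond$feature, hi)
    } else {
      lo <- ceiling(thr)
      if (lo == 1) sprintf("%s > 0", cond$feature)
      else sprintf("%s >= %d", cond$feature, lo)
    }
  } else {
    sprintf("%s %s %.4g", cond$feature, ifelse(cond$op == "<", "<=", ">"), thr)
  }
}

#' Extract anchor-style conjunctive rules from the activity tree
#'
#' Each training compound's root-to-leaf path becomes an IF-THEN rule, which
#' is then greedily pruned: conditions are dropped one at a time — always
#' the drop that best preserves empirical precision on the dataset — for as
#' long as precision stays at or above `precision_threshold` (anchor-style
#' sufficiency on the actual data; no perturbation sampling). Duplicate
#' rules are merged and ranked by coverage. Leaf rules whose full path never
#' reaches the threshold are kept but flagged `below_threshold`.
#'
#' @param tree `urea_tree` from [train_activity_tree()].
#' @param descriptors the descriptor data.frame the tree was trained on.
#' @param classes activity classes for the same rows.
#' @param precision_threshold minimum empirical precision (default 0.80).
#' @return data.frame of class `urea_rules`: `rule_id`, `conditions`
#'   (rendered string), `predicted_class`, `n_active`, `n_inactive`,
#'   `n_total`, `precision_pct`, `below_threshold`; the parsed condition
#'   lists are attached as attribute `"condition_list"`.
#' @export
extract_rules <- function(tree, descriptors, classes,
                          precision_threshold = 0.80) {
  stopifnot(inherits(tree, "urea_tree"))
  classes <- as.character(classes)
  paths <- .tree_paths(tree$fit)
  int_feats <- vapply(descriptors, function(x) all(x == round(x)), logical(1))

  prune_path <- function(conds, pred) {
    repeat {
      if (length(conds) <= 1) break
      precs <- vapply(seq_along(conds), function(j) {
        cov <- .rule_cover(conds[-j], descriptors)
        sum(classes[cov] == pred) / sum(cov)
      }, numeric(1))
      jbest <- which.max(precs)
      if (precs[jbest] >= precision_threshold) conds <- conds[-jbest]
      else break
    }
    conds
  }

  seen <- character(0)
  rows <- list(); cond_lists <- list()
  for (p in paths) {
    cov0 <- .rule_cover(p$conditions, descriptors)
    if (!any(cov0)) next
    prec0 <- sum(classes[cov0] == p$predicted_class) / sum(cov0)
    conds <- if (prec0 >= precision_threshold)
      prune_path(p$conditions, p$predicted_class) else p$conditions
    rendered <- vapply(conds, function(cond)
      .render_condition(cond, int_feats[[cond$feature]]), character(1))
    key <- paste(p$predicted_class, paste(sort(rendered), collapse = "; "))
    if (key %in% seen) next
    seen <- c(seen, key)
    cov <- .rule_cover(conds, descriptors)
    n_act <- sum(classes[cov] == "active")
    n_inact <- sum(classes[cov] == "inactive")
    prec <- rule_precision(n_act, n_inact, p$predicted_class)
    rows[[length(rows) + 1]] <- data.frame(
      conditions = paste(rendered, collapse = "; "),
      predicted_class = p$predicted_class,
      n_active = n_act, n_inactive = n_inact, n_total = n_act + n_inact,
      precision_pct = prec,
      below_threshold = prec < 100 * precision_threshold,
      stringsAsFactors = FALSE)
    cond_lists[[length(cond_lists) + 1]] <- conds
  }
  out <- do.call(rbind, rows)
  o <- order(-out$n_total, out$conditions)
  out <- out[o, , drop = FALSE]
  out <- cbind(rule_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "condition_list") <- cond_lists[o]
  class(out) <- c("urea_rules", class(out))
  out
}

#' @export
print.urea_rules <- function(x, ...) {
  cat(sprintf("%d conjunctive activity rules (%d at/above precision threshold)\n",
              nrow(x), sum(!x$below_threshold)))
  NextMethod()
}

#' Precision of a rule from its coverage counts
#'
#' The printed-precision convention: percentage of covered compounds
#' belonging to the rule's predicted class, to one decimal, halves rounded
#' up.
#'
#' @param n_active,n_inactive covered compounds per class.
#' @param predicted_class `"active"` or `"inactive"`.
#' @return precision in percent (one decimal), `NA` for empty coverage.
#' @export
#' @examples
#' rule_precision(15, 240, "inactive")  # 94.1
rule_precision <- function(n_active, n_inactive, predicted_class) {
  n <- n_active + n_inactive
  if (n == 0) return(NA_real_)
  hits <- if (predicted_class == "active") n_active else n_inactive
  round_half_up(100 * hits / n, 1)
}

#' Evaluate a rule's conditions on a dataset
#'
#' @param conditions list of `(feature, op, threshold)` conditions (see the
#'   `"condition_list"` attribute of [extract_rules()]).
#' @param descriptors descriptor data.frame.
#' @param classes activity classes.
#' @param predicted_class the class the rule asserts.
#' @return list `n_active`, `n_inactive`, `n_total`, `precision_pct`
#'   (flagged `NA` when nothing is covered).
#' @export
rule_metrics <- function(conditions, descriptors, classes, predicted_class) {
  cov <- .rule_cover(conditions, descriptors)
  n_act <- sum(classes[cov] == "active")
  n_inact <- sum(classes[cov] == "inactive")
  list(n_active = n_act, n_inactive = n_inact, n_total = n_act + n_inact,
       precision_pct = rule_precision(n_act, n_inact, predicted_class))
}

#' Friedman one-vs-all interaction statistic
#'
#' Measures how strongly a feature interacts with all remaining features in
#' a fitted model's prediction surface: the variance of the difference
#' between the centered full partial-dependence and its additive
#' decomposition (feature term + rest term), normalized by the variance of
#' the full partial dependence, clipped to `[0, 1]`. 0 means the feature
#' enters the model additively; larger values mean its effect depends on
#' the other features.
#'
#' @param model a `urea_tree`, or any model usable via `predict_fun`.
#' @param descriptors descriptor data.frame (the evaluation distribution).
#' @param feature feature name.
#' @param predict_fun function(data.frame) -> numeric prediction; defaults
#'   to the tree's probability of the active class.
#' @param max_rows evaluation subsample cap (default 500; partial
#'   dependences cost O(n^2) model calls).
#' @param seed subsampling seed.
#' @return H statistic in `[0, 1]`.
#' @export
feature_interaction <- function(model, descriptors, feature,
                                predict_fun = NULL, max_rows = 500,
                                seed = 1) {
  if (is.null(predict_fun)) {
    stopifnot(inherits(model, "urea_tree"))
    predict_fun <- function(d) stats::predict(model$fit, d)[, "active"]
  }
  stopifnot(feature %in% names(descriptors))
  n <- nrow(descriptors)
  if (n > max_rows) {
    set.seed(seed)
    descriptors <- descriptors[sample.int(n, max_rows), , drop = FALSE]
    n <- max_rows
  }
  # partial dependences over the empirical distribution; anchor-major grids
  # of n^2 rows, donor index cycling fastest
  f_full <- predict_fun(descriptors)
  # PD of `feature`: anchor supplies the feature value, donors the rest
  grid_j <- descriptors[rep(seq_len(n), times = n), , drop = FALSE]
  grid_j[[feature]] <- rep(descriptors[[feature]], each = n)
  pd_j <- colMeans(matrix(predict_fun(grid_j), n, n))
  # PD of the complement: anchor supplies the rest, donors the feature
  grid_rest <- descriptors[rep(seq_len(n), each = n), , drop = FALSE]
  grid_rest[[feature]] <- rep(descriptors[[feature]], times = n)
  pd_rest <- colMeans(matrix(predict_fun(grid_rest), n, n))

  ctr <- function(x) x - mean(x)
  num <- sum((ctr(f_full) - ctr(pd_j) - ctr(pd_rest))^2)
  den <- sum(ctr(f_full)^2)
  if (den < 1e-12) return(0)
  min(max(num / den, 0), 1)
}
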