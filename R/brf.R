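## Balanced random forest built from scratch: per-tree class-balanced
## bootstraps (each tree sees n_min samples drawn with replacement from each
## class), CART trees with gini or entropy impurity, and random feature
## subsampling per node.

#' Class-balanced bootstrap indices
#'
#' Draws, with replacement, `n_min` indices from each class where `n_min`
#' is the minority class size, so every bootstrap has equal class counts.
#'
#' @param labels 0/1 vector with both classes present.
#' @param seed RNG seed.
#' @return integer index vector of length `2 * n_min`.
#' @export
balanced_bootstrap <- function(labels, seed = 1L) {
  cls <- unique(labels)
  if (length(cls) < 2L) stop("both classes must be present")
  n_min <- min(table(labels))
  with_seed(seed, {
    unlist(lapply(cls, function(g) {
      idx <- which(labels == g)
      idx[sample.int(length(idx), n_min, replace = TRUE)]
    }))
  })
}

impurity_fun <- function(criterion) {
  if (criterion == "gini") function(p) 2 * p * (1 - p)
  else function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

## Fit one CART tree; returns a flat node table (parallel vectors).
fit_tree <- function(X, y, max_depth = Inf, min_samples_split = 2L,
                     min_samples_leaf = 1L, max_features = "sqrt",
                     criterion = "gini") {
  imp <- impurity_fun(criterion)
  p <- ncol(X)
  mtry <- if (identical(max_features, "sqrt")) max(1L, floor(sqrt(p)))
          else max(1L, floor(as.numeric(max_features) * p))
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = NA_integer_,
                                         threshold = NA_real_, left = NA_integer_,
                                         right = NA_integer_, prob = NA_real_)
    length(nodes)
  }
  grow <- function(idx, depth) {
    id <- new_node()
    yy <- y[idx]
    prob <- mean(yy)
    nodes[[id]]$prob <<- prob
    n <- length(idx)
    if (n < min_samples_split || depth >= max_depth || prob == 0 || prob == 1)
      return(id)
    feats <- sample.int(p, mtry)
    best <- list(gain = 0)
    for (f in feats) {
      xv <- X[idx, f]
      ord <- order(xv)
      xs <- xv[ord]; ys <- yy[ord]
      cum_pos <- cumsum(ys)
      distinct <- which(diff(xs) > 0)
      if (!length(distinct)) next
      nl <- distinct
      ok <- nl >= min_samples_leaf & (n - nl) >= min_samples_leaf
      if (!any(ok)) next
      nl <- nl[ok]
      pl <- cum_pos[nl] / nl
      pr <- (sum(ys) - cum_pos[nl]) / (n - nl)
      gain <- imp(prob) - (nl * imp(pl) + (n - nl) * imp(pr)) / n
      j <- which.max(gain)
      if (gain[j] > best$gain + 1e-12) {
        cut_at <- nl[j]
        best <- list(gain = gain[j], feature = f,
                     threshold = (xs[cut_at] + xs[cut_at + 1]) / 2)
      }
    }
    if (best$gain <= 0) return(id)
    go_left <- X[idx, best$feature] <= best$threshold
    lid <- grow(idx[go_left], depth + 1L)
    rid <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_len(nrow(X)), 0L)
  nodes
}

predict_tree <- function(nodes, X) {
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (is.na(nd$feature)) return(nd$prob)
      id <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }, 0)
}

#' Balanced random forest hyperparameter grid
#'
#' Default grids: the knobs explored are tree depth, forest size, split and
#' leaf minima, per-node feature subsampling, bootstrap use and the split
#' criterion.
#'
#' @param max_depth list of depths (`Inf` = unlimited).
#' @param n_estimators forest sizes.
#' @param min_samples_split,min_samples_leaf split/leaf minima.
#' @param max_features `"sqrt"` or a fraction of features per node.
#' @param bootstrap must include `TRUE` (balanced bootstraps).
#' @param criterion `"gini"` and/or `"entropy"`.
#' @param cv_folds grid-search folds (default 5).
#' @param seed RNG seed.
#' @return object of class `brf_config`.
#' @export
brf_config <- function(max_depth = list(3, 5, Inf),
                       n_estimators = c(100L, 300L),
                       min_samples_split = c(2L, 5L),
                       min_samples_leaf = c(1L, 3L),
                       max_features = list("sqrt", 0.5),
                       bootstrap = TRUE,
                       criterion = c("gini", "entropy"),
                       cv_folds = 5L, seed = 1L) {
  stopifnot(all(unlist(n_estimators) >= 1), isTRUE(all(bootstrap)))
  structure(list(max_depth = max_depth, n_estimators = n_estimators,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf,
                 max_features = max_features, bootstrap = TRUE,
                 criterion = criterion, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "brf_config")
}

fit_brf_fixed <- function(X, y, pars, seed) {
  trees <- vector("list", pars$n_estimators)
  for (t in seq_len(pars$n_estimators)) {
    bs <- balanced_bootstrap(y, derive_seed(seed, paste0("bs", t)))
    trees[[t]] <- with_seed(derive_seed(seed, paste0("tree", t)),
      fit_tree(X[bs, , drop = FALSE], y[bs],
               max_depth = pars$max_depth,
               min_samples_split = pars$min_samples_split,
               min_samples_leaf = pars$min_samples_leaf,
               max_features = pars$max_features,
               criterion = pars$criterion))
  }
  structure(list(trees = trees, pars = pars, features = colnames(X)),
            class = "pr_brf")
}

#' Predicted positive-class probabilities of a balanced random forest
#' @param object a fitted `pr_brf`.
#' @param newdata matrix with the training feature columns.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.pr_brf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features))
    newdata <- newdata[, object$features, drop = FALSE]
  rowMeans(vapply(object$trees, function(tr) predict_tree(tr, newdata),
                  numeric(nrow(newdata))))
}

brf_grid <- function(config) {
  grid <- expand.grid(md = seq_along(config$max_depth),
                      ne = seq_along(config$n_estimators),
                      mss = seq_along(config$min_samples_split),
                      msl = seq_along(config$min_samples_leaf),
                      mf = seq_along(config$max_features),
                      cr = seq_along(config$criterion))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    list(max_depth = config$max_depth[[g$md]],
         n_estimators = config$n_estimators[[g$ne]],
         min_samples_split = config$min_samples_split[[g$mss]],
         min_samples_leaf = config$min_samples_leaf[[g$msl]],
         max_features = config$max_features[[g$mf]],
         criterion = config$criterion[[g$cr]])
  })
}

#' Grid-searched balanced random forest
#'
#' Stratified `cv_folds`-fold cross-validated AUC over the hyperparameter
#' grid; the best point (ties to the first grid entry) is refit on the full
#' training set. Deterministic under `config$seed`.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param config a [brf_config()].
#' @return fitted `pr_brf` with `cv_results` and `best_pars` attached.
#' @export
fit_brf <- function(X, y, config = brf_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), min(table(y)) >= config$cv_folds)
  grid <- brf_grid(config)
  fold <- stratified_folds(y, config$cv_folds, derive_seed(config$seed, "cv"))
  cv_auc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    aucs <- numeric(config$cv_folds)
    for (k in seq_len(config$cv_folds)) {
      tr <- which(fold != k); va <- which(fold == k)
      fit <- fit_brf_fixed(X[tr, , drop = FALSE], y[tr], grid[[gi]],
                           derive_seed(config$seed, paste0("g", gi, "k", k)))
      aucs[k] <- auc_rank(y[va], predict(fit, X[va, , drop = FALSE]))
    }
    cv_auc[gi] <- mean(aucs)
  }
  best <- which.max(cv_auc)
  model <- fit_brf_fixed(X, y, grid[[best]], derive_seed(config$seed, "final"))
  model$cv_results <- data.frame(grid_index = seq_along(grid), cv_auc = cv_auc)
  model$best_pars <- grid[[best]]
  model
}

#' Rank-statistic AUC (Mann-Whitney with midranks)
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion and ROC evaluation of a classifier on a test set
#'
#' Classes are predicted at probability threshold 0.5 (positive class =
#' deceased at one year). Reports counts, sensitivity, specificity, plain
#' and balanced accuracy, rank AUC and the ROC sweep.
#'
#' @param probs predicted positive-class probabilities.
#' @param labels 0/1 test labels (both classes required).
#' @param threshold classification cutoff, default 0.5.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, `balanced_accuracy`, `auc`, `roc` (data frame fpr/tpr).
#' @export
evaluate_classifier <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("AUC undefined: one-class test set")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  cuts <- sort(unique(c(-Inf, probs, Inf)), decreasing = TRUE)
  roc <- data.frame(
    fpr = vapply(cuts, function(ct) sum(probs >= ct & labels == 0), 0) / sum(labels == 0),
    tpr = vapply(cuts, function(ct) sum(probs >= ct & labels == 1), 0) / sum(labels == 1))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels),
       balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
       auc = auc_rank(labels, probs), roc = roc)
}
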