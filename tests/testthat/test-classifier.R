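test_that("balanced bootstraps draw n_min from each class, every tree", {
  y <- rep(c(0L, 1L), c(30, 10))
  for (s in 1:20) {
    bs <- balanced_bootstrap(y, seed = s)
    expect_length(bs, 20L)
    expect_equal(as.vector(table(y[bs])), c(10L, 10L))
  }
  # balanced input reduces to an ordinary half-size bootstrap per class
  yb <- rep(c(0L, 1L), each = 12)
  expect_equal(as.vector(table(yb[balanced_bootstrap(yb, 1)])), c(12L, 12L))
  expect_error(balanced_bootstrap(rep(1L, 10)), "both classes")
})

test_that("majority-class inclusion frequency matches the binomial closed form", {
  y <- rep(c(0L, 1L), c(30, 10))
  hits <- integer(30)
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    bs <- balanced_bootstrap(y, seed = s)
    hits <- hits + (seq_len(30) %in% bs)
  }
  p_incl <- 1 - (1 - 1 / 30)^10      # 10 draws among 30 majority items
  se_item <- sqrt(p_incl * (1 - p_incl) / n_rep)
  expect_lt(abs(mean(hits / n_rep) - p_incl), 3 * se_item / sqrt(30))
  expect_lt(max(abs(hits / n_rep - p_incl)), 5 * se_item)
})

# direct fixed-hyperparameter fit (no grid search) to keep the null fast
fit_brf_quick <- function(X, y, cfg) {
  petrad:::fit_brf_fixed(X, y,
    list(max_depth = 3, n_estimators = 15L, min_samples_split = 2L,
         min_samples_leaf = 1L, max_features = "sqrt", criterion = "gini"),
    seed = sample.int(1e6, 1))
}

test_that("a stump separates separable 1D data perfectly", {
  X <- matrix(c(1:10), ncol = 1, dimnames = list(NULL, "x"))
  y <- as.integer(X[, 1] > 5)
  cfg <- brf_config(max_depth = list(1), n_estimators = 20L,
                    min_samples_split = 2L, min_samples_leaf = 1L,
                    max_features = list("sqrt"), criterion = "gini",
                    cv_folds = 2L, seed = 1L)
  fit <- fit_brf(X, y, cfg)
  expect_equal(auc_rank(y, predict(fit, X)), 1)
})

test_that("grid search is deterministic under one seed", {
  set.seed(51)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] + rnorm(60, sd = 0.6) > 0)
  cfg <- brf_config(max_depth = list(3, Inf), n_estimators = 25L,
                    min_samples_split = 2L, min_samples_leaf = 1L,
                    max_features = list("sqrt"), criterion = c("gini", "entropy"),
                    cv_folds = 3L, seed = 9L)
  f1 <- fit_brf(X, y, cfg)
  f2 <- fit_brf(X, y, cfg)
  expect_identical(f1$best_pars, f2$best_pars)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("confusion metrics and their arithmetic identities", {
  # tp 9, fn 2, tn 6, fp 3 -> sens 0.82, spec 0.67, acc 0.75 (rounded)
  labels <- rep(c(1L, 1L, 0L, 0L), c(9, 2, 6, 3))
  probs <- rep(c(0.9, 0.1, 0.2, 0.8), c(9, 2, 6, 3))
  ev <- evaluate_classifier(probs, labels)
  expect_equal(c(ev$tp, ev$fn, ev$tn, ev$fp), c(9, 2, 6, 3))
  expect_equal(round(ev$sensitivity, 2), 0.82)
  expect_equal(round(ev$specificity, 2), 0.67)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$sensitivity, ev$tp / (ev$tp + ev$fn))
  expect_equal(ev$specificity, ev$tn / (ev$tn + ev$fp))
  # perfect predictor
  pv <- evaluate_classifier(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(pv$auc, 1)
  expect_equal(pv$fp + pv$fn, 0)
  expect_error(evaluate_classifier(c(0.2, 0.6), c(1, 1)), "one-class")
})

test_that("AUC equals the Mann-Whitney statistic and is monotone invariant", {
  set.seed(52)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(40)
    u <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
    expect_equal(auc_rank(y, s), u / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
    expect_equal(auc_rank(y, s), auc_rank(y, exp(s)))
  }
})

test_that("label-permutation null centres test AUC at one half", {
  set.seed(53)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c(0L, 1L), c(30, 20))
  cfg <- brf_config(max_depth = list(3), n_estimators = 15L,
                    min_samples_split = 2L, min_samples_leaf = 1L,
                    max_features = list("sqrt"), criterion = "gini",
                    cv_folds = 2L, seed = 2L)
  aucs <- vapply(1:100, function(i) {
    yp <- sample(y)
    fit <- fit_brf_quick(X[1:35, ], yp[1:35], cfg)
    auc_rank(yp[36:50], predict(fit, X[36:50, ]))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})
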