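## Survival workflow: stratified split, preprocessing, elastic-net Cox with
## nested cross-validated frequency-based selection of seven features, risk
## stratification and its evaluation.

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Stratified train/test split
#'
#' Splits subject indices into train and test, stratifying on the one-year
#' outcome jointly with the given categorical columns; when that produces a
#' stratum too small to allocate, it falls back to outcome-only
#' stratification with a warning. Test size is `round(n * test_fraction)`
#' allocated proportionally by largest remainder, so event proportions in
#' train and test differ by at most one subject's worth.
#'
#' @param data data frame with the outcome column and any stratification
#'   columns.
#' @param test_fraction held-out fraction, default 0.2.
#' @param seed RNG seed.
#' @param outcome_col binary outcome column name, default `one_year_dead`.
#' @param strat_cols additional categorical columns to stratify jointly.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L,
                             outcome_col = "one_year_dead",
                             strat_cols = character(0)) {
  n <- nrow(data)
  stopifnot(n >= 10L, test_fraction > 0, test_fraction < 1)
  m <- round(n * test_fraction)
  make_strata <- function(cols) {
    if (!length(cols)) factor(rep("all", n))
    else interaction(lapply(cols, function(cc) data[[cc]]), drop = TRUE)
  }
  strata <- make_strata(c(outcome_col, strat_cols))
  if (length(strat_cols) && min(table(strata)) < 2L) {
    warning("stratum of size < 2; falling back to outcome-only stratification")
    strata <- make_strata(outcome_col)
  }
  tab <- table(strata)
  quota_raw <- m * as.numeric(tab) / n
  quota <- floor(quota_raw)
  rem <- m - sum(quota)
  if (rem > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(tab), function(s) {
      members <- which(strata == names(tab)[s])
      if (quota[s] == 0) integer(0)
      else members[sample.int(length(members), quota[s])]
    }))
  })
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_len(n), test_idx), test = test_idx)
}

#' Min-max normalization and one-hot encoding learned on the training set
#'
#' Continuous columns are mapped with the training minimum and range
#' (constant columns map to 0 with a warning; test values outside the
#' training range extrapolate beyond \[0, 1\] without clipping). Factor or
#' character columns are expanded to one binary column per training-set
#' level; an unseen test category yields an all-zero row with a warning.
#'
#' @param train,test data frames with identical columns.
#' @param exclude column names to pass through untouched (ids, outcomes).
#' @return list with matrices `train` and `test` plus `params`.
#' @export
preprocess_tables <- function(train, test = NULL, exclude = character(0)) {
  cols <- setdiff(names(train), exclude)
  enc_one <- function(df, params) {
    pieces <- list()
    for (cc in cols) {
      p <- params[[cc]]
      if (p$type == "continuous") {
        v <- (df[[cc]] - p$min) / p$range
        if (p$range == 0) v <- rep(0, nrow(df))
        pieces[[cc]] <- matrix(v, ncol = 1, dimnames = list(NULL, cc))
      } else {
        x <- as.character(df[[cc]])
        unseen <- setdiff(unique(x), p$levels)
        if (length(unseen))
          warning("unseen categor", if (length(unseen) > 1) "ies" else "y",
                  " in '", cc, "': ", paste(unseen, collapse = ", "))
        mat <- vapply(p$levels, function(l) as.numeric(x == l),
                      numeric(length(x)))
        if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(x))
        colnames(mat) <- paste0(cc, "=", p$levels)
        pieces[[cc]] <- mat
      }
    }
    do.call(cbind, pieces)
  }
  params <- list()
  for (cc in cols) {
    v <- train[[cc]]
    if (is.numeric(v)) {
      rg <- max(v) - min(v)
      if (rg == 0) warning("constant continuous column '", cc, "' mapped to 0")
      params[[cc]] <- list(type = "continuous", min = min(v), range = rg)
    } else {
      params[[cc]] <- list(type = "categorical",
                           levels = sort(unique(as.character(v))))
    }
  }
  list(train = enc_one(train, params),
       test = if (!is.null(test)) enc_one(test, params),
       params = params)
}

pad_two_cols <- function(x) {
  if (ncol(x) >= 2L) return(list(x = x, padded = FALSE))
  list(x = cbind(x, .pad. = 0), padded = TRUE)
}

#' Elastic-net penalized Cox fit at fixed hyperparameters
#'
#' Minimizes the negative mean log partial likelihood (Breslow ties) plus
#' `alpha * (l1_ratio * |b|_1 + (1 - l1_ratio)/2 * |b|_2^2)`; covariates are
#' standardized internally for the penalty and coefficients are returned on
#' the original scale (delegated to glmnet).
#'
#' @param x numeric covariate matrix.
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param l1_ratio elastic-net mixing in \[0, 1\].
#' @param alpha penalty strength (glmnet's lambda).
#' @return named coefficient vector.
#' @export
fit_encox <- function(x, time, event, l1_ratio = 0.5, alpha = 0.01) {
  stopifnot(sum(event) >= 2, all(time > 0))
  x <- as.matrix(x)
  pd <- pad_two_cols(x)
  y <- survival::Surv(time, event)
  lam <- if (alpha > 0) c(alpha * 1.0001, alpha) else c(0.01, 0)
  fit <- glmnet::glmnet(pd$x, y, family = "cox", alpha = l1_ratio,
                        lambda = lam, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  b <- as.numeric(stats::coef(fit, s = alpha))
  names(b) <- colnames(pd$x)
  if (pd$padded) b <- b[setdiff(names(b), ".pad.")]
  b
}

#' Configuration of the nested elastic-net Cox selection workflow
#'
#' @param l1_ratio_grid elastic-net mixing values explored.
#' @param alpha_min_ratio_grid ratios of the smallest to largest penalty on
#'   the regularization path.
#' @param n_alphas path length per (l1_ratio, alpha_min_ratio).
#' @param outer_folds outer CV folds (default 5).
#' @param inner_folds folds of each inner CV (default 5).
#' @param inner_repeats inner CV repetitions with distinct seeds.
#' @param n_select number of features selected by frequency (default 7).
#' @param final_ridge tiny L2 penalty stabilising the selected-feature
#'   model.
#' @param seed RNG seed; all fold assignments derive from it.
#' @return object of class `encox_config`.
#' @export
encox_config <- function(l1_ratio_grid = c(0.1, 0.5, 0.9),
                         alpha_min_ratio_grid = c(0.01, 0.1),
                         n_alphas = 20L, outer_folds = 5L, inner_folds = 5L,
                         inner_repeats = 10L, n_select = 7L,
                         final_ridge = 1e-6, seed = 1L) {
  stopifnot(all(l1_ratio_grid >= 0), all(l1_ratio_grid <= 1),
            all(alpha_min_ratio_grid > 0), all(alpha_min_ratio_grid < 1),
            n_alphas >= 2L, outer_folds >= 2L, inner_folds >= 2L,
            inner_repeats >= 1L, n_select >= 1L)
  structure(list(l1_ratio_grid = l1_ratio_grid,
                 alpha_min_ratio_grid = alpha_min_ratio_grid,
                 n_alphas = as.integer(n_alphas),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 inner_repeats = as.integer(inner_repeats),
                 n_select = as.integer(n_select),
                 final_ridge = final_ridge, seed = as.integer(seed)),
            class = "encox_config")
}

## event-stratified fold assignment
stratified_folds <- function(event, k, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    for (g in unique(event)) {
      idx <- which(event == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Nested cross-validated elastic-net Cox feature selection
#'
#' The training cohort is split into `outer_folds` folds. Within each outer
#' training set, `inner_repeats` repetitions of `inner_folds`-fold CV grid
#' search over (`l1_ratio`, `alpha_min_ratio`, alpha-path) pick the best
#' hyperparameters by mean validation concordance; the model refit on the
#' full outer training set at those hyperparameters contributes its
#' non-zero coefficients, ranked by absolute value, to the repetition
#' record. The `n_select` most frequent features across repetitions form
#' that fold's model, fit with a tiny ridge penalty and scored on the outer
#' test fold. The fold with the best outer concordance is the winner and is
#' carried forward without refitting.
#'
#' @param x numeric matrix of candidate features (training subjects).
#' @param time,event survival outcome of the training subjects.
#' @param config an [encox_config()].
#' @return object of class `selection_result`: `selected`, `coefficients`,
#'   `frequencies` (winner fold), `outer_scores`, `winner_fold`, `folds`
#'   (per-fold details).
#' @export
nested_select <- function(x, time, event, config = encox_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  p <- ncol(x)
  y <- survival::Surv(time, event)
  outer_fold <- stratified_folds(event, config$outer_folds,
                                 derive_seed(config$seed, "outer"))
  folds <- vector("list", config$outer_folds)
  for (f in seq_len(config$outer_folds)) {
    otr <- which(outer_fold != f); ote <- which(outer_fold == f)
    freq <- setNames(numeric(p), colnames(x))
    coef_sums <- setNames(numeric(p), colnames(x))
    for (rep_i in seq_len(config$inner_repeats)) {
      sel <- inner_grid_select(x[otr, , drop = FALSE], time[otr], event[otr],
                               config, derive_seed(config$seed,
                                                   paste0("f", f, "r", rep_i)))
      if (length(sel$nonzero)) {
        freq[sel$nonzero] <- freq[sel$nonzero] + 1
        coef_sums[sel$nonzero] <- coef_sums[sel$nonzero] +
          abs(sel$coefficients[sel$nonzero])
      }
    }
    selected <- select_by_frequency(freq, coef_sums, config$n_select)
    b <- fit_encox(x[otr, selected, drop = FALSE], time[otr], event[otr],
                   l1_ratio = 0, alpha = config$final_ridge)
    sc <- as.numeric(x[ote, selected, drop = FALSE] %*% b)
    oc <- tryCatch(concordance_index(time[ote], event[ote], sc),
                   error = function(e) NA_real_)
    folds[[f]] <- list(selected = selected, coefficients = b,
                       frequencies = freq[order(-freq)],
                       outer_concordance = oc,
                       train_idx = otr, test_idx = ote)
  }
  outer_scores <- vapply(folds, `[[`, 0, "outer_concordance")
  if (all(is.na(outer_scores)))
    stop("no outer fold produced a comparable test pair")
  winner <- which.max(ifelse(is.na(outer_scores), -Inf, outer_scores))
  structure(list(selected = folds[[winner]]$selected,
                 coefficients = folds[[winner]]$coefficients,
                 frequencies = folds[[winner]]$frequencies,
                 outer_scores = outer_scores, winner_fold = winner,
                 folds = folds, config = config),
            class = "selection_result")
}

## one inner repetition: grid search by inner CV, refit, return nonzero set
inner_grid_select <- function(x, time, event, config, seed) {
  y <- survival::Surv(time, event)
  fold <- stratified_folds(event, config$inner_folds, seed)
  pd <- pad_two_cols(x)
  best <- list(c = -Inf)
  for (l1 in config$l1_ratio_grid) for (amr in config$alpha_min_ratio_grid) {
    path <- glmnet::glmnet(pd$x, y, family = "cox", alpha = max(l1, 1e-3),
                           nlambda = config$n_alphas, lambda.min.ratio = amr)
    lam <- path$lambda
    if (length(lam) < 2L) next
    cmat <- matrix(NA_real_, config$inner_folds, length(lam))
    for (k in seq_len(config$inner_folds)) {
      tr <- which(fold != k); va <- which(fold == k)
      if (sum(event[tr]) < 2L || sum(event[va]) < 1L) next
      fitk <- tryCatch(
        glmnet::glmnet(pd$x[tr, , drop = FALSE], y[tr, ], family = "cox",
                       alpha = max(l1, 1e-3), lambda = lam),
        error = function(e) NULL)
      if (is.null(fitk)) next
      pr <- predict(fitk, newx = pd$x[va, , drop = FALSE], s = lam)
      for (j in seq_len(ncol(pr))) {
        cmat[k, j] <- tryCatch(
          concordance_index(time[va], event[va], pr[, j]),
          error = function(e) NA_real_)
      }
    }
    mc <- colMeans(cmat, na.rm = TRUE)
    mc[is.nan(mc)] <- -Inf
    j <- which.max(mc)
    if (mc[j] > best$c)
      best <- list(c = mc[j], l1 = l1, amr = amr, lambda = lam[j])
  }
  if (!is.finite(best$c)) return(list(nonzero = character(0), coefficients = NULL))
  b <- fit_encox(x, time, event, l1_ratio = best$l1, alpha = best$lambda)
  nz <- names(b)[b != 0]
  list(nonzero = nz[order(-abs(b[nz]))], coefficients = b, best = best)
}

## frequency selection with the documented tie-breaks: frequency desc, mean
## absolute coefficient desc, then name order
select_by_frequency <- function(freq, coef_sums, n_select) {
  p <- length(freq)
  if (p <= n_select) return(names(freq))
  avail <- names(freq)[freq > 0]
  if (length(avail) < n_select) {
    warning("only ", length(avail), " features were ever selected; ",
            "padding to ", n_select, " by name order")
    pad <- setdiff(names(freq), avail)
    return(c(avail[order(-freq[avail], -coef_sums[avail], avail)],
             sort(pad))[seq_len(min(n_select, p))])
  }
  mean_abs <- ifelse(freq > 0, coef_sums / pmax(freq, 1), 0)
  ord <- order(-freq, -mean_abs, names(freq))
  names(freq)[ord][seq_len(n_select)]
}

#' Linear risk score of a fitted coefficient vector
#'
#' @param coefficients named numeric vector.
#' @param newdata matrix or data frame containing all coefficient columns.
#' @return numeric scores (one per row).
#' @export
risk_score <- function(coefficients, newdata) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(names(coefficients), colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  as.numeric(newdata[, names(coefficients), drop = FALSE] %*% coefficients)
}

#' Mean-threshold risk grouping
#'
#' High risk strictly above the mean score; ties at the mean go to low risk.
#'
#' @param scores numeric vector (>= 2 values).
#' @return factor with levels `low`, `high`.
#' @export
mean_split_groups <- function(scores) {
  stopifnot(length(scores) >= 2L)
  g <- factor(ifelse(scores > mean(scores), "high", "low"),
              levels = c("low", "high"))
  if (any(table(g) == 0L)) stop("one risk group is empty under the mean split")
  g
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time,event survival times and 0/1 event indicators.
#' @return data frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (right-continuous; S(0) = 1 is the implicit first value).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) > 0, length(time) == length(event))
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Two-group logrank test
#'
#' Observed-minus-expected events with hypergeometric variance summed over
#' distinct event times; the statistic is chi-squared with 1 df.
#'
#' @param time,event outcome vectors.
#' @param group two-level factor or vector.
#' @return list with `chi2`, `p`, `observed`, `expected` (per group) and a
#'   `degenerate` flag (zero variance gives p = 1).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, all(table(group) > 0))
  if (sum(event) < 1L) stop("no events in either group")
  ut <- sort(unique(time[event == 1]))
  oa <- 0; ea <- 0; v <- 0
  ga <- group == levels(group)[1]
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); na <- sum(at_risk & ga)
    d <- sum(time == t & event == 1)
    da <- sum(time == t & event == 1 & ga)
    oa <- oa + da
    ea <- ea + d * na / n
    if (n > 1) v <- v + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  if (v <= 0)
    return(list(chi2 = 0, p = 1, observed = c(oa, sum(event) - oa),
                expected = c(ea, sum(event) - ea), degenerate = TRUE))
  chi2 <- (oa - ea)^2 / v
  list(chi2 = chi2, p = chi2_upper_p(chi2, 1), observed = c(oa, sum(event) - oa),
       expected = c(ea, sum(event) - ea), degenerate = FALSE)
}

#' Upper-tail probability of the chi-squared distribution
#'
#' @param chi2 statistic (>= 0).
#' @param df degrees of freedom, default 1.
#' @return `P(X >= chi2)`.
#' @export
chi2_upper_p <- function(chi2, df = 1) {
  stopifnot(all(chi2 >= 0))
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Harrell's concordance index
#'
#' Over pairs whose ordering is determinable under right censoring (the
#' earlier time is an event; a subject censored at the event time of
#' another is taken to survive longer), the fraction where the higher risk
#' score falls on the shorter survival; score ties count one half. Pairs
#' tied on event time are not comparable. Matches the convention of
#' `survival::concordance`.
#'
#' @param time,event outcome vectors.
#' @param scores risk scores (higher = shorter predicted survival).
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(time, event, scores) {
  n <- length(time)
  stopifnot(length(event) == n, length(scores) == n)
  conc <- 0; ties <- 0; total <- 0
  for (i in which(event == 1)) {
    later <- time > time[i] | (time == time[i] & event == 0)
    later[i] <- FALSE
    total <- total + sum(later)
    conc <- conc + sum(scores[i] > scores[later])
    ties <- ties + sum(scores[i] == scores[later])
  }
  if (total == 0) stop("no comparable pairs under censoring")
  (conc + 0.5 * ties) / total
}
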