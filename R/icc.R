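#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Decomposes an `n x k` complete matrix (subjects by raters/perturbations)
#' by two-way ANOVA into subject (`MS_R`), rater (`MS_C`) and residual
#' (`MS_E`) mean squares and evaluates
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`.
#' A matrix with zero total variance (all cells equal) is perfectly
#' reproducible: ICC is defined as 1 and flagged degenerate.
#'
#' @param mat numeric matrix, rows = subjects (n >= 3), columns = raters
#'   (k >= 2), no missing cells.
#' @return list with `icc`, `ms_r`, `ms_c`, `ms_e`, `degenerate`.
#' @export
icc21 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 2L) stop("need n >= 3 subjects and k >= 2 raters")
  if (any(!is.finite(mat))) stop("matrix must be complete and finite")
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  ss_r <- k * sum((rm_ - grand)^2)
  ss_c <- n * sum((cm_ - grand)^2)
  ss_t <- sum((mat - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- max(0, ss_e) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  degenerate <- ss_t < .Machine$double.eps * max(1, abs(grand))^2 * n * k
  icc <- if (degenerate || denom == 0) 1 else (ms_r - ms_e) / denom
  list(icc = icc, ms_r = ms_r, ms_c = ms_c, ms_e = ms_e, degenerate = degenerate)
}

#' Screen features for stability across a perturbation family
#'
#' For every feature, builds the subjects-by-perturbations matrix and keeps
#' the feature when ICC(2,1) exceeds the threshold (strict inequality);
#' perfectly reproducible features (ICC exactly 1, including degenerate
#' constants) survive any threshold up to 1. All features remain in the
#' denominator of the summary percentage.
#'
#' @param feature_table data frame from [extract_feature_table()] with
#'   columns `subject`, `mask_label`, `config_id` and one column per feature.
#' @param group_by `"config"` (raters = extraction configurations) or
#'   `"contour"` (raters = mask variants).
#' @param threshold robustness cutoff, default 0.75.
#' @return list with `icc` (data frame: feature, icc, ms_r, ms_c, ms_e,
#'   robust), `robust_features` (character), `summary` (count, total,
#'   percentage rounded to one decimal).
#' @export
screen_robust <- function(feature_table, group_by = c("config", "contour"),
                          threshold = 0.75) {
  group_by <- match.arg(group_by)
  rater_col <- if (group_by == "config") "config_id" else "mask_label"
  other_col <- if (group_by == "config") "mask_label" else "config_id"
  meta <- c("subject", "mask_label", "config_id")
  stopifnot(all(meta %in% names(feature_table)))
  if (length(unique(feature_table[[other_col]])) > 1L)
    stop("feature table must be restricted to a single ", other_col,
         " before screening by ", rater_col)
  feats <- setdiff(names(feature_table), meta)
  subjects <- sort(unique(feature_table$subject))
  raters <- sort(unique(feature_table[[rater_col]]))
  if (length(raters) < 2L) stop("need at least two perturbation levels")
  key <- paste(feature_table$subject, feature_table[[rater_col]], sep = "\r")
  want <- as.vector(outer(subjects, raters, paste, sep = "\r"))
  ord <- match(want, key)
  if (any(is.na(ord))) stop("incomplete two-way layout (missing cells)")
  res <- lapply(feats, function(f) {
    m <- matrix(feature_table[[f]][ord], nrow = length(subjects))
    r <- icc21(m)
    data.frame(feature = f, icc = r$icc, ms_r = r$ms_r, ms_c = r$ms_c,
               ms_e = r$ms_e, robust = r$icc > threshold || r$icc == 1)
  })
  icc_df <- do.call(rbind, res)
  robust_features <- icc_df$feature[icc_df$robust]
  list(icc = icc_df, robust_features = robust_features,
       summary = robustness_summary(length(robust_features), length(feats)))
}

#' Robustness screen summary arithmetic
#'
#' @param count number of robust features.
#' @param total total number of features.
#' @return list with `count`, `total`, `percentage` (100 * count / total,
#'   rounded to one decimal).
#' @export
robustness_summary <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  list(count = as.integer(count), total = as.integer(total),
       percentage = round(100 * count / total, 1))
}

#' Intersect two robust feature sets
#'
#' @param set_params robust features under extraction-parameter perturbation.
#' @param set_contours robust features under contour perturbation.
#' @param schema optional full feature-name ordering to preserve; defaults
#'   to the order of `set_params`.
#' @return character vector of features stable against both perturbations.
#' @export
intersect_robust <- function(set_params, set_contours, schema = NULL) {
  common <- intersect(set_params, set_contours)
  if (length(common) == 0L)
    stop("no feature is robust to both perturbations; consider relaxing the threshold")
  if (!is.null(schema)) common <- schema[schema %in% common]
  common
}
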