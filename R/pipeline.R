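#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations of the full workflow
#' (simulate, segment, extract, screen, survive, classify). The default is a
#' toy-scale configuration that runs in minutes; study-scale runs pass a
#' 99-subject [cohort_spec()] and richer extraction settings.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()] template.
#' @param fractions SUVmax threshold fractions for segmentation.
#' @param configs list of [extraction_config()]s for the parameter screen
#'   (default the six-set grid with a reduced feature-class list).
#' @param reference_config index into `configs` used as the reference
#'   extraction for contour screening and modelling.
#' @param reference_mask mask variant label used for parameter screening
#'   and modelling (default `suv40`).
#' @param icc_threshold robustness cutoff (default 0.75).
#' @param test_fraction held-out fraction (default 0.2).
#' @param encox an [encox_config()].
#' @param brf a [brf_config()].
#' @param seed global seed; stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(n_subjects = 20L, seed = 1L),
                            phantom = phantom_spec(grid_shape = c(20L, 20L, 12L),
                                                   spacing_mm = c(3, 3, 3),
                                                   lesion_radius_mm = 12,
                                                   noise_sd = 0.15),
                            fractions = c(0.35, 0.40, 0.45),
                            configs = extraction_grid(
                              feature_classes = c("firstorder", "glcm", "glszm"),
                              wavelet = FALSE, log_sigmas_mm = numeric(0)),
                            reference_config = 2L,
                            reference_mask = "suv40",
                            icc_threshold = 0.75,
                            test_fraction = 0.2,
                            encox = encox_config(inner_repeats = 3L,
                                                 n_alphas = 10L,
                                                 l1_ratio_grid = c(0.5, 0.9),
                                                 alpha_min_ratio_grid = 0.05),
                            brf = brf_config(max_depth = list(3),
                                             n_estimators = 50L,
                                             min_samples_split = 2L,
                                             min_samples_leaf = c(1L, 3L),
                                             max_features = list("sqrt"),
                                             criterion = "gini",
                                             cv_folds = 3L),
                            seed = 1L) {
  structure(list(cohort = cohort, phantom = phantom, fractions = fractions,
                 configs = configs, reference_config = reference_config,
                 reference_mask = reference_mask,
                 icc_threshold = icc_threshold,
                 test_fraction = test_fraction,
                 encox = encox, brf = brf, seed = as.integer(seed),
                 schema_version = "1"),
            class = "pipeline_config")
}

## clinical + outcome table from a cohort
cohort_table <- function(subjects) {
  clin <- do.call(rbind, lapply(subjects, `[[`, "clinical"))
  data.frame(id = vapply(subjects, `[[`, "", "id"),
             clin,
             time_days = vapply(subjects, `[[`, 0, "survival_time_days"),
             event = vapply(subjects, function(s) s$event, 0L),
             one_year_dead = vapply(subjects, function(s) s$one_year_dead, 0L),
             row.names = NULL)
}

run_survival_variant <- function(x_train, x_test, out_train, out_test, encox) {
  sel <- nested_select(x_train, out_train$time_days, out_train$event, encox)
  scores <- risk_score(sel$coefficients, x_test)
  test_c <- concordance_index(out_test$time_days, out_test$event, scores)
  groups <- tryCatch(mean_split_groups(scores), error = function(e) NULL)
  lr <- NULL; km <- NULL
  if (!is.null(groups)) {
    lr <- logrank_test(out_test$time_days, out_test$event, groups)
    km <- lapply(split(seq_along(groups), groups), function(ii)
      kaplan_meier(out_test$time_days[ii], out_test$event[ii]))
  }
  list(selection = sel, test_concordance = test_c, risk_scores = scores,
       groups = groups, logrank = lr, km = km)
}

#' Run the full workflow: simulate, segment, extract, screen, survive,
#' classify
#'
#' Executes every stage on a synthetic cohort and writes `report.json`
#' (full precision) and `report.md` (rounded) plus Kaplan-Meier curve CSVs
#' under `out_dir`. Fully seeded: the same configuration and seed give a
#' byte-identical JSON report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return the report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  report <- list(schema_version = config$schema_version, seed = config$seed)
  tryCatch({
    subjects <- generate_cohort(config$cohort, config$phantom)
    tab <- cohort_table(subjects)

    stage <- "segment"
    mask_sets <- lapply(seq_along(subjects), function(i)
      make_mask_set(subjects[[i]]$volume, subjects[[i]]$true_mask,
                    true_mask = subjects[[i]]$true_mask,
                    fractions = config$fractions,
                    surrogate_seed = derive_seed(config$seed, paste0("pet", i))))

    stage <- "extract"
    ref_cfg <- config$configs[[config$reference_config]]
    tab_params <- extract_feature_table(subjects, mask_sets,
                                        configs = config$configs,
                                        mask_labels = config$reference_mask)
    tab_contours <- extract_feature_table(subjects, mask_sets,
                                          configs = list(ref_cfg))

    stage <- "screen"
    scr_params <- screen_robust(tab_params, "config", config$icc_threshold)
    scr_contours <- screen_robust(tab_contours, "contour", config$icc_threshold)
    final_feats <- intersect_robust(scr_params$robust_features,
                                    scr_contours$robust_features)
    report$icc <- list(
      params = scr_params$summary, contours = scr_contours$summary,
      intersection = robustness_summary(length(final_feats),
                                        scr_params$summary$total))

    stage <- "survive"
    ref_rows <- tab_contours$mask_label == config$reference_mask
    rad_raw <- tab_contours[ref_rows, final_feats, drop = FALSE]
    rad_raw <- rad_raw[match(tab$id, tab_contours$subject[ref_rows]), ,
                       drop = FALSE]
    split <- split_train_test(tab, config$test_fraction,
                              derive_seed(config$seed, "split"),
                              strat_cols = "gender")
    clin_cols <- setdiff(names(tab), c("id", "time_days", "event", "one_year_dead"))
    pp_clin <- preprocess_tables(tab[split$train, clin_cols, drop = FALSE],
                                 tab[split$test, clin_cols, drop = FALSE])
    pp_rad <- preprocess_tables(rad_raw[split$train, , drop = FALSE],
                                rad_raw[split$test, , drop = FALSE])
    x <- list(
      clinical = list(train = pp_clin$train, test = pp_clin$test),
      radiomics = list(train = pp_rad$train, test = pp_rad$test),
      composite = list(train = cbind(pp_clin$train, pp_rad$train),
                       test = cbind(pp_clin$test, pp_rad$test)))
    out_train <- tab[split$train, ]; out_test <- tab[split$test, ]
    survival_res <- list(); classification_res <- list()
    for (v in names(x)) {
      encox_v <- config$encox
      encox_v$seed <- derive_seed(config$seed, paste0("encox_", v))
      sv <- run_survival_variant(x[[v]]$train, x[[v]]$test,
                                 out_train, out_test, encox_v)
      survival_res[[v]] <- list(
        selected = sv$selection$selected,
        coefficients = as.list(sv$selection$coefficients),
        frequencies = as.list(sv$selection$frequencies),
        outer_scores = sv$selection$outer_scores,
        test_concordance = sv$test_concordance,
        logrank = if (!is.null(sv$logrank))
          list(chi2 = sv$logrank$chi2, p = sv$logrank$p),
        km = sv$km, risk_scores = sv$risk_scores,
        groups = if (!is.null(sv$groups)) as.character(sv$groups))

      stage <- "classify"
      feats_v <- sv$selection$selected
      brf_v <- config$brf
      brf_v$seed <- derive_seed(config$seed, paste0("brf_", v))
      y_train <- out_train$one_year_dead; y_test <- out_test$one_year_dead
      cls <- tryCatch({
        fit <- fit_brf(x[[v]]$train[, feats_v, drop = FALSE], y_train, brf_v)
        ev <- evaluate_classifier(
          predict(fit, x[[v]]$test[, feats_v, drop = FALSE]), y_test)
        ev$roc <- NULL
        c(ev, list(best_cv_auc = max(fit$cv_results$cv_auc)))
      }, error = function(e) list(error = conditionMessage(e)))
      classification_res[[v]] <- cls
      stage <- "survive"
    }
    report$survival <- survival_res
    report$classification <- classification_res
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
    for (v in names(report$survival)) {
      km <- report$survival[[v]]$km
      if (!is.null(km)) for (g in names(km))
        utils::write.csv(km[[g]],
                         file.path(out_dir, sprintf("km_%s_%s.csv", v, g)),
                         row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}

render_report_md <- function(report) {
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  lines <- c("# Robust PET radiomics pipeline report", "",
             sprintf("Seed: %d", report$seed), "",
             "## Feature robustness (ICC 2,1)", "")
  for (fam in names(report$icc)) {
    s <- report$icc[[fam]]
    lines <- c(lines, sprintf("- %s: %d / %d robust (%.1f%%)",
                              fam, s$count, s$total, s$percentage))
  }
  lines <- c(lines, "", "## Survival models", "",
             "| Model | Test concordance | Logrank chi2 | p |",
             "|---|---|---|---|")
  for (v in names(report$survival)) {
    sv <- report$survival[[v]]
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", v,
                              fmt(sv$test_concordance),
                              if (!is.null(sv$logrank)) fmt(sv$logrank$chi2) else "-",
                              if (!is.null(sv$logrank))
                                formatC(sv$logrank$p, digits = 3, format = "g")
                              else "-"))
  }
  lines <- c(lines, "", "## One-year survival classification", "",
             "| Model | AUC | Accuracy | Balanced acc. | Sens | Spec |",
             "|---|---|---|---|---|---|")
  for (v in names(report$classification)) {
    cl <- report$classification[[v]]
    if (!is.null(cl$error)) {
      lines <- c(lines, sprintf("| %s | (failed: %s) | | | | |", v, cl$error))
    } else {
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |", v,
                                fmt(cl$auc), fmt(cl$accuracy),
                                fmt(cl$balanced_accuracy),
                                fmt(cl$sensitivity), fmt(cl$specificity)))
    }
  }
  lines
}
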