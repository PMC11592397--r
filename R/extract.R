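#' Radiomics extraction configuration
#'
#' @param bin_width gray-level bin width in intensity units; the robustness
#'   grid uses 5, 25 and 75.
#' @param resample resample to `target_spacing_mm` before extraction?
#' @param target_spacing_mm isotropic target spacing used when `resample`.
#' @param wavelet include the eight Haar wavelet subband images?
#' @param log_sigmas_mm Laplacian-of-Gaussian scales (mm); empty for none.
#' @param feature_classes subset of `firstorder`, `shape`, `glcm`, `glrlm`,
#'   `glszm`, `ngtdm`, `gldm`.
#' @param id optional configuration label used in feature tables.
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, resample = FALSE,
                              target_spacing_mm = c(1, 1, 1),
                              wavelet = TRUE, log_sigmas_mm = c(2, 4),
                              feature_classes = c("firstorder", "shape", "glcm",
                                                  "glrlm", "glszm", "ngtdm", "gldm"),
                              id = NULL) {
  known <- c("firstorder", "shape", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  stopifnot(bin_width > 0, all(log_sigmas_mm > 0), length(feature_classes) > 0,
            all(feature_classes %in% known), all(target_spacing_mm > 0))
  if (is.null(id))
    id <- sprintf("bw%g_%s", bin_width, if (resample) "rs" else "orig")
  structure(list(bin_width = bin_width, resample = resample,
                 target_spacing_mm = as.numeric(target_spacing_mm),
                 wavelet = wavelet, log_sigmas_mm = as.numeric(log_sigmas_mm),
                 feature_classes = feature_classes, id = id),
            class = "extraction_config")
}

#' The six extraction-parameter sets of the robustness screen
#'
#' Bin widths 5, 25 and 75 crossed with extraction at the original
#' resolution or after resampling to 1 mm isotropic.
#'
#' @param ... passed to [extraction_config()] (e.g. `feature_classes`).
#' @return list of six `extraction_config` objects.
#' @export
extraction_grid <- function(...) {
  out <- list()
  for (rs in c(FALSE, TRUE)) for (bw in c(5, 25, 75))
    out[[length(out) + 1L]] <- extraction_config(bin_width = bw, resample = rs, ...)
  out
}

intensity_family <- function(class, values, levels_arr, voxel_volume) {
  switch(class,
    firstorder = firstorder_features(values, levels_arr[!is.na(levels_arr)],
                                     voxel_volume),
    glcm = glcm_features(levels_arr),
    glrlm = glrlm_features(levels_arr),
    glszm = glszm_features(levels_arr),
    ngtdm = ngtdm_features(levels_arr),
    gldm = gldm_features(levels_arr))
}

#' Extract the full radiomics feature vector for one VOI
#'
#' Applies resampling when configured, derives the image variants (original,
#' LoG per sigma, eight wavelet subbands), discretizes intensities within
#' the mask per variant, and evaluates every configured feature class.
#' Shape features are geometry-only and computed once, on the original mask.
#' Names have the form `image_class_Feature` and their order is
#' deterministic for a fixed configuration.
#'
#' @param volume a [pr_volume()].
#' @param mask 0/1 `pr_volume` on the same grid.
#' @param config an [extraction_config()].
#' @return named numeric feature vector with attributes `config_id` and
#'   `mask_label` (if the mask carries one).
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "pr_volume"), inherits(config, "extraction_config"))
  m <- mask_array(mask)
  if (!identical(dim(m), dim(volume$values))) stop("mask grid mismatch")
  if (!any(m)) stop("empty mask")
  if (config$resample) {
    rs <- resample_volume(volume, mask, config$target_spacing_mm)
    volume <- rs$volume
    m <- mask_array(rs$mask)
  }
  spacing <- volume$spacing_mm
  images <- list(original = list(values = volume$values, mask = m,
                                 spacing = spacing))
  for (s in config$log_sigmas_mm) {
    nm <- sprintf("log-sigma-%g-mm", s)
    images[[nm]] <- list(values = log_filter(pr_volume(volume$values, spacing),
                                             s)$values,
                         mask = m, spacing = spacing)
  }
  if (config$wavelet && all(dim(volume$values) >= 2L)) {
    wb <- wavelet_decompose(pr_volume(volume$values, spacing))
    wm <- decimate_mask(m)
    for (nm in names(wb))
      images[[paste0("wavelet-", nm)]] <- list(values = wb[[nm]]$values,
                                               mask = wm, spacing = spacing * 2)
  }
  classes <- config$feature_classes
  out <- numeric(0)
  if ("shape" %in% classes) {
    sf <- tryCatch(shape_features(m, spacing),
                   error = function(e) stop("shape: ", conditionMessage(e)))
    names(sf) <- paste0("original_shape_", names(sf))
    out <- c(out, sf)
  }
  int_classes <- setdiff(classes, "shape")
  for (img in names(images)) {
    vals_arr <- images[[img]]$values
    msk <- images[[img]]$mask
    vv <- vals_arr[msk]
    lv <- array(NA_integer_, dim(vals_arr))
    lv[msk] <- discretize_suv(vv, config$bin_width)
    for (cl in int_classes) {
      f <- tryCatch(
        intensity_family(cl, vv, lv, prod(images[[img]]$spacing)),
        error = function(e) stop(img, "_", cl, ": ", conditionMessage(e)))
      names(f) <- paste0(img, "_", cl, "_", names(f))
      out <- c(out, f)
    }
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature value(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  attr(out, "config_id") <- config$id
  out
}

#' Feature table over subjects, mask variants and configurations
#'
#' @param subjects list of subjects from [generate_cohort()] (with volumes).
#' @param mask_sets optional list of [make_mask_set()] results (one per
#'   subject); when `NULL`, each subject's `true_mask` is used under the
#'   label `true`.
#' @param configs list of [extraction_config()]s.
#' @param mask_labels restrict to these variant labels (default all).
#' @return data frame with columns `subject`, `mask_label`, `config_id`
#'   followed by one column per feature.
#' @export
extract_feature_table <- function(subjects, mask_sets = NULL,
                                  configs = list(extraction_config()),
                                  mask_labels = NULL) {
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    masks <- if (is.null(mask_sets)) list(true = s$true_mask)
             else mask_sets[[i]]$variants
    if (!is.null(mask_labels)) masks <- masks[mask_labels]
    for (ml in names(masks)) for (cfg in configs) {
      fv <- extract_all(s$volume, masks[[ml]], cfg)
      rows[[length(rows) + 1L]] <-
        c(list(subject = s$id, mask_label = ml, config_id = cfg$id),
          as.list(fv))
    }
  }
  nm <- names(rows[[1]])
  stopifnot(all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
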