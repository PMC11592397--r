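#' Default clinical covariate schema
#'
#' Categorical level frequencies mirror the published characteristics of a
#' 99-patient stage IVB NSCLC cohort (40 male / 59 female, 76 ever-smokers,
#' M1a/M1b/M1c 22/13/64, first-line regimen 56/30/9/4, histology 79/15/3/2,
#' median age 67 with range 30-88). Continuous laboratory values use
#' field-typical means and spreads (chosen once; see the methods vignette).
#'
#' @return list of covariate definitions (name, type, and either
#'   `levels`/`weights` or `mean`/`sd`/`min`/`max`).
#' @export
clinical_schema_default <- function() {
  list(
    list(name = "gender", type = "categorical",
         levels = c("Female", "Male"), weights = c(59, 40)),
    list(name = "age", type = "continuous", mean = 66, sd = 12, min = 30, max = 88),
    list(name = "smoking", type = "categorical",
         levels = c("Ever", "Never"), weights = c(76, 23)),
    list(name = "m_stage", type = "categorical",
         levels = c("M1a", "M1b", "M1c"), weights = c(22, 13, 64)),
    list(name = "treatment", type = "categorical",
         levels = c("Chemotherapy", "Targeted", "Immunotherapy", "ChemoImmuno"),
         weights = c(56, 30, 9, 4)),
    list(name = "histology", type = "categorical",
         levels = c("Adenocarcinoma", "Squamous", "LargeCell", "NOS"),
         weights = c(79, 15, 3, 2)),
    list(name = "bmi", type = "continuous", mean = 26.5, sd = 5.5, min = 15, max = 50),
    list(name = "platelet", type = "continuous", mean = 280, sd = 90, min = 80, max = 700),
    list(name = "neutrophil", type = "continuous", mean = 5.5, sd = 2.2, min = 1, max = 15),
    list(name = "copd", type = "categorical",
         levels = c("No", "Yes"), weights = c(70, 30)),
    list(name = "cad", type = "categorical",
         levels = c("No", "Yes"), weights = c(78, 22))
  )
}

#' Specification of a synthetic survival cohort
#'
#' Survival times follow an exponential Cox model: subject hazard is
#' `baseline_hazard * exp(sum(beta_true * x))` where `x` are standardized
#' per-subject lesion parameters (`heterogeneity`, `suv_max`, `radius`).
#' Censoring times are independent exponentials calibrated so roughly
#' `censoring_rate` of subjects are censored under the null.
#'
#' @param n_subjects cohort size (>= 10); default 99.
#' @param event_rate_1yr target fraction deceased at one year under the null
#'   model; sets `baseline_hazard` when that is `NULL`.
#' @param censoring_rate fraction administratively censored.
#' @param beta_true named numeric, planted log-hazard coefficients on the
#'   standardized lesion parameters.
#' @param baseline_hazard constant hazard per day, or `NULL` to derive from
#'   `event_rate_1yr`.
#' @param clinical_schema covariate definitions, default
#'   [clinical_schema_default()].
#' @param seed RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 99L,
                        event_rate_1yr = 0.55,
                        censoring_rate = 0.2,
                        beta_true = c(heterogeneity = 1.2),
                        baseline_hazard = NULL,
                        clinical_schema = clinical_schema_default(),
                        seed = 1L) {
  stopifnot(n_subjects >= 10L, event_rate_1yr > 0, event_rate_1yr < 1,
            censoring_rate >= 0, censoring_rate < 1)
  beta_true <- beta_true[beta_true != 0 | names(beta_true) != ""]
  bad <- setdiff(names(beta_true), c("heterogeneity", "suv_max", "radius"))
  if (length(bad)) stop("unknown planted feature(s): ", paste(bad, collapse = ", "))
  if (is.null(baseline_hazard))
    baseline_hazard <- -log(1 - event_rate_1yr) / 365
  structure(list(n_subjects = as.integer(n_subjects),
                 event_rate_1yr = event_rate_1yr,
                 censoring_rate = censoring_rate,
                 beta_true = beta_true, baseline_hazard = baseline_hazard,
                 clinical_schema = clinical_schema, seed = as.integer(seed)),
            class = "cohort_spec")
}

sample_clinical <- function(schema, n) {
  cols <- lapply(schema, function(s) {
    if (s$type == "categorical") {
      factor(sample(s$levels, n, replace = TRUE, prob = s$weights / sum(s$weights)),
             levels = s$levels)
    } else {
      round(pmin(pmax(stats::rnorm(n, s$mean, s$sd), s$min), s$max), 2)
    }
  })
  names(cols) <- vapply(schema, `[[`, "", "name")
  as.data.frame(cols, stringsAsFactors = FALSE)
}

## ranges of the per-subject latent lesion parameters (relative to template)
latent_ranges <- function(pspec) {
  list(heterogeneity = c(0.05, 0.45),
       suv_max = c(0.6, 1.4) * pspec$suv_max,
       radius = c(0.6, 1.0) * pspec$lesion_radius_mm)
}

#' Generate a synthetic survival cohort
#'
#' Draws per-subject lesion parameters (texture heterogeneity, peak uptake,
#' radius), survival times from the planted exponential Cox model, an
#' administrative censoring time, clinical covariates from the schema, and
#' (optionally) the PET phantom volume and true lesion mask per subject.
#'
#' @param cspec a [cohort_spec()].
#' @param pspec_template a [phantom_spec()] used as the template for every
#'   subject; per-subject `heterogeneity_sd`, `suv_max`, `lesion_radius_mm`
#'   and `seed` are overridden.
#' @param make_volumes generate phantom volumes (`TRUE`) or a tabular-only
#'   cohort with `volume = NULL` for fast statistical studies (`FALSE`).
#' @return list of subjects; each has `id`, `volume`, `true_mask`,
#'   `clinical` (one-row data frame), `latent` (named lesion parameters,
#'   standardized in `latent_z`), `survival_time_days`, `event`,
#'   `one_year_dead`.
#' @export
generate_cohort <- function(cspec, pspec_template = phantom_spec(),
                            make_volumes = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  n <- cspec$n_subjects
  if (all(cspec$beta_true == 0) || length(cspec$beta_true) == 0L)
    message("cohort_spec: all planted coefficients are zero (null cohort)")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cspec$seed)
  rng <- latent_ranges(pspec_template)
  lat <- data.frame(
    heterogeneity = stats::runif(n, rng$heterogeneity[1], rng$heterogeneity[2]),
    suv_max = stats::runif(n, rng$suv_max[1], rng$suv_max[2]),
    radius = stats::runif(n, rng$radius[1], rng$radius[2]))
  # standardize with the theoretical uniform moments (deterministic)
  latz <- as.data.frame(lapply(names(lat), function(nm) {
    r <- rng[[nm]]
    (lat[[nm]] - mean(r)) / ((r[2] - r[1]) / sqrt(12))
  }))
  names(latz) <- names(lat)
  lp <- rep(0, n)
  for (nm in names(cspec$beta_true))
    lp <- lp + cspec$beta_true[[nm]] * latz[[nm]]
  hazard <- cspec$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  if (cspec$censoring_rate > 0) {
    rate_c <- cspec$baseline_hazard *
      cspec$censoring_rate / (1 - cspec$censoring_rate)
    t_cens <- stats::rexp(n, rate = rate_c)
  } else t_cens <- rep(Inf, n)
  # day-resolution times (ties are expected; Breslow handles them downstream)
  time <- pmax(ceiling(pmin(t_event, t_cens)), 1)
  event <- as.integer(t_event <= t_cens)
  clin <- sample_clinical(cspec$clinical_schema, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- NULL; true_mask <- NULL
    if (make_volumes) {
      ps <- pspec_template
      ps$heterogeneity_sd <- lat$heterogeneity[i]
      ps$suv_max <- lat$suv_max[i]
      ps$lesion_radius_mm <- lat$radius[i]
      ps$seed <- derive_seed(cspec$seed, paste0("subject", i))
      ph <- generate_phantom(ps)
      vol <- ph$volume; true_mask <- ph$true_mask
    }
    subjects[[i]] <- list(
      id = sprintf("S%03d", i), volume = vol, true_mask = true_mask,
      clinical = clin[i, , drop = FALSE],
      latent = as.list(lat[i, ]), latent_z = as.list(latz[i, ]),
      survival_time_days = time[i], event = event[i],
      one_year_dead = as.integer(event[i] == 1L && time[i] <= 365))
  }
  attr(subjects, "cohort_spec") <- cspec
  subjects
}

#' Write a cohort to disk (NRRD volumes, CSV tables, JSON manifest)
#'
#' @param subjects output of [generate_cohort()] (with volumes).
#' @param out_dir writable output directory (created if absent).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_cohort <- function(subjects, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- lapply(subjects, function(s) {
    e <- list(id = s$id)
    if (!is.null(s$volume)) {
      vp <- file.path(out_dir, paste0(s$id, "_pet.nrrd"))
      mp <- file.path(out_dir, paste0(s$id, "_mask.nrrd"))
      write_nrrd(s$volume, vp)
      write_nrrd(s$true_mask, mp, type = "uint8")
      e$volume <- basename(vp); e$mask <- basename(mp)
    }
    e
  })
  clin <- do.call(rbind, lapply(subjects, `[[`, "clinical"))
  clin <- cbind(id = vapply(subjects, `[[`, "", "id"), clin)
  utils::write.csv(clin, file.path(out_dir, "clinical.csv"), row.names = FALSE)
  surv <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    time_days = vapply(subjects, `[[`, 0, "survival_time_days"),
    event = vapply(subjects, function(s) s$event, 0L),
    one_year_dead = vapply(subjects, function(s) s$one_year_dead, 0L))
  utils::write.csv(surv, file.path(out_dir, "survival.csv"), row.names = FALSE)
  cs <- attr(subjects, "cohort_spec")
  manifest <- list(
    n_subjects = length(subjects),
    files = list(clinical = "clinical.csv", survival = "survival.csv"),
    subjects = entries,
    ground_truth = if (!is.null(cs)) list(
      beta_true = as.list(cs$beta_true),
      baseline_hazard = cs$baseline_hazard,
      event_rate_1yr = cs$event_rate_1yr,
      censoring_rate = cs$censoring_rate, seed = cs$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
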