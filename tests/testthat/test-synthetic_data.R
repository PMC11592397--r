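test_that("noise-free flat-profile phantom is exactly suv_max inside the lesion", {
  ph <- generate_phantom(tiny_phantom(edge_fraction = 1))
  inside <- ph$true_mask$values == 1
  expect_true(all(ph$volume$values[inside] == 10))
  expect_true(all(ph$volume$values[!inside] == 1))
})

test_that("phantom generation is deterministic and attains suv_max", {
  spec <- tiny_phantom(noise_sd = 0, heterogeneity_sd = 0.3,
                       suv_max = 10, background_suv = 0.5, seed = 1L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_equal(max(a$volume$values), 10)
  # maximum sits inside the lesion
  expect_true(a$true_mask$values[which.max(a$volume$values)] == 1)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(lesion_radius_mm = 200), "contained")
  expect_error(phantom_spec(suv_max = 1, background_suv = 2))
  expect_error(phantom_spec(heterogeneity_sd = 1.2))
})

test_that("null cohort survival times are exponential(baseline_hazard)", {
  # baseline 1/365, beta = 0, no censoring: P(dead at 365) = 1 - exp(-1)
  cs <- cohort_spec(n_subjects = 10000L, censoring_rate = 0,
                    beta_true = c(heterogeneity = 0),
                    baseline_hazard = 1 / 365, seed = 4L)
  subjects <- suppressMessages(generate_cohort(cs, make_volumes = FALSE))
  times <- vapply(subjects, `[[`, 0, "survival_time_days")
  events <- vapply(subjects, function(s) s$event, 0L)
  expect_true(all(events == 1L))
  p_hat <- mean(times <= 365)
  p_true <- 1 - exp(-1)
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * se)
  # KM at t equals the empirical survivor function without censoring
  km <- kaplan_meier(times, events)
  expect_equal(km$surv, 1 - ecdf(times)(km$time), tolerance = 1e-12)
})

test_that("default cohort matches the stated world (n = 99, endpoints consistent)", {
  cs <- cohort_spec(seed = 2L)
  expect_identical(cs$n_subjects, 99L)
  subjects <- generate_cohort(cs, make_volumes = FALSE)
  expect_length(subjects, 99L)
  for (s in subjects) {
    if (s$one_year_dead == 1L) {
      expect_identical(s$event, 1L)
      expect_lte(s$survival_time_days, 365)
    }
    if (s$event == 0L) expect_identical(s$one_year_dead, 0L)
  }
  rate <- mean(vapply(subjects, function(s) s$one_year_dead, 0L))
  se <- sqrt(0.55 * 0.45 / 99)
  expect_lt(abs(rate - 0.55), 4 * se)
})

test_that("cohorts are byte-identical under one seed and vary across seeds", {
  ps <- tiny_phantom(noise_sd = 0.1, heterogeneity_sd = 0.2)
  a <- generate_cohort(cohort_spec(n_subjects = 10L, seed = 9L), ps)
  b <- generate_cohort(cohort_spec(n_subjects = 10L, seed = 9L), ps)
  c2 <- generate_cohort(cohort_spec(n_subjects = 10L, seed = 10L), ps)
  expect_identical(a[[3]]$volume$values, b[[3]]$volume$values)
  expect_identical(a[[3]]$survival_time_days, b[[3]]$survival_time_days)
  expect_false(identical(a[[3]]$volume$values, c2[[3]]$volume$values))
})

test_that("write_cohort round-trips volumes and tables losslessly", {
  out <- withr::local_tempdir()
  ps <- tiny_phantom(noise_sd = 0.1, heterogeneity_sd = 0.2)
  subjects <- generate_cohort(cohort_spec(n_subjects = 10L, seed = 3L), ps)
  manifest <- write_cohort(subjects, out)
  expect_length(manifest$subjects, 10L)
  v <- read_nrrd(file.path(out, manifest$subjects[[4]]$volume))
  m <- read_nrrd(file.path(out, manifest$subjects[[4]]$mask))
  expect_identical(v$values, subjects[[4]]$volume$values)
  expect_identical(v$spacing_mm, subjects[[4]]$volume$spacing_mm)
  expect_identical(m$values, subjects[[4]]$true_mask$values)
  clin <- read.csv(file.path(out, "clinical.csv"))
  schema_names <- vapply(clinical_schema_default(), `[[`, "", "name")
  expect_identical(names(clin), c("id", schema_names))
  surv <- read.csv(file.path(out, "survival.csv"))
  expect_identical(nrow(surv), 10L)
  expect_equal(surv$time_days,
               vapply(subjects, `[[`, 0, "survival_time_days"),
               ignore_attr = TRUE)
})

test_that("clinical covariates follow the schema frequencies", {
  subjects <- suppressMessages(generate_cohort(
    cohort_spec(n_subjects = 2000L, beta_true = c(heterogeneity = 0), seed = 5L),
    make_volumes = FALSE))
  clin <- do.call(rbind, lapply(subjects, `[[`, "clinical"))
  # 59 / 99 female, 76 / 99 ever-smokers: binomial check at n = 2000
  expect_lt(abs(mean(clin$gender == "Female") - 59 / 99), 0.035)
  expect_lt(abs(mean(clin$smoking == "Ever") - 76 / 99), 0.035)
  expect_true(all(levels(clin$m_stage) == c("M1a", "M1b", "M1c")))
  expect_true(all(clin$age >= 30 & clin$age <= 88))
})
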