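# Small deterministic fixtures shared across tests.

tiny_phantom <- function(noise_sd = 0, heterogeneity_sd = 0, seed = 1L, ...) {
  phantom_spec(grid_shape = c(16L, 16L, 12L), spacing_mm = c(3, 3, 3),
               lesion_radius_mm = 10, noise_sd = noise_sd,
               heterogeneity_sd = heterogeneity_sd, seed = seed, ...)
}

# random small integer level array with NA outside a random mask
random_levels <- function(seed, dmax = c(5L, 5L, 3L), ng = 4L,
                          mask_frac = 0.8) {
  set.seed(seed)
  d <- c(sample(2:dmax[1], 1), sample(2:dmax[2], 1), sample(1:dmax[3], 1))
  lv <- array(sample.int(ng, prod(d), replace = TRUE), d)
  drop_n <- floor((1 - mask_frac) * prod(d))
  if (drop_n > 0) lv[sample.int(prod(d), drop_n)] <- NA_integer_
  if (all(is.na(lv))) lv[1] <- 1L
  lv
}

# tabular null or planted cohort + design matrix of latent proxy + noise
tabular_cohort <- function(seed, n = 99L, beta = c(heterogeneity = 1.2),
                           p_noise = 15L, proxy_noise_sd = 0.3) {
  cs <- cohort_spec(n_subjects = n, beta_true = beta, seed = seed)
  subjects <- suppressMessages(generate_cohort(cs, make_volumes = FALSE))
  tab <- data.frame(
    time_days = vapply(subjects, `[[`, 0, "survival_time_days"),
    event = vapply(subjects, function(s) s$event, 0L),
    one_year_dead = vapply(subjects, function(s) s$one_year_dead, 0L))
  set.seed(seed + 1L)
  X <- cbind(
    het_proxy = vapply(subjects, function(s) s$latent_z$heterogeneity, 0) +
      rnorm(n, sd = proxy_noise_sd),
    matrix(rnorm(n * p_noise), n, p_noise,
           dimnames = list(NULL, sprintf("noise%02d", seq_len(p_noise)))))
  list(tab = tab, X = X, subjects = subjects)
}

fast_encox <- function(seed = 1L, inner_repeats = 3L) {
  encox_config(l1_ratio_grid = c(0.5, 0.9), alpha_min_ratio_grid = 0.05,
               n_alphas = 10L, inner_repeats = inner_repeats, seed = seed)
}
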