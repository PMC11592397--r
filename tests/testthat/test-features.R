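test_that("discretization follows the anchored fixed-bin-width rule", {
  expect_identical(discretize_suv(c(0, 4.9, 5, 12), 5), c(1L, 1L, 2L, 3L))
  expect_identical(discretize_suv(rep(3.3, 5), 2), rep(1L, 5))
  expect_identical(discretize_suv(c(1, 9), 100), c(1L, 1L))
  # negative intensities (filtered images) stay anchored at the minimum
  expect_identical(discretize_suv(c(-7, -1, 4), 5), c(1L, 2L, 3L))
  expect_error(discretize_suv(numeric(0), 5))
})

test_that("first-order features match hand arithmetic", {
  f <- firstorder_features(c(1, 1, 2, 2), c(1L, 1L, 2L, 2L))
  expect_equal(f[["Mean"]], 1.5)
  expect_equal(f[["Uniformity"]], 0.5)
  expect_equal(f[["Entropy"]], 1)       # 1 bit, two equally likely levels
  f2 <- firstorder_features(c(0, 10), c(1L, 3L))
  expect_equal(f2[["Range"]], 10)
  expect_equal(f2[["RootMeanSquared"]], sqrt(50))
  cst <- firstorder_features(rep(4, 9), rep(1L, 9))
  expect_equal(cst[["Entropy"]], 0)
  expect_equal(cst[["Uniformity"]], 1)
  expect_equal(cst[["Variance"]], 0)
  expect_equal(cst[["Skewness"]], 0)    # undefined at zero variance -> 0
  expect_length(f, 18L)
})

test_that("GLCM matches the hand-built single-offset matrix and checkerboard", {
  # row [1,1,2,2], offset (0,0,1): P = [[1/3,1/6],[1/6,1/3]], contrast 1/3
  lv <- array(NA_integer_, c(1, 1, 4)); lv[1, 1, ] <- c(1L, 1L, 2L, 2L)
  g <- glcm_features(lv)
  expect_equal(g[["Contrast"]], 1 / 3)
  expect_equal(g[["JointEntropy"]],
               -(2 * (1 / 3) * log2(1 / 3) + 2 * (1 / 6) * log2(1 / 6)))
  expect_equal(glcm_features(array(2L, c(3, 3, 2)))[["JointEntropy"]], 0)
  # 1D alternation: every unit step along the axis changes level by 1
  chk <- array(NA_integer_, c(8, 1, 1)); chk[, 1, 1] <- rep(c(1L, 2L), 4)
  expect_equal(glcm_features(chk)[["Contrast"]], 1)
  # degenerate single level: correlation defined as 1
  expect_equal(glcm_features(array(1L, c(2, 2, 2)))[["Correlation"]], 1)
})

test_that("constant-region texture degenerates as documented", {
  lv <- array(1L, c(3, 3, 1))
  sz <- glszm_features(lv)
  expect_equal(sz[["ZonePercentage"]], 1 / 9)  # one zone of size |mask|
  expect_equal(sz[["LargeAreaEmphasis"]], 81)
  nt <- ngtdm_features(lv)
  expect_equal(nt[["Busyness"]], 0)
  expect_equal(nt[["Contrast"]], 0)
  rl <- glrlm_features(lv)
  expect_equal(rl[["GrayLevelNonUniformityNormalized"]], 1)
})

test_that("texture families equal their brute-force oracles on random images", {
  for (s in 1:25) {
    lv <- random_levels(s)
    for (fam in list(
      list(glcm_features, oracle_glcm_features),
      list(glrlm_features, oracle_glrlm_features),
      list(glszm_features, oracle_glszm_features),
      list(ngtdm_features, oracle_ngtdm_features),
      list(gldm_features, oracle_gldm_features))) {
      got <- fam[[1]](lv); want <- fam[[2]](lv)
      expect_equal(got[sort(names(got))], want[sort(names(got))],
                   tolerance = 1e-10)
    }
  }
})

test_that("direction-averaged GLCM/GLRLM are invariant to grid rotations", {
  set.seed(11)
  lv <- array(sample.int(4, 4 * 4 * 4, replace = TRUE), c(4, 4, 4))
  rot <- aperm(lv[, 4:1, ], c(2, 1, 3))      # 90 degrees about z
  for (fn in list(glcm_features, glrlm_features)) {
    expect_equal(fn(lv), fn(rot), tolerance = 1e-12)
  }
})

test_that("discretized texture is invariant to shifts by a bin-width multiple", {
  set.seed(12)
  vals <- array(runif(60, 0, 30), c(5, 4, 3))
  mk <- function(v) {
    lv <- array(NA_integer_, dim(v)); lv[] <- discretize_suv(as.vector(v), 5); lv
  }
  expect_equal(glcm_features(mk(vals)), glcm_features(mk(vals + 15)))
  expect_equal(gldm_features(mk(vals)), gldm_features(mk(vals + 15)))
})

test_that("shape features: volumes, diameters, sphericity band, scaling law", {
  sv <- array(0, c(5, 5, 5)); sv[3, 3, 3] <- 1
  f1 <- shape_features(sv, c(1, 1, 1))
  expect_equal(f1[["VoxelVolume"]], 1)
  expect_length(f1, 14L)
  # digital ball, radius 10 mm at 1 mm spacing
  co <- (0:24) - 12
  ball <- array(outer(outer(co^2, co^2, "+"), co^2, "+") <= 100, c(25, 25, 25))
  fb <- shape_features(ball, c(1, 1, 1))
  expect_gte(fb[["Sphericity"]], 0.95)
  expect_lte(fb[["Sphericity"]], 1.0)
  expect_equal(fb[["VoxelVolume"]], sum(ball))
  expect_equal(fb[["Maximum3DDiameter"]], 20)
  # doubling the spacing doubles every length, x8 every volume
  f2 <- shape_features(ball, c(2, 2, 2))
  expect_equal(f2[["Maximum3DDiameter"]], 2 * fb[["Maximum3DDiameter"]])
  expect_equal(f2[["SurfaceArea"]], 4 * fb[["SurfaceArea"]], tolerance = 1e-10)
  expect_equal(f2[["MeshVolume"]], 8 * fb[["MeshVolume"]], tolerance = 1e-10)
  expect_error(shape_features(array(0, c(3, 3, 3))), "empty")
})

test_that("wavelet decomposition: vanishing detail, Parseval, impulse taps", {
  cst <- pr_volume(array(3, c(6, 6, 4)))
  wb <- wavelet_decompose(cst)
  expect_identical(names(wb), c("LLL", "LLH", "LHL", "LHH",
                                "HLL", "HLH", "HHL", "HHH"))
  for (nm in setdiff(names(wb), "LLL"))
    expect_equal(max(abs(wb[[nm]]$values)), 0)
  set.seed(4)
  v <- pr_volume(array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  wb2 <- wavelet_decompose(v)
  e <- sum(vapply(wb2, function(s) sum(s$values^2), 0))
  expect_equal(e, sum(v$values^2), tolerance = 1e-8)
  imp <- array(0, c(4, 4, 4)); imp[1, 1, 1] <- 1
  wbi <- wavelet_decompose(pr_volume(imp))
  expect_equal(wbi$LLL$values[1, 1, 1], (1 / sqrt(2))^3)
  expect_equal(wbi$HHH$values[1, 1, 1], (1 / sqrt(2))^3)
  expect_error(wavelet_decompose(pr_volume(array(1, c(1, 4, 4)))), ">= 2")
})

test_that("LoG filter: zero on constants, zero mean, scale selectivity", {
  cst <- pr_volume(array(7, c(8, 8, 8)), c(2, 2, 2))
  expect_equal(max(abs(log_filter(cst, 3)$values)), 0)
  set.seed(5)
  v <- pr_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)))
  expect_equal(mean(log_filter(v, 2)$values), 0, tolerance = 1e-14)
  # a Gaussian blob of scale s0 is most negative at the centre near sigma = s0
  d <- c(21, 21, 21); ctr <- 11; s0 <- 3
  co <- (1:21 - ctr)
  blob <- exp(-outer(outer(co^2, co^2, "+"), co^2, "+") / (2 * s0^2))
  bv <- pr_volume(array(blob, d))
  resp <- vapply(c(1, 2, 3, 5, 8), function(s)
    -log_filter(bv, s)$values[ctr, ctr, ctr] * s^2, 0)  # scale-normalized
  expect_equal(c(1, 2, 3, 5, 8)[which.max(resp)], 3)
  expect_warning(log_filter(v, 0.2), "spacing")
})

test_that("resampling: identity, constants, hand-worked linear midpoint", {
  set.seed(6)
  v <- pr_volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)), c(2, 3, 4))
  idn <- resample_volume(v, target_spacing_mm = c(2, 3, 4))
  expect_equal(idn$volume$values, v$values, tolerance = 1e-12)
  cst <- pr_volume(array(5, c(4, 4, 4)), c(2, 2, 2))
  rs <- resample_volume(cst, target_spacing_mm = c(1.3, 1.3, 1.3))
  expect_equal(range(rs$volume$values), c(5, 5))
  # two voxels [0, 10] at 2 mm: the physical midpoint interpolates to 5
  v2 <- pr_volume(array(c(0, 10), c(2, 1, 1)), c(2, 1, 1))
  rs2 <- resample_volume(v2, target_spacing_mm = c(1, 1, 1))
  expect_equal(rs2$volume$values[2, 1, 1], 5)
  # mask empty after resampling errors
  m <- pr_volume(array(0, c(2, 1, 1)), c(2, 1, 1))
  expect_error(resample_volume(v2, m, c(1, 1, 1)), "empty")
})

test_that("extract_all: counts, schema stability, six-config grid", {
  ph <- generate_phantom(tiny_phantom(noise_sd = 0.1, heterogeneity_sd = 0.2))
  cfg18 <- extraction_config(feature_classes = "firstorder", wavelet = FALSE,
                             log_sigmas_mm = numeric(0))
  expect_length(extract_all(ph$volume, ph$true_mask, cfg18), 18L)
  grid <- extraction_grid(feature_classes = c("firstorder", "glcm"),
                          wavelet = FALSE, log_sigmas_mm = numeric(0))
  expect_length(grid, 6L)
  expect_identical(vapply(grid, function(g) g$bin_width, 0),
                   c(5, 25, 75, 5, 25, 75))
  expect_identical(vapply(grid, function(g) g$resample, TRUE),
                   rep(c(FALSE, TRUE), each = 3))
  # feature count is constant across subjects for a fixed config
  ph2 <- generate_phantom(tiny_phantom(noise_sd = 0.3, heterogeneity_sd = 0.4,
                                       seed = 99L))
  full <- extraction_config(feature_classes = c("firstorder", "shape", "glcm"))
  n1 <- length(extract_all(ph$volume, ph$true_mask, full))
  n2 <- length(extract_all(ph2$volume, ph2$true_mask, full))
  expect_identical(n1, n2)
  expect_identical(names(extract_all(ph$volume, ph$true_mask, full)),
                   names(extract_all(ph2$volume, ph2$true_mask, full)))
  # image variants appear in the names: original + 2 LoG + 8 wavelet
  nm <- names(extract_all(ph$volume, ph$true_mask,
                          extraction_config(feature_classes = c("firstorder"))))
  imgs <- unique(sub("_firstorder_.*$", "", nm))
  expect_length(imgs, 11L)
})
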