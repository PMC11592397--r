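## Texture-matrix feature families on discretized gray levels.
##
## All functions take a 3D integer array `levels` with NA outside the VOI
## (levels 1..Ng inside, as produced by discretize_suv()). Gray levels
## absent from the VOI contribute empty rows, the standard convention for
## fixed-bin-width discretization.

crop_to_mask <- function(levels) {
  idx <- which(!is.na(levels), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty VOI")
  rng <- apply(idx, 2, range)
  levels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
}

## shift with NA fill
shift_arr <- function(arr, o) {
  d <- dim(arr)
  ix <- seq_len(d[1]) + o[1]; iy <- seq_len(d[2]) + o[2]; iz <- seq_len(d[3]) + o[3]
  ok_x <- ix >= 1 & ix <= d[1]; ok_y <- iy >= 1 & iy <= d[2]; ok_z <- iz >= 1 & iz <= d[3]
  out <- array(NA_integer_, d)
  if (any(ok_x) && any(ok_y) && any(ok_z))
    out[ok_x, ok_y, ok_z] <- arr[ix[ok_x], iy[ok_y], iz[ok_z]]
  out
}

all_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' Gray-level co-occurrence matrix features
#'
#' Pair counts are accumulated for each of the 13 unique 3D direction
#' offsets at the given distance, symmetrized, normalized per direction,
#' and the normalized matrices averaged before the 24 features are computed.
#' With a single gray level, Correlation and MCC are defined as 1 and the
#' information measures as 0.
#'
#' @param levels 3D integer array, NA outside the VOI.
#' @param distance offset length in voxels (default 1).
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, distance = 1L) {
  lv <- crop_to_mask(levels)
  ng <- max(lv, na.rm = TRUE)
  offs <- texture_offsets_13() * as.integer(distance)
  mats <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- shift_arr(lv, offs[k, ])
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    cm <- matrix(0, ng, ng)
    tb <- table(factor(lv[ok], levels = 1:ng), factor(nb[ok], levels = 1:ng))
    cm <- cm + tb + t(tb)
    mats[[length(mats) + 1L]] <- cm / sum(cm)
  }
  if (!length(mats)) stop("no co-occurring voxel pairs in VOI")
  P <- Reduce(`+`, mats) / length(mats)
  glcm_from_matrix(P)
}

## the 24 features from a normalized symmetric co-occurrence matrix
glcm_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(1:ng * px); muy <- sum(1:ng * py)
  sigx <- sqrt(sum((1:ng - mux)^2 * px)); sigy <- sqrt(sum((1:ng - muy)^2 * py))
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), 0)
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  da <- sum(k_diff * pxy_diff)
  hxy <- entropy2(P)
  pxpy <- outer(px, py)
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- entropy2(pxpy)
  hx <- entropy2(px); hy <- entropy2(py)
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  mcc <- if (ng > 1L && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (kk in 1:ng) if (py[kk] > 0)
      Q <- Q + outer(P[, kk], P[, kk]) / (px * py[kk])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, if (length(ev) > 1) ev[2] else ev[1]))
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- i != j
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pxy_diff),
    DifferenceVariance = sum((k_diff - da)^2 * pxy_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (any(offd)) sum(P[offd] / (i[offd] - j[offd])^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = entropy2(pxy_sum),
    SumSquares = sum((i - mux)^2 * P)
  )
}

## enumerate maximal runs of equal levels along one direction offset;
## returns a matrix with columns (level, length)
runs_along <- function(lv, o) {
  d <- dim(lv)
  pos <- arrayInd(seq_len(prod(d)), d)
  # a run starts where the predecessor (pos - o) is outside the box
  prev_in <- pos[, 1] - o[1] >= 1 & pos[, 1] - o[1] <= d[1] &
    pos[, 2] - o[2] >= 1 & pos[, 2] - o[2] <= d[2] &
    pos[, 3] - o[3] >= 1 & pos[, 3] - o[3] <= d[3]
  starts <- which(!prev_in)
  out_lvl <- integer(0); out_len <- integer(0)
  for (s in starts) {
    p <- pos[s, ]
    line <- integer(0)
    while (all(p >= 1) && all(p <= d)) {
      line <- c(line, lv[p[1], p[2], p[3]])
      p <- p + o
    }
    r <- rle(line)
    keep <- !is.na(r$values)
    out_lvl <- c(out_lvl, r$values[keep])
    out_len <- c(out_len, r$lengths[keep])
  }
  cbind(level = out_lvl, length = out_len)
}

#' Gray-level run length matrix features
#'
#' Run matrices are accumulated per direction over the 13 unique 3D offsets
#' and averaged; the 16 standard features are computed from the averaged
#' matrix.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels) {
  lv <- crop_to_mask(levels)
  ng <- max(lv, na.rm = TRUE)
  np <- sum(!is.na(lv))
  offs <- texture_offsets_13()
  lmax <- max(dim(lv))
  R <- matrix(0, ng, lmax)
  for (k in seq_len(nrow(offs))) {
    rr <- runs_along(lv, offs[k, ])
    for (q in seq_len(nrow(rr))) R[rr[q, 1], rr[q, 2]] <- R[rr[q, 1], rr[q, 2]] + 1
  }
  R <- R / nrow(offs)
  size_weighted_features(R, np,
    prefix = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
               "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
               "RunLengthNonUniformityNormalized", "RunPercentage",
               "GrayLevelVariance", "RunVariance", "RunEntropy",
               "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
               "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
               "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

#' Gray-level size zone matrix features
#'
#' Zones are 26-connected components of equal gray level; the 16 standard
#' features are computed from the zone-size matrix.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(levels) {
  lv <- crop_to_mask(levels)
  ng <- max(lv, na.rm = TRUE)
  np <- sum(!is.na(lv))
  zl <- integer(0); zs <- integer(0)
  for (g in 1:ng) {
    mg <- !is.na(lv) & lv == g
    if (!any(mg)) next
    lab <- label_components_26(mg)
    sz <- tabulate(lab[lab > 0L])
    zl <- c(zl, rep(g, length(sz))); zs <- c(zs, sz)
  }
  S <- matrix(0, ng, max(zs))
  for (q in seq_along(zl)) S[zl[q], zs[q]] <- S[zl[q], zs[q]] + 1
  size_weighted_features(S, np,
    prefix = c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
               "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
               "SizeZoneNonUniformityNormalized", "ZonePercentage",
               "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
               "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
               "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
               "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

## shared feature arithmetic for run-length and size-zone matrices
## M: ng x smax count matrix (possibly direction-averaged), np voxel count
size_weighted_features <- function(M, np, prefix) {
  ns <- sum(M)
  g <- row(M); s <- col(M)
  p <- M / ns
  mug <- sum(g * p); mus <- sum(s * p)
  vals <- c(
    sum(M / s^2) / ns,
    sum(M * s^2) / ns,
    sum(rowSums(M)^2) / ns,
    sum(rowSums(M)^2) / ns^2,
    sum(colSums(M)^2) / ns,
    sum(colSums(M)^2) / ns^2,
    ns / np,
    sum(p * (g - mug)^2),
    sum(p * (s - mus)^2),
    entropy2(p),
    sum(M / g^2) / ns,
    sum(M * g^2) / ns,
    sum(M / (g^2 * s^2)) / ns,
    sum(M * g^2 / s^2) / ns,
    sum(M * s^2 / g^2) / ns,
    sum(M * g^2 * s^2) / ns
  )
  names(vals) <- prefix
  vals
}

## mean neighbour level (26-neighbourhood, NA-aware) for every VOI voxel
neighbour_means <- function(lv) {
  offs <- all_offsets_26()
  acc <- array(0, dim(lv)); cnt <- array(0L, dim(lv))
  for (k in seq_len(nrow(offs))) {
    nb <- shift_arr(lv, offs[k, ])
    ok <- !is.na(nb)
    acc[ok] <- acc[ok] + nb[ok]
    cnt <- cnt + ok
  }
  list(sum = acc, count = cnt)
}

#' Neighbouring gray tone difference matrix features
#'
#' Neighbourhood means use the 26-neighbourhood restricted to the VOI.
#' On a constant region Busyness, Contrast, Complexity and Strength are 0
#' and Coarseness takes the conventional large-value cap (1e6).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels) {
  lv <- crop_to_mask(levels)
  ng <- max(lv, na.rm = TRUE)
  inm <- !is.na(lv)
  np <- sum(inm)
  nbm <- neighbour_means(lv)
  has_nb <- inm & nbm$count > 0L
  gval <- lv[has_nb]
  aval <- nbm$sum[has_nb] / nbm$count[has_nb]
  n_g <- vapply(1:ng, function(g) sum(gval == g), 0)
  s_g <- vapply(1:ng, function(g) sum(abs(g - aval[gval == g])), 0)
  nv <- sum(n_g)
  p_g <- n_g / nv
  pres <- which(p_g > 0)
  ngp <- length(pres)
  coars_den <- sum(p_g * s_g)
  coarseness <- if (coars_den > 0) min(1 / coars_den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_g[pres], p_g[pres]) * outer(pres, pres, `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_g) / nv
  } else 0
  busy_den <- sum(abs(outer(pres * p_g[pres], pres * p_g[pres], `-`)))
  busyness <- if (busy_den > 0) sum(p_g * s_g) / busy_den else 0
  cplx <- 0; strg <- 0
  if (ngp > 1) {
    for (a in pres) for (b in pres) {
      cplx <- cplx + abs(a - b) * (p_g[a] * s_g[a] + p_g[b] * s_g[b]) /
        (p_g[a] + p_g[b])
      strg <- strg + (p_g[a] + p_g[b]) * (a - b)^2
    }
    cplx <- cplx / nv
    strg <- if (sum(s_g) > 0) strg / sum(s_g) else 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cplx, Strength = strg)
}

#' Gray-level dependence matrix features
#'
#' Dependence of a voxel is one plus the number of 26-neighbours within the
#' VOI whose gray level differs by at most `alpha` (default 0).
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on the gray-level difference.
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, alpha = 0L) {
  lv <- crop_to_mask(levels)
  ng <- max(lv, na.rm = TRUE)
  inm <- !is.na(lv)
  np <- sum(inm)
  offs <- all_offsets_26()
  dep <- array(1L, dim(lv))
  for (k in seq_len(nrow(offs))) {
    nb <- shift_arr(lv, offs[k, ])
    ok <- inm & !is.na(nb) & abs(nb - lv) <= alpha
    dep <- dep + ok
  }
  gval <- lv[inm]; dval <- dep[inm]
  D <- matrix(0, ng, max(dval))
  for (q in seq_along(gval)) D[gval[q], dval[q]] <- D[gval[q], dval[q]] + 1
  nd <- sum(D)
  g <- row(D); k <- col(D)
  p <- D / nd
  mug <- sum(g * p); muk <- sum(k * p)
  c(
    SmallDependenceEmphasis = sum(D / k^2) / nd,
    LargeDependenceEmphasis = sum(D * k^2) / nd,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nd,
    DependenceNonUniformity = sum(colSums(D)^2) / nd,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / nd^2,
    GrayLevelVariance = sum(p * (g - mug)^2),
    DependenceVariance = sum(p * (k - muk)^2),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(D / g^2) / nd,
    HighGrayLevelEmphasis = sum(D * g^2) / nd,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (g^2 * k^2)) / nd,
    SmallDependenceHighGrayLevelEmphasis = sum(D * g^2 / k^2) / nd,
    LargeDependenceLowGrayLevelEmphasis = sum(D * k^2 / g^2) / nd,
    LargeDependenceHighGrayLevelEmphasis = sum(D * g^2 * k^2) / nd
  )
}
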