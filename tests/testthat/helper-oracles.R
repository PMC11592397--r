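# Brute-force enumeration oracles, deliberately written as plain scalar
# loops so they share no code path with the vectorized implementations.

oracle_offsets <- function() {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      offs[[length(offs) + 1L]] <- c(dx, dy, dz)
  }
  offs
}

oracle_inb <- function(p, d) all(p >= 1) && all(p <= d)

# ---- GLCM ----------------------------------------------------------------

oracle_glcm_matrix <- function(lv) {
  d <- dim(lv); ng <- max(lv, na.rm = TRUE)
  mats <- list()
  for (o in oracle_offsets()) {
    cm <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lv[x, y, z]
      if (is.na(a)) next
      q <- c(x, y, z) + o
      if (!oracle_inb(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (is.na(b)) next
      cm[a, b] <- cm[a, b] + 1
      cm[b, a] <- cm[b, a] + 1
    }
    if (sum(cm) > 0) mats[[length(mats) + 1L]] <- cm / sum(cm)
  }
  P <- matrix(0, ng, ng)
  for (m in mats) P <- P + m
  P / length(mats)
}

oracle_glcm_features <- function(lv) {
  P <- oracle_glcm_matrix(lv)
  ng <- nrow(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx2 <- 0; sigy2 <- 0
  for (i in 1:ng) { sigx2 <- sigx2 + (i - mux)^2 * px[i]; sigy2 <- sigy2 + (i - muy)^2 * py[i] }
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(v) { s <- 0; for (x in v) if (x > 0) s <- s - x * log2(x); s }
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Id = 0, Idm = 0, Idmn = 0,
         Idn = 0, InverseVariance = 0, JointEnergy = 0, MaximumProbability = 0,
         SumSquares = 0, prodsum = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - mux - muy)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mux - muy)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - mux - muy)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + (i - j)^2 / ng^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    f["MaximumProbability"] <- max(f["MaximumProbability"], p)
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * p
    f["prodsum"] <- f["prodsum"] + i * j * p
  }
  da <- 0
  for (k in seq_along(pdiff)) da <- da + (k - 1) * pdiff[k]
  dv <- 0
  for (k in seq_along(pdiff)) dv <- dv + ((k - 1) - da)^2 * pdiff[k]
  sa <- 0
  for (k in seq_along(psum)) sa <- sa + k * psum[k]
  hxy <- ent(as.vector(P)); hx <- ent(px); hy <- ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  corr <- if (sigx2 > 0 && sigy2 > 0)
    (f[["prodsum"]] - mux * muy) / sqrt(sigx2 * sigy2) else 1
  mcc <- if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng) for (k in 1:ng)
      if (py[k] > 0) Q[i, j] <- Q[i, j] + P[i, k] * P[j, k] / (px[i] * py[k])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, if (length(ev) > 1) ev[2] else ev[1]))
  } else 1
  out <- c(f[setdiff(names(f), "prodsum")],
           Correlation = corr,
           DifferenceAverage = da, DifferenceEntropy = ent(pdiff),
           DifferenceVariance = dv, JointAverage = mux,
           JointEntropy = hxy, MCC = mcc,
           SumAverage = sa, SumEntropy = ent(psum),
           Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
           Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))))
  out
}

# ---- GLRLM ---------------------------------------------------------------

oracle_glrlm_matrix <- function(lv) {
  d <- dim(lv); ng <- max(lv, na.rm = TRUE)
  lmax <- max(d)
  offs <- oracle_offsets()
  R <- matrix(0, ng, lmax)
  for (o in offs) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      g <- lv[x, y, z]
      if (is.na(g)) next
      prev <- c(x, y, z) - o
      if (oracle_inb(prev, d)) {
        pg <- lv[prev[1], prev[2], prev[3]]
        if (!is.na(pg) && pg == g) next   # not a run start
      }
      len <- 1
      q <- c(x, y, z) + o
      while (oracle_inb(q, d)) {
        qg <- lv[q[1], q[2], q[3]]
        if (is.na(qg) || qg != g) break
        len <- len + 1
        q <- q + o
      }
      R[g, len] <- R[g, len] + 1
    }
  }
  R / length(offs)
}

oracle_szrl_features <- function(M, np, prefix) {
  ns <- sum(M); ng <- nrow(M); smax <- ncol(M)
  vals <- numeric(16)
  mug <- 0; mus <- 0
  for (g in 1:ng) for (s in 1:smax) {
    p <- M[g, s] / ns
    mug <- mug + g * p; mus <- mus + s * p
  }
  rents <- 0
  for (g in 1:ng) for (s in 1:smax) {
    m <- M[g, s]; p <- m / ns
    vals[1] <- vals[1] + m / s^2
    vals[2] <- vals[2] + m * s^2
    vals[8] <- vals[8] + p * (g - mug)^2
    vals[9] <- vals[9] + p * (s - mus)^2
    if (p > 0) rents <- rents - p * log2(p)
    vals[11] <- vals[11] + m / g^2
    vals[12] <- vals[12] + m * g^2
    vals[13] <- vals[13] + m / (g^2 * s^2)
    vals[14] <- vals[14] + m * g^2 / s^2
    vals[15] <- vals[15] + m * s^2 / g^2
    vals[16] <- vals[16] + m * g^2 * s^2
  }
  for (g in 1:ng) vals[3] <- vals[3] + sum(M[g, ])^2
  for (s in 1:smax) vals[5] <- vals[5] + sum(M[, s])^2
  vals[4] <- vals[3] / ns^2; vals[6] <- vals[5] / ns^2
  vals[c(1, 2, 3, 5, 11, 12, 13, 14, 15, 16)] <-
    vals[c(1, 2, 3, 5, 11, 12, 13, 14, 15, 16)] / ns
  vals[7] <- ns / np
  vals[10] <- rents
  names(vals) <- prefix
  vals
}

oracle_glrlm_features <- function(lv) {
  oracle_szrl_features(oracle_glrlm_matrix(lv), sum(!is.na(lv)),
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

# ---- GLSZM ---------------------------------------------------------------

oracle_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lv[x, y, z]
    if (is.na(g) || seen[x, y, z]) next
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!oracle_inb(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        qg <- lv[q[1], q[2], q[3]]
        if (!is.na(qg) && qg == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zones
}

oracle_glszm_features <- function(lv) {
  zones <- oracle_zones(lv)
  ng <- max(lv, na.rm = TRUE)
  smax <- max(vapply(zones, `[`, 0, 2))
  S <- matrix(0, ng, smax)
  for (zn in zones) S[zn[1], zn[2]] <- S[zn[1], zn[2]] + 1
  oracle_szrl_features(S, sum(!is.na(lv)),
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

# ---- NGTDM ---------------------------------------------------------------

oracle_ngtdm_features <- function(lv) {
  d <- dim(lv); ng <- max(lv, na.rm = TRUE)
  n_g <- numeric(ng); s_g <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lv[x, y, z]
    if (is.na(g)) next
    tot <- 0; cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!oracle_inb(q, d)) next
      qg <- lv[q[1], q[2], q[3]]
      if (!is.na(qg)) { tot <- tot + qg; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    n_g[g] <- n_g[g] + 1
    s_g[g] <- s_g[g] + abs(g - tot / cnt)
  }
  nv <- sum(n_g); p_g <- n_g / nv
  pres <- which(p_g > 0); ngp <- length(pres)
  den <- sum(p_g * s_g)
  coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- 0; busy_den <- 0; cplx <- 0; strg <- 0
  if (ngp > 1) {
    for (a in pres) for (b in pres) {
      contrast <- contrast + p_g[a] * p_g[b] * (a - b)^2
      cplx <- cplx + abs(a - b) * (p_g[a] * s_g[a] + p_g[b] * s_g[b]) /
        (p_g[a] + p_g[b])
      strg <- strg + (p_g[a] + p_g[b]) * (a - b)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s_g) / nv
    cplx <- cplx / nv
    strg <- if (sum(s_g) > 0) strg / sum(s_g) else 0
  }
  for (a in pres) for (b in pres)
    busy_den <- busy_den + abs(a * p_g[a] - b * p_g[b])
  busy <- if (busy_den > 0) sum(p_g * s_g) / busy_den else 0
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = strg)
}

# ---- GLDM ----------------------------------------------------------------

oracle_gldm_features <- function(lv, alpha = 0) {
  d <- dim(lv); ng <- max(lv, na.rm = TRUE)
  deps <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lv[x, y, z]
    if (is.na(g)) next
    k <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!oracle_inb(q, d)) next
      qg <- lv[q[1], q[2], q[3]]
      if (!is.na(qg) && abs(qg - g) <= alpha) k <- k + 1
    }
    deps[[length(deps) + 1L]] <- c(g, k)
  }
  kmax <- max(vapply(deps, `[`, 0, 2))
  D <- matrix(0, ng, kmax)
  for (dep in deps) D[dep[1], dep[2]] <- D[dep[1], dep[2]] + 1
  nd <- sum(D)
  mug <- 0; muk <- 0
  for (g in 1:ng) for (k in 1:kmax) {
    p <- D[g, k] / nd; mug <- mug + g * p; muk <- muk + k * p
  }
  out <- numeric(14)
  for (g in 1:ng) for (k in 1:kmax) {
    m <- D[g, k]; p <- m / nd
    out[1] <- out[1] + m / k^2
    out[2] <- out[2] + m * k^2
    out[6] <- out[6] + p * (g - mug)^2
    out[7] <- out[7] + p * (k - muk)^2
    if (p > 0) out[8] <- out[8] - p * log2(p)
    out[9] <- out[9] + m / g^2
    out[10] <- out[10] + m * g^2
    out[11] <- out[11] + m / (g^2 * k^2)
    out[12] <- out[12] + m * g^2 / k^2
    out[13] <- out[13] + m * k^2 / g^2
    out[14] <- out[14] + m * g^2 * k^2
  }
  for (g in 1:ng) out[3] <- out[3] + sum(D[g, ])^2
  for (k in 1:kmax) out[4] <- out[4] + sum(D[, k])^2
  out[5] <- out[4] / nd^2
  out[c(1, 2, 3, 4, 9, 10, 11, 12, 13, 14)] <-
    out[c(1, 2, 3, 4, 9, 10, 11, 12, 13, 14)] / nd
  names(out) <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                  "GrayLevelNonUniformity", "DependenceNonUniformity",
                  "DependenceNonUniformityNormalized", "GrayLevelVariance",
                  "DependenceVariance", "DependenceEntropy",
                  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                  "SmallDependenceLowGrayLevelEmphasis",
                  "SmallDependenceHighGrayLevelEmphasis",
                  "LargeDependenceLowGrayLevelEmphasis",
                  "LargeDependenceHighGrayLevelEmphasis")
  out
}

# ---- ICC -----------------------------------------------------------------

# explicit two-way ANOVA sums with scalar loops
oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + mat[i, j]
  grand <- grand / (n * k)
  ssr <- 0
  for (i in 1:n) {
    rm_ <- 0
    for (j in 1:k) rm_ <- rm_ + mat[i, j]
    ssr <- ssr + k * (rm_ / k - grand)^2
  }
  ssc <- 0
  for (j in 1:k) {
    cm_ <- 0
    for (i in 1:n) cm_ <- cm_ + mat[i, j]
    ssc <- ssc + n * (cm_ / n - grand)^2
  }
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (mat[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
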