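## Image-domain operators shared by the phantom generator and the feature
## extractor: separable Gaussian smoothing, Laplacian-of-Gaussian, one-level
## 3D Haar wavelet decomposition, trilinear resampling and SUV discretization.

## 1D convolution along axis `axis` with a symmetric kernel, reflect
## (edge-repeating) boundary handling. kernel is indexed -r..r.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (k in -r:r) {
    idx <- seq_len(n) + k
    while (any(idx < 1L | idx > n)) {     # repeat for axes shorter than r
      idx[idx < 1L] <- 1L - idx[idx < 1L]
      idx[idx > n] <- 2L * n + 1L - idx[idx > n]
    }
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[k + r + 1L] * shifted
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(( -r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## Separable Gaussian smoothing at a physical scale (mm); sigma is divided by
## the per-axis spacing.
gaussian_smooth <- function(arr, sigma_mm, spacing_mm) {
  out <- arr
  for (a in 1:3) {
    s <- sigma_mm / spacing_mm[a]
    if (s <= 0) next
    out <- convolve_axis(out, gaussian_kernel(s), a)
  }
  out
}

#' Laplacian-of-Gaussian filtered image
#'
#' Gaussian smoothing at a physical scale followed by the discrete Laplacian
#' (second central differences scaled by the squared spacing, reflect
#' boundary). The response to a constant field is exactly zero, and the mean
#' response over any volume is exactly zero (the reflected second difference
#' telescopes).
#'
#' @param vol a [pr_volume()].
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @return a `pr_volume` of the filtered values on the same grid.
#' @export
log_filter <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "pr_volume"), sigma_mm > 0)
  if (sigma_mm < min(vol$spacing_mm) / 2)
    warning("LoG sigma ", sigma_mm, " mm is below half the minimum voxel spacing")
  sm <- gaussian_smooth(vol$values, sigma_mm, vol$spacing_mm)
  lap <- array(0, dim(sm))
  for (a in 1:3) {
    h2 <- vol$spacing_mm[a]^2
    lap <- lap + convolve_axis(sm, c(1, -2, 1), a) / h2
  }
  pr_volume(lap, vol$spacing_mm, vol$origin_mm)
}

haar_axis <- function(arr, axis, high = FALSE) {
  d <- dim(arr)
  n <- d[axis]
  if (n %% 2L == 1L) {               # symmetric pad: replicate last sample
    idx <- c(seq_len(n), n)
    arr <- switch(axis,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    n <- n + 1L
  }
  odd <- seq(1L, n, by = 2L); evn <- odd + 1L
  pick <- function(i) switch(axis,
                             arr[i, , , drop = FALSE],
                             arr[, i, , drop = FALSE],
                             arr[, , i, drop = FALSE])
  if (high) (pick(odd) - pick(evn)) / sqrt(2) else (pick(odd) + pick(evn)) / sqrt(2)
}

#' One-level 3D Haar wavelet decomposition
#'
#' Decimated separable Haar transform giving eight subbands labelled
#' `LLL` ... `HHH` (letter i = filter applied along axis i). For even axis
#' lengths the transform is orthonormal, so subband energies sum exactly to
#' the input energy; odd axes are symmetrically padded by one sample first.
#'
#' @param vol a [pr_volume()]; every axis must have length >= 2.
#' @return named list of eight `pr_volume` subbands (spacing doubled).
#' @export
wavelet_decompose <- function(vol) {
  stopifnot(inherits(vol, "pr_volume"))
  if (any(dim(vol$values) < 2L)) stop("each axis length must be >= 2")
  out <- list()
  for (b1 in c("L", "H")) {
    s1 <- haar_axis(vol$values, 1L, b1 == "H")
    for (b2 in c("L", "H")) {
      s2 <- haar_axis(s1, 2L, b2 == "H")
      for (b3 in c("L", "H")) {
        s3 <- haar_axis(s2, 3L, b3 == "H")
        out[[paste0(b1, b2, b3)]] <-
          pr_volume(s3, vol$spacing_mm * 2, vol$origin_mm)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

## Decimate a logical mask to the Haar subband grid: a coarse voxel is kept
## when any voxel of its 2x2x2 block is in the mask.
decimate_mask <- function(mask) {
  or_axis <- function(arr, axis) {
    d <- dim(arr); n <- d[axis]
    if (n %% 2L == 1L) {
      idx <- c(seq_len(n), n)
      arr <- switch(axis, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
      n <- n + 1L
    }
    odd <- seq(1L, n, by = 2L); evn <- odd + 1L
    pick <- function(i) switch(axis, arr[i, , , drop = FALSE],
                               arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
    pick(odd) | pick(evn)
  }
  m <- mask
  for (a in 1:3) m <- or_axis(m, a)
  m
}

#' Resample a volume (and mask) to a target voxel spacing
#'
#' Trilinear interpolation for intensities, nearest neighbour for the mask.
#' The output grid keeps the input origin; the number of output voxels per
#' axis is `round(extent / target)` so physical extent is preserved to
#' within one voxel.
#'
#' @param vol a [pr_volume()].
#' @param mask a 0/1 `pr_volume` on the same grid, or `NULL`.
#' @param target_spacing_mm numeric length-3 (> 0), default 1 mm isotropic.
#' @return list with elements `volume` and `mask` (mask `NULL` if not given).
#' @export
resample_volume <- function(vol, mask = NULL, target_spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(vol, "pr_volume"), all(target_spacing_mm > 0))
  d <- dim(vol$values)
  extent <- d * vol$spacing_mm
  nd <- pmax(1L, as.integer(round(extent / target_spacing_mm)))
  # fractional input-grid coordinates of the output voxel centres
  coord <- lapply(1:3, function(a)
    ((seq_len(nd[a]) - 1) * target_spacing_mm[a]) / vol$spacing_mm[a] + 1)
  interp <- function(values, nearest = FALSE) {
    out <- array(0, nd)
    cx <- coord[[1]]; cy <- coord[[2]]; cz <- coord[[3]]
    if (nearest) {
      ix <- pmin(pmax(round(cx), 1), d[1])
      iy <- pmin(pmax(round(cy), 1), d[2])
      iz <- pmin(pmax(round(cz), 1), d[3])
      return(array(values[cbind(rep(ix, times = nd[2] * nd[3]),
                                rep(rep(iy, each = nd[1]), times = nd[3]),
                                rep(iz, each = nd[1] * nd[2]))], nd))
    }
    fx <- pmin(pmax(cx, 1), d[1]); fy <- pmin(pmax(cy, 1), d[2])
    fz <- pmin(pmax(cz, 1), d[3])
    x0 <- pmin(floor(fx), d[1] - ifelse(d[1] > 1, 1, 0)); tx <- fx - x0
    y0 <- pmin(floor(fy), d[2] - ifelse(d[2] > 1, 1, 0)); ty <- fy - y0
    z0 <- pmin(floor(fz), d[3] - ifelse(d[3] > 1, 1, 0)); tz <- fz - z0
    x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
    TX <- rep(tx, times = nd[2] * nd[3])
    TY <- rep(rep(ty, each = nd[1]), times = nd[3])
    TZ <- rep(tz, each = nd[1] * nd[2])
    gx0 <- rep(x0, times = nd[2] * nd[3]); gx1 <- rep(x1, times = nd[2] * nd[3])
    gy0 <- rep(rep(y0, each = nd[1]), times = nd[3])
    gy1 <- rep(rep(y1, each = nd[1]), times = nd[3])
    gz0 <- rep(z0, each = nd[1] * nd[2]); gz1 <- rep(z1, each = nd[1] * nd[2])
    v <- function(ix, iy, iz) values[cbind(ix, iy, iz)]
    acc <- v(gx0, gy0, gz0) * (1 - TX) * (1 - TY) * (1 - TZ) +
      v(gx1, gy0, gz0) * TX * (1 - TY) * (1 - TZ) +
      v(gx0, gy1, gz0) * (1 - TX) * TY * (1 - TZ) +
      v(gx1, gy1, gz0) * TX * TY * (1 - TZ) +
      v(gx0, gy0, gz1) * (1 - TX) * (1 - TY) * TZ +
      v(gx1, gy0, gz1) * TX * (1 - TY) * TZ +
      v(gx0, gy1, gz1) * (1 - TX) * TY * TZ +
      v(gx1, gy1, gz1) * TX * TY * TZ
    array(acc, nd)
  }
  vol_out <- pr_volume(interp(vol$values), target_spacing_mm, vol$origin_mm)
  mask_out <- NULL
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "pr_volume")) mask$values else mask
    mo <- interp(mv, nearest = TRUE)
    if (sum(mo) == 0) stop("mask empty after resampling")
    mask_out <- pr_volume(mo, target_spacing_mm, vol$origin_mm)
  }
  list(volume = vol_out, mask = mask_out)
}

#' Fixed-bin-width gray-level discretization
#'
#' `level(x) = floor(x / W) - floor(min(x) / W) + 1`, anchoring the first bin
#' at the volume-of-interest minimum so levels run 1..Ng.
#'
#' @param values numeric vector of intensities inside the VOI.
#' @param bin_width bin width W in intensity units (> 0).
#' @return integer vector of gray levels.
#' @export
discretize_suv <- function(values, bin_width) {
  stopifnot(length(values) > 0, bin_width > 0, all(is.finite(values)))
  as.integer(floor(values / bin_width) - floor(min(values) / bin_width) + 1)
}
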