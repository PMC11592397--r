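## 3D shape features from the binary mask geometry.
##
## The lesion surface is the triangulated 0.5-isosurface of the zero-padded
## lesion indicator after mild Gaussian anti-aliasing (sigma = 0.8 voxels).
## Each grid cell between eight voxel centres is split into six tetrahedra
## around the main diagonal and each mixed tetrahedron contributes its
## linearly interpolated isosurface triangles. Meshing the raw binary
## indicator (vertices at edge midpoints) overestimates the area of a
## digital ball by 25-30 percent; the anti-aliased isosurface is accurate
## to about 1-2 percent (digital ball sphericity 0.98-0.995). Masks too
## small to survive smoothing (peak below 0.5) fall back to the raw
## indicator. The mesh is closed and consistently oriented, giving surface
## area and the enclosed volume (divergence theorem).

## corner offsets of a cell, indexed 1..8
.cell_corners <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                          0,0,1, 1,0,1, 1,1,1, 0,1,1),
                        ncol = 3, byrow = TRUE)
## Kuhn decomposition: six tetrahedra around the 1-7 diagonal
.cell_tets <- matrix(c(1,2,3,7, 1,3,4,7, 1,4,8,7,
                       1,8,5,7, 1,5,6,7, 1,6,2,7),
                     ncol = 4, byrow = TRUE)

## Triangulate one tetrahedron family across many cells at once.
## verts: list of 4 (n x 3) corner coordinate matrices; vals: list of 4
## corner field values. Returns list(area, volume) with outward orientation.
tet_mesh_contrib <- function(verts, vals) {
  area <- 0; vol <- 0
  inside <- vapply(vals, function(v) v > 0.5, logical(length(vals[[1]])))
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = 1)
  case_id <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
  tri_accum <- function(p1, p2, p3, ref_in) {
    # orient outward (normal away from the inside reference point)
    u <- p2 - p1; v <- p3 - p1
    nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    ctr <- (p1 + p2 + p3) / 3
    s <- sign(nx * (ctr[, 1] - ref_in[, 1]) + ny * (ctr[, 2] - ref_in[, 2]) +
                nz * (ctr[, 3] - ref_in[, 3]))
    s[s == 0] <- 1
    a2 <- sqrt(nx^2 + ny^2 + nz^2)
    # signed volume of (origin, p1, p2, p3) with outward orientation
    det3 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
    list(area = sum(a2) / 2, vol = sum(s * det3) / 6)
  }
  for (cs in 1:14) {
    sel <- which(case_id == cs)
    if (!length(sel)) next
    inbits <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
    outbits <- setdiff(1:4, inbits)
    P <- lapply(verts, function(m) m[sel, , drop = FALSE])
    V <- lapply(vals, function(v) v[sel])
    mid <- function(i, j) {   # linear interpolation of the 0.5 crossing
      tt <- (0.5 - V[[i]]) / (V[[j]] - V[[i]])
      P[[i]] + tt * (P[[j]] - P[[i]])
    }
    ref <- Reduce(`+`, P[inbits]) / length(inbits)
    if (length(inbits) == 1L || length(inbits) == 3L) {
      odd <- if (length(inbits) == 1L) inbits else outbits
      oth <- setdiff(1:4, odd)
      r <- tri_accum(mid(odd, oth[1]), mid(odd, oth[2]), mid(odd, oth[3]), ref)
      area <- area + r$area; vol <- vol + r$vol
    } else {                                   # 2 in / 2 out: quad
      a <- inbits[1]; b <- inbits[2]; cc <- outbits[1]; dd <- outbits[2]
      q1 <- mid(a, cc); q2 <- mid(a, dd); q3 <- mid(b, dd); q4 <- mid(b, cc)
      r1 <- tri_accum(q1, q2, q3, ref); r2 <- tri_accum(q1, q3, q4, ref)
      area <- area + r1$area + r2$area; vol <- vol + r1$vol + r2$vol
    }
  }
  list(area = area, volume = vol)
}

## Surface area and enclosed volume of the anti-aliased 0.5-isosurface.
mask_mesh <- function(mask, spacing, sigma_vox = 0.8) {
  d <- dim(mask)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  fld <- pad
  if (sigma_vox > 0) {
    k <- gaussian_kernel(sigma_vox)
    for (a in 1:3) fld <- convolve_axis(fld, k, a)
    if (max(fld) <= 0.5) fld <- pad    # tiny mask: raw indicator fallback
  }
  pd <- dim(fld)
  nc <- pd - 1L
  corner_val <- function(off) {
    fld[(1 + off[1]):(nc[1] + off[1]),
        (1 + off[2]):(nc[2] + off[2]),
        (1 + off[3]):(nc[3] + off[3])]
  }
  vals <- lapply(seq_len(8), function(i) corner_val(.cell_corners[i, ]))
  ins <- lapply(vals, function(v) v > 0.5)
  any_in <- Reduce(`|`, ins)
  all_in <- Reduce(`&`, ins)
  mixed <- which(any_in & !all_in)
  if (!length(mixed)) return(list(area = 0, volume = 0))
  base <- arrayInd(mixed, nc)           # cell origin = padded voxel index
  base_phys <- sweep(base - 1, 2, spacing, `*`)  # coordinate of corner 1
  area <- 0; vol <- 0
  for (t in seq_len(6)) {
    ci <- .cell_tets[t, ]
    verts <- lapply(ci, function(i)
      sweep(base_phys, 2, .cell_corners[i, ] * spacing, `+`))
    vv <- lapply(ci, function(i) vals[[i]][mixed])
    r <- tet_mesh_contrib(verts, vv)
    area <- area + r$area; vol <- vol + r$volume
  }
  # fully-inside cells are enclosed by the mesh; vol is the total volume
  list(area = area, volume = abs(vol))
}

boundary_voxels <- function(mask) {
  d <- dim(mask)
  shift <- function(arr, axis, by) {
    idx <- seq_len(d[axis]) + by
    pad_val <- FALSE
    idx[idx < 1 | idx > d[axis]] <- NA
    out <- switch(axis,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    out[is.na(out)] <- pad_val
    out
  }
  nb_all <- mask
  for (a in 1:3) for (b in c(-1L, 1L)) nb_all <- nb_all & shift(mask, a, b)
  mask & !nb_all
}

max_pairwise_dist <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  best <- 0
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = step)) {
    rows <- s:min(n, s + step - 1L)
    dd <- outer(coords[rows, 1], coords[, 1], `-`)^2 +
      outer(coords[rows, 2], coords[, 2], `-`)^2 +
      outer(coords[rows, 3], coords[, 3], `-`)^2
    best <- max(best, max(dd))
  }
  sqrt(best)
}

#' 3D shape features of a lesion mask
#'
#' The 14 standard shape features: mesh/voxel volume, triangulated surface
#' area, surface-to-volume ratio, sphericity, maximum 3D diameter, the three
#' maximum in-plane 2D diameters, principal-moment axis lengths, elongation
#' and flatness. For a single-voxel mask the axis lengths are 0 and
#' elongation/flatness are defined as 1.
#'
#' @param mask 0/1 mask, `pr_volume` or 3D array.
#' @param spacing_mm voxel spacing (taken from the mask when a `pr_volume`).
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "pr_volume")) {
    if (is.null(spacing_mm)) spacing_mm <- mask$spacing_mm
    mask <- mask_array(mask)
  } else {
    mask <- mask_array(mask)
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  }
  if (!any(mask)) stop("empty mask")
  n <- sum(mask)
  vox_vol <- prod(spacing_mm)
  mesh <- mask_mesh(mask, spacing_mm)
  A <- mesh$area; V <- mesh$volume
  coords <- sweep(arrayInd(which(mask), dim(mask)) - 1, 2, spacing_mm, `*`)
  bnd <- sweep(arrayInd(which(boundary_voxels(mask)), dim(mask)) - 1, 2,
               spacing_mm, `*`)
  max2d <- function(plane_axes, group_axis) {
    g <- bnd[, group_axis]
    best <- 0
    for (u in unique(g)) {
      cc <- bnd[g == u, plane_axes, drop = FALSE]
      if (nrow(cc) >= 2L) {
        dd <- outer(cc[, 1], cc[, 1], `-`)^2 + outer(cc[, 2], cc[, 2], `-`)^2
        best <- max(best, max(dd))
      }
    }
    sqrt(best)
  }
  if (n > 1L) {
    ev <- sort(eigen(stats::cov(coords) * (n - 1) / n,
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    axis_len <- 4 * sqrt(ev)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    axis_len <- c(0, 0, 0); elong <- 1; flat <- 1
  }
  c(
    MeshVolume = V,
    VoxelVolume = n * vox_vol,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = (36 * pi * V^2)^(1 / 3) / A,
    Maximum3DDiameter = max_pairwise_dist(bnd),
    Maximum2DDiameterSlice = max2d(c(1, 2), 3),
    Maximum2DDiameterColumn = max2d(c(1, 3), 2),
    Maximum2DDiameterRow = max2d(c(2, 3), 1),
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = elong,
    Flatness = flat
  )
}
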