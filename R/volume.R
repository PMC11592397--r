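#' 3D scalar volume with physical geometry
#'
#' A `pr_volume` is the package's carrier for PET intensities (SUV-scaled)
#' and for binary masks: a 3D numeric array plus per-axis voxel spacing and
#' the physical position of the first voxel centre.
#'
#' @param values 3D numeric array.
#' @param spacing_mm numeric length-3, voxel size per axis in mm (> 0).
#' @param origin_mm numeric length-3, physical coordinate of voxel (1,1,1).
#' @return An object of class `pr_volume`.
#' @export
pr_volume <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be three finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "pr_volume")
}

#' @method print pr_volume
#' @export
print.pr_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pr_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.pr_volume <- function(x) dim(x$values)

is_mask <- function(x) {
  v <- if (inherits(x, "pr_volume")) x$values else x
  is.array(v) && length(dim(v)) == 3L && all(v %in% c(0, 1))
}

mask_array <- function(x) {
  v <- if (inherits(x, "pr_volume")) x$values else x
  storage.mode(v) <- "logical"
  v
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

#' Physical voxel-centre coordinates of a volume grid
#'
#' @param vol a `pr_volume`.
#' @return list of three numeric vectors (x, y, z centre coordinates, mm).
#' @keywords internal
voxel_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin_mm[a] + (seq_len(d[a]) - 1) * vol$spacing_mm[a])
}

## 26-connectivity component labelling on a logical 3D array.
## Vectorised: voxel indices become graph vertices, edges come from the 13
## unique positive offsets; igraph does the labelling.
label_components_26 <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  if (length(idx) == 1L) { lab[idx] <- 1L; return(lab) }
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lut <- integer(prod(d)); lut[key] <- seq_along(idx)
  offs <- texture_offsets_13()
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    q1 <- pos[, 1] + o[1]; q2 <- pos[, 2] + o[2]; q3 <- pos[, 3] + o[3]
    ok <- q1 >= 1 & q1 <= d[1] & q2 >= 1 & q2 <= d[2] & q3 >= 1 & q3 <= d[3]
    if (!any(ok)) next
    nk <- (q3[ok] - 1) * (d[1] * d[2]) + (q2[ok] - 1) * d[1] + q1[ok]
    j <- lut[nk]
    hit <- j > 0L
    from <- c(from, which(ok)[hit]); to <- c(to, j[hit])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_along(idx)
  lab[idx] <- as.integer(comp)
  lab
}

## The 13 unique 3D direction offsets (half of the 26-neighbourhood).
texture_offsets_13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

## Binary dilation by one voxel, 26-connectivity.
dilate_26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) - dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) - dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) - dz, 1L), d[3])
    out <- out | mask[sx, sy, sz]
  }
  out
}

## derive a 31-bit child seed from (seed, tag); keeps values < 2^31
derive_seed <- function(seed, tag) {
  x <- (as.numeric(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(tag))) x <- (x * 48271 + ch) %% 2147483647
  as.integer(x)
}
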