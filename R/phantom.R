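#' Specification of a synthetic PET lesion phantom
#'
#' Describes one PET-like volume: a spherical avid lesion with a radial
#' uptake profile and a multiplicative Gaussian-random-field texture, on a
#' uniform background, with additive Gaussian noise. Defaults emulate a
#' primary lung lesion imaged at typical PET resolution (about 3 mm voxels,
#' in-plane resolutions of real scans range from roughly 2.7 to 5.5 mm).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3 voxel size (mm).
#' @param lesion_center_mm physical centre of the lesion sphere (mm);
#'   default is the grid centre.
#' @param lesion_radius_mm sphere radius (mm).
#' @param suv_max peak lesion uptake (SUV); the realized maximum equals this
#'   exactly when `noise_sd = 0`.
#' @param background_suv mean background uptake (SUV), `< suv_max`.
#' @param texture_scale_mm correlation length of the intra-lesion
#'   heterogeneity field (mm).
#' @param heterogeneity_sd SD of the multiplicative texture field, in
#'   `[0, 1)`; the field is clipped to `1 +/- 3 * heterogeneity_sd`.
#' @param noise_sd additive Gaussian noise SD (SUV).
#' @param edge_fraction uptake at the sphere boundary as a fraction of the
#'   peak (parabolic radial profile); `1` gives a flat profile.
#' @param seed RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 24L),
                         spacing_mm = c(3, 3, 3),
                         lesion_center_mm = NULL,
                         lesion_radius_mm = 15,
                         suv_max = 10,
                         background_suv = 1,
                         texture_scale_mm = 3,
                         heterogeneity_sd = 0.2,
                         noise_sd = 0.2,
                         edge_fraction = 0.25,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lesion_center_mm)) lesion_center_mm <- (grid_shape - 1) * spacing_mm / 2
  spec <- list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
               lesion_center_mm = as.numeric(lesion_center_mm),
               lesion_radius_mm = lesion_radius_mm, suv_max = suv_max,
               background_suv = background_suv,
               texture_scale_mm = texture_scale_mm,
               heterogeneity_sd = heterogeneity_sd, noise_sd = noise_sd,
               edge_fraction = edge_fraction, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$grid_shape) == 3L, all(s$grid_shape >= 2L),
            all(s$spacing_mm > 0), s$lesion_radius_mm > 0,
            s$suv_max > s$background_suv, s$background_suv >= 0,
            s$heterogeneity_sd >= 0, s$heterogeneity_sd < 1,
            s$noise_sd >= 0, s$texture_scale_mm > 0,
            s$edge_fraction > 0, s$edge_fraction <= 1)
  lo <- s$lesion_center_mm - s$lesion_radius_mm
  hi <- s$lesion_center_mm + s$lesion_radius_mm
  if (any(lo < 0) || any(hi > (s$grid_shape - 1) * s$spacing_mm))
    stop("lesion sphere is not fully contained in the grid")
  invisible(s)
}

#' Generate a PET phantom volume and its true lesion mask
#'
#' The lesion sphere carries `suv_max * profile(r) * texture`, where
#' `profile(r) = 1 - (1 - edge_fraction) * (r/R)^2` and the texture field is
#' smoothed white noise rescaled to `heterogeneity_sd` and clipped at three
#' SDs around 1. The product is renormalized to a maximum of 1 over the
#' lesion so the realized lesion maximum equals `suv_max` exactly in the
#' noise-free case. Background voxels carry `background_suv`. Additive
#' Gaussian noise with SD `noise_sd` is applied everywhere. Identical seeds
#' give identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [pr_volume()]) and `true_mask` (0/1
#'   `pr_volume`, the exact sphere support).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  co <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec$spacing_mm[a])
  r2 <- outer(outer((co[[1]] - spec$lesion_center_mm[1])^2,
                    (co[[2]] - spec$lesion_center_mm[2])^2, "+"),
              (co[[3]] - spec$lesion_center_mm[3])^2, "+")
  r <- sqrt(r2)
  inside <- r <= spec$lesion_radius_mm
  if (!any(inside)) stop("lesion sphere contains no voxel centre")
  profile <- 1 - (1 - spec$edge_fraction) * (r / spec$lesion_radius_mm)^2
  vals <- array(spec$background_suv, d)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  tex <- array(1, d)
  if (spec$heterogeneity_sd > 0) {
    w <- array(stats::rnorm(prod(d)), d)
    f <- gaussian_smooth(w, spec$texture_scale_mm, spec$spacing_mm)
    f <- f / stats::sd(f) * spec$heterogeneity_sd
    f <- pmin(pmax(f, -3 * spec$heterogeneity_sd), 3 * spec$heterogeneity_sd)
    tex <- array(1 + f, d)
  }
  shape_fld <- profile * tex
  shape_fld <- shape_fld / max(shape_fld[inside])
  vals[inside] <- spec$suv_max * shape_fld[inside]
  if (spec$noise_sd > 0)
    vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
  list(volume = pr_volume(vals, spec$spacing_mm),
       true_mask = pr_volume(array(as.numeric(inside), d), spec$spacing_mm))
}
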