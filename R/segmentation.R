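#' Maximum standardized uptake value within a seed region
#'
#' @param volume a [pr_volume()].
#' @param seed_mask nonempty 0/1 mask (`pr_volume` or array) on the same grid.
#' @return scalar SUVmax.
#' @export
lesion_suvmax <- function(volume, seed_mask) {
  stopifnot(inherits(volume, "pr_volume"))
  m <- mask_array(seed_mask)
  if (!identical(dim(m), dim(volume$values))) stop("seed mask grid mismatch")
  if (!any(m)) stop("seed mask is empty")
  max(volume$values[m])
}

## Largest 26-connected component of `candidate` that intersects the seed.
## Ties on size: greater seed overlap, then lexicographically smallest
## centroid.
largest_component_touching <- function(candidate, seed) {
  lab <- label_components_26(candidate)
  touching <- sort(unique(lab[seed & lab > 0L]))
  if (length(touching) == 0L) {
    # fall back to components nearest in space is out of scope; no overlap
    touching <- sort(unique(lab[lab > 0L]))
    if (length(touching) == 0L) return(NULL)
  }
  sizes <- vapply(touching, function(l) sum(lab == l), 0L)
  best <- touching[sizes == max(sizes)]
  if (length(best) > 1L) {
    ov <- vapply(best, function(l) sum(lab == l & seed), 0L)
    best <- best[ov == max(ov)]
    if (length(best) > 1L) {
      cent <- t(vapply(best, function(l)
        colMeans(arrayInd(which(lab == l), dim(lab))), numeric(3)))
      best <- best[order(cent[, 1], cent[, 2], cent[, 3])][1]
    }
  }
  lab == best[1]
}

#' Fixed-threshold SUVmax contour
#'
#' Keeps the largest 26-connected component of
#' `{v : v >= fraction * SUVmax}` that intersects the seed region. SUVmax is
#' taken over the seed region; the comparison is closed (`>=`).
#'
#' @param volume a [pr_volume()].
#' @param seed_mask nonempty 0/1 mask on the volume grid.
#' @param fraction threshold fraction of SUVmax, in (0, 1).
#' @return 0/1 `pr_volume` contour mask.
#' @export
threshold_contour <- function(volume, seed_mask, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  suvmax <- lesion_suvmax(volume, seed_mask)
  cutoff <- fraction * suvmax
  cand <- volume$values >= cutoff
  if (!any(cand))
    stop(sprintf("no voxel reaches the %.0f%% SUVmax threshold (cutoff %.3g)",
                 100 * fraction, cutoff))
  comp <- largest_component_touching(cand, mask_array(seed_mask))
  if (is.null(comp) || !any(comp))
    stop(sprintf("empty contour at fraction %.2f", fraction))
  pr_volume(array(as.numeric(comp), dim(comp)), volume$spacing_mm, volume$origin_mm)
}

#' The five contour variants of one lesion
#'
#' Produces the mask set used for contour-robustness screening:
#' three SUVmax threshold contours (default 35/40/45 percent), a CT-window
#' volume-perception surrogate (`ct_perception`: the ground-truth lesion
#' support when available, otherwise the seed region), and a PET
#' volume-perception surrogate (`pet_perception`: the 40 percent contour
#' dilated by one voxel with seeded random boundary flips, emulating blur
#' and display-setting variability; deterministic under `surrogate_seed`).
#'
#' @param volume a [pr_volume()].
#' @param seed_mask nonempty 0/1 mask on the volume grid.
#' @param true_mask optional ground-truth lesion support for `ct_perception`.
#' @param fractions three threshold fractions, default `c(0.35, 0.40, 0.45)`.
#' @param surrogate_seed seed for the boundary flips of `pet_perception`.
#' @param flip_prob boundary flip probability (default 0.2).
#' @return object of class `pr_mask_set`: list with `variants` (named list
#'   `ct_perception`, `pet_perception`, `suv35`, `suv40`, `suv45`) and
#'   `suv_max`.
#' @export
make_mask_set <- function(volume, seed_mask, true_mask = NULL,
                          fractions = c(0.35, 0.40, 0.45),
                          surrogate_seed = 1L, flip_prob = 0.2) {
  stopifnot(length(fractions) == 3L, all(diff(fractions) > 0))
  suvmax <- lesion_suvmax(volume, seed_mask)
  thr <- lapply(fractions, function(f) threshold_contour(volume, seed_mask, f))
  names(thr) <- sprintf("suv%02.0f", 100 * fractions)
  ct <- if (!is.null(true_mask)) {
    pr_volume(array(as.numeric(mask_array(true_mask)), dim(volume$values)),
              volume$spacing_mm, volume$origin_mm)
  } else {
    pr_volume(array(as.numeric(mask_array(seed_mask)), dim(volume$values)),
              volume$spacing_mm, volume$origin_mm)
  }
  pet <- pet_perception_surrogate(thr[[2]], surrogate_seed, flip_prob)
  variants <- c(list(ct_perception = ct, pet_perception = pet), thr)
  empty <- vapply(variants, function(m) sum(m$values) == 0, TRUE)
  if (any(empty))
    stop("empty contour variant(s): ", paste(names(variants)[empty], collapse = ", "))
  structure(list(variants = variants, suv_max = suvmax), class = "pr_mask_set")
}

## dilate the reference contour by one voxel, then flip boundary voxels off
## with probability flip_prob; keep the largest component
pet_perception_surrogate <- function(ref_mask, seed = 1L, flip_prob = 0.2) {
  m <- mask_array(ref_mask)
  dil <- dilate_26(m)
  interior <- dil & !dilate_26(!dil)     # voxels whose full neighbourhood is inside
  boundary <- which(dil & !interior)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, "pet_perception"))
  drop <- boundary[stats::runif(length(boundary)) < flip_prob]
  out <- dil
  out[drop] <- FALSE
  if (!any(out)) out <- m
  comp <- largest_component_touching(out, m)
  if (!is.null(comp)) out <- comp
  pr_volume(array(as.numeric(out), dim(out)), ref_mask$spacing_mm, ref_mask$origin_mm)
}

#' Dice overlap of two masks
#' @param a,b 0/1 masks on a common grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  ma <- mask_array(a); mb <- mask_array(b)
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
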