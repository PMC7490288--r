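#' Rigid translation of a volume
#'
#' Translates a volume by a world-space offset in millimetres and resamples
#' it onto the same grid (out-of-field voxels are filled with
#' 0 / background). Intensity volumes use separable linear interpolation;
#' label volumes must use nearest-neighbour resampling.
#'
#' @param volume 3-D array.
#' @param offset_mm Length-3 offset in millimetres (world frame).
#' @param grid A [grid_spec()].
#' @param mode `"linear"` or `"nearest"`. Linear mode on an integer (label)
#'   volume is an error.
#' @param fill Fill value for voxels translated in from outside the field.
#' @return Translated volume.
#' @export
translate_volume <- function(volume, offset_mm, grid,
                             mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  check_volume_grid(volume, grid)
  if (mode == "linear" && is.integer(volume))
    stop("translate_volume: linear interpolation on an integer label ",
         "volume; use mode = 'nearest'")
  out <- volume
  off_vox <- offset_mm / grid$voxel_size_mm
  for (a in 1:3) {
    if (off_vox[a] == 0) next
    out <- shift_axis(out, a, off_vox[a], mode, fill)
  }
  out
}

# Shift all fibres along `axis` by a fractional voxel offset: the output at
# index i samples the input at i - off.
shift_axis <- function(arr, axis, off, mode, fill) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dim(m) <- c(n, prod(d[perm][-1]))
  src <- seq_len(n) - off
  if (mode == "nearest") {
    i0 <- round(src)
    ok <- i0 >= 1 & i0 <= n
    y <- m[ifelse(ok, i0, 1L), , drop = FALSE]
    y[!ok, ] <- fill
  } else {
    i0 <- floor(src)
    w <- src - i0
    ok0 <- i0 >= 1 & i0 <= n
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= n
    y0 <- m[ifelse(ok0, i0, 1L), , drop = FALSE]
    y0[!ok0, ] <- fill
    y1 <- m[ifelse(ok1, i0 + 1L, 1L), , drop = FALSE]
    y1[!ok1, ] <- fill
    y <- (1 - w) * y0 + w * y1
  }
  dim(y) <- d[perm]
  out <- aperm(y, order(perm))
  if (is.integer(arr) && mode == "nearest") storage.mode(out) <- "integer"
  out
}

#' Translate a parcellation (misregistration surrogate)
#'
#' Applies a rigid translation to the label volume with nearest-neighbour
#' resampling, emulating a PET-to-MR registration error: the anatomical side
#' moves while the PET image stays fixed, so labels are resampled exactly
#' once and the PET intensities are never interpolated.
#'
#' @param parc A `parcellation`.
#' @param offset_mm Length-3 offset in millimetres.
#' @return The translated `parcellation`.
#' @export
translate_parcellation <- function(parc, offset_mm) {
  parc$labels <- translate_volume(parc$labels, offset_mm, parc$grid,
                                  mode = "nearest", fill = 0L)
  counts <- region_voxel_counts(parc)
  if (any(counts == 0))
    stop("translate_parcellation: region '", names(counts)[counts == 0][1],
         "' was translated out of the field of view")
  parc
}

# Deterministic candidate ordering: squared distance from the region
# centroid (ascending), ties broken by linear index.
order_by_centroid <- function(idx, dim3, centroid, decreasing = FALSE) {
  co <- arrayInd(idx, dim3)
  d2 <- (co[, 1] - centroid[1])^2 + (co[, 2] - centroid[2])^2 +
    (co[, 3] - centroid[3])^2
  idx[order(d2, idx, decreasing = decreasing)]
}

#' Rescale the volume of parcellation regions (mis-segmentation surrogate)
#'
#' Grows (factor > 1) or shrinks (factor < 1) each target region to the
#' requested voxel-count ratio by deterministic morphological dilation or
#' erosion with a 6-connected structuring element, one shell at a time with
#' partial-shell voxel selection ordered by distance from the region
#' centroid then linear index. Gained voxels are taken from spatially
#' adjacent labels; lost voxels are returned to the majority adjacent label,
#' so the total brain-mask voxel count is conserved.
#'
#' @param parc A `parcellation`.
#' @param region Region names or ids to rescale (each rescaled in turn).
#' @param factor Positive target volume ratio.
#' @param tolerance Acceptable relative deviation of the achieved ratio.
#' @return The rescaled `parcellation` with attribute `achieved_factors`.
#' @export
rescale_region_volume <- function(parc, region, factor, tolerance = 0.05) {
  if (factor <= 0) stop("rescale_region_volume: factor must be > 0")
  ids <- if (is.character(region))
    parc$regions$region_id[match(region, parc$regions$name)]
  else as.integer(region)
  if (any(is.na(ids)) || !all(ids %in% parc$regions$region_id))
    stop("rescale_region_volume: unknown region ",
         paste(region[is.na(ids) | !(ids %in% parc$regions$region_id)],
               collapse = ", "))
  achieved <- numeric(0)
  for (id in ids) {
    parc$labels <- rescale_one_region(parc, id, factor, tolerance)
    nm <- parc$regions$name[parc$regions$region_id == id]
    achieved[nm] <- sum(parc$labels == id) /
      max(1L, attr(parc$labels, "n0"))
    attr(parc$labels, "n0") <- NULL
  }
  attr(parc, "achieved_factors") <- achieved
  parc
}

rescale_one_region <- function(parc, id, factor, tolerance) {
  labels <- parc$labels
  d <- dim(labels)
  region <- labels == id
  n0 <- sum(region)
  if (n0 == 0) stop("rescale_region_volume: region ", id, " is empty")
  target <- max(1L, as.integer(round(factor * n0)))
  centroid <- colMeans(arrayInd(which(region), d))
  if (target > n0) {
    while (sum(labels == id) < target) {
      region <- labels == id
      cand <- which(neighbor_union(region) & !region & labels > 0L)
      if (length(cand) == 0) {
        ach <- sum(labels == id) / n0
        if (abs(ach - factor) <= tolerance * factor) break
        stop("rescale_region_volume: region ", id, " cannot reach factor ",
             factor, "; achievable range is about [",
             round(1 / n0, 3), ", ", round(ach, 3), "]")
      }
      need <- target - sum(labels == id)
      take <- order_by_centroid(cand, d, centroid)[seq_len(min(need,
                                                               length(cand)))]
      labels[take] <- id
    }
  } else if (target < n0) {
    while (sum(labels == id) > target) {
      region <- labels == id
      boundary <- which(region & !morph_erode(region))
      excess <- sum(labels == id) - target
      if (length(boundary) == 0 || sum(region) - length(boundary) < 0) {
        stop("rescale_region_volume: region ", id, " would vanish before ",
             "reaching factor ", factor)
      }
      drop <- order_by_centroid(boundary, d, centroid, decreasing = TRUE)
      drop <- drop[seq_len(min(excess, length(drop)))]
      labels[drop] <- reassign_labels(labels, drop, id, d)
    }
  }
  ach <- sum(labels == id) / n0
  if (abs(ach - factor) > tolerance * factor)
    stop("rescale_region_volume: achieved factor ", round(ach, 3),
         " for region ", id, " outside tolerance of target ", factor)
  attr(labels, "n0") <- n0
  labels
}

# Majority label among the 6-neighbours (excluding the shrinking region and
# background); widened to the 26-neighbourhood when empty. Ties break to the
# smallest label.
reassign_labels <- function(labels, voxels, id, d) {
  co <- arrayInd(voxels, d)
  vapply(seq_along(voxels), function(k) {
    for (radius in 1:2) {
      offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                    dz = -radius:radius))
      if (radius == 1)
        offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
      else
        offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
      nb <- sweep(offs, 2, co[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      ls <- labels[cbind(nb[, 1], nb[, 2], nb[, 3])]
      ls <- ls[ls > 0L & ls != id]
      if (length(ls) > 0) {
        tab <- sort(table(ls), decreasing = TRUE)
        best <- as.integer(names(tab)[tab == tab[1]])
        return(min(best))
      }
    }
    stop("rescale_region_volume: no adjacent label to receive voxel ",
         voxels[k])
  }, integer(1))
}

#' The study's canonical perturbation grids
#'
#' The default error magnitudes of the three error sources: PSF FWHM values
#' of 5, 6, 8 and 9 mm against a true 7 mm (mismatch -2, -1, +1, +2 mm);
#' lateral (X) translations of -5.4, -2.7, +2.7 and +5.4 mm and axial (Z)
#' translations of -4.9, -2.4, +2.4 and +4.9 mm (one and two voxel pitches);
#' hippocampus volume factors 0.5, 0.7, 1.4 and 1.6; global cortical volume
#' factors 0.6, 0.8, 1.3 and 1.5. The cortex set for global rescaling is
#' every grey matter ribbon region (temporal, parietal, occipital, residual
#' cortex; both hemispheres), excluding the subcortical blobs and the
#' cerebellum.
#'
#' @return Named list of default magnitude vectors and the cortex region set.
#' @export
canonical_perturbations <- function() {
  list(
    true_fwhm_mm = 7,
    fwhm_used_mm = c(5, 6, 8, 9),
    x_offsets_mm = c(-5.4, -2.7, 2.7, 5.4),
    z_offsets_mm = c(-4.9, -2.4, 2.4, 4.9),
    hippocampus_factors = c(0.5, 0.7, 1.4, 1.6),
    cortex_factors = c(0.6, 0.8, 1.3, 1.5),
    hippocampus_regions = c("hippocampus_l", "hippocampus_r"),
    cortex_regions = c("mid_inferior_temporal_l", "mid_inferior_temporal_r",
                       "parietal_l", "parietal_r",
                       "occipital_l", "occipital_r",
                       "other_cortex_l", "other_cortex_r")
  )
}
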