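#' @section Phantom anatomy:
#' The digital phantom is a geometric surrogate for an MRI-based brain
#' parcellation: nested ellipsoids form a CSF envelope, a thin cortical grey
#' matter ribbon and a white matter core; ellipsoidal blobs embedded in the
#' white matter stand in for hippocampus, parahippocampal gyrus and fusiform
#' gyrus (bilateral, mirror-symmetric about the mid-sagittal plane); angular
#' sectors of the ribbon define temporal, parietal and occipital cortex; a
#' separate two-shell ellipsoid below the cerebrum provides cerebellar grey
#' and white matter. This reproduces the spill-over topology that drives the
#' partial volume effect (thin grey matter sandwiched between hot white
#' matter and cold CSF) without real anatomy.
#' @name phantom-anatomy
#' @keywords internal
NULL

REGION_TABLE <- data.frame(
  region_id = 1:18,
  name = c("cerebral_wm", "csf", "cerebellar_gm", "cerebellar_wm",
           "mid_inferior_temporal_l", "mid_inferior_temporal_r",
           "parietal_l", "parietal_r",
           "occipital_l", "occipital_r",
           "parahippocampal_l", "parahippocampal_r",
           "hippocampus_l", "hippocampus_r",
           "fusiform_l", "fusiform_r",
           "other_cortex_l", "other_cortex_r"),
  tissue_class = c("WM", "CSF", "GM", "WM", rep("GM", 14)),
  laterality = c(rep("midline", 4),
                 rep(c("left", "right"), 7)),
  stringsAsFactors = FALSE
)

# Base names of the six analysis ROIs (left/right pairs in REGION_TABLE).
ANALYSIS_ROIS <- c("mid_inferior_temporal", "parietal", "occipital",
                   "parahippocampal", "hippocampus", "fusiform")

#' Phantom geometry and truth-table configuration
#'
#' Returns the full parameter set of the geometric phantom for one condition.
#' All linear sizes are millimetres. The truth SUVR tables are package
#' defaults chosen to emulate a tau tracer with high non-specific white-matter
#' binding: the AD condition has a thinner cortex, a smaller hippocampus,
#' higher target-region uptake and elevated white matter. Every entry can be
#' overridden via the `config` argument of [build_phantom()].
#'
#' @param preset `"HC"` or `"AD"`.
#' @param scale Global scale factor applied to every linear size (use < 1 to
#'   fit the anatomy into small test grids).
#' @return A named list of geometry parameters and truth tables.
#' @export
phantom_config <- function(preset = c("HC", "AD"), scale = 1) {
  preset <- match.arg(preset)
  cortical_thickness <- if (preset == "AD") 3.2 else 4.5
  hippo_scale <- if (preset == "AD") 0.82 else 1.0
  cfg <- list(
    scale = scale,
    center_offset_mm = c(0, 5, 15),      # cerebrum centre rel. volume centre
    csf_outer_semi_mm = c(70, 85, 55),   # outer CSF envelope
    csf_thickness_mm = 4,
    cortical_thickness_mm = cortical_thickness,
    ventricle_semi_mm = c(12, 25, 9),
    hippo_center_mm = c(28, -5, -26),    # rel. cerebrum centre; x mirrored
    hippo_semi_mm = c(9, 14, 6.5) * hippo_scale,
    parahippo_center_mm = c(20, -8, -36),
    parahippo_semi_mm = c(7, 12, 4.5),
    fusiform_center_mm = c(38, -16, -28),
    fusiform_semi_mm = c(6, 13, 5),
    cerebellum_center_mm = c(0, -58, -45),
    cerebellum_semi_mm = c(30, 24, 18),
    cerebellum_gm_thickness_mm = 5,
    surface_jitter_sd = 0.02,            # relative radial roughness
    truth_suvr = list(
      HC = c(cerebral_wm = 1.8, csf = 0.05, cerebellar_gm = 1.0,
             cerebellar_wm = 1.8, mid_inferior_temporal = 1.2,
             parietal = 1.1, occipital = 1.1, parahippocampal = 1.2,
             hippocampus = 1.1, fusiform = 1.2, other_cortex = 1.0),
      AD = c(cerebral_wm = 2.0, csf = 0.05, cerebellar_gm = 1.0,
             cerebellar_wm = 2.0, mid_inferior_temporal = 2.2,
             parietal = 1.1, occipital = 1.1, parahippocampal = 2.4,
             hippocampus = 1.8, fusiform = 2.0, other_cortex = 1.0)
    )
  )
  sz <- c("center_offset_mm", "csf_outer_semi_mm", "csf_thickness_mm",
          "cortical_thickness_mm", "ventricle_semi_mm", "hippo_center_mm",
          "hippo_semi_mm", "parahippo_center_mm", "parahippo_semi_mm",
          "fusiform_center_mm", "fusiform_semi_mm", "cerebellum_center_mm",
          "cerebellum_semi_mm", "cerebellum_gm_thickness_mm")
  for (f in sz) cfg[[f]] <- cfg[[f]] * scale
  cfg
}

# Squared normalised ellipsoid radius field.
ellipsoid_rho2 <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2
}

# Smooth random field with zero mean and given sd, used as relative radial
# roughness so the phantom surfaces are not perfect ellipsoids.
surface_jitter <- function(grid, sd, seed) {
  if (sd <= 0) return(array(0, grid$shape))
  set.seed(seed)
  j <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  j <- gaussian_blur(j, fwhm_mm = 25, grid = grid)
  s <- stats::sd(j)
  if (s == 0) return(array(0, grid$shape))
  j / s * sd
}

#' Build the parcellated digital brain phantom
#'
#' Deterministically generates the integer label volume and region table for
#' one condition. The same `(preset, grid, seed)` always yields bit-identical
#' labels; the seed controls only a mild smooth roughening of the ellipsoid
#' surfaces (an "individual anatomy" effect).
#'
#' @param preset `"HC"` (healthy control) or `"AD"` (thinner cortex, smaller
#'   hippocampus).
#' @param grid A [grid_spec()].
#' @param seed Integer seed for the surface roughness field.
#' @param config Geometry/truth configuration, by default
#'   `phantom_config(preset)`. Pass a modified copy to override any entry.
#' @return An object of class `parcellation`: list with `grid`, `labels`
#'   (integer 3-D array, 0 = background), `regions` (data frame with
#'   `region_id`, `name`, `tissue_class`, `laterality`, `suvr_HC`, `suvr_AD`)
#'   and `config`.
#' @export
build_phantom <- function(preset = c("HC", "AD"), grid = grid_spec(),
                          seed = 1L, config = phantom_config(preset)) {
  preset <- match.arg(preset)
  ax <- grid_axes_mm(grid)
  X <- array(ax[[1]], grid$shape)
  Y <- array(rep(ax[[2]], each = grid$shape[1]), grid$shape)
  Z <- array(rep(ax[[3]], each = prod(grid$shape[1:2])), grid$shape)
  c0 <- grid_center_mm(grid) + config$center_offset_mm

  jit <- surface_jitter(grid, config$surface_jitter_sd, seed)
  grow <- (1 + jit)^2

  id <- function(nm) REGION_TABLE$region_id[REGION_TABLE$name == nm]
  labels <- array(0L, grid$shape)

  # nested cerebral shells: CSF envelope > GM ribbon > WM core
  semi_csf <- config$csf_outer_semi_mm
  semi_gmo <- semi_csf - config$csf_thickness_mm
  semi_gmi <- semi_gmo - config$cortical_thickness_mm
  in_csf <- ellipsoid_rho2(X, Y, Z, c0, semi_csf) <= grow
  in_gmo <- ellipsoid_rho2(X, Y, Z, c0, semi_gmo) <= grow
  in_gmi <- ellipsoid_rho2(X, Y, Z, c0, semi_gmi) <= grow
  labels[in_csf] <- id("csf")

  # cortical ribbon split into lobar sectors on normalised coordinates
  ribbon <- in_gmo & !in_gmi
  ux <- (X - c0[1]) / semi_gmo[1]
  uy <- (Y - c0[2]) / semi_gmo[2]
  uz <- (Z - c0[3]) / semi_gmo[3]
  left <- ux <= 0
  occ <- ribbon & (uy <= -0.62)
  par_ <- ribbon & !occ & (uz >= 0.45) & (uy <= 0.30)
  temp <- ribbon & !occ & !par_ &
    (uz <= -0.15) & (abs(ux) >= 0.25) & (uy < 0.35)
  oth <- ribbon & !occ & !par_ & !temp
  labels[occ & left] <- id("occipital_l")
  labels[occ & !left] <- id("occipital_r")
  labels[par_ & left] <- id("parietal_l")
  labels[par_ & !left] <- id("parietal_r")
  labels[temp & left] <- id("mid_inferior_temporal_l")
  labels[temp & !left] <- id("mid_inferior_temporal_r")
  labels[oth & left] <- id("other_cortex_l")
  labels[oth & !left] <- id("other_cortex_r")

  labels[in_gmi] <- id("cerebral_wm")

  # ventricular CSF inside the white matter core
  vent <- ellipsoid_rho2(X, Y, Z, c0, config$ventricle_semi_mm) <= 1 & in_gmi
  labels[vent] <- id("csf")

  # subcortical blobs carved out of white matter (hippocampus assigned last
  # so it keeps its voxels wherever blobs would overlap)
  carve <- function(labels, center_rel, semi, id_l, id_r) {
    for (s in c(-1, 1)) {
      ctr <- c0 + center_rel * c(s, 1, 1)
      blob <- ellipsoid_rho2(X, Y, Z, ctr, semi) <= 1 &
        labels == id("cerebral_wm")
      labels[blob] <- if (s < 0) id_l else id_r
    }
    labels
  }
  labels <- carve(labels, config$fusiform_center_mm, config$fusiform_semi_mm,
                  id("fusiform_l"), id("fusiform_r"))
  labels <- carve(labels, config$parahippo_center_mm,
                  config$parahippo_semi_mm,
                  id("parahippocampal_l"), id("parahippocampal_r"))
  labels <- carve(labels, config$hippo_center_mm, config$hippo_semi_mm,
                  id("hippocampus_l"), id("hippocampus_r"))

  # cerebellum occupies background/CSF below the cerebrum, never cerebral GM/WM
  cb_ctr <- c0 + config$cerebellum_center_mm
  cb_out <- ellipsoid_rho2(X, Y, Z, cb_ctr, config$cerebellum_semi_mm) <= grow
  cb_in <- ellipsoid_rho2(
    X, Y, Z, cb_ctr,
    config$cerebellum_semi_mm - config$cerebellum_gm_thickness_mm) <= grow
  free <- labels == 0L | labels == id("csf")
  labels[cb_out & !cb_in & free] <- id("cerebellar_gm")
  labels[cb_in & free] <- id("cerebellar_wm")

  regions <- REGION_TABLE
  base <- sub("_(l|r)$", "", regions$name)
  regions$suvr_HC <- unname(config$truth_suvr$HC[base])
  regions$suvr_AD <- unname(config$truth_suvr$AD[base])

  counts <- tabulate(labels, nbins = max(regions$region_id))
  empty <- regions$name[counts[regions$region_id] == 0]
  if (length(empty) > 0)
    stop("build_phantom: grid too small to realize region '", empty[1],
         "' (and ", length(empty) - 1, " more); enlarge the grid or shrink ",
         "the geometry via phantom_config(scale = ...)")

  structure(list(grid = grid, labels = labels, regions = regions,
                 preset = preset, seed = as.integer(seed), config = config),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = max(x$regions$region_id))
  cat(sprintf("<parcellation> preset %s, %d regions, %d brain voxels on %d x %d x %d grid\n",
              x$preset, nrow(x$regions), sum(x$labels > 0L),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  df <- x$regions[, c("region_id", "name", "tissue_class")]
  df$voxels <- counts[x$regions$region_id]
  print(df, row.names = FALSE)
  invisible(x)
}

# Voxel count per region id (named vector).
region_voxel_counts <- function(parc) {
  counts <- tabulate(parc$labels, nbins = max(parc$regions$region_id))
  stats::setNames(counts[parc$regions$region_id], parc$regions$name)
}

#' Assign ground-truth SUVR values to a parcellation
#'
#' Produces the piecewise-constant true SUVR volume for one condition. Values
#' come from the parcellation's truth table (`suvr_HC` / `suvr_AD` columns)
#' and are renormalised so that the cerebellar grey matter — the SUVR
#' reference region — is exactly 1. The truth volume is never filtered.
#'
#' @param parcellation A [build_phantom()] result.
#' @param condition `"HC"` or `"AD"`.
#' @return An object of class `truth_image`: list with `grid`, `values`
#'   (3-D array) and `condition`.
#' @export
assign_truth <- function(parcellation, condition = c("HC", "AD")) {
  condition <- match.arg(condition)
  col <- paste0("suvr_", condition)
  vals <- parcellation$regions[[col]]
  if (is.null(vals) || any(!is.finite(vals)))
    stop("assign_truth: missing truth SUVR for region '",
         parcellation$regions$name[which(!is.finite(vals))[1]],
         "' under condition ", condition)
  ref <- vals[parcellation$regions$name == "cerebellar_gm"]
  vals <- vals / ref
  lut <- numeric(max(parcellation$regions$region_id) + 1L)
  lut[parcellation$regions$region_id + 1L] <- vals
  values <- array(lut[parcellation$labels + 1L], parcellation$grid$shape)
  structure(list(grid = parcellation$grid, values = values,
                 condition = condition),
            class = "truth_image")
}

#' Build the two-tissue attenuation map
#'
#' All brain-tissue voxels receive the 511 keV linear attenuation coefficient
#' of soft tissue (0.096 per cm); a skull shell generated by morphological
#' dilation of the brain mask receives the bone value (0.144 per cm); the
#' exterior is 0.
#'
#' @param parcellation A [build_phantom()] result.
#' @param skull_voxels Thickness of the morphological bone shell in voxels.
#' @return An object of class `attenuation_map`: list with `grid` and `mu`
#'   (3-D array, per cm).
#' @export
build_attenuation <- function(parcellation, skull_voxels = 2L) {
  brain <- parcellation$labels > 0L
  shell <- morph_dilate(brain, iterations = skull_voxels) & !brain
  mu <- array(0, parcellation$grid$shape)
  mu[brain] <- 0.096
  mu[shell] <- 0.144
  structure(list(grid = parcellation$grid, mu = mu),
            class = "attenuation_map")
}

#' Point-source object
#'
#' A single-voxel impulse (total content = `amplitude`) at the voxel nearest
#' to `center_mm`, used to measure the effective resolution of the simulation
#' chain.
#'
#' @param grid A [grid_spec()].
#' @param center_mm World coordinates of the source, millimetres; defaults to
#'   the grid centre.
#' @param amplitude Total source content.
#' @return A `truth_image` with condition `"point"`.
#' @export
make_point_source <- function(grid, center_mm = grid_center_mm(grid),
                              amplitude = 1) {
  hi <- (grid$shape - 1) * grid$voxel_size_mm
  if (any(center_mm < -grid$voxel_size_mm / 2) ||
      any(center_mm > hi + grid$voxel_size_mm / 2))
    stop("make_point_source: center (", paste(signif(center_mm, 4),
         collapse = ", "), ") mm lies outside the grid")
  idx <- pmin(pmax(round(center_mm / grid$voxel_size_mm) + 1, 1), grid$shape)
  values <- array(0, grid$shape)
  values[idx[1], idx[2], idx[3]] <- amplitude
  structure(list(grid = grid, values = values, condition = "point"),
            class = "truth_image")
}
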