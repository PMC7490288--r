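#' Write a volume as NIfTI-1
#'
#' @param volume 3-D array.
#' @param grid A [grid_spec()] supplying the voxel dimensions.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, e.g. `"float"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, grid, path, datatype = "float") {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a volume and its grid from NIfTI-1
#'
#' @param path NIfTI file.
#' @return List with `values` (3-D array) and `grid` ([grid_spec()]).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(values = arr,
       grid = grid_spec(dim(arr), RNifti::pixdim(img)[1:3]))
}

#' Write a phantom to disk
#'
#' Writes the label map (`labels.nii`, int16), the truth SUVR images for
#' both conditions (`truth_HC.nii`, `truth_AD.nii`, float32), the
#' attenuation map (`mu_map.nii`, float32) and the region table
#' (`regions.csv`).
#'
#' @param parc A `parcellation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(parc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume_nifti(parc$labels, parc$grid, file.path(dir, "labels.nii"),
                     datatype = "int16")
  for (cond in c("HC", "AD"))
    write_volume_nifti(assign_truth(parc, cond)$values, parc$grid,
                       file.path(dir, paste0("truth_", cond, ".nii")))
  write_volume_nifti(build_attenuation(parc)$mu, parc$grid,
                     file.path(dir, "mu_map.nii"))
  utils::write.csv(parc$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a parcellation from a label NIfTI and region CSV
#'
#' @param labels_path NIfTI label map (integers).
#' @param regions_path CSV with columns `region_id`, `name`, `tissue_class`,
#'   `laterality` and optional `suvr_HC`, `suvr_AD`.
#' @return A `parcellation`.
#' @export
read_parcellation <- function(labels_path, regions_path) {
  v <- read_volume_nifti(labels_path)
  labels <- v$values
  storage.mode(labels) <- "integer"
  regions <- utils::read.csv(regions_path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "tissue_class", "laterality")
  if (!all(need %in% names(regions)))
    stop("read_parcellation: region table must have columns ",
         paste(need, collapse = ", "))
  structure(list(grid = v$grid, labels = labels, regions = regions,
                 preset = NA_character_, seed = NA_integer_,
                 config = NULL),
            class = "parcellation")
}
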