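#' Image grid specification
#'
#' Defines the voxel lattice shared by all volumes in a study: array shape and
#' physical voxel size. World coordinates are `index * voxel_size` with a
#' 0-based index origin at the volume corner, so the centre of voxel
#' `(i, j, k)` (1-based R index) sits at `((i-1) * dx, (j-1) * dy, (k-1) * dz)`
#' millimetres.
#'
#' @param shape Integer triple `(nx, ny, nz)`; every dimension must be at
#'   least 8. Default `c(128, 128, 63)`.
#' @param voxel_size_mm Positive real triple, millimetres per voxel along each
#'   axis. Default `c(2.682, 2.682, 2.425)`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 32))
#' g$voxel_size_mm
#' @export
grid_spec <- function(shape = c(128L, 128L, 63L),
                      voxel_size_mm = c(2.682, 2.682, 2.425)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(voxel_size_mm) == 3)
  if (any(shape < 8L))
    stop("grid_spec: all dimensions must be >= 8, got (",
         paste(shape, collapse = ", "), ")")
  if (any(voxel_size_mm <= 0))
    stop("grid_spec: voxel sizes must be positive")
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

# World-coordinate (mm) vectors of voxel centres along each axis.
grid_axes_mm <- function(grid) {
  lapply(1:3, function(a) (seq_len(grid$shape[a]) - 1) * grid$voxel_size_mm[a])
}

# Centre of the volume in mm (midpoint of the voxel-centre range).
grid_center_mm <- function(grid) {
  (grid$shape - 1) * grid$voxel_size_mm / 2
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!isTRUE(all.equal(a$shape, b$shape)) ||
      !isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)))
    stop("grid mismatch between ", what)
  invisible(TRUE)
}

check_volume_grid <- function(vol, grid) {
  if (!identical(dim(vol), as.integer(grid$shape)))
    stop("volume dimensions (", paste(dim(vol), collapse = ", "),
         ") do not match grid (", paste(grid$shape, collapse = ", "), ")")
  invisible(TRUE)
}
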