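# Independent brute-force oracles for the ROI-based corrections, built from
# dense 1-D convolution matrices and base linear algebra. Because the slab
# phantom's regions are functions of x only, the 3-D problem factorises and
# the cross-sectional weights cancel from both the transfer-matrix and the
# normal-equation solves, so these 1-D solutions predict the 3-D package
# results exactly.

conv_matrix_1d <- function(n, sigma_vox) {
  k <- pvcsim:::gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok]
  }
  K
}

slab_profile <- function(parc) {
  # region id along x (slabs are constant in y, z)
  parc$labels[, 1, 1]
}

oracle_gtm_1d <- function(parc, truth_values, fwhm_mm) {
  prof <- slab_profile(parc)
  n <- length(prof)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / parc$grid$voxel_size_mm[1]
  K <- conv_matrix_1d(n, sigma_vox)
  nr <- nrow(parc$regions)
  ind <- sapply(seq_len(nr), function(j) as.numeric(prof == j))
  rsf1 <- K %*% ind
  omega <- matrix(0, nr, nr)
  for (i in seq_len(nr))
    omega[i, ] <- colMeans(rsf1[prof == i, , drop = FALSE])
  y1 <- K %*% truth_values[prof]
  b <- vapply(seq_len(nr), function(i) mean(y1[prof == i]), numeric(1))
  solve(omega, b)
}

oracle_labbe_1d <- function(parc, truth_values, fwhm_mm) {
  prof <- slab_profile(parc)
  n <- length(prof)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / parc$grid$voxel_size_mm[1]
  K <- conv_matrix_1d(n, sigma_vox)
  nr <- nrow(parc$regions)
  ind <- sapply(seq_len(nr), function(j) as.numeric(prof == j))
  A1 <- K %*% ind
  y1 <- K %*% truth_values[prof]
  qr.solve(crossprod(A1), crossprod(A1, y1))[, 1]
}
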