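#' Region spread functions
#'
#' The shared substrate of every correction: for each region `j`, the
#' point-spread function applied to its indicator volume,
#' `RSF_j = PSF (x) 1_j`. Over a set of regions that partitions the field of
#' view the stack sums to 1 everywhere (up to boundary truncation).
#'
#' @param parc A `parcellation`.
#' @param psf A [psf_model()].
#' @return An object of class `rsf_stack`: list with `rsf` (one volume per
#'   region, in `parc$regions` row order), `psf` and `parc_regions`.
#' @export
region_spread_functions <- function(parc, psf) {
  if (psf$fwhm_mm <= 0) stop("region_spread_functions: fwhm must be > 0")
  counts <- region_voxel_counts(parc)
  if (any(counts == 0))
    stop("region_spread_functions: empty region '",
         names(counts)[counts == 0][1], "'")
  rsf <- lapply(parc$regions$region_id, function(id) {
    gaussian_blur(array(as.numeric(parc$labels == id), parc$grid$shape),
                  psf$fwhm_mm, parc$grid)
  })
  names(rsf) <- parc$regions$name
  structure(list(rsf = rsf, psf = psf, parc_regions = parc$regions),
            class = "rsf_stack")
}

# Mean image value per region, in parc$regions row order.
region_means_of <- function(image, parc) {
  lab <- as.vector(parc$labels)
  keep <- lab > 0L
  sums <- rowsum(as.vector(image)[keep], lab[keep], reorder = TRUE)
  cnts <- rowsum(rep(1, sum(keep)), lab[keep], reorder = TRUE)
  m <- as.vector(sums / cnts)
  names(m) <- parc$regions$name[match(as.integer(rownames(sums)),
                                      parc$regions$region_id)]
  m[parc$regions$name]
}

# Geometric transfer matrix: omega[i, j] = mean of RSF_j over region i.
gtm_matrix <- function(parc, rsf) {
  lab <- as.vector(parc$labels)
  keep <- lab > 0L
  labk <- lab[keep]
  n <- nrow(parc$regions)
  omega <- matrix(0, n, n,
                  dimnames = list(parc$regions$name, parc$regions$name))
  cnts <- rowsum(rep(1, length(labk)), labk, reorder = TRUE)
  ord <- match(as.integer(rownames(cnts)), parc$regions$region_id)
  for (j in seq_len(n)) {
    s <- rowsum(as.vector(rsf$rsf[[j]])[keep], labk, reorder = TRUE)
    omega[ord, j] <- s / cnts
  }
  omega
}

#' Geometric transfer matrix correction (ROI-based)
#'
#' Solves `omega %*% t = b` where `b` holds the observed regional means and
#' `omega[i, j]` is the mean spill-over fraction of region `j` into region
#' `i` under the PSF. Exact for noiseless piecewise-constant activity.
#'
#' @param image Observed 3-D volume.
#' @param parc A `parcellation`.
#' @param psf A [psf_model()].
#' @param rsf Optional precomputed [region_spread_functions()] stack.
#' @param max_condition Fail when the condition number of omega exceeds this.
#' @return Named numeric vector of estimated regional values (in
#'   `parc$regions` row order), with attributes `condition_number` and
#'   `omega`.
#' @export
gtm_solve <- function(image, parc, psf, rsf = NULL, max_condition = 1e8) {
  if (is.null(rsf)) rsf <- region_spread_functions(parc, psf)
  omega <- gtm_matrix(parc, rsf)
  kap <- kappa(omega, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("gtm_solve: geometric transfer matrix is ill-conditioned ",
         "(condition number ", format(kap, digits = 4), ")")
  b <- region_means_of(image, parc)
  t_hat <- solve(omega, b)
  names(t_hat) <- parc$regions$name
  attr(t_hat, "condition_number") <- kap
  attr(t_hat, "omega") <- omega
  t_hat
}

#' Labbe correction (ROI-based, voxel-domain least squares)
#'
#' Fits the observed image over the brain mask to a superposition of region
#' spread functions, `y(v) ~ sum_j t_j RSF_j(v)`, by solving the normal
#' equations. Accounts for spill-over from source voxels into target regions
#' and, like GTM, is exact for noiseless piecewise-constant activity.
#'
#' @inheritParams gtm_solve
#' @return Named numeric vector of estimated regional values with attribute
#'   `condition_number` (of the normal matrix).
#' @export
labbe_solve <- function(image, parc, psf, rsf = NULL, max_condition = 1e10) {
  if (is.null(rsf)) rsf <- region_spread_functions(parc, psf)
  mask <- parc$labels > 0L
  A <- vapply(rsf$rsf, function(r) r[mask], numeric(sum(mask)))
  G <- crossprod(A)
  kap <- kappa(G, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("labbe_solve: normal matrix is rank-deficient or ill-conditioned ",
         "(condition number ", format(kap, digits = 4), ")")
  t_hat <- as.vector(solve(G, crossprod(A, image[mask])))
  names(t_hat) <- parc$regions$name
  attr(t_hat, "condition_number") <- kap
  t_hat
}

# Tissue-class masks and their spread functions (GM / WM / CSF).
class_rsf <- function(parc, psf) {
  cls <- c("GM", "WM", "CSF")
  masks <- lapply(cls, function(k) {
    ids <- parc$regions$region_id[parc$regions$tissue_class == k]
    array(as.numeric(parc$labels %in% ids), parc$grid$shape)
  })
  names(masks) <- cls
  rsf <- lapply(masks, gaussian_blur, fwhm_mm = psf$fwhm_mm,
                grid = parc$grid)
  list(masks = masks, rsf = rsf)
}

#' Mueller-Gartner correction (voxel-based, grey matter)
#'
#' Removes the modelled spill-in from white matter (and, in the default
#' three-compartment mode, CSF) and divides by the grey matter spread
#' function: `c(v) = (y(v) - mu_WM RSF_WM(v) - mu_CSF RSF_CSF(v)) /
#' RSF_GM(v)` wherever `RSF_GM(v) >= gm_threshold`. The class mean values
#' `mu_WM`, `mu_CSF` are estimated by a class-level GTM solve on the GM / WM
#' / CSF masks.
#'
#' @inheritParams gtm_solve
#' @param gm_threshold Minimum grey matter spread-function value defining the
#'   corrected voxel domain.
#' @param compartments 3 (GM, WM, CSF; default) or 2 (GM, WM only).
#' @return Corrected volume; voxels outside the domain are 0. Attributes:
#'   `domain` (logical array), `class_means` (the GTM-estimated mu values),
#'   `n_flagged` (GM-mask voxels excluded by the threshold).
#' @export
mg_correct <- function(image, parc, psf, gm_threshold = 0.5,
                       compartments = 3L) {
  cr <- class_rsf(parc, psf)
  if (sum(cr$masks$GM) == 0) stop("mg_correct: empty grey matter mask")
  use <- c("GM", "WM", "CSF")[seq_len(compartments)]
  n <- length(use)
  omega <- matrix(0, n, n, dimnames = list(use, use))
  b <- numeric(n)
  for (i in seq_len(n)) {
    m <- cr$masks[[use[i]]] > 0
    for (j in seq_len(n)) omega[i, j] <- mean(cr$rsf[[use[j]]][m])
    b[i] <- mean(image[m])
  }
  mu <- solve(omega, b)
  names(mu) <- use
  spill <- mu[["WM"]] * cr$rsf$WM
  if (n >= 3) spill <- spill + mu[["CSF"]] * cr$rsf$CSF
  domain <- cr$rsf$GM >= gm_threshold
  out <- array(0, dim(image))
  out[domain] <- (image[domain] - spill[domain]) / cr$rsf$GM[domain]
  attr(out, "domain") <- domain
  attr(out, "class_means") <- mu
  attr(out, "n_flagged") <- sum(cr$masks$GM > 0 & !domain)
  out
}

#' Paint-by-number synthetic image
#'
#' Assigns each region's value to all of its voxels; background is 0.
#'
#' @param parc A `parcellation`.
#' @param means Numeric vector of regional values in `parc$regions` row
#'   order (as returned by [gtm_solve()] etc.).
#' @return 3-D volume.
#' @export
synthetic_image <- function(parc, means) {
  if (length(means) != nrow(parc$regions))
    stop("synthetic_image: need one value per region (",
         nrow(parc$regions), "), got ", length(means))
  if (any(!is.finite(means)))
    stop("synthetic_image: non-finite value for region '",
         parc$regions$name[which(!is.finite(means))[1]], "'")
  lut <- numeric(max(parc$regions$region_id) + 1L)
  lut[parc$regions$region_id + 1L] <- means
  array(lut[parc$labels + 1L], parc$grid$shape)
}

#' Yang voxel-wise correction
#'
#' Multiplicative correction against a synthetic piecewise-constant prior:
#' `c(v) = y(v) * s(v) / (PSF (x) s)(v)`. Voxels where both `s` and the
#' blurred prior vanish are set to 0; a positive numerator over a vanishing
#' denominator is flagged.
#'
#' @param image Observed 3-D volume.
#' @param s Synthetic prior volume (see [synthetic_image()]).
#' @param psf A [psf_model()].
#' @param grid The shared [grid_spec()].
#' @return Corrected volume with attribute `n_flagged`.
#' @export
yang_correct <- function(image, s, psf, grid) {
  denom <- gaussian_blur(s, psf$fwhm_mm, grid)
  eps <- 1e-12 * max(abs(s))
  bad <- denom <= eps
  out <- array(0, dim(image))
  ok <- !bad
  out[ok] <- image[ok] * s[ok] / denom[ok]
  attr(out, "n_flagged") <- sum(bad & s > eps)
  out
}

#' Region-based voxel-wise (RBV) correction
#'
#' Yang correction seeded with the GTM regional estimates: the synthetic
#' prior is the paint-by-number image of the GTM solution.
#'
#' @inheritParams gtm_solve
#' @return Corrected volume with attribute `region_means` (the GTM solution).
#' @export
rbv_correct <- function(image, parc, psf, rsf = NULL) {
  means <- gtm_solve(image, parc, psf, rsf = rsf)
  s <- synthetic_image(parc, means)
  out <- yang_correct(image, s, psf, parc$grid)
  attr(out, "region_means") <- means
  out
}

#' Iterative Yang correction
#'
#' Starts from the observed regional means and repeats: build the synthetic
#' prior, apply the Yang correction, update the regional means from the
#' corrected image. Ten iterations by default.
#'
#' @inheritParams gtm_solve
#' @param n_iter Number of iterations (>= 1).
#' @return Corrected volume with attribute `region_means` (final means).
#' @export
iy_correct <- function(image, parc, psf, n_iter = 10L) {
  if (n_iter < 1L) stop("iy_correct: n_iter must be >= 1")
  m <- region_means_of(image, parc)
  out <- image
  for (i in seq_len(n_iter)) {
    s <- synthetic_image(parc, m)
    out <- yang_correct(image, s, psf, parc$grid)
    m <- region_means_of(out, parc)
  }
  attr(out, "region_means") <- m
  out
}

#' Structural-functional synergy resolution recovery (SFS-RR)
#'
#' Wavelet-domain fusion of the observed (functional) image with a synthetic
#' structural image: both are decomposed with a separable 3-D Haar wavelet
#' transform; every detail subband is blended as
#' `(1 - alpha) * functional + alpha * structural`; the functional
#' approximation band is kept; the result is inverse-transformed. The
#' structural prior is the paint-by-number image of the observed regional
#' means (`"roi_means"`, the base algorithm) or of the GTM estimates
#' (`"gtm_means"`, the modified variant).
#'
#' @inheritParams gtm_solve
#' @param wcfg A [wavelet_config()].
#' @param structural_source `"roi_means"` or `"gtm_means"`.
#' @return Corrected volume with attribute `structural_means`.
#' @export
sfsrr_correct <- function(image, parc, psf, wcfg = wavelet_config(),
                          structural_source = c("roi_means", "gtm_means"),
                          rsf = NULL) {
  structural_source <- match.arg(structural_source)
  means <- if (structural_source == "roi_means") region_means_of(image, parc)
           else gtm_solve(image, parc, psf, rsf = rsf)
  s <- synthetic_image(parc, means)
  pf <- pad_dyadic(image, wcfg$n_levels)
  ps <- pad_dyadic(s, wcfg$n_levels)
  wf <- dwt3(pf$x, wcfg$n_levels)
  ws <- dwt3(ps$x, wcfg$n_levels)
  for (l in seq_len(wcfg$n_levels)) {
    for (nm in names(wf$details[[l]])) {
      a <- blend_alpha(wf$details[[l]][[nm]], ws$details[[l]][[nm]], wcfg)
      wf$details[[l]][[nm]] <- (1 - a) * wf$details[[l]][[nm]] +
        a * ws$details[[l]][[nm]]
    }
  }
  out <- crop_to(idwt3(wf), pf$orig)
  attr(out, "structural_means") <- means
  out
}
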