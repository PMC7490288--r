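test_that("region spread functions saturate, bound and sum to one", {
  parc <- slab_parcellation()
  psf <- psf_model(7)
  rsf <- region_spread_functions(parc, psf)
  for (r in rsf$rsf) {
    expect_true(all(r >= -1e-6 & r <= 1 + 1e-6))
  }
  # interior = beyond the truncated kernel's support radius from any face
  interior <- deep_interior(array(TRUE, parc$grid$shape), 7)
  expect_gt(sum(interior), 50)
  total <- Reduce(`+`, rsf$rsf)
  expect_lt(max(abs(total[interior] - 1)), 1e-6)
  # deep inside a region the spread function saturates at 1
  in1 <- parc$labels == 1L & deep_interior(parc$labels == 1L, 5)
  expect_gt(sum(in1), 20)
  expect_lt(max(abs(rsf$rsf[[1]][in1] - 1)), 1e-3)
  # a vanishing PSF reduces the stack to the indicators
  rsf0 <- region_spread_functions(parc, psf_model(0.5))
  expect_equal(rsf0$rsf[[2]], array(as.numeric(parc$labels == 2L),
                                    parc$grid$shape))
})

test_that("GTM is exact on matched-blur piecewise-constant activity", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  tv <- pvcsim:::region_means_of(truth$values, parc)
  est <- gtm_solve(obs, parc, psf_model(7))
  expect_lt(max(abs(est / tv - 1)), 1e-6)
  expect_true(is.finite(attr(est, "condition_number")))
  # vanishing PSF: transfer matrix is the identity, estimates = ROI means
  est0 <- gtm_solve(obs, parc, psf_model(0.5))
  expect_equal(strip_attrs(est0),
               strip_attrs(pvcsim:::region_means_of(obs, parc)),
               tolerance = 1e-9)
  expect_error(gtm_solve(obs, parc, psf_model(7), max_condition = 1),
               "condition number")
})

test_that("GTM and Labbe match the brute-force 1-D oracles", {
  parc <- slab_parcellation(values = c(2, 1, 0.5), classes = c("GM", "WM",
                                                               "CSF"))
  truth <- slab_truth(parc)
  obs <- gaussian_blur(truth$values, 8, parc$grid)
  or_g <- oracle_gtm_1d(parc, parc$regions$suvr_HC, 8)
  or_l <- oracle_labbe_1d(parc, parc$regions$suvr_HC, 8)
  est_g <- gtm_solve(obs, parc, psf_model(8))
  est_l <- labbe_solve(obs, parc, psf_model(8))
  expect_lt(max(abs(unname(est_g) - or_g)), 1e-8)
  expect_lt(max(abs(unname(est_l) - or_l)), 1e-8)
  # 4-region variant
  parc4 <- slab_parcellation()
  obs4 <- gaussian_blur(slab_truth(parc4)$values, 7, parc4$grid)
  expect_lt(max(abs(unname(gtm_solve(obs4, parc4, psf_model(7))) -
                      oracle_gtm_1d(parc4, parc4$regions$suvr_HC, 7))),
            1e-8)
  expect_lt(max(abs(unname(labbe_solve(obs4, parc4, psf_model(7))) -
                      oracle_labbe_1d(parc4, parc4$regions$suvr_HC, 7))),
            1e-8)
})

test_that("Labbe is exact on matched blur and reduces to ROI means", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  tv <- pvcsim:::region_means_of(truth$values, parc)
  est <- labbe_solve(obs, parc, psf_model(7))
  expect_lt(max(abs(est / tv - 1)), 1e-6)
  est0 <- labbe_solve(obs, parc, psf_model(0.5))
  expect_equal(strip_attrs(est0),
               strip_attrs(pvcsim:::region_means_of(obs, parc)),
               tolerance = 1e-9)
})

test_that("Mueller-Gartner is self-consistent and inverts its own model", {
  parc <- slab_parcellation(values = c(1.4, 1.4, 1.4),
                            classes = c("GM", "WM", "CSF"),
                            shape = c(60, 24, 24))
  img <- array(1.4, parc$grid$shape)
  out <- mg_correct(img, parc, psf_model(7))
  dom <- attr(out, "domain")
  gm_deep <- parc$labels == 1L & deep_interior(parc$labels == 1L, 6)
  expect_lt(max(abs(out[dom & gm_deep] - 1.4)), 1e-6)

  # three-compartment phantom (GM hot, WM warm, CSF cold), matched blur
  parc3 <- slab_parcellation(values = c(1.8, 0.9, 0), shape = c(60, 24, 24),
                             classes = c("GM", "WM", "CSF"))
  truth3 <- slab_truth(parc3)
  obs3 <- gaussian_blur(truth3$values, 7, parc3$grid)
  out3 <- mg_correct(obs3, parc3, psf_model(7))
  gm_int <- parc3$labels == 1L & deep_interior(parc3$labels == 1L, 4)
  expect_lt(max(abs(out3[gm_int] / 1.8 - 1)), 0.02)

  # impossible threshold flags everything out of the domain
  out_empty <- mg_correct(obs3, parc3, psf_model(7), gm_threshold = 1 + 1e-9)
  expect_false(any(attr(out_empty, "domain")))
  expect_equal(max(abs(out_empty)), 0)
  expect_gt(attr(out_empty, "n_flagged"), 0)
})

test_that("synthetic images are exact paint-by-number round trips", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  tv <- pvcsim:::region_means_of(truth$values, parc)
  expect_equal(synthetic_image(parc, tv), truth$values, tolerance = 1e-12)
  ones <- synthetic_image(parc, rep(1, nrow(parc$regions)))
  expect_true(all(ones[parc$labels > 0] == 1))
  expect_true(all(ones[parc$labels == 0] == 0))
  expect_equal(pvcsim:::region_means_of(ones, parc),
               stats::setNames(rep(1, nrow(parc$regions)),
                               parc$regions$name))
  expect_error(synthetic_image(parc, tv[-1]), "one value per region")
})

test_that("Yang correction obeys its algebraic identities", {
  parc <- slab_parcellation()
  g <- parc$grid
  psf <- psf_model(7)
  s <- synthetic_image(parc, parc$regions$suvr_HC)
  img <- gaussian_blur(s, 7, g)
  # image = PSF (x) s  =>  corrected = s
  out <- yang_correct(img, s, psf, g)
  expect_lt(max(abs(out - s)), 1e-6 * max(s))
  # uniform prior: corrected = image beyond the kernel support radius
  u <- array(1, g$shape)
  out_u <- yang_correct(img, u, psf, g)
  interior <- deep_interior(array(TRUE, g$shape), 7)
  expect_gt(sum(interior), 50)
  expect_lt(max(abs((out_u - img)[interior])), 1e-6)
  # scale invariance of the prior
  expect_equal(yang_correct(img, 3 * s, psf, g), out, tolerance = 1e-12)
})

test_that("RBV recovers matched-blur activity voxel-wise", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  out <- rbv_correct(obs, parc, psf_model(7))
  interior <- deep_interior(parc$labels > 0, 2)
  expect_lt(max(abs(out[interior] / truth$values[interior] - 1)), 0.01)
  m <- pvcsim:::region_means_of(out, parc)
  expect_equal(strip_attrs(m), strip_attrs(attr(out, "region_means")),
               tolerance = 0.01)
})

test_that("iterative Yang converges on resolvable anatomy", {
  parc <- slab_parcellation()
  truth <- slab_truth(parc)
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  psf <- psf_model(7)
  # one iteration is the Yang correction with the observed-mean prior
  m0 <- pvcsim:::region_means_of(obs, parc)
  manual <- yang_correct(obs, synthetic_image(parc, m0), psf, parc$grid)
  it1 <- iy_correct(obs, parc, psf, n_iter = 1)
  expect_equal(unclass(it1), unclass(manual), ignore_attr = TRUE)

  tv <- parc$regions$suvr_HC
  errs <- vapply(1:10, function(k) {
    m <- pvcsim:::region_means_of(iy_correct(obs, parc, psf, n_iter = k),
                                  parc)
    max(abs(unname(m) / tv - 1))
  }, numeric(1))
  expect_lt(errs[10], 0.02)
  expect_true(all(diff(errs[2:10]) <= 1e-9))
  expect_equal(formals(iy_correct)$n_iter, 10L)
})

test_that("wavelet decomposition round-trips and SFS-RR blends correctly", {
  set.seed(4)
  x <- array(stats::rnorm(32 * 16 * 16), c(32, 16, 16))
  w <- pvcsim:::dwt3(x, 3)
  expect_lt(max(abs(pvcsim:::idwt3(w) - x)), 1e-12)

  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  psf <- psf_model(7)
  # zero structural fraction: identity up to transform round-trip
  out0 <- sfsrr_correct(obs, parc, psf,
                        wavelet_config(structural_fraction = 0))
  expect_lt(max(abs(out0 - obs)), 1e-6)
  # full structural fraction with the image as its own prior: identity
  pf <- pvcsim:::pad_dyadic(obs, 4)
  wf <- pvcsim:::dwt3(pf$x, 4)
  ws <- pvcsim:::dwt3(pf$x, 4)
  for (l in 1:4) for (nm in names(wf$details[[l]]))
    wf$details[[l]][[nm]] <- 0 * wf$details[[l]][[nm]] + ws$details[[l]][[nm]]
  self_blend <- pvcsim:::crop_to(pvcsim:::idwt3(wf), pf$orig)
  expect_lt(max(abs(self_blend - obs)), 1e-6)
  # modified variant beats the base variant on the blurred phantom
  tv <- pvcsim:::region_means_of(truth$values, parc)
  base <- sfsrr_correct(obs, parc, psf, structural_source = "roi_means")
  mod <- sfsrr_correct(obs, parc, psf, structural_source = "gtm_means")
  rois <- grep("hippocampus|temporal|fusiform", parc$regions$name)
  pd <- function(out) {
    m <- pvcsim:::region_means_of(out, parc)
    abs(100 * (m[rois] - tv[rois]) / tv[rois])
  }
  expect_true(all(pd(mod) <= pd(base) + 1e-6))
})

test_that("per-subband energy matching yields admissible weights", {
  parc <- slab_parcellation()
  obs <- gaussian_blur(slab_truth(parc)$values, 7, parc$grid)
  out <- sfsrr_correct(obs, parc, psf_model(7),
                       wavelet_config(n_levels = 2,
                                      weighting_rule = "per_subband_fit"))
  expect_true(all(is.finite(out)))
  expect_equal(dim(out), parc$grid$shape)
})

test_that("the pvc() front-end dispatches and its methods are coherent", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- gaussian_blur(truth$values, 7, parc$grid)
  rsf <- region_spread_functions(parc, psf_model(7))
  tv <- pvcsim:::region_means_of(truth$values, parc)

  fit <- pvc(obs, parc, 7, method = "gtm", rsf = rsf)
  expect_s3_class(fit, "pvc")
  expect_lt(max(abs(coef(fit) / tv - 1)), 1e-6)
  expect_equal(dim(fitted(fit)), parc$grid$shape)
  # matched-blur exact fit leaves near-zero residuals
  expect_lt(max(abs(residuals(fit))), 1e-6 * max(obs))
  expect_output(print(fit), "GTM")
  expect_output(print(summary(fit)), "condition number")

  for (m in c("labbe", "mg", "rbv", "iy", "sfsrr", "modsfsrr")) {
    f <- pvc(obs, parc, 7, method = m, rsf = rsf)
    expect_equal(dim(f$corrected), parc$grid$shape)
    expect_true(is.numeric(coef(f)))
  }
  # precomputed stack must not change the answer
  expect_equal(coef(pvc(obs, parc, 7, method = "rbv")),
               coef(pvc(obs, parc, 7, method = "rbv", rsf = rsf)))
})
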