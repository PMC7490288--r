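test_that("FWHM/sigma conversion matches the closed form", {
  expect_equal(fwhm_to_sigma(7), 2.9726, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(6), 2.5480, tolerance = 1e-4)
  for (x in c(0.5, 3, 11))
    expect_equal(fwhm_to_sigma(x) * 2 * sqrt(2 * log(2)), x)
  expect_error(fwhm_to_sigma(0), "positive")
  expect_equal(psf_model(7)$sigma_mm, fwhm_to_sigma(7))
})

test_that("Gaussian blur preserves constants, mass and the semigroup", {
  g <- grid_spec(c(48, 48, 24), c(2.682, 2.682, 2.425))
  u <- array(1, g$shape)
  bu <- gaussian_blur(u, 6, g)
  expect_lt(max(abs(bu[15:34, 15:34, 10:15] - 1)), 1e-6)
  expect_identical(gaussian_blur(u, 0, g), u)

  ps <- make_point_source(g, amplitude = 10)
  expect_equal(sum(gaussian_blur(ps$values, 8, g)), 10, tolerance = 1e-6)

  # composition of blurs at the scanner's physical scales
  b2 <- gaussian_blur(gaussian_blur(ps$values, 6, g), 8, g)
  b1 <- gaussian_blur(ps$values, sqrt(36 + 64), g)
  expect_lt(max(abs(b2 - b1)) / max(b1), 1e-4)
})

test_that("resolution estimation recovers the blur applied to a point", {
  g <- grid_spec(c(48, 48, 24), c(2.682, 2.682, 2.425))
  ps <- make_point_source(g, amplitude = 100)
  for (f in c(5, 7))
    expect_equal(estimate_fwhm(gaussian_blur(ps$values, f, g), g), f,
                 tolerance = 0.1 / f)
  # robust to additive noise at 1 percent of peak
  b <- gaussian_blur(ps$values, 7, g)
  set.seed(11)
  bn <- b + array(stats::rnorm(length(b), sd = 0.01 * max(b)), dim(b))
  expect_equal(estimate_fwhm(bn, g), 7, tolerance = 0.3 / 7)
})

test_that("forward projection reproduces chord lengths and Beer-Lambert", {
  g <- grid_spec(c(64, 64, 8), c(2, 2, 2))
  acq <- acquisition_config(n_angles = 12)
  expect_equal(max(abs(forward_project(array(0, g$shape), NULL, acq,
                                       g)$prompts)), 0)
  # centred uniform disk, radius 30 mm, value 1.5
  ax <- (seq_len(64) - (64 + 1) / 2) * 2
  R2 <- outer(ax^2, ax^2, "+")
  disk <- array(rep(as.numeric(R2 < 30^2) * 1.5, 8), g$shape)
  sino <- forward_project(disk, NULL, acq, g)
  central <- sino$prompts[1, 32:33, 4]
  expect_equal(mean(central), 2 * 30 * 1.5, tolerance = 0.02)
  # uniform attenuator over the same disk
  mu <- structure(list(grid = g, mu = (disk > 0) * 0.096),
                  class = "attenuation_map")
  sa <- forward_project(disk, mu, acq, g)
  expect_equal(mean(sa$attenuation_factors[1, 32:33, 4]),
               exp(-0.096 * 2 * 3), tolerance = 0.02)
  expect_error(forward_project(disk, mu, acq, grid_spec(c(32, 32, 8))),
               "do not match")
})

test_that("precorrection is exact in the noiseless limit and seeded", {
  parc <- slab_parcellation()
  truth <- slab_truth(parc)
  acq <- acquisition_config(n_angles = 24, noise_scale = 1)
  sino <- forward_project(truth$values, NULL, acq, parc$grid)
  noiseless <- degrade_and_precorrect(sino, seed = 1, add_noise = FALSE)
  line_integrals <- sino$prompts / sino$attenuation_factors
  expect_equal(noiseless$corrected, line_integrals, tolerance = 1e-12)

  n1 <- degrade_and_precorrect(sino, seed = 7)
  n2 <- degrade_and_precorrect(sino, seed = 7)
  n3 <- degrade_and_precorrect(sino, seed = 8)
  expect_identical(n1$corrected, n2$corrected)
  expect_false(identical(n1$corrected, n3$corrected))
})

test_that("the Poisson stage is unbiased and has the nominal variance", {
  parc <- slab_parcellation()
  truth <- slab_truth(parc)
  acq <- acquisition_config(n_angles = 24, noise_scale = 1)
  sino <- forward_project(truth$values, NULL, acq, parc$grid)
  truth_bin <- degrade_and_precorrect(sino, add_noise = FALSE)$corrected[5, 8, 4]
  reps <- vapply(1:200, function(s)
    degrade_and_precorrect(sino, seed = s)$corrected[5, 8, 4], numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - truth_bin), 3 * se)

  # variance of the raw noisy bin ~ mean / noise_scale
  tot <- sino$prompts + degrade_and_precorrect(sino,
    add_noise = FALSE)$scatter_estimate +
    degrade_and_precorrect(sino, add_noise = FALSE)$randoms_estimate
  lam <- tot[5, 8, 4]
  noisy <- vapply(1:500, function(s) {
    d <- degrade_and_precorrect(sino, seed = s)
    (d$corrected * sino$attenuation_factors)[5, 8, 4] +
      d$scatter_estimate[5, 8, 4] + d$randoms_estimate[5, 8, 4]
  }, numeric(1))
  expect_equal(stats::var(noisy), lam / acq$noise_scale, tolerance = 0.2)
})

test_that("FBP reconstructs projections faithfully", {
  g <- grid_spec(c(64, 64, 8), c(2.682, 2.682, 2.425))
  acq <- acquisition_config()
  zero <- forward_project(array(0, g$shape), NULL, acq, g)
  zero <- degrade_and_precorrect(zero, add_noise = FALSE)
  expect_equal(max(abs(fbp_reconstruct(
    zero, recon_config(post_filter_fwhm_mm = 0), g))), 0)

  ax <- (seq_len(64) - (64 + 1) / 2) * 2.682
  R2 <- outer(ax^2, ax^2, "+")
  smooth <- gaussian_blur(array(rep(as.numeric(R2 < 40^2), 8), g$shape),
                          8, g)
  sino <- degrade_and_precorrect(forward_project(smooth, NULL, acq, g),
                                 add_noise = FALSE)
  rec <- fbp_reconstruct(sino, recon_config(post_filter_fwhm_mm = 0), g)
  interior <- smooth > 0.05 * max(smooth)
  expect_lt(sqrt(mean((rec[interior] - smooth[interior])^2)) / max(smooth),
            0.05)
})

test_that("the noiseless chain is linear and seeded noise reproducible", {
  parc <- slab_parcellation()
  truth <- slab_truth(parc)
  acq <- acquisition_config(n_angles = 36)
  s1 <- simulate_observed(truth, NULL, acq, recon_config(), seed = 1,
                          add_noise = FALSE)
  truth2 <- truth; truth2$values <- 2 * truth$values
  s2 <- simulate_observed(truth2, NULL, acq, recon_config(), seed = 1,
                          add_noise = FALSE)
  expect_lt(max(abs(s2 - 2 * s1)) / max(abs(s1)), 1e-6)

  n1 <- simulate_observed(truth, NULL, acq, recon_config(), seed = 3)
  n2 <- simulate_observed(truth, NULL, acq, recon_config(), seed = 3)
  n3 <- simulate_observed(truth, NULL, acq, recon_config(), seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("image-space mode with zero noise is exactly a Gaussian blur", {
  parc <- test_phantom("HC")
  truth <- assign_truth(parc, "HC")
  obs <- simulate_observed(truth, mode = "image-space", add_noise = FALSE,
                           image_fwhm_mm = 7)
  expect_identical(obs, gaussian_blur(truth$values, 7, truth$grid))
})

test_that("a small hot region in a cooler neighbourhood is underestimated", {
  cfg <- phantom_config("HC", scale = 0.5)
  cfg$truth_suvr$HC[["hippocampus"]] <- 2.5
  cfg$truth_suvr$HC[["cerebral_wm"]] <- 0.3
  parc <- build_phantom("HC", test_grid(), seed = 1, config = cfg)
  truth <- assign_truth(parc, "HC")
  obs <- simulate_observed(truth, build_attenuation(parc),
                           acquisition_config(), recon_config(), seed = 1,
                           add_noise = FALSE)
  hip <- parc$labels %in%
    parc$regions$region_id[grepl("^hippocampus", parc$regions$name)]
  expect_lt(mean(obs[hip]), mean(truth$values[hip]))
})
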