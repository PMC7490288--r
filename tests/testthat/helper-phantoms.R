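# Shared fixtures, all generated in code.

test_grid <- function() grid_spec(c(64, 64, 32))

# Half-scale brain phantom: fast, but with deliberately harsh PVE
# (sub-voxel cortical ribbon); used where exact-tolerance claims do not
# depend on the anatomy being resolvable.
test_phantom <- function(preset = "HC", seed = 1L) {
  build_phantom(preset, test_grid(), seed = seed,
                config = phantom_config(preset, scale = 0.5))
}

# Slab phantom: regions are x-slabs spanning the full cross-section, so
# every region is thick and the geometry is effectively one-dimensional.
slab_parcellation <- function(values = c(2, 1, 0.5, 1.5),
                              shape = c(48, 16, 16),
                              voxel = c(2, 2, 2),
                              classes = c("GM", "WM", "CSF", "GM")) {
  n <- length(values)
  g <- grid_spec(shape, voxel)
  labels <- array(0L, shape)
  bounds <- round(seq(0, shape[1], length.out = n + 1))
  for (j in seq_len(n))
    labels[(bounds[j] + 1):bounds[j + 1], , ] <- j
  regions <- data.frame(
    region_id = seq_len(n), name = paste0("slab", seq_len(n)),
    tissue_class = classes[seq_len(n)], laterality = "midline",
    suvr_HC = values, suvr_AD = values, stringsAsFactors = FALSE)
  structure(list(grid = g, labels = labels, regions = regions,
                 preset = "slab", seed = 0L, config = NULL),
            class = "parcellation")
}

slab_truth <- function(parc) {
  structure(list(grid = parc$grid,
                 values = synthetic_image(parc, parc$regions$suvr_HC),
                 condition = "HC"),
            class = "truth_image")
}

strip_attrs <- function(x) {
  attributes(x) <- NULL
  x
}

# Interior mask: brain voxels at least `r` voxels away from any label change
# and from the volume faces.
deep_interior <- function(mask, r = 4L) {
  m <- pvcsim:::morph_erode(mask, r)
  d <- dim(mask)
  m[c(seq_len(r), d[1] - seq_len(r) + 1L), , ] <- FALSE
  m[, c(seq_len(r), d[2] - seq_len(r) + 1L), ] <- FALSE
  m[, , c(seq_len(r), d[3] - seq_len(r) + 1L)] <- FALSE
  m
}
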