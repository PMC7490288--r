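# pvcsim

Error-propagation analysis of partial volume correction (PVC) for brain
PET, as a reproducible simulation pipeline in R.

## The problem

Brain PET images are blurred by the scanner's point-spread function (PSF),
so small or thin structures — a few-millimetre cortical ribbon, the
hippocampus — lose signal to their neighbours and receive spill-in from
theirs: the partial volume effect (PVE). Post-reconstruction PVC inverts
this blur using an anatomical parcellation from MRI and a Gaussian PSF
model. But the inputs to PVC are themselves imperfect in clinical work:
the assumed FWHM is off by a millimetre, the PET–MR registration by a
pixel, the segmentation draws a structure too large or too small. Every
such input error propagates through the correction into the reported
regional values.

`pvcsim` quantifies that propagation for seven classical PVC algorithms —
Müller-Gärtner (MG), geometric transfer matrix (GTM), Labbé, region-based
voxel-wise (RBV), iterative Yang (IY), and two wavelet-domain
structural–functional resolution-recovery variants (SFS-RR, mod SFS-RR) —
in the setting of a tau tracer with strong non-specific white-matter
binding. It is aimed at researchers choosing or stress-testing a PVC
pipeline.

## What it computes

For a region `r` of a reference-normalised image (SUVR, cerebellar grey
matter reference), the outcome is

```
%difference = 100 · (ROI_PVC − ROI_true) / ROI_true
```

evaluated over a factorial study: {HC, AD} phantom conditions ×
{no error, FWHM mismatch ∓1/∓2 mm, rigid X/Z misregistration of one/two
pixels, hippocampal or global-cortical volume rescaling} × 7 algorithms ×
6 analysis ROIs (middle+inferior temporal, parietal, occipital,
parahippocampal, hippocampus, fusiform) × {error-free, perturbed} ROI
templates.

The pipeline is fully synthetic and deterministic under a seed:

1. **Phantom** (`build_phantom`) — a parcellated geometric brain (nested
   ellipsoids: CSF envelope, thin cortical grey-matter ribbon, white
   matter core, embedded subcortical blobs, separate cerebellum) with
   known piecewise-constant truth SUVR per condition and a two-tissue
   attenuation map, on a 128 × 128 × 63 grid of 2.682 × 2.682 × 2.425 mm
   voxels.
2. **Simulator** (`simulate_observed`) — analytic forward projection with
   attenuation, scatter/randoms background added then exactly subtracted,
   scaled Poisson noise, ramp-filter FBP, 6 mm Gaussian post-filter. The
   chain's effective resolution is measured from a point source
   (`calibrate_chain_fwhm`, ≈6.5 mm by default) and handed to PVC as the
   true FWHM.
3. **PVC** (`pvc`) — one front-end over the seven algorithms, returning a
   classed fit with `coef`/`fitted`/`residuals`/`summary` methods.
4. **Perturbations** (`translate_parcellation`,
   `rescale_region_volume`) — deterministic misregistration and
   mis-segmentation of the anatomical inputs.
5. **Experiment driver** (`run_experiment_grid`) — the factorial study as
   a tidy long-format CSV.

## Worked example

```r
library(pvcsim)

parc  <- build_phantom("HC", grid_spec(c(64, 64, 32)), seed = 1,
                       config = phantom_config("HC", scale = 0.5))
truth <- assign_truth(parc, "HC")
obs   <- simulate_observed(truth, mode = "image-space", add_noise = FALSE,
                           image_fwhm_mm = 7)

fit <- pvc(obs, parc, fwhm_mm = 7, method = "gtm")
fit
#> <pvc> method GTM, PSF FWHM 7.00 mm, 18 regions
#>   transfer-matrix condition number: 40.9
#>   regional estimates (head):
#>             cerebral_wm                     csf           cerebellar_gm
#>                    1.80                    0.05                    1.00
#>           cerebellar_wm mid_inferior_temporal_l mid_inferior_temporal_r
#>                    1.80                    1.20                    1.20

tmpl <- make_roi_template(parc)
data.frame(
  true                = extract_suvr(truth$values, tmpl),
  uncorrected_pctdiff = percent_difference(extract_suvr(obs, tmpl),
                                           extract_suvr(truth$values, tmpl)),
  gtm_pctdiff         = percent_difference(extract_suvr(fit$corrected, tmpl),
                                           extract_suvr(truth$values, tmpl)))
#>                       true uncorrected_pctdiff gtm_pctdiff
#> mid_inferior_temporal  1.2              -1.371           0
#> parietal               1.1               6.144           0
#> occipital              1.1              10.026           0
#> parahippocampal        1.2              58.952           0
#> hippocampus            1.1              76.202           0
#> fusiform               1.2              43.830           0
```

On this half-scale phantom the uncorrected hippocampus SUVR is biased by
+76% (spill-in from the hotter white matter it is embedded in); the GTM
correction, given the matched PSF and the true parcellation, removes the
bias entirely — the blur here is exactly the Gaussian the algorithm
assumes, which is the ideal condition. The full experiment replaces this
blur with the complete projection/reconstruction chain and then degrades
the PVC inputs on purpose:

```r
cfg <- experiment_grid(scenarios = c("ideal", "fwhm_mismatch"),
                       add_noise = FALSE, seed = 1)
res <- run_experiment_grid(cfg, out_dir = "experiment_out")
```

A command-line wrapper for the individual stages is in
`inst/cli/pvcsim.R` (`phantom`, `simulate`, `pvc`, `experiment`
subcommands).

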