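#' Build an ROI analysis template from a parcellation
#'
#' Selects the six analysis ROIs (middle+inferior temporal, parietal,
#' occipital, parahippocampal gyrus, hippocampus, fusiform), either with the
#' left and right hemispheres united (the default) or kept separate (used
#' for lateral-translation scenarios, where the two hemispheres are affected
#' oppositely).
#'
#' @param parc The `parcellation` the template is drawn from (the error-free
#'   one for `variant = "true_template"`, the perturbed one for
#'   `variant = "perturbed_template"`).
#' @param unite_lr Unite left/right region pairs into one ROI.
#' @param variant `"true_template"` or `"perturbed_template"` (metadata).
#' @return An object of class `roi_template`: list with `labels`, `grid`,
#'   `rois` (named list of region-id vectors), `reference_id`, `regions`,
#'   `variant`.
#' @export
make_roi_template <- function(parc, unite_lr = TRUE,
                              variant = c("true_template",
                                          "perturbed_template")) {
  variant <- match.arg(variant)
  rid <- function(nm) parc$regions$region_id[parc$regions$name == nm]
  rois <- list()
  for (base in ANALYSIS_ROIS) {
    l <- rid(paste0(base, "_l")); r <- rid(paste0(base, "_r"))
    if (length(l) == 0 || length(r) == 0)
      stop("make_roi_template: analysis ROI '", base, "' missing")
    if (unite_lr) rois[[base]] <- c(l, r)
    else {
      rois[[paste0(base, "_l")]] <- l
      rois[[paste0(base, "_r")]] <- r
    }
  }
  counts <- region_voxel_counts(parc)
  for (nm in names(rois))
    if (sum(counts[match(rois[[nm]], parc$regions$region_id)]) == 0)
      stop("make_roi_template: ROI '", nm, "' is empty")
  structure(list(labels = parc$labels, grid = parc$grid, rois = rois,
                 reference_id = rid("cerebellar_gm"),
                 regions = parc$regions, variant = variant),
            class = "roi_template")
}

#' Extract reference-normalised ROI values (SUVR)
#'
#' Computes the mean over each template ROI and divides by the
#' cerebellar-grey-matter reference mean. Accepts either a corrected volume
#' or a vector of regional means (ROI-based algorithms); for the latter,
#' united ROIs are voxel-count-weighted means of their member regions.
#'
#' @param x 3-D volume, or a named numeric vector of regional means in the
#'   template's region-table order.
#' @param template A [make_roi_template()] result.
#' @param domain Optional logical volume restricting the analysed voxels
#'   (e.g. the Mueller-Gartner corrected domain).
#' @return Named numeric vector of SUVR values, one per template ROI.
#' @export
extract_suvr <- function(x, template, domain = NULL) {
  if (is.array(x) && length(dim(x)) == 3) {
    roi_mean <- function(ids) {
      m <- template$labels %in% ids
      dim(m) <- dim(template$labels)
      if (!is.null(domain)) m <- m & domain
      if (!any(m)) return(NA_real_)
      mean(x[m])
    }
    ref <- roi_mean(template$reference_id)
    vals <- vapply(template$rois, roi_mean, numeric(1))
  } else {
    means <- x
    counts <- tabulate(template$labels,
                       nbins = max(template$regions$region_id))
    wmean <- function(ids) {
      i <- match(ids, template$regions$region_id)
      w <- counts[ids]
      if (sum(w) == 0) return(NA_real_)
      sum(means[i] * w) / sum(w)
    }
    ref <- wmean(template$reference_id)
    vals <- vapply(template$rois, wmean, numeric(1))
  }
  if (!is.finite(ref) || ref <= 0)
    stop("extract_suvr: reference-region mean is not positive (",
         format(ref), ")")
  vals / ref
}

#' Percent difference against truth
#'
#' The study's outcome measure:
#' `100 * (roi_pvc - roi_true) / roi_true`.
#'
#' @param roi_pvc Corrected (or uncorrected) ROI value.
#' @param roi_true True ROI value (nonzero).
#' @return Percent difference (vectorised).
#' @export
percent_difference <- function(roi_pvc, roi_true) {
  if (any(roi_true == 0)) stop("percent_difference: roi_true is zero")
  100 * (roi_pvc - roi_true) / roi_true
}

#' Configuration of the full error-propagation experiment
#'
#' Describes the factorial study: conditions, algorithms, error scenarios
#' with their canonical magnitude grids, the simulation settings, and the
#' image grid. The ideal (error-free) scenario is always included as the
#' baseline.
#'
#' @param conditions Phantom conditions to simulate.
#' @param algorithms Correction algorithms (driver codes as reported in the
#'   result table).
#' @param scenarios Which error scenarios to run (`"ideal"` is always added).
#' @param grid Image [grid_spec()].
#' @param phantom_scale Global anatomy scale (see [phantom_config()]).
#' @param seed Base seed (phantom surfaces + noise realisations).
#' @param acq,recon Simulator configuration.
#' @param sim_mode `"projection"` or `"image-space"`.
#' @param add_noise Poisson noise on/off.
#' @param true_fwhm_mm The resolution handed to PVC in error-free cells;
#'   `NULL` (default) calibrates it from a point source passed through the
#'   configured chain (see [calibrate_chain_fwhm()]). The FWHM-mismatch
#'   scenario applies the canonical mismatch offsets (-2, -1, +1, +2 mm)
#'   relative to this value.
#' @param perturb Magnitude grids, see [canonical_perturbations()].
#' @param segmentation_conditions Conditions for which the segmentation-error
#'   scenarios are run (default HC only).
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(conditions = c("HC", "AD"),
                            algorithms = c("MG", "GTM", "LABBE", "RBV",
                                           "IY", "SFSRR", "modSFSRR"),
                            scenarios = c("ideal", "fwhm_mismatch",
                                          "translation_x", "translation_z",
                                          "volume_scale_hippocampus",
                                          "volume_scale_cortex"),
                            grid = grid_spec(), phantom_scale = 1,
                            seed = 1L,
                            acq = acquisition_config(),
                            recon = recon_config(),
                            sim_mode = "projection", add_noise = TRUE,
                            true_fwhm_mm = NULL,
                            perturb = canonical_perturbations(),
                            segmentation_conditions = "HC") {
  scenarios <- union("ideal", scenarios)
  structure(list(conditions = conditions, algorithms = algorithms,
                 scenarios = scenarios, grid = grid,
                 phantom_scale = phantom_scale, seed = as.integer(seed),
                 acq = acq, recon = recon, sim_mode = sim_mode,
                 add_noise = add_noise, true_fwhm_mm = true_fwhm_mm,
                 perturb = perturb,
                 segmentation_conditions = segmentation_conditions),
            class = "experiment_grid")
}

algo_code <- c(none = "none", MG = "mg", GTM = "gtm", LABBE = "labbe",
               RBV = "rbv", IY = "iy", SFSRR = "sfsrr",
               modSFSRR = "modsfsrr")

#' Run the factorial error-propagation experiment
#'
#' For every cell of the study — condition x scenario x error magnitude x
#' algorithm x ROI (x template variant where anatomy is perturbed) — the
#' driver simulates (once per condition) the pseudo-observed image, applies
#' the perturbation to the PVC inputs, runs the algorithm, extracts
#' reference-normalised ROI values with the requested template(s), and
#' records the percent difference against the true SUVR. The true ROI value
#' always comes from the unperturbed truth image with the error-free
#' template. Fully deterministic for a fixed configuration.
#'
#' @param cfg An [experiment_grid()].
#' @param out_dir Optional directory; when given, `results.csv` is written
#'   there with canonical number formatting (byte-identical across reruns).
#' @param verbose Print per-cell progress.
#' @return A long-format data frame (class `pvc_result_table`) with columns
#'   `condition`, `algorithm`, `error_kind`, `error_magnitude`, `roi_name`,
#'   `template_variant`, `roi_pvc`, `roi_true`, `pct_difference`. Failed
#'   cells are recorded in the `failures` attribute and skipped.
#' @export
run_experiment_grid <- function(cfg, out_dir = NULL, verbose = FALSE) {
  records <- list()
  failures <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cfg$true_fwhm_mm)) {
    if (cfg$sim_mode == "image-space") {
      cfg$true_fwhm_mm <- 7
    } else {
      say("calibrating chain resolution from a point source")
      cfg$true_fwhm_mm <- calibrate_chain_fwhm(cfg$grid, cfg$acq, cfg$recon)
      say("effective chain FWHM: %.3f mm", cfg$true_fwhm_mm)
    }
  }
  mismatch_mm <- cfg$perturb$fwhm_used_mm - cfg$perturb$true_fwhm_mm
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    pcfg <- phantom_config(cond, scale = cfg$phantom_scale)
    parc <- build_phantom(cond, cfg$grid, seed = cfg$seed, config = pcfg)
    truth <- assign_truth(parc, cond)
    mu <- build_attenuation(parc)
    say("[%s] simulating pseudo-observed image", cond)
    observed <- simulate_observed(truth, mu, cfg$acq, cfg$recon,
                                  seed = cfg$seed + ci,
                                  mode = cfg$sim_mode,
                                  add_noise = cfg$add_noise)
    tmpl_true_u <- make_roi_template(parc, TRUE, "true_template")
    tmpl_true_s <- make_roi_template(parc, FALSE, "true_template")
    truth_suvr_u <- extract_suvr(truth$values, tmpl_true_u)
    truth_suvr_s <- extract_suvr(truth$values, tmpl_true_s)

    cells <- list()
    add_cell <- function(kind, mag, parc_pvc, fwhm, unite_lr, both_tmpl,
                         algos = cfg$algorithms) {
      cells[[length(cells) + 1L]] <<- list(
        kind = kind, mag = mag, parc_pvc = parc_pvc, fwhm = fwhm,
        unite_lr = unite_lr, both_tmpl = both_tmpl, algos = algos)
    }
    add_cell("none", 0, parc, cfg$true_fwhm_mm, TRUE, FALSE,
             c("none", cfg$algorithms))
    if ("fwhm_mismatch" %in% cfg$scenarios)
      for (dm in mismatch_mm)
        add_cell("fwhm_mismatch", dm, parc, cfg$true_fwhm_mm + dm, TRUE,
                 FALSE)
    if ("translation_x" %in% cfg$scenarios)
      for (dx in cfg$perturb$x_offsets_mm)
        add_cell("translation_x", dx,
                 translate_parcellation(parc, c(dx, 0, 0)),
                 cfg$true_fwhm_mm, FALSE, TRUE)
    if ("translation_z" %in% cfg$scenarios)
      for (dz in cfg$perturb$z_offsets_mm)
        add_cell("translation_z", dz,
                 translate_parcellation(parc, c(0, 0, dz)),
                 cfg$true_fwhm_mm, TRUE, TRUE)
    if (cond %in% cfg$segmentation_conditions) {
      if ("volume_scale_hippocampus" %in% cfg$scenarios)
        for (fc in cfg$perturb$hippocampus_factors)
          add_cell("volume_scale_hippocampus", fc,
                   rescale_region_volume(parc,
                                         cfg$perturb$hippocampus_regions,
                                         fc),
                   cfg$true_fwhm_mm, TRUE, TRUE)
      if ("volume_scale_cortex" %in% cfg$scenarios)
        for (fc in cfg$perturb$cortex_factors)
          add_cell("volume_scale_cortex", fc,
                   rescale_region_volume(parc, cfg$perturb$cortex_regions,
                                         fc),
                   cfg$true_fwhm_mm, TRUE, TRUE)
    }

    for (cell in cells) {
      say("[%s] scenario %s, magnitude %s", cond, cell$kind,
          format(cell$mag))
      psf <- psf_model(cell$fwhm)
      rsf <- tryCatch(region_spread_functions(cell$parc_pvc, psf),
                      error = function(e) e)
      if (inherits(rsf, "error")) {
        failures <- c(failures, sprintf("%s/%s/%s: %s", cond, cell$kind,
                                        format(cell$mag),
                                        conditionMessage(rsf)))
        next
      }
      truth_suvr <- if (cell$unite_lr) truth_suvr_u else truth_suvr_s
      tmpls <- list(true_template = make_roi_template(
        parc, cell$unite_lr, "true_template"))
      if (cell$both_tmpl)
        tmpls$perturbed_template <- make_roi_template(
          cell$parc_pvc, cell$unite_lr, "perturbed_template")
      for (algo in cell$algos) {
        res <- tryCatch({
          if (algo == "none") list(image = observed, domain = NULL)
          else {
            fit <- pvc(observed, cell$parc_pvc, cell$fwhm,
                       method = algo_code[[algo]], rsf = rsf)
            list(image = fit$corrected, domain = fit$diagnostics$domain)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, sprintf("%s/%s/%s/%s: %s", cond,
                                          cell$kind, format(cell$mag), algo,
                                          conditionMessage(res)))
          next
        }
        for (tv in names(tmpls)) {
          suvr <- tryCatch(extract_suvr(res$image, tmpls[[tv]],
                                        domain = res$domain),
                           error = function(e) e)
          if (inherits(suvr, "error")) {
            failures <- c(failures, sprintf("%s/%s/%s/%s/%s: %s", cond,
                                            cell$kind, format(cell$mag),
                                            algo, tv,
                                            conditionMessage(suvr)))
            next
          }
          records[[length(records) + 1L]] <- data.frame(
            condition = cond, algorithm = algo, error_kind = cell$kind,
            error_magnitude = cell$mag, roi_name = names(suvr),
            template_variant = tv, roi_pvc = unname(suvr),
            roi_true = unname(truth_suvr[names(suvr)]),
            pct_difference = unname(percent_difference(
              suvr, truth_suvr[names(suvr)])),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  class(out) <- c("pvc_result_table", "data.frame")
  attr(out, "failures") <- failures
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_table(out, file.path(out_dir, "results.csv"))
  }
  out
}

#' Write a result table as CSV with canonical number formatting
#'
#' Numbers are printed with `%.10g` so that deterministic reruns produce
#' byte-identical files.
#'
#' @param x A result table from [run_experiment_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  y <- as.data.frame(x)
  for (cl in c("error_magnitude", "roi_pvc", "roi_true", "pct_difference"))
    y[[cl]] <- sprintf("%.10g", y[[cl]])
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bar chart of percent differences for one scenario cell
#'
#' Convenience plot: grouped bars of `pct_difference` by ROI and algorithm
#' for a single condition / error kind / magnitude / template variant.
#'
#' @param x A `pvc_result_table`.
#' @param condition,error_kind,error_magnitude,template_variant Cell
#'   selectors.
#' @param ... Passed to [graphics::barplot()].
#' @return The barplot midpoints, invisibly.
#' @export
plot_result_cell <- function(x, condition = "HC", error_kind = "none",
                             error_magnitude = 0,
                             template_variant = "true_template", ...) {
  sel <- x$condition == condition & x$error_kind == error_kind &
    abs(x$error_magnitude - error_magnitude) < 1e-9 &
    x$template_variant == template_variant
  d <- x[sel, ]
  if (nrow(d) == 0) stop("plot_result_cell: no matching records")
  m <- tapply(d$pct_difference, list(d$algorithm, d$roi_name), mean)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "% difference vs true SUVR",
                    las = 2, ...)
}
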