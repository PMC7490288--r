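# Full-chain study results shared by the acceptance tests: the ideal,
# FWHM-mismatch and hippocampus-rescaling scenarios on the default
# 128 x 128 x 63 grid, noise off (the deterministic limit the ordering and
# monotonicity properties are stated in). Computed once per session.
chain_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_grid(
        scenarios = c("ideal", "fwhm_mismatch", "volume_scale_hippocampus"),
        add_noise = FALSE, seed = 1)
      cache <<- run_experiment_grid(cfg)
    }
    cache
  }
})
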