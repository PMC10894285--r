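# Shared study configuration for the analysis scripts.
#
# One synthetic Cerrado-like landscape: 200 x 200 cells of 1 km^2 (4 Mha),
# four two-year calibration periods (2008-2016), conversion histories from
# a sparse generating model, protected share 8.3%, heavy-tailed property
# mosaic under regional Legal Reserve regimes. All scripts derive every
# random quantity from STUDY_SEED, so the whole analysis replays bit for
# bit.

library(cerradosim)

STUDY_SEED <- 2024L

study_config <- function() {
  run_config(
    synth = synth_config(seed = STUDY_SEED),
    mcmc = mcmc_config(n_iter = 4000L, burn_in = 2000L,
                       seed = STUDY_SEED + 1L),
    selection = "forward",
    horizon_year = 2070L,
    n_iterations = 100L,
    projection_seed = STUDY_SEED + 2L,
    scenarios = list(protect30 = scenario_config(
      "protect30",
      large_property_rule = list(threshold_ha = 2500,
                                 protected_fraction = 0.30))))
}

results_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
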