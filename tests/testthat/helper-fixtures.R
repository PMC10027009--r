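# Shared fixtures; heavy objects are computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# cheap MC table for unit tests (2e4 photons/node)
fx_table_small <- function() fixture("table_small", function() {
  cfg <- speckperf_config()
  cfg$mc$n_photons <- 2e4
  run_mc_grid(cfg, seed = 421)
})

# reduced-resolution Doppler config for spectrum tests
fx_doppler_config <- function() {
  cfg <- speckperf_config()
  cfg$doppler$n_bins <- 2^12
  cfg
}

# small fixed tissue model at median-ish parameters
fx_model <- function(c_blood = 0.55, mean_speed = 1, tops = NULL) {
  cfg <- speckperf_config()
  set.seed(77)
  m <- sample_tissue_model(cfg, restricted = TRUE)
  m$c_blood_upper <- m$c_blood_lower <- c_blood
  if (!is.null(tops)) {
    m$speed <- build_speed_distribution(rep(1, length(tops)), 1, top_speeds = tops)
  }
  m$speed <- speckperf:::scale_mean_speed(m$speed, mean_speed)
  m
}

# desk-scale study pipeline shared by the acceptance tests (runs once)
fx_study <- function() fixture("study", function() {
  cfg <- speckperf_config()
  melsci_study(cfg, seed = 9001, verbose = FALSE)
})
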