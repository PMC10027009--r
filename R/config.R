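#' Default configuration for the forward model and training pipeline
#'
#' Returns the full nested configuration used throughout the package: optical
#' constants at 780 nm, the tissue-parameter distributions of the randomized
#' three-layer skin model, Monte Carlo transport settings, Doppler-spectrum
#' and contrast-quadrature settings, the biological-zero and contrast-noise
#' models, and neural-network training defaults. Every entry can be overridden
#' from a YAML file via [read_config()].
#'
#' Tissue-parameter distributions are specified as a family plus support and
#' median. Supported families: `"truncexp"` (exponential decay truncated to
#' the support, decay rate solved so the median matches), `"lognormal"`
#' (truncated, median = `median`, log-sd `sdlog`), and `"uniform"`.
#'
#' @param restricted logical; if `TRUE` the sampler fixes epidermis thickness,
#'   reduced scattering, epidermis absorption, vessel diameter and oxygen
#'   saturation at their configured medians (ablation bounding achievable
#'   accuracy; only blood fraction and the speed distribution vary, and
#'   contrast noise is omitted downstream).
#' @return nested list of configuration blocks.
#' @export
speckperf_config <- function(restricted = FALSE) {
  list(
    optics = list(
      lambda_mm = 780e-6,       # laser wavelength, mm
      n_tissue = 1.4,
      n_outside = 1.0,
      gk_g = 0.948,             # Gegenbauer kernel gGk
      gk_alpha = 1.0,           # Gegenbauer kernel alphaGk
      mus_blood = 222,          # scattering coefficient of whole blood, mm^-1
      mua_blood_oxy = 0.40,     # mm^-1, oxygenated whole blood at 780 nm
      mua_blood_deoxy = 0.58,   # mm^-1, deoxygenated whole blood at 780 nm
      mua_dermis_baseline = 0.02 # mm^-1, bloodless dermis
    ),
    tissue_model = list(
      restricted = restricted,
      t_epi     = list(family = "truncexp", support = c(0.04, 1.0),  median = 0.205),
      mua_epi   = list(family = "truncexp", support = c(0.01, 3.5),  median = 0.25),
      musp      = list(family = "lognormal", support = c(0.5, 4.5),  median = 1.6, sdlog = 0.35),
      c_blood   = list(family = "truncexp", support = c(0.01, 4.0),  median = 0.55),
      s_oxy     = list(family = "uniform",  support = c(0, 1),       median = 0.5),
      d_vessels = list(family = "truncexp", support = c(0.004, 0.6), median = 0.055),
      mean_speed = list(family = "truncexp", support = c(0.05, 20),  median = 1.0),
      diff_frac = 0.5,          # layer difference: +/-50% of the average
      top_speeds = 0.5 * 2^(0:9), # mm/s, exponentially increasing top speeds
      speed_kernel_sd = c(0.5, 1.2), # range of log-kernel widths for weights
      t_dermis_upper = 0.2      # mm, fixed
    ),
    mc = list(
      grid_t_epi = c(0.04, 0.08, 0.14, 0.25, 0.45, 0.70, 1.00),
      grid_musp  = c(0.5, 0.9, 1.3, 1.8, 2.5, 3.4, 4.5),
      n_photons = 1e5,
      g_transport = 0,          # transport anisotropy (HG); mus = musp/(1-g)
      n_bins = 40,              # joint path-length bins per layer
      l_min = c(0.05, 0.005, 0.005), # mm, lower edge of first positive bin
      l_max = c(50, 200, 400),  # mm, upper bin edge per layer
      z_max = 40,               # mm, photons deeper than this are terminated
      l_total_max = 400         # mm, total path-length cutoff
    ),
    doppler = list(
      f_max = 2e5,              # Hz, histogram grid ceiling
      n_bins = 2^14,
      n_max_cap = 64,           # cap on number of Doppler shifts composed
      n_tail_prob = 1e-4,       # residual shift-count mass folded into n_max
      pgf_size = 128,           # FFT size for shift-count inversion
      n_speed_sub = 24,         # sub-nodes when marginalizing over a uniform speed
      kernel_nw = 4000,         # phase-function nodes for the shift kernel
      kernel_ns = 3000          # s-grid size for the A(v*tau) kernel table
    ),
    bz = list(
      enabled = TRUE,
      offset_mean = -5.3, offset_sd = 0.125,
      slope_mean = -5.2e-5, slope_sd = 6e-6
    ),
    contrast = list(
      exposures_ms = c(1, 2, 4, 8, 16, 32, 64),
      beta = 1,
      n_panels = 36,            # log-spaced quadrature panels per exposure
      panel_lo = 1e-9,          # lowest panel edge in u = tau/T
      gl_points = 6,            # Gauss-Legendre points per panel
      noise = list(
        eta1 = 0.02,
        eta_diff = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01), # T = 2..64 ms
        clip_floor = 1e-4
      )
    ),
    ann = list(
      hidden = 25,
      restarts = 5,
      lr = 3e-3,
      batch = 256,
      patience = 50,
      max_epochs = 3000,
      eps_floor = 1e-6          # floor on true total perfusion in wMSE/wMAPE
    ),
    dataset = list(
      n_train_pool = 10000,
      n_eval = 10000,
      split = c(train = 0.70, val = 0.15, test = 0.15)
    )
  )
}

#' Read a YAML configuration, merged over the package defaults
#'
#' @param path path to a YAML file; keys mirror [speckperf_config()]. Missing
#'   keys keep their default values (deep merge).
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  deep_merge(speckperf_config(), user)
}

deep_merge <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    if (!is.null(base[[nm]]) && is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
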