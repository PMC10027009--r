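#' Gegenbauer kernel phase function utilities
#'
#' The single-scattering angular distribution of light on red blood cells is
#' modeled with the two-parameter Gegenbauer kernel (GK) phase function
#' \deqn{p(\cos\theta) \propto (1 + g_{Gk}^2 - 2 g_{Gk}\cos\theta)^{-(\alpha_{Gk}+1)},}
#' which reduces to Henyey-Greenstein for \eqn{\alpha_{Gk} = 1/2}. Its first
#' moment (the anisotropy factor g) is computed by quadrature. The substitution
#' \eqn{w = (1+g^2-2g\cos\theta)^{-\alpha}} makes the phase function exactly
#' uniform in \eqn{w}, so equally spaced \eqn{w} nodes integrate the sharp
#' forward peak without loss of accuracy.
#'
#' @param gGk asymmetry parameter, 0 < gGk < 1.
#' @param alphaGk shape parameter, > -1/2 and nonzero.
#' @param n number of quadrature nodes.
#' @return `gegenbauer_anisotropy`: the anisotropy factor (mean cosine).
#' @export
gegenbauer_anisotropy <- function(gGk, alphaGk, n = 200000) {
  nodes <- gk_nodes(gGk, alphaGk, n)
  mean(nodes$cos_theta)
}

# Equal-weight quadrature nodes of the GK phase function.
# Returns cos(theta) and sin(theta/2) at nodes that are equiprobable under the
# phase function, so any expectation over scattering angle is a plain mean.
gk_nodes <- function(gGk, alphaGk, n = 4000) {
  if (!is.finite(gGk) || gGk <= 0 || gGk >= 1)
    stop("gGk must be in (0, 1)")
  if (!is.finite(alphaGk) || alphaGk <= -0.5 || alphaGk == 0)
    stop("alphaGk must be > -1/2 and nonzero (non-normalizable otherwise)")
  w1 <- (1 + gGk)^(-2 * alphaGk)
  w2 <- (1 - gGk)^(-2 * alphaGk)
  lo <- min(w1, w2); hi <- max(w1, w2)
  w <- seq(lo, hi, length.out = 2L * n + 1L)[seq(2L, 2L * n, by = 2L)]
  y <- w^(-1 / alphaGk)                      # y = 1 + g^2 - 2 g cos(theta)
  cos_theta <- (1 + gGk^2 - y) / (2 * gGk)
  cos_theta <- pmin(1, pmax(-1, cos_theta))
  list(cos_theta = cos_theta,
       sin_half = sqrt(pmax(0, (1 - cos_theta) / 2)))
}

#' Normalized Gegenbauer kernel phase function density
#'
#' Density over \eqn{\cos\theta} (i.e. \eqn{2\pi p(\cos\theta)} integrates to 1
#' over \eqn{[-1, 1]}).
#'
#' @rdname gegenbauer_anisotropy
#' @param cos_theta cosine of the scattering angle.
#' @return `gk_phase_density`: density values at `cos_theta`.
#' @export
gk_phase_density <- function(cos_theta, gGk, alphaGk) {
  if (gGk <= 0 || gGk >= 1 || alphaGk <= -0.5 || alphaGk == 0)
    stop("invalid Gegenbauer parameters")
  y <- 1 + gGk^2 - 2 * gGk * cos_theta
  norm <- ((1 - gGk)^(-2 * alphaGk) - (1 + gGk)^(-2 * alphaGk)) / (2 * gGk * alphaGk)
  y^(-(alphaGk + 1)) / norm
}

# ---------------------------------------------------------------------------
# Single-shift decorrelation kernel
#
# One Doppler shift from an RBC with speed v produces the frequency
#   f = (2 n v / lambda) sin(theta/2) cos(psi),
# theta ~ GK phase function, cos(psi) ~ U[-1, 1]. The lag-domain transform of
# the single-shift spectrum depends on v and tau only through s = v * tau:
#   A(s) = E_theta[ sinc( (4 pi n s / lambda) sin(theta/2) ) ],
# (the psi average of cos is exactly sinc). For a uniform speed distribution
# on [0, v_top] the marginalized transform is the running mean
#   Abar(x) = (1/x) int_0^x A(s) ds  evaluated at x = v_top * tau.
# Both are tabulated once per optics configuration and interpolated.
# ---------------------------------------------------------------------------

shift_kernel <- function(config = speckperf_config()) {
  op <- config$optics
  key <- paste0("kernel_", paste(op$gk_g, op$gk_alpha, op$n_tissue, op$lambda_mm,
                                 config$doppler$kernel_nw, config$doppler$kernel_ns,
                                 sep = "_"))
  cached <- .speckperf_cache[[key]]
  if (!is.null(cached)) return(cached)

  nodes <- gk_nodes(op$gk_g, op$gk_alpha, config$doppler$kernel_nw)
  sh <- nodes$sin_half
  cst <- 4 * pi * op$n_tissue / op$lambda_mm   # rad per mm of s, at sin(theta/2)=1
  s_grid <- 10^seq(-8, 2, length.out = config$doppler$kernel_ns)
  A <- vapply(s_grid, function(s) {
    x <- cst * s * sh
    mean(ifelse(x < 1e-12, 1, sin(x) / x))
  }, numeric(1))
  # running mean Abar(x) = (1/x) int_0^x A; A ~ 1 below the grid
  cum <- cumsum(c(0, diff(s_grid) * (head(A, -1) + tail(A, -1)) / 2)) + s_grid[1]
  Abar <- cum / s_grid
  logs <- log(s_grid)
  kern <- list(
    s_grid = s_grid, A = A, Abar = Abar,
    A_at = function(s) {
      v <- approx(logs, A, log(pmax(s, s_grid[1])), rule = 2)$y
      v[s < s_grid[1]] <- 1
      v
    },
    Abar_at = function(s) {
      v <- approx(logs, Abar, log(pmax(s, s_grid[1])), rule = 2)$y
      v[s < s_grid[1]] <- 1
      v
    }
  )
  .speckperf_cache[[key]] <- kern
  kern
}
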