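# Doppler power-spectrum composition -----------------------------------------
#
# The optical Doppler spectrum H(f) of detected light is composed from
# (i) the single-shift spectrum of one scattering event on a moving RBC,
# (ii) the distribution P(n) of the number of Doppler shifts per detected
# photon (compound Poisson, vessel-packaged, mixed over the absorption-
# weighted path-length distribution), and (iii) n-fold spectral
# self-composition: H(f) = sum_n P(n) H_n(f). Spectra are one-sided
# histograms; the f = 0 bin carries the unshifted (static) delta. All
# composition is done on the symmetric two-sided extension where, because the
# spectra are even, cross-correlation and convolution coincide.

new_doppler_histogram <- function(mass, config) {
  nb <- config$doppler$n_bins
  df <- config$doppler$f_max / (nb - 1)
  h <- list(freq = (seq_len(nb) - 1) * df, mass = mass, df = df,
            f_max = config$doppler$f_max)
  class(h) <- "doppler_histogram"
  h
}

#' @export
print.doppler_histogram <- function(x, ...) {
  cat(sprintf("Doppler histogram: %d bins to %.3g kHz, zero-shift weight %.4f, total %.6f\n",
              length(x$mass), x$f_max / 1e3, x$mass[1], sum(x$mass)))
  invisible(x)
}

# symmetric two-sided extension (length 2 nb) and fold-back
two_sided_mass <- function(mass) {
  nb <- length(mass)
  M <- numeric(2 * nb)
  M[1] <- mass[1]
  M[2:nb] <- mass[2:nb] / 2
  M[(2 * nb):(nb + 2)] <- M[(2 * nb):(nb + 2)] + mass[2:nb] / 2
  M
}

fold_mass <- function(M) {
  nb <- length(M) / 2
  mass <- numeric(nb)
  mass[1] <- M[1]
  mass[2:nb] <- M[2:nb] + M[(2 * nb):(nb + 2)]
  mass
}

#' Doppler spectrum of singly shifted light at one RBC speed
#'
#' Analytic (quadrature) spectrum of |f| for one Doppler shift:
#' \eqn{f = (2 n_{tissue} v/\lambda)\sin(\theta/2)\cos\psi} with the
#' scattering angle drawn from the Gegenbauer kernel phase function and a
#' random angle \eqn{\psi} between light and RBC direction
#' (\eqn{\cos\psi \sim U[-1,1]}, so |f| given \eqn{\theta} is uniform on
#' \eqn{[0, f_{max}(\theta)]}). Folded one-sided; sums to 1.
#'
#' @param v RBC speed, mm/s.
#' @param config configuration list.
#' @return a `doppler_histogram`.
#' @export
single_shift_histogram <- function(v, config = speckperf_config()) {
  nb <- config$doppler$n_bins
  df <- config$doppler$f_max / (nb - 1)
  if (v < 0 || !is.finite(v)) stop("v must be finite and >= 0")
  mass <- numeric(nb)
  if (v == 0) {
    mass[1] <- 1
    return(new_doppler_histogram(mass, config))
  }
  fmax_v <- 2 * config$optics$n_tissue * v / config$optics$lambda_mm
  if (fmax_v > config$doppler$f_max)
    stop(sprintf("grid overflow: speed %.3g mm/s needs f_max >= %.4g Hz (grid has %.4g)",
                 v, fmax_v, config$doppler$f_max))
  nodes <- gk_nodes(config$optics$gk_g, config$optics$gk_alpha,
                    config$doppler$kernel_nw)
  Fv <- sort(pmax(fmax_v * nodes$sin_half, 1e-300))
  edges <- c(0, (seq_len(nb - 1) - 0.5) * df, config$doppler$f_max)
  # G(e) = sum_nodes min(F, e)/F, via sorted F + suffix sums of 1/F
  inv <- 1 / Fv
  suff <- c(rev(cumsum(rev(inv))), 0)       # suff[i] = sum_{k>=i} 1/F_k
  idx <- findInterval(edges, Fv)            # number of F <= e
  G <- idx + edges * suff[idx + 1]
  mass <- diff(G) / length(Fv)
  new_doppler_histogram(mass, config)
}

#' Doppler spectrum of singly shifted light for a uniform speed component
#'
#' Exact marginalization of the single-shift spectrum over a uniform speed
#' distribution on \eqn{[0, v_{top}]}: given the scattering angle,
#' \eqn{|f| = f_{max}(\theta)\, v\, |\cos\psi| / v_{top}} is a product of two
#' independent uniforms, whose CDF \eqn{C(x) = x(1 - \ln x)} (x = f scaled by
#' the per-angle ceiling) is accumulated analytically over the phase-function
#' quadrature nodes.
#'
#' @param v_top top speed of the uniform component, mm/s.
#' @param config configuration list.
#' @return a `doppler_histogram`.
#' @export
uniform_speed_shift_histogram <- function(v_top, config = speckperf_config()) {
  nb <- config$doppler$n_bins
  df <- config$doppler$f_max / (nb - 1)
  if (v_top < 0 || !is.finite(v_top)) stop("v_top must be finite and >= 0")
  if (v_top == 0) {
    mass <- numeric(nb); mass[1] <- 1
    return(new_doppler_histogram(mass, config))
  }
  fmax_v <- 2 * config$optics$n_tissue * v_top / config$optics$lambda_mm
  if (fmax_v > config$doppler$f_max)
    stop(sprintf("grid overflow: top speed %.3g mm/s needs f_max >= %.4g Hz (grid has %.4g)",
                 v_top, fmax_v, config$doppler$f_max))
  nodes <- gk_nodes(config$optics$gk_g, config$optics$gk_alpha,
                    config$doppler$kernel_nw)
  a <- sort(pmax(fmax_v * nodes$sin_half, 1e-300))  # per-node ceiling F*v_top
  edges <- c(0, (seq_len(nb - 1) - 0.5) * df, config$doppler$f_max)
  # sum over nodes of C(e; a) = (e/a)(1 - log(e/a)) for e < a, else 1
  s1 <- c(rev(cumsum(rev(1 / a))), 0)          # suffix sums of 1/a
  s2 <- c(rev(cumsum(rev(log(a) / a))), 0)     # suffix sums of log(a)/a
  idx <- findInterval(edges, a)                # nodes with a <= e
  e <- edges
  csum <- idx + e * (1 - log(pmax(e, 1e-300))) * s1[idx + 1] + e * s2[idx + 1]
  csum[e == 0] <- 0
  mass <- pmax(diff(csum), 0) / length(a)
  new_doppler_histogram(mass, config)
}

# effective support of a histogram: largest frequency with tail mass > tol
mass_support <- function(h, tol = 1e-9) {
  tailm <- rev(cumsum(rev(h$mass)))
  idx <- which(tailm > tol)
  h$freq[max(idx)]
}

#' Spectrum of light Doppler shifted n times
#'
#' Computed as the (n-1)-fold cross-correlation of the single-shift spectrum
#' with itself, carried out on the symmetric two-sided extension via FFT
#' (even spectra: correlation equals convolution), then folded back
#' one-sided. Normalization is preserved.
#'
#' @param single a normalized single-shift `doppler_histogram`.
#' @param n number of shifts (>= 1); `n = 1` returns the input.
#' @return a `doppler_histogram`.
#' @export
n_shift_histogram <- function(single, n) {
  stopifnot(inherits(single, "doppler_histogram"))
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (n == 1) return(single)
  # compose on a 2x zero-padded grid so mass beyond f_max is measured, not
  # silently aliased
  nb <- length(single$mass)
  M <- two_sided_mass(c(single$mass, numeric(nb)))
  Fn <- fft(M)^n
  Hn <- pmax(Re(fft(Fn, inverse = TRUE)) / length(M), 0)
  full <- fold_mass(Hn)
  over <- sum(full[(nb + 1):(2 * nb)])
  if (over > 1e-6)
    stop(sprintf("grid overflow: %d-fold spectrum carries %.3g mass beyond f_max = %.4g Hz",
                 n, over, single$f_max))
  out <- single
  out$mass <- full[seq_len(nb)] / sum(full[seq_len(nb)])
  out
}

#' Distribution of the number of Doppler shifts in a perfused layer
#'
#' Blood is confined to discrete vessels, so shift counts over-disperse
#' relative to a plain Poisson: a photon with path length l in the layer
#' crosses `Poisson(l * 4 c_blood / (pi d))` vessels (mean-chord geometry of
#' randomly oriented cylinders, mean chord pi d / 4) and collects
#' `Poisson(mus_blood * pi d / 4)` shifts per crossing. The compound
#' distribution is mixed over the layer's path-length distribution and
#' evaluated exactly through its probability generating function on the unit
#' circle (inverse FFT). As the vessel diameter goes to zero it converges to
#' the homogeneous `Poisson(l * c_blood/100 * mus_blood)` limit.
#'
#' @param lengths path lengths, mm.
#' @param weights nonnegative weights of `lengths` (normalized internally).
#' @param c_blood blood tissue fraction, %.
#' @param d_vessels vessel diameter, mm.
#' @param mus_blood scattering coefficient of whole blood, mm^-1.
#' @param n_size FFT size (doubled automatically until the tail is captured).
#' @return object of class `shift_count`: list with `n` (0, 1, ...) and
#'   probabilities `p`.
#' @export
shift_count_distribution <- function(lengths, weights, c_blood, d_vessels,
                                     mus_blood = speckperf_config()$optics$mus_blood,
                                     n_size = 128) {
  if (c_blood < 0 || d_vessels <= 0 || mus_blood <= 0)
    stop("invalid blood parameters")
  if (length(lengths) != length(weights) || any(weights < 0))
    stop("lengths/weights mismatch or negative weights")
  w <- weights / sum(weights)
  lam_per_mm <- 4 * (c_blood / 100) / (pi * d_vessels)  # vessel passages / mm
  mu <- mus_blood * pi * d_vessels / 4                  # shifts per passage
  repeat {
    om <- 2 * pi * (seq_len(n_size) - 1) / n_size
    z <- exp(1i * om)
    inner <- exp(mu * (z - 1)) - 1
    G <- colSums(w * exp(outer(lengths * lam_per_mm, inner)))
    p <- pmax(Re(fft(G)) / n_size, 0)
    if (p[n_size] < 1e-9 || n_size >= 4096) break
    n_size <- n_size * 2
  }
  out <- list(n = seq_len(n_size) - 1, p = p / sum(p))
  class(out) <- "shift_count"
  out
}

# Shift-count distribution over both dermis layers jointly, mixed over the
# absorption-weighted joint (l_upper, l_lower) path-length cells. W2 need not
# be normalized. Returns the probability vector over n = 0..n_size-1.
shift_count_joint <- function(W2, l2, l3, rate2, mu2, rate3, mu3, n_size = 128) {
  W2 <- W2 / sum(W2)
  om <- 2 * pi * (seq_len(n_size) - 1) / n_size
  z <- exp(1i * om)
  B2 <- exp(mu2 * (z - 1)) - 1
  B3 <- exp(mu3 * (z - 1)) - 1
  E2 <- exp(outer(l2 * rate2, B2))    # nb x n_size
  E3 <- exp(outer(l3 * rate3, B3))
  G <- colSums(E2 * (W2 %*% E3))
  pmax(Re(fft(G)) / n_size, 0)
}

# Truncate a shift-count pmf: smallest n with cumulative mass > 1 - tail_prob,
# capped; residual mass assigned to the cap.
truncate_shift_counts <- function(p, tail_prob = 1e-4, cap = 64) {
  cum <- cumsum(p)
  n_max <- min(which(cum > 1 - tail_prob)[1] - 1, cap, length(p) - 1)
  if (is.na(n_max)) n_max <- min(cap, length(p) - 1)
  out <- p[seq_len(n_max + 1)]
  out[n_max + 1] <- out[n_max + 1] + max(0, 1 - sum(out))
  out / sum(out)
}

#' Compose the Doppler histogram of a tissue model
#'
#' Combines the RBC speed distribution, the absorption-weighted path-length
#' distribution and the vessel-packaged shift-count statistics into the final
#' Doppler spectrum \eqn{H(f) = \sum_n P(n) H_n(f)}, where the single-shift
#' spectrum is marginalized over the speed distribution (shift probability
#' proportional to RBC concentration, independent of speed) and \eqn{H_n} is
#' its n-fold composition. The f = 0 bin weight equals the zero-shift
#' probability P(0).
#'
#' @param model a `skin_model`.
#' @param dist absorption-weighted `pathlength_dist` (see
#'   [apply_absorption()]).
#' @param config configuration list.
#' @return a normalized `doppler_histogram` with attribute `p_zero_shift`.
#' @export
compose_doppler_histogram <- function(model, dist, config = speckperf_config()) {
  stopifnot(inherits(model, "skin_model"), inherits(dist, "pathlength_dist"))
  nb <- dim(dist$w)
  W2 <- colSums(matrix(dist$w, nb[1], nb[2] * nb[3]))
  dim(W2) <- c(nb[2], nb[3])

  op <- config$optics
  rate2 <- 4 * (model$c_blood_upper / 100) / (pi * model$d_vessels_upper)
  rate3 <- 4 * (model$c_blood_lower / 100) / (pi * model$d_vessels_lower)
  mu2 <- op$mus_blood * pi * model$d_vessels_upper / 4
  mu3 <- op$mus_blood * pi * model$d_vessels_lower / 4
  p_n <- shift_count_joint(W2, dist$reps[[2]], dist$reps[[3]],
                           rate2, mu2, rate3, mu3, config$doppler$pgf_size)
  p_n <- truncate_shift_counts(p_n, config$doppler$n_tail_prob,
                               config$doppler$n_max_cap)

  # speed-marginalized single-shift spectrum: exact uniform-component average
  sp <- model$speed
  h1 <- numeric(config$doppler$n_bins)
  for (k in seq_along(sp$top_speeds)) {
    if (sp$weights[k] <= 0) next
    h1 <- h1 + sp$weights[k] *
      uniform_speed_shift_histogram(sp$top_speeds[k], config)$mass
  }
  h1 <- h1 / sum(h1)

  # compose on a 2x zero-padded grid; mass landing beyond f_max is measured
  # and rejected rather than silently aliased
  nb_f <- length(h1)
  n_hi <- length(p_n) - 1
  M1 <- fft(two_sided_mass(c(h1, numeric(nb_f))))
  acc <- rep(p_n[1] + 0i, length(M1))
  cur <- rep(1 + 0i, length(M1))
  for (n in seq_len(n_hi)) {
    cur <- cur * M1
    acc <- acc + p_n[n + 1] * cur
  }
  Hts <- pmax(Re(fft(acc, inverse = TRUE)) / length(acc), 0)
  full <- fold_mass(Hts)
  over <- sum(full[(nb_f + 1):(2 * nb_f)])
  if (over > 1e-6)
    stop(sprintf("grid overflow: composed spectrum carries %.3g mass beyond f_max = %.4g Hz",
                 over, config$doppler$f_max))
  mass <- full[seq_len(nb_f)]
  mass <- mass / sum(mass)
  h <- new_doppler_histogram(mass, config)
  attr(h, "p_zero_shift") <- p_n[1]
  attr(h, "p_n") <- p_n
  h
}

#' Add the biological-zero component to a Doppler histogram
#'
#' During full arterial occlusion a residual high-frequency component remains
#' in measured Doppler spectra (Brownian RBC motion and interstitial
#' macromolecule movement). It is modeled empirically as
#' \deqn{H_{BZ}(f) = 0 \ (f = 0); \quad 10^{\xi_{offset} + f \xi_{slope}} \ (f > 0),}
#' with \eqn{\xi_{offset} \sim N(-5.3, 0.125)} and \eqn{\xi_{slope} \sim
#' N(-5.2\times10^{-5}, 6\times10^{-6})}. The component is added (as spectral
#' density times bin width) to the normalized histogram, which is then
#' renormalized. Its effect is negligible under normal flow.
#'
#' @param H a normalized `doppler_histogram`.
#' @param config configuration list (block `bz`).
#' @param xi_offset,xi_slope optional fixed values; drawn from the configured
#'   normal distributions when `NULL`.
#' @return the `doppler_histogram` with BZ added, attributes `xi_offset`,
#'   `xi_slope`.
#' @export
add_biological_zero <- function(H, config = speckperf_config(),
                                xi_offset = NULL, xi_slope = NULL) {
  stopifnot(inherits(H, "doppler_histogram"))
  bz <- config$bz
  if (is.null(xi_offset)) xi_offset <- rnorm(1, bz$offset_mean, bz$offset_sd)
  if (is.null(xi_slope)) xi_slope <- rnorm(1, bz$slope_mean, bz$slope_sd)
  add <- 10^(xi_offset + H$freq * xi_slope) * H$df
  add[1] <- 0
  H$mass <- H$mass + add
  H$mass <- H$mass / sum(H$mass)
  attr(H, "xi_offset") <- xi_offset
  attr(H, "xi_slope") <- xi_slope
  H
}

# Draw biological-zero parameters and return the lag-domain description used
# by the fast forward path: total spectral mass A (relative to a unit
# histogram) and the closed-form autocorrelation of the normalized BZ
# spectrum, g1_bz(tau) = alpha^2 / (alpha^2 + (2 pi tau)^2) for the
# exponential-in-frequency density with decay alpha = -ln(10) * xi_slope.
bz_draw <- function(config, xi_offset = NULL, xi_slope = NULL) {
  bz <- config$bz
  if (is.null(xi_offset)) xi_offset <- rnorm(1, bz$offset_mean, bz$offset_sd)
  if (is.null(xi_slope)) xi_slope <- rnorm(1, bz$slope_mean, bz$slope_sd)
  xi_slope <- min(xi_slope, -1e-6)
  alpha <- -log(10) * xi_slope
  list(xi_offset = xi_offset, xi_slope = xi_slope,
       A = 10^xi_offset / alpha,
       g1 = function(tau) alpha^2 / (alpha^2 + (2 * pi * tau)^2))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached.
gauss_legendre <- function(n) {
  key <- paste0("gl_", n)
  cached <- .speckperf_cache[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  out <- list(x = x, w = w)
  .speckperf_cache[[key]] <- out
  out
}
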