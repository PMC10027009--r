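# Multi-exposure speckle contrast --------------------------------------------
#
# Wiener-Khinchine: the electric field autocorrelation is the inverse Fourier
# transform of the Doppler power spectrum, g1(tau) = |F^-1{H(f)}|. Contrast at
# exposure time T follows the standard triangular-window integral
#   K^2(T) = (2 beta / T) int_0^T |g1(tau)|^2 (1 - tau/T) dtau.
# Quadrature uses composite Gauss-Legendre on log-spaced panels in u = tau/T,
# which resolves decorrelation scales from microseconds (fast flow,
# biological zero) to the full 64 ms exposure.

#' Field autocorrelation from a Doppler histogram
#'
#' Evaluates \eqn{|g^{(1)}(\tau)|} as the magnitude of the inverse Fourier
#' transform of the symmetric two-sided extension of H(f);
#' \eqn{|g^{(1)}(0)| = 1} for a normalized histogram, and the result is
#' insensitive to any overall rescaling of H.
#'
#' @param H a `doppler_histogram`.
#' @param tau lag times, s.
#' @return numeric vector of |g1| at `tau`.
#' @export
autocorrelation_from_histogram <- function(H, tau) {
  stopifnot(inherits(H, "doppler_histogram"))
  m <- H$mass / sum(H$mass)
  out <- numeric(length(tau))
  # chunk the outer product to bound memory on long tau grids
  chunk <- max(1L, floor(4e6 / length(m)))
  for (s in seq(1, length(tau), by = chunk)) {
    idx <- s:min(s + chunk - 1, length(tau))
    out[idx] <- abs(cos(outer(tau[idx], 2 * pi * H$freq)) %*% m)
  }
  as.numeric(out)
}

# Quadrature nodes for one exposure: returns u nodes and weights such that
# K^2 = 2 beta * sum(w * g1(T u)^2); the (1 - u) window is folded into w.
contrast_nodes <- function(config = speckperf_config()) {
  key <- paste0("cn_", config$contrast$n_panels, "_", config$contrast$panel_lo,
                "_", config$contrast$gl_points)
  cached <- .speckperf_cache[[key]]
  if (!is.null(cached)) return(cached)
  ct <- config$contrast
  gl <- gauss_legendre(ct$gl_points)
  eu <- 10^seq(log10(ct$panel_lo), 0, length.out = ct$n_panels + 1)
  u <- as.vector(vapply(seq_len(ct$n_panels), function(p)
    (eu[p] + eu[p + 1]) / 2 + (eu[p + 1] - eu[p]) / 2 * gl$x,
    numeric(ct$gl_points)))
  w <- as.vector(vapply(seq_len(ct$n_panels), function(p)
    (eu[p + 1] - eu[p]) / 2 * gl$w, numeric(ct$gl_points)))
  w <- w * (1 - u)
  # sliver [0, panel_lo]: g1 ~ g1(0) there
  out <- list(u = c(ct$panel_lo / 2, u),
              w = c(ct$panel_lo * (1 - ct$panel_lo / 2), w))
  .speckperf_cache[[key]] <- out
  out
}

#' Speckle contrast at one exposure time from |g1|
#'
#' Evaluates \eqn{K(T) = \sqrt{(2\beta/T)\int_0^T |g^{(1)}(\tau)|^2
#' (1-\tau/T)\,d\tau}} by composite Gauss-Legendre quadrature on log-spaced
#' panels. With \eqn{\beta = 1} and \eqn{|g^{(1)}| \equiv 1} (static target)
#' the result is exactly 1.
#'
#' @param g1 either a function of lag tau (in seconds) returning |g1|, or a
#'   list/data.frame with components `tau` and `g1` (interpolated linearly).
#' @param T_ms exposure time(s), ms.
#' @param beta coherence factor (> 0).
#' @param config configuration list.
#' @return numeric vector of K at each exposure.
#' @export
contrast_from_autocorrelation <- function(g1, T_ms, beta = 1,
                                          config = speckperf_config()) {
  if (any(T_ms <= 0)) stop("exposure time must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  if (!is.function(g1)) {
    tab <- g1
    if (is.null(tab$tau) || is.null(tab$g1)) stop("g1 must be a function or a list with tau and g1")
    g1 <- approxfun(tab$tau, tab$g1, rule = 2)
  }
  nodes <- contrast_nodes(config)
  vapply(T_ms, function(Tm) {
    Ts <- Tm * 1e-3
    vals <- g1(Ts * nodes$u)
    sqrt(2 * beta * sum(nodes$w * vals^2))
  }, numeric(1))
}

#' Multi-exposure contrast container
#'
#' @param K contrast values at the seven canonical exposures.
#' @param exposures_ms exposure times, ms.
#' @param noisy logical flag.
#' @return object of class `mexp_contrast` with fields `exposures_ms`, `K`
#'   and `K2` (the squared contrast used as network input).
#' @export
mexp_contrast <- function(K, exposures_ms = c(1, 2, 4, 8, 16, 32, 64),
                          noisy = FALSE) {
  stopifnot(length(K) == length(exposures_ms))
  out <- list(exposures_ms = exposures_ms, K = as.numeric(K),
              K2 = as.numeric(K)^2, noisy = noisy)
  class(out) <- "mexp_contrast"
  out
}

#' @export
print.mexp_contrast <- function(x, ...) {
  cat("Multi-exposure speckle contrast", if (x$noisy) "(noisy)" else "(noise-free)", "\n")
  print(setNames(round(x$K, 4), paste0(x$exposures_ms, "ms")))
  invisible(x)
}

#' @export
plot.mexp_contrast <- function(x, ...) {
  graphics::plot(x$exposures_ms, x$K, log = "x", type = "b", pch = 16,
                 xlab = "exposure time [ms]", ylab = "contrast K", ...)
  invisible(x)
}

#' Add measurement noise to multi-exposure contrast
#'
#' Contrast noise is a sequence of correlated random offsets proportional to
#' the average contrast over all exposures:
#' \deqn{K_{noise}(1) = \langle K\rangle_T\, \xi_1 \eta_1,\qquad
#'   K_{noise}(T) = K_{noise}(T/2) + \langle K\rangle_T\, \xi_T\,
#'   \eta_{diff}(T)} for T = 2..64 ms, with \eqn{\xi_T} i.i.d. standard
#' normal. Noisy contrast is clipped at a small positive floor so squared
#' contrast and single-exposure perfusion stay finite.
#'
#' @param K an `mexp_contrast`, or a numeric matrix (rows = samples, 7
#'   columns in exposure order).
#' @param config configuration list (block `contrast$noise`).
#' @param xi optional matrix/vector of the standard-normal draws (for tests);
#'   drawn internally when `NULL`.
#' @return same shape as the input, with noise added.
#' @export
add_contrast_noise <- function(K, config = speckperf_config(), xi = NULL) {
  ns <- config$contrast$noise
  single <- inherits(K, "mexp_contrast")
  Km <- if (single) matrix(K$K, 1) else as.matrix(K)
  ne <- ncol(Km)
  if (is.null(xi)) xi <- matrix(rnorm(nrow(Km) * ne), nrow(Km), ne)
  xi <- matrix(xi, nrow(Km), ne)
  avgK <- rowMeans(Km)
  noise <- matrix(0, nrow(Km), ne)
  noise[, 1] <- avgK * xi[, 1] * ns$eta1
  for (j in 2:ne)
    noise[, j] <- noise[, j - 1] + avgK * xi[, j] * ns$eta_diff[j - 1]
  out <- pmax(Km + noise, ns$clip_floor)
  if (single) mexp_contrast(out[1, ], K$exposures_ms, noisy = TRUE) else out
}

#' Single-exposure perfusion estimate
#'
#' The inverse-contrast model \eqn{P_{SE}(T) = 1/K(T) - 1} (arbitrary units),
#' the conventional single-exposure LSCI perfusion index used for
#' comparison.
#'
#' @param K contrast value(s), > 0.
#' @return perfusion estimate(s), arbitrary units.
#' @export
single_exposure_perfusion <- function(K) {
  if (any(K <= 0)) stop("contrast must be > 0")
  1 / K - 1
}
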