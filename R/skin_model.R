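#' Sample a randomized three-layer skin tissue model
#'
#' Draws one realization of the three-layer skin model: a bloodless epidermis
#' with variable thickness and melanin-driven absorption, a 0.2 mm upper dermis
#' and a semi-infinite lower dermis. Blood tissue fraction, oxygen saturation
#' and vessel diameter differ between the two dermis layers; each is drawn as a
#' randomized average plus a randomized bounded difference so the layers never
#' diverge too far. The RBC speed distribution is a weighted sum of ten uniform
#' distributions with exponentially increasing top speeds (vessels with
#' parabolic flow profiles); weights are randomized per model around a sampled
#' target mean speed.
#'
#' With `restricted = TRUE`, epidermis thickness, reduced scattering,
#' epidermis absorption, vessel diameter and oxygen saturation are pinned at
#' their configured medians and only blood fraction and the speed distribution
#' vary (the ablation used to bound achievable inversion accuracy).
#'
#' @param config configuration list from [speckperf_config()].
#' @param restricted logical; overrides `config$tissue_model$restricted`.
#' @return an object of class `skin_model`: a list with fields `t_epi`,
#'   `mua_epi`, `musp`, `c_blood_upper`, `c_blood_lower`, `s_oxy_upper`,
#'   `s_oxy_lower`, `d_vessels_upper`, `d_vessels_lower`, `speed` (a
#'   [build_speed_distribution()] object with unit total; per-layer
#'   concentrations scale it), and `t_dermis_upper`.
#' @export
sample_tissue_model <- function(config = speckperf_config(), restricted = NULL) {
  tm <- config$tissue_model
  if (is.null(restricted)) restricted <- isTRUE(tm$restricted)
  med <- function(p) p$median
  draw <- function(p) sample_param_dist(p, 1)

  if (restricted) {
    t_epi <- med(tm$t_epi); mua_epi <- med(tm$mua_epi); musp <- med(tm$musp)
    d_avg <- med(tm$d_vessels); s_avg <- med(tm$s_oxy)
    d_dif <- 0; s_dif <- 0
  } else {
    t_epi <- draw(tm$t_epi); mua_epi <- draw(tm$mua_epi); musp <- draw(tm$musp)
    d_avg <- draw(tm$d_vessels); s_avg <- draw(tm$s_oxy)
    d_dif <- runif(1, -tm$diff_frac, tm$diff_frac)
    s_dif <- runif(1, -tm$diff_frac, tm$diff_frac)
  }
  c_avg <- draw(tm$c_blood)
  c_dif <- runif(1, -tm$diff_frac, tm$diff_frac)

  m_target <- draw(tm$mean_speed)
  sdk <- runif(1, tm$speed_kernel_sd[1], tm$speed_kernel_sd[2])
  tops <- tm$top_speeds
  raw <- rexp(length(tops)) * exp(-(log(tops / 2) - log(m_target))^2 / (2 * sdk^2))
  if (sum(raw) <= 0) raw <- exp(-(log(tops / 2) - log(m_target))^2 / (2 * sdk^2))

  model <- list(
    t_epi = t_epi, mua_epi = mua_epi, musp = musp,
    c_blood_upper = c_avg * (1 + c_dif), c_blood_lower = c_avg * (1 - c_dif),
    s_oxy_upper = pmin(1, pmax(0, s_avg * (1 + s_dif))),
    s_oxy_lower = pmin(1, pmax(0, s_avg * (1 - s_dif))),
    d_vessels_upper = d_avg * (1 + d_dif), d_vessels_lower = d_avg * (1 - d_dif),
    speed = build_speed_distribution(raw, 1, top_speeds = tops),
    t_dermis_upper = tm$t_dermis_upper,
    restricted = restricted
  )
  class(model) <- "skin_model"
  model
}

#' @export
print.skin_model <- function(x, ...) {
  cat("Three-layer skin model\n")
  cat(sprintf("  epidermis: t = %.3f mm, mua = %.3f mm^-1\n", x$t_epi, x$mua_epi))
  cat(sprintf("  musp (all layers): %.2f mm^-1\n", x$musp))
  cat(sprintf("  dermis upper: c_blood = %.3f%%, S_oxy = %.2f, d = %.3f mm\n",
              x$c_blood_upper, x$s_oxy_upper, x$d_vessels_upper))
  cat(sprintf("  dermis lower: c_blood = %.3f%%, S_oxy = %.2f, d = %.3f mm\n",
              x$c_blood_lower, x$s_oxy_lower, x$d_vessels_lower))
  cat(sprintf("  mean RBC speed: %.2f mm/s\n", x$speed$mean_speed))
  invisible(x)
}

# Draw n values from one configured parameter distribution.
sample_param_dist <- function(p, n) {
  lo <- p$support[1]; hi <- p$support[2]
  switch(p$family,
    uniform = runif(n, lo, hi),
    truncexp = rtruncexp(n, lo, hi, p$median),
    lognormal = {
      x <- rlnorm(n, meanlog = log(p$median), sdlog = p$sdlog)
      while (any(bad <- x < lo | x > hi))
        x[bad] <- rlnorm(sum(bad), meanlog = log(p$median), sdlog = p$sdlog)
      x
    },
    stop("unknown distribution family: ", p$family)
  )
}

# Truncated exponential decay on [lo, hi] with the given median.
# Density ~ exp(-x / beta); beta solved so that the truncated median matches.
rtruncexp <- function(n, lo, hi, median_target) {
  stopifnot(lo < median_target, median_target < (lo + hi) / 2)
  beta <- truncexp_rate(lo, hi, median_target)
  u <- runif(n)
  lo - beta * log1p(u * expm1(-(hi - lo) / beta))
}

truncexp_rate <- function(lo, hi, median_target) {
  key <- paste0("texp_", lo, "_", hi, "_", median_target)
  cached <- .speckperf_cache[[key]]
  if (!is.null(cached)) return(cached)
  f <- function(beta) {
    # stable form of the truncated-exponential CDF at the median
    -expm1(-(median_target - lo) / beta) / -expm1(-(hi - lo) / beta) - 0.5
  }
  beta <- uniroot(f, lower = 1e-6 * (hi - lo), upper = 100 * (hi - lo),
                  tol = 1e-12)$root
  .speckperf_cache[[key]] <- beta
  beta
}

#' Build an RBC speed distribution from mixture weights
#'
#' The RBC speed distribution is a weighted sum of uniform distributions on
#' \eqn{[0, v_k]} with exponentially increasing top speeds \eqn{v_k}
#' (parabolic flow profiles in vessels with different average speeds). The
#' density is scaled so it integrates to the total RBC tissue fraction
#' `c_blood`; it is piecewise constant and nonincreasing in speed.
#'
#' @param weights 10 nonnegative mixture weights (not all zero); normalized
#'   internally.
#' @param c_blood total RBC tissue fraction in %.
#' @param top_speeds top speeds of the uniform components, mm/s.
#' @return object of class `speed_distribution` with fields `top_speeds`,
#'   `weights`, `c_blood`, `mean_speed` and `density` (a function of v in
#'   %RBC per (mm/s)).
#' @export
build_speed_distribution <- function(weights, c_blood,
                                     top_speeds = 0.5 * 2^(0:9)) {
  if (length(weights) != length(top_speeds))
    stop("weights and top_speeds must have equal length")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be nonnegative and finite")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  if (c_blood < 0) stop("c_blood must be >= 0")
  w <- weights / sum(weights)
  sd <- list(
    top_speeds = top_speeds,
    weights = w,
    c_blood = c_blood,
    mean_speed = sum(w * top_speeds / 2),
    density = function(v) {
      vapply(v, function(vi)
        c_blood * sum(w[top_speeds > vi] / top_speeds[top_speeds > vi]),
        numeric(1))
    }
  )
  class(sd) <- "speed_distribution"
  sd
}

#' @export
print.speed_distribution <- function(x, ...) {
  cat(sprintf("RBC speed distribution: %d uniform components, c_blood = %.3f%%, mean speed = %.3f mm/s\n",
              length(x$weights), x$c_blood, x$mean_speed))
  invisible(x)
}

# Band integrals int v * u_k(v) dv of the unit uniform component on [0, v_top]
# over the band [lo, hi): equals (min(hi,vt)^2 - min(lo,vt)^2) / (2 vt).
speed_band_integrals <- function(top_speeds, bands = c(0, 1, 10, Inf)) {
  nb <- length(bands) - 1
  B <- matrix(0, length(top_speeds), nb)
  for (j in seq_len(nb)) {
    lo <- bands[j]; hi <- bands[j + 1]
    B[, j] <- (pmin(hi, top_speeds)^2 - pmin(lo, top_speeds)^2) / (2 * top_speeds)
  }
  B[top_speeds <= 0, ] <- 0
  B
}

#' True speed-resolved perfusion of a tissue model
#'
#' Perfusion over a speed band is \eqn{P[v_{min},v_{max}] =
#' \int_{v_{min}}^{v_{max}} v\, c_{RBC}(v)\, dv} in %RBC x mm/s. The
#' contribution of each layer is weighted by the fraction of detected photon
#' path length spent in that layer (the sampling volume), so a thicker
#' bloodless epidermis lowers total perfusion even at fixed dermis properties.
#'
#' @param model a `skin_model`.
#' @param sampling_weights length-3 nonnegative vector (epidermis, upper
#'   dermis, lower dermis) summing to 1: fraction of detected photon path
#'   length per layer. See [sampling_volume_weights()].
#' @param bands band edges in mm/s; default the three reported bands.
#' @return object of class `speed_perfusion`: named numeric with `p_low`
#'   (0-1 mm/s), `p_mid` (1-10), `p_high` (>10) and `p_total`.
#' @export
true_perfusion <- function(model, sampling_weights, bands = c(0, 1, 10, Inf)) {
  w <- sampling_weights
  if (length(w) != 3 || any(w < 0) || any(!is.finite(w)))
    stop("sampling_weights must be 3 nonnegative finite values")
  if (abs(sum(w) - 1) > 1e-6) stop("sampling_weights must sum to 1")
  B <- speed_band_integrals(model$speed$top_speeds, bands)
  band_unit <- as.vector(crossprod(model$speed$weights, B)) # per unit c_blood
  p <- (w[2] * model$c_blood_upper + w[3] * model$c_blood_lower) * band_unit
  out <- c(p_low = p[1], p_mid = p[2], p_high = p[3], p_total = sum(p))
  class(out) <- "speed_perfusion"
  out
}

#' @export
print.speed_perfusion <- function(x, ...) {
  v <- unclass(x)
  cat("Speed-resolved perfusion [%RBC x mm/s]\n")
  cat(sprintf("  0-1 mm/s: %.4f   1-10 mm/s: %.4f   >10 mm/s: %.4f   total: %.4f\n",
              v["p_low"], v["p_mid"], v["p_high"], v["p_total"]))
  invisible(x)
}
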