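#' Run the Monte Carlo grid of photon-transport simulations
#'
#' Simulates photon random walks in the three-layer slab for every node of a
#' (epidermis thickness, reduced scattering) grid and stores, per node, the
#' joint histogram of per-layer path lengths of photons exiting the top
#' surface. Transport is absorption-free; absorption is applied afterwards per
#' tissue model via Beer-Lambert weighting ([apply_absorption()]). A joint
#' (not per-layer-marginal) histogram is kept because Beer-Lambert weighting
#' on correlated per-layer paths requires the joint distribution.
#'
#' @param config configuration list; `config$mc` holds the grids, photon
#'   count, bin layout and termination depths.
#' @param seed integer seed for reproducibility.
#' @param verbose print per-node progress.
#' @return object of class `pathlength_table`.
#' @export
run_mc_grid <- function(config = speckperf_config(), seed = 1L, verbose = FALSE) {
  mc <- config$mc
  tm_sup_t <- config$tissue_model$t_epi$support
  tm_sup_m <- config$tissue_model$musp$support
  if (min(mc$grid_t_epi) > tm_sup_t[1] || max(mc$grid_t_epi) < tm_sup_t[2] ||
      min(mc$grid_musp) > tm_sup_m[1] || max(mc$grid_musp) < tm_sup_m[2])
    stop("MC grid does not cover the tissue-model supports for t_epi / musp")
  if (mc$n_photons < 1e4) stop("n_photons must be >= 1e4")

  edges <- lapply(1:3, function(i)
    c(0, 10^seq(log10(mc$l_min[i]), log10(mc$l_max[i]), length.out = mc$n_bins)))
  reps <- lapply(edges, function(e) {
    r <- sqrt(e[-length(e)] * e[-1])    # geometric-mean representative
    r[1] <- 0                           # zero/underflow bin
    r
  })
  reps[[1]][1] <- edges[[1]][2] / 2     # epidermis path is never exactly 0

  nt <- length(mc$grid_t_epi); nm <- length(mc$grid_musp)
  counts <- array(0, dim = c(nt, nm, mc$n_bins, mc$n_bins, mc$n_bins))
  detected <- matrix(0, nt, nm)
  set.seed(seed)
  for (i in seq_len(nt)) for (j in seq_len(nm)) {
    res <- mc_layer_slab(mc$grid_t_epi[i], config$tissue_model$t_dermis_upper,
                         mc$grid_musp[j], as.integer(mc$n_photons),
                         config$optics$n_tissue / config$optics$n_outside,
                         mc$g_transport,
                         edges[[1]], edges[[2]], edges[[3]],
                         mc$z_max, mc$l_total_max)
    stopifnot(abs(res$n_detected + res$n_deep + res$n_killed - mc$n_photons) < 1e-9)
    counts[i, j, , , ] <- res$counts
    detected[i, j] <- res$n_detected
    if (verbose)
      message(sprintf("node t_epi=%.2f musp=%.2f: detected %.0f / %d",
                      mc$grid_t_epi[i], mc$grid_musp[j], res$n_detected,
                      mc$n_photons))
  }
  tab <- list(grid_t_epi = mc$grid_t_epi, grid_musp = mc$grid_musp,
              edges = edges, reps = reps, counts = counts,
              detected = detected, n_photons = mc$n_photons, seed = seed,
              transport = sprintf("HG g=%.2f at musp/(1-g) (similarity)",
                                  mc$g_transport))
  class(tab) <- "pathlength_table"
  tab
}

#' @export
print.pathlength_table <- function(x, ...) {
  cat(sprintf("Path-length table: %d x %d grid (t_epi x musp), %s photons/node\n",
              length(x$grid_t_epi), length(x$grid_musp),
              format(x$n_photons, big.mark = ",")))
  cat(sprintf("  joint histogram %d^3 log bins; mean detection fraction %.2f\n",
              length(x$reps[[1]]), mean(x$detected) / x$n_photons))
  invisible(x)
}

#' Persist / load a path-length table
#'
#' Tables are stored with base R serialization (single portable file).
#' @param table a `pathlength_table`.
#' @param path file path.
#' @rdname pathlength_io
#' @export
write_pathlength_table <- function(table, path) {
  stopifnot(inherits(table, "pathlength_table"))
  saveRDS(table, path)
  invisible(path)
}

#' @rdname pathlength_io
#' @export
read_pathlength_table <- function(path) {
  tab <- readRDS(path)
  stopifnot(inherits(tab, "pathlength_table"))
  tab
}

#' Interpolate the joint path-length distribution at arbitrary parameters
#'
#' Bilinear interpolation of the normalized joint path-length histograms of
#' the four surrounding grid nodes. At a grid node the stored (normalized)
#' distribution is returned unchanged. Queries outside the grid raise an
#' error (no extrapolation).
#'
#' @param table a `pathlength_table` from [run_mc_grid()].
#' @param t_epi epidermis thickness, mm.
#' @param musp reduced scattering coefficient, mm^-1.
#' @return object of class `pathlength_dist`: list with the joint probability
#'   array `w` (summing to 1), per-layer representative path lengths `reps`
#'   and bin `edges`.
#' @export
interpolate_pathlengths <- function(table, t_epi, musp) {
  gt <- table$grid_t_epi; gm <- table$grid_musp
  if (t_epi < min(gt) || t_epi > max(gt) || musp < min(gm) || musp > max(gm))
    stop(sprintf("query (t_epi=%.3g, musp=%.3g) outside the simulated grid",
                 t_epi, musp))
  i <- max(1L, min(length(gt) - 1L, findInterval(t_epi, gt)))
  j <- max(1L, min(length(gm) - 1L, findInterval(musp, gm)))
  fx <- (t_epi - gt[i]) / (gt[i + 1] - gt[i])
  fy <- (musp - gm[j]) / (gm[j + 1] - gm[j])
  norm_node <- function(a, b) {
    w <- table$counts[a, b, , , ]
    w / sum(w)
  }
  w <- (1 - fx) * (1 - fy) * norm_node(i, j) +
       fx * (1 - fy) * norm_node(i + 1, j) +
       (1 - fx) * fy * norm_node(i, j + 1) +
       fx * fy * norm_node(i + 1, j + 1)
  out <- list(w = w, reps = table$reps, edges = table$edges,
              t_epi = t_epi, musp = musp, absorbed = FALSE)
  class(out) <- "pathlength_dist"
  out
}

#' Apply Beer-Lambert absorption weighting to a path-length distribution
#'
#' Each joint path-length cell with per-layer paths (l1, l2, l3) is reweighted
#' by `exp(-mua_epi*l1 - mua_upper*l2 - mua_lower*l3)`. Relative weights are
#' retained (total weight becomes the detected fraction after absorption);
#' normalization is deferred to the Doppler composition.
#'
#' @param dist a `pathlength_dist` from [interpolate_pathlengths()].
#' @param mua_epi,mua_upper,mua_lower absorption coefficients, mm^-1.
#' @return the reweighted `pathlength_dist` (field `absorbed = TRUE`).
#' @export
apply_absorption <- function(dist, mua_epi, mua_upper, mua_lower) {
  mua <- c(mua_epi, mua_upper, mua_lower)
  if (any(!is.finite(mua)) || any(mua < 0)) stop("mua must be finite and >= 0")
  a1 <- exp(-mua[1] * dist$reps[[1]])
  a2 <- exp(-mua[2] * dist$reps[[2]])
  a3 <- exp(-mua[3] * dist$reps[[3]])
  nb <- dim(dist$w)
  w <- dist$w * a1                                   # recycles along dim 1
  w <- w * rep(a2, each = nb[1])                     # dim 2
  w <- w * rep(a3, each = nb[1] * nb[2])             # dim 3
  dist$w <- w
  dist$absorbed <- TRUE
  dist
}

#' Sampling-volume weights of the three layers
#'
#' Fraction of total (absorption-weighted) detected photon path length spent
#' in each layer; used to weight per-layer perfusion so the true perfusion
#' reflects the sampling volume.
#'
#' @param dist a `pathlength_dist` (typically after [apply_absorption()]).
#' @return length-3 numeric summing to 1 (epidermis, upper dermis, lower
#'   dermis).
#' @export
sampling_volume_weights <- function(dist) {
  nb <- dim(dist$w)
  m <- numeric(3)
  m[1] <- sum(rowSums(dist$w) * dist$reps[[1]])
  m[2] <- sum(apply(dist$w, 2, sum) * dist$reps[[2]])
  m[3] <- sum(apply(dist$w, 3, sum) * dist$reps[[3]])
  m / sum(m)
}

#' Dermis absorption coefficient with the vessel packaging effect
#'
#' Blood confined to discrete vessels absorbs less than the same amount of
#' homogeneously distributed blood because highly absorbing vessel cores
#' self-shield. The cylindrical packaging factor
#' \deqn{C_{pack} = \frac{1 - e^{-2\mu_{a,blood} R}}{2 \mu_{a,blood} R}, \quad R = d/2}
#' multiplies the blood contribution:
#' \deqn{\mu_{a,dermis} = c_{blood} C_{pack} \mu_{a,blood}(S_{oxy}) + (1 - c_{blood}) \mu_{a,baseline}.}
#' Whole-blood absorption mixes the oxygenated and deoxygenated coefficients
#' at 780 nm linearly in the oxygen saturation.
#'
#' @param c_blood blood tissue fraction, % (0-100 scale).
#' @param s_oxy oxygen saturation, fraction in [0, 1].
#' @param d_vessels vessel diameter, mm.
#' @param optics optics configuration block (defaults from
#'   [speckperf_config()]).
#' @return absorption coefficient of the dermis layer, mm^-1.
#' @export
dermis_absorption <- function(c_blood, s_oxy, d_vessels,
                              optics = speckperf_config()$optics) {
  if (any(s_oxy < 0 | s_oxy > 1)) stop("s_oxy must be within [0, 1]")
  if (any(c_blood < 0)) stop("c_blood must be >= 0")
  if (any(d_vessels <= 0)) stop("d_vessels must be > 0")
  mua_blood <- s_oxy * optics$mua_blood_oxy + (1 - s_oxy) * optics$mua_blood_deoxy
  cf <- c_blood / 100
  x <- 2 * mua_blood * (d_vessels / 2)
  cpack <- ifelse(x < 1e-9, 1, (1 - exp(-x)) / x)
  cf * cpack * mua_blood + (1 - cf) * optics$mua_dermis_baseline
}
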