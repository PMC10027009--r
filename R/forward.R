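# Fast forward model: tissue model -> multi-exposure contrast ----------------
#
# Composition is carried out in the lag domain. Because the n-shift spectrum
# is the n-fold convolution of the single-shift spectrum, its Fourier
# transform is a(tau)^n, so
#   g1(tau) = sum_n P(n) a(tau)^n,
# where a(tau) is the speed-marginalized single-shift autocorrelation
# assembled from the precomputed kernel Abar(v_top * tau) (see shift_kernel).
# This avoids discretizing H(f) entirely and evaluates one tissue model in a
# few milliseconds, which is what makes 10^4..10^5-model training corpora
# practical. The histogram route (compose_doppler_histogram +
# autocorrelation_from_histogram) implements the same mathematics bin-wise
# and is used as a cross-check in the test suite.

forward_context <- function(table, config = speckperf_config()) {
  nodes <- contrast_nodes(config)
  T_s <- config$contrast$exposures_ms * 1e-3
  nn <- length(nodes$u)
  # pre-normalized node histograms as flat vectors (fast bilinear mixing)
  nt <- length(table$grid_t_epi); nm <- length(table$grid_musp)
  node_w <- vector("list", nt * nm)
  for (i in seq_len(nt)) for (j in seq_len(nm)) {
    w <- as.vector(table$counts[i, j, , , ])
    node_w[[i + nt * (j - 1)]] <- w / sum(w)
  }
  list(
    kern = shift_kernel(config),
    nodes = nodes,
    T_s = T_s,
    tau_all = as.vector(outer(nodes$u, T_s)),  # nn x n_exposures
    nn = nn,
    table = table,
    node_w = node_w,
    nt = nt,
    config = config,
    pld_cache = new.env(parent = emptyenv())
  )
}

# interpolated path-length distribution with a small memo (sweeps, restricted
# datasets and image fixtures reuse identical (t_epi, musp) pairs)
cached_pld <- function(ctx, t_epi, musp) {
  key <- paste0(signif(t_epi, 12), "_", signif(musp, 12))
  hit <- ctx$pld_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(ctx$pld_cache)) > 32) rm(list = ls(ctx$pld_cache), envir = ctx$pld_cache)
  gt <- ctx$table$grid_t_epi; gm <- ctx$table$grid_musp
  if (t_epi < min(gt) || t_epi > max(gt) || musp < min(gm) || musp > max(gm))
    stop(sprintf("query (t_epi=%.3g, musp=%.3g) outside the simulated grid",
                 t_epi, musp))
  i <- max(1L, min(length(gt) - 1L, findInterval(t_epi, gt)))
  j <- max(1L, min(length(gm) - 1L, findInterval(musp, gm)))
  fx <- (t_epi - gt[i]) / (gt[i + 1] - gt[i])
  fy <- (musp - gm[j]) / (gm[j + 1] - gm[j])
  nt <- ctx$nt
  w <- (1 - fx) * (1 - fy) * ctx$node_w[[i + nt * (j - 1)]] +
       fx * (1 - fy) * ctx$node_w[[i + 1 + nt * (j - 1)]] +
       (1 - fx) * fy * ctx$node_w[[i + nt * j]] +
       fx * fy * ctx$node_w[[i + 1 + nt * j]]
  nb <- vapply(ctx$table$reps, length, integer(1))
  dim(w) <- nb
  val <- structure(list(w = w, reps = ctx$table$reps, edges = ctx$table$edges,
                        t_epi = t_epi, musp = musp, absorbed = FALSE),
                   class = "pathlength_dist")
  ctx$pld_cache[[key]] <- val
  val
}

# Forward-evaluate one skin model. Returns noise-free contrast at the seven
# exposures, true speed-resolved perfusion weighted by the sampling volume,
# and diagnostics. BZ parameters are drawn unless supplied.
forward_one <- function(model, ctx, bz = TRUE, bz_params = NULL) {
  config <- ctx$config
  pld <- cached_pld(ctx, model$t_epi, model$musp)
  mua2 <- dermis_absorption(model$c_blood_upper, model$s_oxy_upper,
                            model$d_vessels_upper, config$optics)
  mua3 <- dermis_absorption(model$c_blood_lower, model$s_oxy_lower,
                            model$d_vessels_lower, config$optics)
  nb <- dim(pld$w)
  a1 <- exp(-model$mua_epi * pld$reps[[1]])
  a2 <- exp(-mua2 * pld$reps[[2]])
  a3 <- exp(-mua3 * pld$reps[[3]])
  w <- pld$w * a1
  w <- w * rep(a2, each = nb[1])
  w <- w * rep(a3, each = nb[1] * nb[2])

  flat <- matrix(w, nb[1], nb[2] * nb[3])
  rs1 <- rowSums(flat)
  W2 <- matrix(colSums(flat), nb[2], nb[3])
  l1 <- pld$reps[[1]]; l2 <- pld$reps[[2]]; l3 <- pld$reps[[3]]
  m <- c(sum(rs1 * l1), sum(rowSums(W2) * l2), sum(colSums(W2) * l3))
  samp_w <- m / sum(m)

  op <- config$optics
  rate2 <- 4 * (model$c_blood_upper / 100) / (pi * model$d_vessels_upper)
  rate3 <- 4 * (model$c_blood_lower / 100) / (pi * model$d_vessels_lower)
  mu2 <- op$mus_blood * pi * model$d_vessels_upper / 4
  mu3 <- op$mus_blood * pi * model$d_vessels_lower / 4
  p_n <- shift_count_joint(W2, l2, l3, rate2, mu2, rate3, mu3,
                           config$doppler$pgf_size)
  p_n <- truncate_shift_counts(p_n, config$doppler$n_tail_prob,
                               config$doppler$n_max_cap)

  # speed-marginalized single-shift autocorrelation on all quadrature lags
  sp <- model$speed
  Amat <- ctx$kern$Abar_at(outer(sp$top_speeds, ctx$tau_all))
  dim(Amat) <- c(length(sp$top_speeds), length(ctx$tau_all))
  a <- as.vector(crossprod(sp$weights, Amat))

  g1 <- rep(p_n[1], length(a))
  pow <- rep(1, length(a))
  for (n in seq_len(length(p_n) - 1)) {
    pow <- pow * a
    g1 <- g1 + p_n[n + 1] * pow
  }

  bzp <- NULL
  if (bz) {
    bzp <- if (is.null(bz_params)) bz_draw(config) else bz_params
    g1 <- (g1 + bzp$A * bzp$g1(ctx$tau_all)) / (1 + bzp$A)
  }

  g1sq <- matrix(g1^2, ctx$nn, length(ctx$T_s))
  K2 <- 2 * config$contrast$beta * as.vector(crossprod(ctx$nodes$w, g1sq))
  K <- sqrt(pmax(K2, 0))

  ptrue <- true_perfusion(model, samp_w)
  list(K = K, K2 = K2, ptrue = ptrue, sampling_weights = samp_w,
       p_zero_shift = p_n[1], mean_shifts = sum(seq_along(p_n[-1]) * p_n[-1]),
       bz = bzp)
}

#' Forward-model a tissue model to multi-exposure speckle contrast
#'
#' Runs the full physics chain for one tissue model: path-length
#' interpolation at its (epidermis thickness, reduced scattering),
#' Beer-Lambert absorption with vessel-packaged dermis absorption,
#' vessel-packaged compound-Poisson Doppler shift counts, lag-domain spectral
#' composition, optional biological zero, and the triangular-window contrast
#' integral at the seven canonical exposure times.
#'
#' @param model a `skin_model`.
#' @param table a `pathlength_table`.
#' @param config configuration list.
#' @param bz add the biological-zero component (random draw unless
#'   `bz_params` given).
#' @param bz_params optional list from `bz_draw()` fixing the BZ draw.
#' @return list with `contrast` (an [mexp_contrast()], noise-free),
#'   `perfusion` (a `speed_perfusion`), `sampling_weights`, `p_zero_shift`
#'   and `mean_shifts`.
#' @export
forward_contrast <- function(model, table, config = speckperf_config(),
                             bz = TRUE, bz_params = NULL) {
  ctx <- forward_context(table, config)
  res <- forward_one(model, ctx, bz = bz, bz_params = bz_params)
  list(contrast = mexp_contrast(res$K, config$contrast$exposures_ms),
       perfusion = res$ptrue,
       sampling_weights = res$sampling_weights,
       p_zero_shift = res$p_zero_shift,
       mean_shifts = res$mean_shifts)
}

#' Generate a synthetic multi-exposure contrast dataset
#'
#' Samples `n` randomized tissue models, forward-models each to noise-free
#' multi-exposure contrast, adds the biological-zero component (per-model
#' random draw) and, unless the dataset is restricted, measurement noise, and
#' records the true speed-resolved perfusion. Rows are assigned to
#' train/validation/test splits (or all to `"eval"`).
#'
#' @param n number of tissue models.
#' @param table a `pathlength_table`.
#' @param config configuration list.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param restricted restricted ablation (non-perfusion parameters at their
#'   medians, no contrast noise); default from the configuration.
#' @param split either `"pool"` (70/15/15 train/val/test) or `"eval"`.
#' @param noise add contrast noise (forced off for restricted datasets).
#' @param bz add the biological-zero component.
#' @return a `data.frame` of class `melsci_dataset`: tissue parameters,
#'   noise-free contrast `k_*`, noisy contrast `kn_*`, squared network inputs
#'   `k2_*`, perfusion targets `p_low/p_mid/p_high/p_total` and `split`.
#' @export
melsci_dataset <- function(n, table, config = speckperf_config(), seed = 1L,
                           restricted = NULL, split = c("pool", "eval"),
                           noise = TRUE, bz = TRUE) {
  split <- match.arg(split)
  tm <- config$tissue_model
  if (is.null(restricted)) restricted <- isTRUE(tm$restricted)
  if (restricted) noise <- FALSE
  set.seed(seed)
  ctx <- forward_context(table, config)

  K <- matrix(0, n, length(config$contrast$exposures_ms))
  P <- matrix(0, n, 4)
  pars <- matrix(0, n, 12)
  for (i in seq_len(n)) {
    mod <- sample_tissue_model(config, restricted = restricted)
    res <- forward_one(mod, ctx, bz = bz)
    K[i, ] <- res$K
    P[i, ] <- unclass(res$ptrue)
    pars[i, ] <- c(mod$t_epi, mod$mua_epi, mod$musp,
                   mod$c_blood_upper, mod$c_blood_lower,
                   mod$s_oxy_upper, mod$s_oxy_lower,
                   mod$d_vessels_upper, mod$d_vessels_lower,
                   mod$speed$mean_speed, res$p_zero_shift, res$mean_shifts)
  }
  Kn <- if (noise) add_contrast_noise(K, config) else K

  df <- as.data.frame(pars)
  names(df) <- c("t_epi", "mua_epi", "musp", "c_blood_upper", "c_blood_lower",
                 "s_oxy_upper", "s_oxy_lower", "d_vessels_upper",
                 "d_vessels_lower", "mean_speed", "p_zero_shift", "mean_shifts")
  ne <- ncol(K)
  df[paste0("k_", seq_len(ne))] <- K
  df[paste0("kn_", seq_len(ne))] <- Kn
  df[paste0("k2_", seq_len(ne))] <- Kn^2
  df$p_low <- P[, 1]; df$p_mid <- P[, 2]; df$p_high <- P[, 3]; df$p_total <- P[, 4]

  if (split == "pool") {
    fr <- config$dataset$split
    lab <- rep(c("train", "val", "test"),
               times = c(round(fr[1] * n), round(fr[2] * n), 0))
    lab <- c(lab, rep("test", n - length(lab)))
    df$split <- sample(lab)
  } else {
    df$split <- "eval"
  }
  attr(df, "restricted") <- restricted
  attr(df, "seed") <- seed
  attr(df, "noise") <- noise
  class(df) <- c("melsci_dataset", "data.frame")
  df
}

#' Extract the network input matrix / target matrix from a dataset
#'
#' @param data a `melsci_dataset` (or compatible data.frame).
#' @rdname melsci_dataset_access
#' @return `dataset_inputs`: n x 7 matrix of squared contrast;
#'   `dataset_targets`: n x 3 matrix of speed-resolved perfusion.
#' @export
dataset_inputs <- function(data) {
  as.matrix(data[paste0("k2_", 1:7)])
}

#' @rdname melsci_dataset_access
#' @export
dataset_targets <- function(data) {
  as.matrix(data[c("p_low", "p_mid", "p_high")])
}
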