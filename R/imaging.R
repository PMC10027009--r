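# Per-pixel imaging -----------------------------------------------------------

#' Multi-exposure contrast image stack container
#'
#' @param contrast array height x width x 7 (or frames x H x W x 7 with a
#'   time dimension) of contrast values.
#' @param exposures_ms exposure labels; must be the seven canonical values.
#' @param intensity optional mean-intensity image.
#' @param meta optional metadata list (seed, scene configuration, ...).
#' @return object of class `contrast_stack`.
#' @export
contrast_stack <- function(contrast, exposures_ms = c(1, 2, 4, 8, 16, 32, 64),
                           intensity = NULL, meta = list()) {
  d <- dim(contrast)
  if (!(length(d) %in% c(3, 4)) || d[length(d)] != length(exposures_ms))
    stop("contrast must be H x W x 7 or T x H x W x 7")
  if (!identical(as.numeric(exposures_ms), c(1, 2, 4, 8, 16, 32, 64)))
    stop("exposure labels must be 1,2,4,8,16,32,64 ms")
  if (any(contrast <= 0) || any(contrast > 1.5))
    stop("contrast values must lie in (0, 1.5]")
  out <- list(contrast = contrast, exposures_ms = as.numeric(exposures_ms),
              intensity = intensity, meta = meta)
  class(out) <- "contrast_stack"
  out
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$contrast)
  if (length(d) == 3)
    cat(sprintf("Contrast image stack: %d x %d pixels, 7 exposures\n", d[1], d[2]))
  else
    cat(sprintf("Contrast image stack: %d frames, %d x %d pixels, 7 exposures\n",
                d[1], d[2], d[3]))
  invisible(x)
}

#' Read/write image containers
#'
#' Containers are persisted with base R serialization (lossless round trip).
#' `write_stack_tiff` additionally exports a 32-bit float multi-channel TIFF
#' (requires the `tiff` package).
#'
#' @param x a `contrast_stack` or `perfusion_image`.
#' @param path file path.
#' @rdname stack_io
#' @export
write_image_container <- function(x, path) {
  stopifnot(inherits(x, "contrast_stack") || inherits(x, "perfusion_image"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_image_container <- function(path) {
  readRDS(path)
}

#' @rdname stack_io
#' @export
write_stack_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  stopifnot(inherits(x, "contrast_stack"), length(dim(x$contrast)) == 3)
  tiff::writeTIFF(lapply(1:7, function(j) x$contrast[, , j]), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Per-pixel perfusion inference on a contrast image stack
#'
#' Applies the trained network to each pixel's squared multi-exposure
#' contrast vector (vectorized over the frame; pixels are independent, no
#' spatial coupling). Negative network outputs are retained here; clamping
#' happens only at rendering.
#'
#' @param model a `perfann`.
#' @param stack a `contrast_stack` (single frame, H x W x 7).
#' @return object of class `perfusion_image`: list of H x W maps `p_low`,
#'   `p_mid`, `p_high`, `p_total` in %RBC x mm/s.
#' @export
predict_image <- function(model, stack) {
  stopifnot(inherits(stack, "contrast_stack"))
  d <- dim(stack$contrast)
  if (length(d) != 3) stop("predict_image expects a single frame (H x W x 7)")
  if (d[3] != 7) stop("format error: expected 7 contrast channels")
  x <- matrix(stack$contrast, d[1] * d[2], 7)^2
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(model, x)
  dt <- proc.time()[["elapsed"]] - t0
  out <- list(p_low = matrix(pred[, 1], d[1], d[2]),
              p_mid = matrix(pred[, 2], d[1], d[2]),
              p_high = matrix(pred[, 3], d[1], d[2]),
              p_total = matrix(pred[, 4], d[1], d[2]),
              elapsed_s = dt)
  class(out) <- "perfusion_image"
  out
}

#' @export
print.perfusion_image <- function(x, ...) {
  cat(sprintf("Perfusion image %d x %d; median total %.3f %%RBC mm/s (%.1f ms/frame)\n",
              nrow(x$p_total), ncol(x$p_total), median(x$p_total),
              1e3 * x$elapsed_s))
  invisible(x)
}

#' @export
plot.perfusion_image <- function(x, component = "p_total", mask = NULL, ...) {
  img <- pmax(x[[component]], 0)
  rng <- color_scale(x, if (is.null(mask)) matrix(TRUE, nrow(img), ncol(img)) else mask,
                     component = component)
  graphics::image(t(img[nrow(img):1, ]), zlim = rng, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "inferno"), axes = FALSE, ...)
  invisible(x)
}

#' Synthesize a multi-exposure contrast image fixture
#'
#' Builds a synthetic scene (a stand-in for the instrument): the frame is
#' partitioned into labeled regions, each assigned a tissue model; every
#' pixel of a region receives that model's forward-modeled contrast plus
#' independent per-pixel measurement noise. Ground-truth perfusion maps come
#' from the tissue models. Optional temporal phases rescale each region's
#' blood fraction and mean speed over time (e.g. baseline / occlusion /
#' reperfusion trajectories).
#'
#' @param scene list with `labels` (integer H x W matrix, regions numbered
#'   1..R covering the frame) and `regions`: a list per region with either a
#'   `model` (a `skin_model`) or `c_blood` / `mean_speed` multipliers applied
#'   to a sampled base model.
#' @param table a `pathlength_table`.
#' @param config configuration list.
#' @param seed integer seed.
#' @param noise add per-pixel contrast noise.
#' @param phases optional list of lists with `frames`, `c_scale`,
#'   `speed_scale` (per-region vectors or scalars); produces a time series.
#' @return list with `stack` (a `contrast_stack` or list of them per phase),
#'   `truth` (ground-truth `perfusion_image`), `models` (per-region models).
#' @export
synth_image_fixture <- function(scene, table, config = speckperf_config(),
                                seed = 1L, noise = TRUE, phases = NULL) {
  set.seed(seed)
  labels <- scene$labels
  nr <- length(scene$regions)
  if (!all(sort(unique(as.vector(labels))) == seq_len(nr)))
    stop("scene regions must cover the frame with labels 1..R")
  ctx <- forward_context(table, config)

  models <- lapply(seq_len(nr), function(r) {
    reg <- scene$regions[[r]]
    if (!is.null(reg$model)) return(reg$model)
    mod <- sample_tissue_model(config)
    if (!is.null(reg$c_blood)) {
      mod$c_blood_upper <- reg$c_blood
      mod$c_blood_lower <- reg$c_blood
    }
    if (!is.null(reg$mean_speed))
      mod$speed <- scale_mean_speed(mod$speed, reg$mean_speed)
    mod
  })

  render_frame <- function(mods) {
    K <- lapply(mods, function(m) forward_one(m, ctx, bz = TRUE)$K)
    P <- lapply(mods, function(m) {
      res <- forward_one(m, ctx, bz = FALSE)
      unclass(res$ptrue)
    })
    H <- nrow(labels); W <- ncol(labels)
    arr <- array(0, c(H, W, 7))
    truth <- list(p_low = matrix(0, H, W), p_mid = matrix(0, H, W),
                  p_high = matrix(0, H, W), p_total = matrix(0, H, W))
    for (r in seq_along(mods)) {
      px <- labels == r
      for (j in 1:7) {
        ch <- arr[, , j]; ch[px] <- K[[r]][j]; arr[, , j] <- ch
      }
      truth$p_low[px] <- P[[r]][1]; truth$p_mid[px] <- P[[r]][2]
      truth$p_high[px] <- P[[r]][3]; truth$p_total[px] <- P[[r]][4]
    }
    if (noise) {
      flat <- matrix(arr, H * W, 7)
      flat <- add_contrast_noise(flat, config)
      arr <- array(pmin(flat, 1.5), c(H, W, 7))
    }
    class(truth) <- "perfusion_image"
    truth$elapsed_s <- 0
    list(stack = contrast_stack(arr, meta = list(seed = seed)), truth = truth)
  }

  if (is.null(phases)) {
    fr <- render_frame(models)
    return(list(stack = fr$stack, truth = fr$truth, models = models))
  }
  out <- lapply(phases, function(ph) {
    mods <- lapply(seq_len(nr), function(r) {
      m <- models[[r]]
      cs <- if (length(ph$c_scale) >= r) ph$c_scale[r] else ph$c_scale[1]
      ss <- if (length(ph$speed_scale) >= r) ph$speed_scale[r] else ph$speed_scale[1]
      m$c_blood_upper <- m$c_blood_upper * cs
      m$c_blood_lower <- m$c_blood_lower * cs
      m$speed <- scale_mean_speed(m$speed, m$speed$mean_speed * ss)
      m
    })
    fr <- render_frame(mods)
    fr$frames <- ph$frames
    fr
  })
  list(phases = out, models = models)
}

# rescale a speed distribution to a target mean speed (scales the top speeds;
# the forward model handles arbitrary tops continuously)
scale_mean_speed <- function(sp, target_mean) {
  s <- target_mean / sp$mean_speed
  build_speed_distribution(sp$weights, sp$c_blood, top_speeds = sp$top_speeds * s)
}

#' ROI statistics of a perfusion image
#'
#' Mean, standard deviation and coefficient of variation (CV = 100 SD/mean)
#' per perfusion component within a mask. The sample SD convention (divide by
#' N - 1) is the default; set `population = TRUE` to divide by N.
#'
#' @param image a `perfusion_image`.
#' @param mask logical H x W matrix, nonempty.
#' @param population use population SD (divide by N) rather than sample SD.
#' @return data.frame with rows per component and columns `mean`, `sd`, `cv`.
#' @export
roi_stats <- function(image, mask, population = FALSE) {
  stopifnot(inherits(image, "perfusion_image"))
  if (!any(mask)) stop("mask is empty")
  comp <- c("p_low", "p_mid", "p_high", "p_total")
  rows <- lapply(comp, function(cp) {
    v <- image[[cp]][mask]
    m <- mean(v)
    s <- if (population) sqrt(mean((v - m)^2)) else sd(v)
    if (m == 0) stop("undefined CV: zero mean in ROI for ", cp)
    data.frame(component = cp, mean = m, sd = s, cv = 100 * s / m)
  })
  do.call(rbind, rows)
}

#' Display range for perfusion image rendering
#'
#' The color scale of each image is set to `factor` times the mean value in
#' the reference region (factor 3 by default); falls back to the whole-image
#' mean for an empty mask.
#'
#' @param image a `perfusion_image`.
#' @param mask logical matrix.
#' @param factor scale factor.
#' @param component which map.
#' @return numeric `c(0, factor * mean)`.
#' @export
color_scale <- function(image, mask, factor = 3, component = "p_total") {
  img <- pmax(image[[component]], 0)
  m <- if (any(mask)) mean(img[mask]) else mean(img)
  c(0, factor * m)
}

#' Centered moving-average smoothing of a time series
#'
#' @param series numeric vector, uniformly sampled.
#' @param window window length in seconds.
#' @param fs sampling frequency, Hz.
#' @return smoothed series (edges use the truncated window).
#' @export
temporal_smooth <- function(series, window, fs) {
  k <- max(1L, round(window * fs))
  if (k == 1) return(series)
  n <- length(series)
  half <- (k - 1) %/% 2
  half_up <- k - 1 - half
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half_up)
    mean(series[lo:hi])
  }, numeric(1))
}
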