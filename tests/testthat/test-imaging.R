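make_stack <- function(H = 6, W = 5, seed = 61) {
  set.seed(seed)
  arr <- array(runif(H * W * 7, 0.3, 0.9), c(H, W, 7))
  contrast_stack(arr)
}

make_net <- function() {
  set.seed(62)
  structure(list(
    W1 = matrix(rnorm(175, sd = 0.3), 7, 25), b1 = rnorm(25, sd = 0.1),
    W2 = matrix(rnorm(75, sd = 0.3), 25, 3), b2 = c(0.1, 0.2, 0.3),
    input_mean = rep(0.4, 7), input_sd = rep(0.15, 7),
    config = speckperf_config()$ann), class = "perfann")
}

test_that("contrast stacks validate their format", {
  expect_error(contrast_stack(array(0.5, c(4, 4, 6))), "H x W x 7")
  expect_error(contrast_stack(array(0.5, c(4, 4, 7)), exposures_ms = 1:7),
               "exposure labels")
  expect_error(contrast_stack(array(2, c(4, 4, 7))), "contrast values")
  s <- make_stack()
  expect_s3_class(s, "contrast_stack")
})

test_that("image containers round-trip losslessly", {
  s <- make_stack()
  f <- tempfile()
  write_image_container(s, f)
  s2 <- read_image_container(f)
  expect_identical(s$contrast, s2$contrast)
  unlink(f)
})

test_that("per-pixel inference equals a looped per-pixel oracle and is permutation-equivariant", {
  s <- make_stack()
  net <- make_net()
  img <- predict_image(net, s)
  d <- dim(s$contrast)
  for (px in list(c(1, 1), c(3, 4), c(6, 5))) {
    ref <- predict(net, matrix(s$contrast[px[1], px[2], ]^2, 1))
    expect_equal(c(img$p_low[px[1], px[2]], img$p_mid[px[1], px[2]],
                   img$p_high[px[1], px[2]], img$p_total[px[1], px[2]]),
                 unname(ref[1, ]), tolerance = 1e-12)
  }
  expect_equal(img$p_total, img$p_low + img$p_mid + img$p_high, tolerance = 1e-12)
  # permuting pixel positions permutes outputs identically
  perm <- sample(d[1])
  s2 <- contrast_stack(s$contrast[perm, , ])
  img2 <- predict_image(net, s2)
  expect_equal(img2$p_total, img$p_total[perm, ], tolerance = 1e-12)
  # constant stack gives constant maps
  sc <- contrast_stack(array(0.6, c(4, 4, 7)))
  imgc <- predict_image(net, sc)
  expect_equal(max(imgc$p_total) - min(imgc$p_total), 0)
  expect_error(predict_image(net, list()), "contrast_stack")
})

test_that("ROI statistics implement the sample-SD CV convention", {
  img <- structure(list(p_low = matrix(1, 2, 2), p_mid = matrix(1, 2, 2),
                        p_high = matrix(1, 2, 2),
                        p_total = matrix(c(1, 3, 1, 3), 2, 2)),
                   class = "perfusion_image")
  mask <- matrix(TRUE, 2, 2)
  st <- roi_stats(img, mask)
  expect_equal(st$cv[st$component == "p_low"], 0)
  # two pixels 1 and 3: mean 2, SD sqrt(2) (divide by N - 1), CV 70.7%
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st2 <- roi_stats(img, mask2)
  tot <- st2[st2$component == "p_total", ]
  expect_equal(tot$mean, 2)
  expect_equal(tot$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(tot$cv, 70.71068, tolerance = 1e-4)
  # CV invariant to positive rescaling
  img2 <- img; img2$p_total <- 13 * img$p_total
  expect_equal(roi_stats(img2, mask2)$cv, st2$cv, tolerance = 1e-12)
  expect_error(roi_stats(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("color scale is factor x ROI mean with whole-image fallback", {
  img <- structure(list(p_total = matrix(c(0.5, 0.5, 2, 2), 2, 2)),
                   class = "perfusion_image")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(color_scale(img, mask), c(0, 1.5))
  expect_equal(color_scale(img, mask, factor = 2), c(0, 1))
  expect_equal(color_scale(img, matrix(FALSE, 2, 2)), c(0, 3 * 1.25))
})

test_that("temporal smoothing is a centered truncated-window mean", {
  x <- rep(2, 20)
  expect_equal(temporal_smooth(x, 0.5, 16), x)
  expect_equal(temporal_smooth(1:10, 0.06, 16), 1:10)  # window = 1 sample
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  sm <- temporal_smooth(imp, 3, 1)  # 3-sample window
  expect_equal(sm, c(0, 0, 1/3, 1/3, 1/3, 0, 0))
})

test_that("synthetic two-region fixtures order contrast and truth correctly", {
  tab <- fx_table_small()
  cfg <- speckperf_config()
  labels <- matrix(1L, 10, 10); labels[, 6:10] <- 2L
  m_slow <- fx_model(c_blood = 0.55, mean_speed = 0.5)
  m_fast <- fx_model(c_blood = 0.55, mean_speed = 50)
  scene <- list(labels = labels,
                regions = list(list(model = m_slow), list(model = m_fast)))
  fx <- synth_image_fixture(scene, tab, cfg, seed = 63, noise = FALSE)
  # fast region: higher p_high in truth, lower 64 ms contrast
  expect_gt(median(fx$truth$p_high[labels == 2]),
            median(fx$truth$p_high[labels == 1]))
  expect_lt(median(fx$stack$contrast[, , 7][labels == 2]),
            median(fx$stack$contrast[, , 7][labels == 1]))
  # zero-noise rendering is reproducible
  fx2 <- synth_image_fixture(scene, tab, cfg, seed = 63, noise = FALSE)
  expect_identical(fx$stack$contrast, fx2$stack$contrast)
  expect_error(synth_image_fixture(list(labels = matrix(3L, 2, 2),
                                        regions = list(list())),
                                   tab, cfg), "cover")
})

test_that("occlusion-like phases make the low-speed band dominant", {
  tab <- fx_table_small()
  cfg <- speckperf_config()
  labels <- matrix(1L, 6, 6)
  scene <- list(labels = labels,
                regions = list(list(c_blood = 0.55, mean_speed = 1.5)))
  fx <- synth_image_fixture(scene, tab, cfg, seed = 64, noise = FALSE,
                            phases = list(
                              list(frames = 2, c_scale = 1, speed_scale = 1),
                              list(frames = 2, c_scale = 1, speed_scale = 0.05)))
  occl <- fx$phases[[2]]$truth
  expect_gt(occl$p_low[1, 1], occl$p_mid[1, 1])
  expect_gt(occl$p_low[1, 1], occl$p_high[1, 1])
})

test_that("the command-line interface prints usage", {
  cli <- system.file("cli", "speckperf", package = "speckperf")
  expect_true(nzchar(cli))
  res <- suppressWarnings(system2("Rscript", cli, stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  expect_true(any(grepl("usage:", res)))
})
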