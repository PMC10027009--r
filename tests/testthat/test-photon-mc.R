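cfg <- speckperf_config()

test_that("photon weight is conserved and runs are seed-reproducible", {
  edges <- lapply(1:3, function(i) c(0, 10^seq(-2, log10(400), length.out = 20)))
  run <- function() speckperf:::mc_layer_slab(0.2, 0.2, 1.6, 20000L, 1.4, 0,
                                              edges[[1]], edges[[2]], edges[[3]],
                                              40, 400)
  set.seed(11); r1 <- run()
  expect_equal(r1$n_detected + r1$n_deep + r1$n_killed, 20000, tolerance = 1e-9)
  set.seed(11); r2 <- run()
  expect_identical(r1$counts, r2$counts)
})

test_that("thick epidermis leaves essentially no dermis path length", {
  edges <- lapply(1:3, function(i) c(0, 10^seq(-2, log10(400), length.out = 20)))
  set.seed(12)
  r <- speckperf:::mc_layer_slab(30, 0.2, 1.6, 5000L, 1.4, 0,
                                 edges[[1]], edges[[2]], edges[[3]], 40, 400)
  expect_lt(r$mean_l[2] + r$mean_l[3], 1e-3)
  expect_gt(r$n_detected, 0)
})

test_that("path lengths rescale exactly under the scattering similarity relation", {
  # doubling musp with all geometry in transport-mean-free-path units halves
  # every path: with a common seed the walks are identical up to scale
  e1 <- lapply(1:3, function(i) c(0, 10^seq(-2, log10(400), length.out = 24)))
  e2 <- lapply(e1, function(e) e / 2)
  set.seed(13)
  r1 <- speckperf:::mc_layer_slab(0.2, 0.2, 1.6, 10000L, 1.4, 0,
                                  e1[[1]], e1[[2]], e1[[3]], 40, 400)
  set.seed(13)
  r2 <- speckperf:::mc_layer_slab(0.1, 0.1, 3.2, 10000L, 1.4, 0,
                                  e2[[1]], e2[[2]], e2[[3]], 20, 200)
  expect_identical(r1$counts, r2$counts)
  expect_equal(r1$mean_l, 2 * r2$mean_l, tolerance = 1e-12)
})

test_that("mean detected path length decreases with increasing scattering", {
  tab <- fx_table_small()
  mean_path <- vapply(seq_along(tab$grid_musp), function(j) {
    w <- tab$counts[3, j, , , ]
    nb <- dim(w)
    flat <- matrix(w, nb[1], nb[2] * nb[3])
    W2 <- matrix(colSums(flat), nb[2], nb[3])
    (sum(rowSums(flat) * tab$reps[[1]]) + sum(rowSums(W2) * tab$reps[[2]]) +
       sum(colSums(W2) * tab$reps[[3]])) / sum(w)
  }, numeric(1))
  expect_true(all(diff(mean_path) < 0))
})

test_that("interpolation returns stored distributions at nodes and averages between", {
  tab <- fx_table_small()
  d_node <- interpolate_pathlengths(tab, tab$grid_t_epi[2], tab$grid_musp[3])
  w_ref <- tab$counts[2, 3, , , ]
  expect_equal(d_node$w, w_ref / sum(w_ref), tolerance = 1e-12)
  expect_equal(sum(d_node$w), 1, tolerance = 1e-12)
  tmid <- (tab$grid_t_epi[2] + tab$grid_t_epi[3]) / 2
  d_mid <- interpolate_pathlengths(tab, tmid, tab$grid_musp[3])
  w3 <- tab$counts[3, 3, , , ]
  expect_equal(d_mid$w, 0.5 * w_ref / sum(w_ref) + 0.5 * w3 / sum(w3),
               tolerance = 1e-12)
  expect_error(interpolate_pathlengths(tab, 2.0, 1.6), "outside")
  expect_error(interpolate_pathlengths(tab, 0.2, 5.5), "outside")
})

test_that("Beer-Lambert weighting reproduces the analytic cell factor", {
  tab <- fx_table_small()
  d <- interpolate_pathlengths(tab, 0.2, 1.6)
  d0 <- apply_absorption(d, 0, 0, 0)
  expect_equal(d0$w, d$w, tolerance = 1e-15)
  # single cell: weight factor exp(-0.1*0.5 - 0.2*1.0 - 0.3*2.0) = exp(-0.85)
  i <- findInterval(0.5, d$edges[[1]]); j <- findInterval(1.0, d$edges[[2]])
  k <- findInterval(2.0, d$edges[[3]])
  da <- apply_absorption(d, 0.1, 0.2, 0.3)
  fac <- da$w[i, j, k] / d$w[i, j, k]
  expect_equal(fac, exp(-0.1 * d$reps[[1]][i] - 0.2 * d$reps[[2]][j] -
                          0.3 * d$reps[[3]][k]), tolerance = 1e-12)
  expect_equal(exp(-0.1 * 0.5 - 0.2 * 1.0 - 0.3 * 2.0), 0.4274, tolerance = 1e-4)
  # infinite epidermis absorption removes all weight
  dInf <- apply_absorption(d, 1e6, 0, 0)
  expect_lt(sum(dInf$w), 1e-10)
  expect_error(apply_absorption(d, -0.1, 0, 0), "mua")
})

test_that("sampling-volume weights are a valid composition", {
  tab <- fx_table_small()
  d <- apply_absorption(interpolate_pathlengths(tab, 0.2, 1.6), 0.25, 0.03, 0.03)
  w <- sampling_volume_weights(d)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  # thicker epidermis shifts weight into the epidermis
  d2 <- apply_absorption(interpolate_pathlengths(tab, 0.7, 1.6), 0.25, 0.03, 0.03)
  expect_gt(sampling_volume_weights(d2)[1], w[1])
})

test_that("dermis absorption follows the vessel-packaging model", {
  op <- cfg$optics
  expect_equal(dermis_absorption(0, 0.5, 0.05), op$mua_dermis_baseline)
  # homogeneous limit: packaging factor -> 1 as d -> 0
  mua_b <- 0.5 * op$mua_blood_oxy + 0.5 * op$mua_blood_deoxy
  expect_equal(dermis_absorption(100, 0.5, 1e-9), mua_b, tolerance = 1e-6)
  # packaging factor strictly decreasing in vessel diameter
  ds <- 10^seq(-3, -0.3, length.out = 20)
  mua <- dermis_absorption(1, 0.5, ds)
  expect_true(all(diff(mua) < 0))
  expect_error(dermis_absorption(1, 1.5, 0.05), "s_oxy")
  expect_error(dermis_absorption(1, 0.5, 0), "d_vessels")
})

test_that("MC diffuse reflectance matches diffusion theory at high albedo", {
  # semi-infinite medium: Farrell dipole model, total reflectance
  # R = a'/2 [exp(-mueff z0) + exp(-mueff (z0 + 2 zb))]
  musp <- 1.6
  edges <- lapply(1:3, function(i) c(0, 10^seq(-2.3, log10(3000), length.out = 64)))
  set.seed(14)
  r <- speckperf:::mc_layer_slab(0.2, 0.2, musp, 40000L, 1.4, 0,
                                 edges[[1]], edges[[2]], edges[[3]], 300, 3000)
  reps <- lapply(edges, function(e) {
    rp <- sqrt(e[-length(e)] * e[-1]); rp[1] <- 0; rp
  })
  nb <- dim(r$counts)
  for (mua in c(0.016, 0.008)) {   # musp/mua >= 100
    w <- r$counts * exp(-mua * reps[[1]])
    w <- w * rep(exp(-mua * reps[[2]]), each = nb[1])
    w <- w * rep(exp(-mua * reps[[3]]), each = nb[1] * nb[2])
    R_mc <- sum(w) / 40000
    mutp <- mua + musp; z0 <- 1 / mutp; D <- 1 / (3 * mutp)
    mueff <- sqrt(mua / D)
    nrel <- 1.4
    rd <- -1.440 / nrel^2 + 0.710 / nrel + 0.668 + 0.0636 * nrel
    A <- (1 + rd) / (1 - rd)
    zb <- 2 * A * D
    R_th <- (musp / mutp) / 2 * (exp(-mueff * z0) + exp(-mueff * (z0 + 2 * zb)))
    expect_lt(abs(R_mc - R_th) / R_th, 0.10)
  }
})

test_that("grid runner validates its configuration", {
  bad <- speckperf_config()
  bad$mc$grid_t_epi <- c(0.1, 0.3)   # does not cover the t_epi support
  expect_error(run_mc_grid(bad, seed = 1), "does not cover")
  bad2 <- speckperf_config()
  bad2$mc$n_photons <- 100
  expect_error(run_mc_grid(bad2, seed = 1), "n_photons")
})

test_that("path-length tables round-trip through their container", {
  tab <- fx_table_small()
  f <- tempfile(fileext = ".rds")
  write_pathlength_table(tab, f)
  tab2 <- read_pathlength_table(f)
  expect_identical(tab$counts, tab2$counts)
  expect_identical(tab$edges, tab2$edges)
  unlink(f)
})
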