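dcfg <- fx_doppler_config()

test_that("Gegenbauer anisotropy matches known values", {
  expect_equal(gegenbauer_anisotropy(0.948, 1.0), 0.991, tolerance = 1e-3)
  # alpha = 0.5 reduces to Henyey-Greenstein, anisotropy = g
  for (g in c(0.3, 0.7, 0.948))
    expect_equal(gegenbauer_anisotropy(g, 0.5), g, tolerance = 1e-6)
  # isotropic limit
  expect_lt(gegenbauer_anisotropy(1e-4, 1.0), 1e-3)
  expect_error(gegenbauer_anisotropy(1.2, 1.0), "gGk")
  expect_error(gegenbauer_anisotropy(0.9, -0.6), "alphaGk")
})

test_that("phase-function density normalizes and matches node sampling", {
  norm <- integrate(function(mu) gk_phase_density(mu, 0.948, 1.0), -1, 1,
                    rel.tol = 1e-9, subdivisions = 2000L)$value
  expect_equal(norm, 1, tolerance = 1e-6)
  mom <- integrate(function(mu) mu * gk_phase_density(mu, 0.948, 1.0), -1, 1,
                   rel.tol = 1e-9, subdivisions = 2000L)$value
  nodes <- speckperf:::gk_nodes(0.948, 1.0, 50000)
  expect_equal(mean(nodes$cos_theta), mom, tolerance = 1e-4)
})

test_that("single-shift histogram is a valid spectrum with the analytic ceiling", {
  h0 <- single_shift_histogram(0, dcfg)
  expect_equal(h0$mass[1], 1)
  h <- single_shift_histogram(2, dcfg)
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  fmax_v <- 2 * dcfg$optics$n_tissue * 2 / dcfg$optics$lambda_mm
  expect_equal(sum(h$mass[h$freq > fmax_v]), 0)
  expect_error(single_shift_histogram(100, dcfg), "grid overflow")
})

test_that("single-shift histogram agrees with Monte Carlo sampling of (theta, psi)", {
  h <- single_shift_histogram(2, dcfg)
  nodes <- speckperf:::gk_nodes(dcfg$optics$gk_g, dcfg$optics$gk_alpha, 4000)
  set.seed(21)
  n <- 1e6
  sh <- nodes$sin_half[sample.int(length(nodes$sin_half), n, replace = TRUE)]
  f <- abs((2 * dcfg$optics$n_tissue * 2 / dcfg$optics$lambda_mm) * sh *
             runif(n, -1, 1))
  bin <- pmin(pmax(round(f / h$df), 0), length(h$mass) - 1) + 1
  p_mc <- tabulate(bin, length(h$mass)) / n
  se <- sqrt(h$mass * (1 - h$mass) / n)   # SE from the expected mass
  sel <- h$mass > 1e-5
  frac_bad <- mean((abs(h$mass - p_mc) / (3 * pmax(se, 1e-9)))[sel] > 1)
  expect_lt(frac_bad, 0.015)
  expect_lt(max(abs(h$mass - p_mc)[sel]), 1e-3)
})

test_that("uniform-speed marginal equals the average of fixed-speed spectra", {
  hu <- uniform_speed_shift_histogram(2, dcfg)
  expect_equal(sum(hu$mass), 1, tolerance = 1e-9)
  vs <- seq(0.005, 2, by = 0.005)
  havg <- Reduce(`+`, lapply(vs, function(v) single_shift_histogram(v, dcfg)$mass)) /
    length(vs)
  expect_lt(max(abs(hu$mass - havg)[-1]), 2e-3)
})

test_that("n-fold composition reproduces exhaustive convolution of a two-point spectrum", {
  # single spectrum {+-f0: 1/2 each}; two shifts: {0: 1/2, 2 f0: 1/2} one-sided
  h <- single_shift_histogram(0, dcfg)
  j0 <- 101
  h$mass <- numeric(length(h$mass)); h$mass[j0] <- 1
  h2 <- n_shift_histogram(h, 2)
  expect_equal(h2$mass[1], 0.5, tolerance = 1e-9)
  expect_equal(h2$mass[2 * (j0 - 1) + 1], 0.5, tolerance = 1e-9)
  expect_equal(sum(h2$mass), 1, tolerance = 1e-9)
  expect_identical(n_shift_histogram(h, 1), h)
  expect_error(n_shift_histogram(h, 0), "positive integer")
})

test_that("n-fold composition preserves normalization and detects overflow", {
  h <- single_shift_histogram(1.5, dcfg)
  for (n in c(2, 5, 17)) {
    hn <- n_shift_histogram(h, n)
    expect_equal(sum(hn$mass), 1, tolerance = 1e-9)
  }
  hb <- single_shift_histogram(40, dcfg)   # support ~ f_max/1.4
  expect_error(n_shift_histogram(hb, 16), "grid overflow")
})

test_that("shift-count distribution has the required limits and dispersion", {
  p0 <- shift_count_distribution(c(1, 3), c(0.5, 0.5), 0, 0.05)
  expect_equal(p0$p[1], 1, tolerance = 1e-12)
  # homogeneous limit d -> 0: plain Poisson(l c/100 mus_blood)
  l <- 2; cb <- 0.5; mus_b <- 222
  pd <- shift_count_distribution(l, 1, cb, 1e-5, mus_b)
  pois <- dpois(pd$n, l * cb / 100 * mus_b)
  expect_lt(sum(abs(pd$p - pois)) / 2, 1e-3)
  # finite vessels over-disperse: variance/mean > 1
  pv <- shift_count_distribution(l, 1, cb, 0.1, mus_b)
  mu <- sum(pv$n * pv$p)
  v <- sum((pv$n - mu)^2 * pv$p)
  expect_gt(v / mu, 1.5)
  expect_equal(mu, l * cb / 100 * mus_b, tolerance = 1e-3)
  expect_error(shift_count_distribution(l, 1, -1, 0.1), "invalid")
})

test_that("joint shift counts match direct simulation of the compound process", {
  set.seed(22)
  l2 <- c(0.5, 2); l3 <- c(1, 4)
  W2 <- matrix(c(0.4, 0.2, 0.3, 0.1), 2, 2)
  rate2 <- 4 * 0.006 / (pi * 0.05); mu2 <- 222 * pi * 0.05 / 4
  rate3 <- 4 * 0.004 / (pi * 0.08); mu3 <- 222 * pi * 0.08 / 4
  p <- speckperf:::shift_count_joint(W2, l2, l3, rate2, mu2, rate3, mu3, 256)
  n_sim <- 4e5
  cell <- sample.int(4, n_sim, replace = TRUE, prob = as.vector(W2))
  idx <- arrayInd(cell, c(2, 2))
  n2 <- rpois(n_sim, mu2 * rpois(n_sim, l2[idx[, 1]] * rate2))
  n3 <- rpois(n_sim, mu3 * rpois(n_sim, l3[idx[, 2]] * rate3))
  p_sim <- tabulate(pmin(n2 + n3, 255) + 1, 256) / n_sim
  se <- sqrt(pmax(p_sim, 1e-8) / n_sim)
  sel <- p > 1e-4
  expect_lt(max(abs(p - p_sim)[sel] / (3 * se[sel] + 1e-6)), 1.2)
})

test_that("composed Doppler histogram is normalized with the correct static weight", {
  tab <- fx_table_small()
  m <- fx_model(c_blood = 0.4, tops = c(0.5, 1, 2))
  pld <- interpolate_pathlengths(tab, m$t_epi, m$musp)
  pldA <- apply_absorption(pld, m$mua_epi, 0.03, 0.03)
  H <- compose_doppler_histogram(m, pldA, dcfg)
  expect_equal(sum(H$mass), 1, tolerance = 1e-9)
  # the f = 0 bin carries the zero-shift delta plus the (small) dynamic mass
  # that falls inside the first half-bin of the discretization
  expect_gte(H$mass[1] + 1e-12, attr(H, "p_zero_shift"))
  expect_lt(H$mass[1] - attr(H, "p_zero_shift"), 0.05)
  # zero blood: pure delta at f = 0
  m0 <- m; m0$c_blood_upper <- m0$c_blood_lower <- 0
  H0 <- compose_doppler_histogram(m0, pldA, dcfg)
  expect_equal(H0$mass[1], 1, tolerance = 1e-12)
})

test_that("speed scaling shifts the dynamic spectrum as H(f/s)/s", {
  tab <- fx_table_small()
  m <- fx_model(c_blood = 0.3, tops = c(0.5, 1))
  pldA <- apply_absorption(interpolate_pathlengths(tab, m$t_epi, m$musp),
                           m$mua_epi, 0.03, 0.03)
  cfg2 <- fx_doppler_config()
  H1 <- compose_doppler_histogram(m, pldA, cfg2)
  m2 <- m
  m2$speed <- build_speed_distribution(m$speed$weights, 1,
                                       top_speeds = 2 * m$speed$top_speeds)
  H2 <- compose_doppler_histogram(m2, pldA, cfg2)
  # dynamic part of H2 at 2f equals dynamic part of H1 at f, halved in density:
  # compare tail masses above matched cut frequencies
  cuts <- c(500, 1000, 2000, 4000)
  t1 <- vapply(cuts, function(cc) sum(H1$mass[H1$freq > cc]), numeric(1))
  t2 <- vapply(cuts, function(cc) sum(H2$mass[H2$freq > 2 * cc]), numeric(1))
  expect_equal(t1, t2, tolerance = 0.05)
})

test_that("biological zero has the stated spectral form and negligible normal-flow effect", {
  cfg2 <- fx_doppler_config()
  h <- single_shift_histogram(0, cfg2)   # static spectrum
  Hb <- add_biological_zero(h, cfg2, xi_offset = -5.3, xi_slope = -5.2e-5)
  add <- Hb$mass
  A_tot <- sum(10^(-5.3 + h$freq[-1] * -5.2e-5) * h$df)
  # BZ adds nothing at f = 0: that bin is only rescaled by the renormalization
  expect_equal(add[1], 1 / (1 + A_tot), tolerance = 1e-9)
  # 10^(offset + f slope): monotone decreasing over f > 0
  expect_true(all(diff(add[-1]) < 0))
  log_add <- log10(add[-1] * (1 + A_tot) / h$df)
  fit <- coef(lm(log_add ~ h$freq[-1]))
  expect_equal(unname(fit[1]), -5.3, tolerance = 1e-6)
  expect_equal(unname(fit[2]), -5.2e-5, tolerance = 1e-9)
  # negligible effect on contrast under normal flow
  tab <- fx_table_small()
  m <- fx_model(c_blood = 0.55, mean_speed = 1)
  bzp <- speckperf:::bz_draw(speckperf_config(), xi_offset = -5.3,
                             xi_slope = -5.2e-5)
  K_no <- forward_contrast(m, tab, bz = FALSE)$contrast$K
  K_bz <- forward_contrast(m, tab, bz = TRUE, bz_params = bzp)$contrast$K
  expect_lt(max(abs(K_bz - K_no) / K_no), 0.05)
})

test_that("lag-domain fast path agrees with the histogram route", {
  tab <- fx_table_small()
  cfg2 <- speckperf_config()
  cfg2$doppler$n_bins <- 2^16      # fine grid so discretization is negligible
  m <- fx_model(c_blood = 0.5, tops = c(0.5, 1, 2))
  m$speed <- build_speed_distribution(c(0.4, 0.4, 0.2), 1, top_speeds = c(0.5, 1, 2))
  pld <- interpolate_pathlengths(tab, m$t_epi, m$musp)
  mua2 <- dermis_absorption(m$c_blood_upper, m$s_oxy_upper, m$d_vessels_upper)
  mua3 <- dermis_absorption(m$c_blood_lower, m$s_oxy_lower, m$d_vessels_lower)
  pldA <- apply_absorption(pld, m$mua_epi, mua2, mua3)
  H <- compose_doppler_histogram(m, pldA, cfg2)
  g1h <- function(tau) autocorrelation_from_histogram(H, tau)
  K_hist <- contrast_from_autocorrelation(g1h, c(1, 2, 4, 8, 16, 32, 64), 1, cfg2)
  K_fast <- forward_contrast(m, tab, cfg2, bz = FALSE)$contrast$K
  expect_equal(K_hist[1:5], K_fast[1:5], tolerance = 5e-3)
  expect_equal(K_hist[6:7], K_fast[6:7], tolerance = 2e-2)
})
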