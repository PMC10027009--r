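# Full simulation-study driver -----------------------------------------------

#' Normalized single-exposure perfusion comparison
#'
#' Evaluates the inverse-contrast single-exposure estimator
#' \eqn{P_{SE}(T) = 1/K(T) - 1} against true total perfusion on a dataset.
#' Because \eqn{P_{SE}} is in arbitrary units, each exposure's estimate is
#' normalized to have the same mean as true total perfusion over the low
#' range (0 to 2.5 %RBC x mm/s) before computing MAPE and R^2.
#'
#' @param data a `melsci_dataset` (noisy contrast columns `kn_*` are used).
#' @param range_max upper end of the normalization range, %RBC x mm/s.
#' @return data.frame with one row per exposure: `exposure_ms`, `mape`, `r2`.
#' @export
single_exposure_comparison <- function(data, range_max = 2.5) {
  true_tot <- data$p_total
  sel <- true_tot <= range_max
  exposures <- c(1, 2, 4, 8, 16, 32, 64)
  rows <- lapply(seq_along(exposures), function(j) {
    pse <- single_exposure_perfusion(data[[paste0("kn_", j)]])
    pse_n <- pse * mean(true_tot[sel]) / mean(pse[sel])
    data.frame(exposure_ms = exposures[j],
               mape = mape(pse_n, true_tot),
               r2 = r_squared(pse_n, true_tot))
  })
  do.call(rbind, rows)
}

#' Run the complete simulation study
#'
#' The full pipeline behind the reported evaluation numbers: simulate the
#' Monte Carlo path-length grid, generate the main (randomized, noisy,
#' biological-zero) training pool and evaluation set plus the restricted
#' ablation datasets, train and select the main and restricted networks,
#' evaluate both, evaluate the normalized single-exposure estimators, and run
#' the blood-fraction and mean-speed linearity sweeps.
#'
#' @param config configuration list.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_train,n_eval dataset sizes (defaults from the configuration).
#' @param n_sweep randomized models per sweep point.
#' @param sweep_factors multiplicative sweep grid around the anchors
#'   (0.55 %RBC blood fraction, 1 mm/s mean speed); the default spans
#'   0.2x to 5x, staying inside the generator supports.
#' @param table optional precomputed `pathlength_table` (skips the MC stage).
#' @param verbose print stage progress.
#' @return list with `table`, `net_main`, `net_restricted`, `eval_main`,
#'   `eval_restricted` (metric tables), `pse` (single-exposure comparison),
#'   `sweep_c`, `sweep_v` (sweep tables), `slopes` and `deviations`
#'   (linearity summaries), and the datasets.
#' @export
melsci_study <- function(config = speckperf_config(), seed = 1L,
                         n_train = NULL, n_eval = NULL, n_sweep = 1000,
                         sweep_factors = c(0.2, 0.4, 0.7, 1, 1.5, 2.5, 5),
                         table = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(n_train)) n_train <- config$dataset$n_train_pool
  if (is.null(n_eval)) n_eval <- config$dataset$n_eval
  base <- as.integer(seed) %% 100000L

  if (is.null(table)) {
    say("simulating Monte Carlo path-length grid")
    table <- run_mc_grid(config, seed = base + 1L)
  }
  say("generating main datasets (%d train pool, %d eval)", n_train, n_eval)
  pool <- melsci_dataset(n_train, table, config, seed = base + 2L, split = "pool")
  eval_ds <- melsci_dataset(n_eval, table, config, seed = base + 3L, split = "eval")
  say("generating restricted datasets")
  pool_r <- melsci_dataset(n_train, table, config, seed = base + 4L,
                           restricted = TRUE, split = "pool")
  eval_r <- melsci_dataset(n_eval, table, config, seed = base + 5L,
                           restricted = TRUE, split = "eval")

  say("training main network")
  net_main <- perfann(pool, config, seed = base + 6L, verbose = verbose)
  say("training restricted network")
  net_restr <- perfann(pool_r, config, seed = base + 7L, verbose = verbose)

  eval_main <- evaluate_perfann(net_main, eval_ds)
  eval_restr <- evaluate_perfann(net_restr, eval_r)
  pse <- single_exposure_comparison(eval_ds)

  say("running linearity sweeps")
  sweep_c <- sweep_parameter(net_main, table, "c_blood",
                             values = 0.55 * sweep_factors, reference = 0.55,
                             n_models = n_sweep, config = config,
                             seed = base + 8L)
  sweep_v <- sweep_parameter(net_main, table, "mean_speed",
                             values = 1 * sweep_factors, reference = 1,
                             n_models = n_sweep, config = config,
                             seed = base + 9L)
  deviations <- vapply(c("rel_ann", "rel_se1", "rel_se8", "rel_se64"),
                       function(col) mean(c(sweep_deviation(sweep_c, col),
                                            sweep_deviation(sweep_v, col))),
                       numeric(1))
  list(table = table,
       pool = pool, eval_ds = eval_ds, pool_r = pool_r, eval_r = eval_r,
       net_main = net_main, net_restricted = net_restr,
       eval_main = eval_main, eval_restricted = eval_restr,
       pse = pse,
       sweep_c = sweep_c, sweep_v = sweep_v,
       slopes = c(c_blood = sweep_slope(sweep_c), mean_speed = sweep_slope(sweep_v)),
       deviations = deviations)
}
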