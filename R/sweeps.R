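# Parameter sweep experiments -------------------------------------------------
#
# One skin parameter at a time is swept over a wide range while all other
# parameters stay at their sampled values; for each sweep point the median
# relative change (vs. each model's value at the reference point) in the ANN
# total perfusion and in the single-exposure estimates is compared with the
# relative change in true perfusion.

#' Sweep a tissue parameter and record perfusion responses
#'
#' For `n_models` randomized tissue models, sets the swept parameter to each
#' value in turn (blood fraction in %, mean speed in mm/s, or t_epi, musp,
#' d_vessels in their units), forward-models contrast (with biological zero
#' and optionally noise), and records the median over models of the relative
#' change (value / reference value) of: true total perfusion, ANN-predicted
#' total perfusion, and single-exposure perfusion at 1, 8 and 64 ms.
#'
#' @param model_ann a trained `perfann`.
#' @param table a `pathlength_table`.
#' @param param one of `"c_blood"`, `"mean_speed"`, `"t_epi"`, `"musp"`,
#'   `"d_vessels"`.
#' @param values sweep values (the reference value must be among them).
#' @param reference the reference value changes are computed against.
#' @param n_models number of randomized models per sweep point.
#' @param config configuration list.
#' @param seed integer seed.
#' @param noise add contrast noise before prediction.
#' @return data.frame with one row per sweep value: `value`, `rel_true`,
#'   `rel_ann`, `rel_se1`, `rel_se8`, `rel_se64` (medians of relative
#'   changes).
#' @export
sweep_parameter <- function(model_ann, table, param, values, reference,
                            n_models = 1000, config = speckperf_config(),
                            seed = 1L, noise = TRUE) {
  stopifnot(param %in% c("c_blood", "mean_speed", "t_epi", "musp", "d_vessels"))
  set.seed(seed)
  ctx <- forward_context(table, config)
  exp_idx <- match(c(1, 8, 64), config$contrast$exposures_ms)
  vals <- c(reference, setdiff(values, reference))

  base_models <- lapply(seq_len(n_models), function(i) sample_tissue_model(config))
  # fix BZ per model across the sweep so responses are paired
  bzs <- lapply(seq_len(n_models), function(i) bz_draw(config))

  set_param <- function(mod, v) {
    switch(param,
      c_blood = { mod$c_blood_upper <- v; mod$c_blood_lower <- v; mod },
      mean_speed = { mod$speed <- scale_mean_speed(mod$speed, v); mod },
      t_epi = { mod$t_epi <- v; mod },
      musp = { mod$musp <- v; mod },
      d_vessels = { mod$d_vessels_upper <- v; mod$d_vessels_lower <- v; mod })
  }

  eval_point <- function(v, xi) {
    K <- matrix(0, n_models, 7)
    ptot <- numeric(n_models)
    for (i in seq_len(n_models)) {
      res <- forward_one(set_param(base_models[[i]], v), ctx,
                         bz = TRUE, bz_params = bzs[[i]])
      K[i, ] <- res$K
      ptot[i] <- unclass(res$ptrue)["p_total"]
    }
    Kn <- if (noise) add_contrast_noise(K, config, xi = xi) else K
    pann <- predict(model_ann, Kn^2)[, "p_total"]
    pse <- 1 / Kn - 1
    list(ptot = ptot, pann = pann, pse = pse[, exp_idx, drop = FALSE])
  }

  # shared noise innovations across sweep points (paired comparison)
  xi <- matrix(rnorm(n_models * 7), n_models, 7)
  ref <- eval_point(vals[1], xi)
  rows <- lapply(vals, function(v) {
    pt <- if (v == vals[1]) ref else eval_point(v, xi)
    data.frame(
      param = param, value = v,
      rel_true = median(pt$ptot / ref$ptot),
      rel_ann = median(pt$pann / ref$pann),
      rel_se1 = median(pt$pse[, 1] / ref$pse[, 1]),
      rel_se8 = median(pt$pse[, 2] / ref$pse[, 2]),
      rel_se64 = median(pt$pse[, 3] / ref$pse[, 3])
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$value), ]
}

#' Mean percentage deviation of a sweep response from the true response
#'
#' Average over sweep points of `100 |rel_est / rel_true - 1|`, the
#' combined-linearity summary used to compare estimators across the blood
#' fraction and mean-speed sweeps.
#'
#' @param sweep_df output of [sweep_parameter()].
#' @param column which response column (e.g. `"rel_ann"`, `"rel_se64"`).
#' @param drop_reference exclude the reference point (deviation 0 by
#'   construction).
#' @return mean percentage deviation.
#' @export
sweep_deviation <- function(sweep_df, column = "rel_ann", drop_reference = TRUE) {
  df <- sweep_df
  if (drop_reference) {
    is_ref <- df$rel_true == 1 & df$rel_ann == 1 & df$rel_se1 == 1
    df <- df[!is_ref, ]
  }
  mean(100 * abs(df[[column]] / df$rel_true - 1))
}

#' Log-log response slope of a sweep
#'
#' Ordinary least squares slope of `log(rel_est)` against `log(rel_true)`
#' across the sweep points; 1 for a perfectly proportional estimator.
#'
#' @param sweep_df output of [sweep_parameter()].
#' @param column response column.
#' @return slope.
#' @export
sweep_slope <- function(sweep_df, column = "rel_ann") {
  x <- log(sweep_df$rel_true)
  y <- log(pmax(sweep_df[[column]], 1e-12))
  keep <- is.finite(x) & is.finite(y) & abs(x) > 1e-12
  sum(x[keep] * y[keep]) / sum(x[keep]^2)
}
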