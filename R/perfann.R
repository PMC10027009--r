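#' Fit the perfusion neural network on a synthetic contrast dataset
#'
#' Trains the 7-25-3 fully connected network (squared multi-exposure contrast
#' in, speed-resolved perfusion out; tanh hidden activation, linear output)
#' with the total-perfusion-weighted mean square error loss ([wmse_loss()]).
#' Inputs are standardized per feature with training-split statistics stored
#' in the model. Training uses minibatch Adam with early stopping on the
#' validation split; `restarts` networks are trained from random
#' initializations and the one with the lowest test-split wMSE is selected
#' (the separate evaluation dataset provides the unbiased metric).
#'
#' @param data a [melsci_dataset()] with a `split` column containing
#'   `"train"`, `"val"` and `"test"` rows; or a list with elements `x`
#'   (n x 7), `y` (n x 3) and `split`.
#' @param config configuration list; block `ann` holds hidden size, restarts,
#'   learning rate, batch size, patience and epoch budget.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param restarts,hidden optional overrides of the configured values.
#' @param verbose print restart summaries.
#' @return an object of class `perfann`: weights and biases, input-scaling
#'   constants, restart scores, training metadata.
#' @export
perfann <- function(data, config = speckperf_config(), seed = 1L,
                    restarts = NULL, hidden = NULL, verbose = FALSE) {
  an <- config$ann
  if (!is.null(restarts)) an$restarts <- restarts
  if (!is.null(hidden)) an$hidden <- hidden
  if (is.data.frame(data)) {
    x <- dataset_inputs(data); y <- dataset_targets(data); split <- data$split
  } else {
    x <- as.matrix(data$x); y <- as.matrix(data$y); split <- data$split
  }
  if (max(apply(y, 2, function(c) diff(range(c)))) == 0)
    stop("degenerate dataset: all targets identical")
  itr <- split == "train"; iva <- split == "val"; ite <- split == "test"
  if (!any(itr) || !any(iva) || !any(ite))
    stop("data must contain train, val and test splits")

  mu <- colMeans(x[itr, , drop = FALSE])
  sg <- apply(x[itr, , drop = FALSE], 2, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  tot_tr <- pmax(rowSums(y[itr, , drop = FALSE]), an$eps_floor)
  tot_va <- pmax(rowSums(y[iva, , drop = FALSE]), an$eps_floor)

  set.seed(seed)
  fits <- vector("list", an$restarts)
  scores <- numeric(an$restarts)
  for (r in seq_len(an$restarts)) {
    fit <- train_mlp(xs[itr, , drop = FALSE], y[itr, , drop = FALSE], tot_tr,
                     xs[iva, , drop = FALSE], y[iva, , drop = FALSE], tot_va, an)
    pred_te <- mlp_forward(fit, xs[ite, , drop = FALSE])
    scores[r] <- mean(wmse_loss(pred_te, y[ite, , drop = FALSE], an$eps_floor))
    fits[[r]] <- fit
    if (verbose)
      message(sprintf("restart %d: %d epochs, test wMSE %.5g", r, fit$epochs, scores[r]))
  }
  best <- which.min(scores)
  model <- fits[[best]]
  model$input_mean <- mu
  model$input_sd <- sg
  model$restart_scores <- scores
  model$selected <- best
  model$seed <- seed
  model$config <- an
  model$n_train <- sum(itr)
  class(model) <- "perfann"
  model
}

# minibatch Adam with validation early stopping
train_mlp <- function(xtr, ytr, tot_tr, xva, yva, tot_va, an) {
  n_in <- ncol(xtr); n_h <- an$hidden; n_out <- ncol(ytr)
  W1 <- matrix(rnorm(n_in * n_h, sd = sqrt(1 / n_in)), n_in, n_h)
  b1 <- numeric(n_h)
  W2 <- matrix(rnorm(n_h * n_out, sd = sqrt(1 / n_h)), n_h, n_out)
  b2 <- numeric(n_out)
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(pars, function(p) p * 0)
  vel <- lapply(pars, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8; t_step <- 0
  n <- nrow(xtr); bs <- min(an$batch, n)
  best_val <- Inf; best_pars <- pars; wait <- 0; epoch <- 0

  while (epoch < an$max_epochs) {
    epoch <- epoch + 1
    ord <- sample.int(n)
    for (s in seq(1, n, by = bs)) {
      idx <- ord[s:min(s + bs - 1, n)]
      xb <- xtr[idx, , drop = FALSE]
      h <- tanh(sweep(xb %*% pars$W1, 2, pars$b1, "+"))
      out <- sweep(h %*% pars$W2, 2, pars$b2, "+")
      # d wMSE / d out, averaged over batch and components
      dout <- 2 * (out - ytr[idx, , drop = FALSE]) / tot_tr[idx] /
        (length(idx) * n_out)
      gW2 <- crossprod(h, dout)
      gb2 <- colSums(dout)
      dh <- (dout %*% t(pars$W2)) * (1 - h^2)
      gW1 <- crossprod(xb, dh)
      gb1 <- colSums(dh)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      t_step <- t_step + 1
      for (nm in names(pars)) {
        mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
        vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1a^t_step)
        vhat <- vel[[nm]] / (1 - b2a^t_step)
        pars[[nm]] <- pars[[nm]] - an$lr * mhat / (sqrt(vhat) + epsa)
      }
    }
    hv <- tanh(sweep(xva %*% pars$W1, 2, pars$b1, "+"))
    pv <- sweep(hv %*% pars$W2, 2, pars$b2, "+")
    val <- mean((pv - yva)^2 / tot_va)
    if (val < best_val * (1 - 1e-5)) {
      best_val <- val; best_pars <- pars; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= an$patience) break
    }
  }
  c(best_pars, list(val_loss = best_val, epochs = epoch))
}

mlp_forward <- function(model, xs) {
  h <- tanh(sweep(xs %*% model$W1, 2, model$b1, "+"))
  sweep(h %*% model$W2, 2, model$b2, "+")
}

#' Predict speed-resolved perfusion from squared contrast
#'
#' Forward pass of the trained network. Outputs can be slightly negative
#' (linear output layer); they are clamped only when rendering images, never
#' for metric computation.
#'
#' @param object a `perfann` model.
#' @param newdata n x 7 matrix of squared multi-exposure contrast, or a
#'   `melsci_dataset`.
#' @param ... unused.
#' @return n x 4 matrix with columns `p_low`, `p_mid`, `p_high`, `p_total`.
#' @export
predict.perfann <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) dataset_inputs(newdata) else rbind(newdata)
  if (ncol(x) != length(object$input_mean))
    stop(sprintf("expected %d input features, got %d",
                 length(object$input_mean), ncol(x)))
  if (any(!is.finite(x))) stop("non-finite inputs")
  xs <- sweep(sweep(x, 2, object$input_mean), 2, object$input_sd, "/")
  out <- mlp_forward(object, xs)
  cbind(p_low = out[, 1], p_mid = out[, 2], p_high = out[, 3],
        p_total = rowSums(out))
}

#' @export
print.perfann <- function(x, ...) {
  cat(sprintf("Perfusion network: %d-%d-%d (tanh / linear), trained on %d samples\n",
              length(x$input_mean), ncol(x$W1), ncol(x$W2), x$n_train))
  cat(sprintf("  %d restarts, selected #%d (test wMSE %.4g), %d epochs\n",
              length(x$restart_scores), x$selected,
              x$restart_scores[x$selected], x$epochs))
  invisible(x)
}

#' @export
summary.perfann <- function(object, data = NULL, ...) {
  print(object)
  if (!is.null(data)) {
    ev <- evaluate_perfann(object, data)
    cat("Evaluation:\n")
    print(ev)
  }
  invisible(object)
}

#' @export
coef.perfann <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}

#' Evaluate a trained network on a dataset
#'
#' Computes the summary metrics: wMAPE per speed component, unweighted MAPE
#' for total perfusion, and R^2 for each component and the total.
#'
#' @param model a `perfann`.
#' @param data a `melsci_dataset` (typically the held-out evaluation set).
#' @return data.frame with one row per quantity (`p_low`, `p_mid`, `p_high`,
#'   `p_total`) and columns `wmape` (NA for total), `mape` (total only) and
#'   `r2`.
#' @export
evaluate_perfann <- function(model, data) {
  pred <- predict(model, data)
  true <- dataset_targets(data)
  true_tot <- data$p_total
  wm <- wmape(pred[, 1:3], true, model$config$eps_floor)
  data.frame(
    component = c("p_low", "p_mid", "p_high", "p_total"),
    wmape = c(wm, NA),
    mape = c(NA, NA, NA, mape(pred[, 4], true_tot, model$config$eps_floor)),
    r2 = c(r_squared(pred[, 1], true[, 1]), r_squared(pred[, 2], true[, 2]),
           r_squared(pred[, 3], true[, 3]), r_squared(pred[, 4], true_tot))
  )
}

#' Binned prediction-vs-truth plot
#'
#' Mean predicted perfusion in quantile bins of true perfusion with the mean
#' absolute deviation band, against the ideal identity line.
#'
#' @param x a `perfann`.
#' @param data a `melsci_dataset`.
#' @param component one of `"p_low"`, `"p_mid"`, `"p_high"`, `"p_total"`.
#' @param n_bins number of quantile bins.
#' @param ... passed to plot.
#' @export
plot.perfann <- function(x, data, component = "p_total", n_bins = 50, ...) {
  pred <- predict(x, data)[, component]
  true <- if (component == "p_total") data$p_total else data[[component]]
  qs <- quantile(true, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(true, unique(qs), include.lowest = TRUE)
  mt <- tapply(true, bin, mean)
  mp <- tapply(pred, bin, mean)
  dv <- tapply(pred, bin, function(v) mean(abs(v - mean(v))))
  graphics::plot(mt, mp, type = "n", xlab = "true perfusion [%RBC mm/s]",
                 ylab = "predicted perfusion [%RBC mm/s]", ...)
  graphics::polygon(c(mt, rev(mt)), c(mp + dv, rev(mp - dv)),
                    col = grDevices::adjustcolor("steelblue", 0.4), border = NA)
  graphics::lines(mt, mp, lwd = 2)
  graphics::abline(0, 1, col = "red", lty = 2)
  invisible(x)
}

#' Serialize / load a trained network as portable JSON
#'
#' @param model a `perfann`.
#' @param path file path.
#' @rdname perfann_io
#' @export
write_perfann <- function(model, path) {
  stopifnot(inherits(model, "perfann"))
  payload <- list(
    format_version = 1L,
    architecture = c(length(model$input_mean), ncol(model$W1), ncol(model$W2)),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    input_mean = model$input_mean, input_sd = model$input_sd,
    seed = model$seed, restart_scores = model$restart_scores,
    selected = model$selected, epochs = model$epochs,
    n_train = model$n_train, config = model$config
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname perfann_io
#' @export
read_perfann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- p$architecture
  model <- list(
    W1 = matrix(unlist(p$W1), arch[1], arch[2]),
    b1 = as.numeric(p$b1),
    W2 = matrix(unlist(p$W2), arch[2], arch[3]),
    b2 = as.numeric(p$b2),
    input_mean = as.numeric(p$input_mean),
    input_sd = as.numeric(p$input_sd),
    seed = p$seed, restart_scores = as.numeric(p$restart_scores),
    selected = p$selected, epochs = p$epochs, n_train = p$n_train,
    config = p$config
  )
  class(model) <- "perfann"
  model
}
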