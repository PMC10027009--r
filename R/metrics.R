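# Evaluation metrics ----------------------------------------------------------
#
# Speed-resolved errors are normalized by each sample's TOTAL true perfusion
# (not the band's own value), so small bands do not inflate relative errors
# unless total perfusion is also small. Total and single-exposure perfusion
# use plain MAPE.

#' Weighted mean square error (training loss)
#'
#' \deqn{wMSE(j) = \frac{1}{N}\sum_i \frac{(P_{pred,j,i} - P_{true,j,i})^2}{P_{true,tot,i}}}
#' with the per-sample true total perfusion floored at `eps`.
#'
#' @param pred,true n x 3 matrices (or length-3 vectors) of speed-resolved
#'   perfusion.
#' @param eps floor on the true total perfusion.
#' @return `wmse_loss`: length-3 vector of per-component losses.
#' @export
wmse_loss <- function(pred, true, eps = 1e-6) {
  pred <- rbind(pred); true <- rbind(true)
  if (!all(dim(pred) == dim(true)) || ncol(pred) != 3)
    stop("pred and true must be n x 3 of equal shape")
  tot <- pmax(rowSums(true), eps)
  colMeans((pred - true)^2 / tot)
}

#' Weighted mean absolute percentage error
#'
#' \deqn{wMAPE(j) = \frac{100}{N}\sum_i \frac{|P_{pred,j,i} - P_{true,j,i}|}{P_{true,tot,i}}}
#'
#' @rdname wmse_loss
#' @return `wmape`: length-3 vector of percentages.
#' @export
wmape <- function(pred, true, eps = 1e-6) {
  pred <- rbind(pred); true <- rbind(true)
  if (!all(dim(pred) == dim(true)) || ncol(pred) != 3)
    stop("pred and true must be n x 3 of equal shape")
  tot <- pmax(rowSums(true), eps)
  100 * colMeans(abs(pred - true) / tot)
}

#' Unweighted mean absolute percentage error
#'
#' @param pred,true numeric vectors (e.g. total perfusion).
#' @param eps floor on the true values.
#' @return percentage.
#' @export
mape <- function(pred, true, eps = 1e-6) {
  if (length(pred) != length(true) || length(true) == 0)
    stop("pred and true must be nonempty and of equal length")
  100 * mean(abs(pred - true) / pmax(abs(true), eps))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} against the mean of the true values:
#' the proportion of variance in perfusion explained by the prediction.
#'
#' @param pred,true numeric vectors.
#' @return R squared.
#' @export
r_squared <- function(pred, true) {
  if (length(pred) != length(true) || length(true) == 0)
    stop("pred and true must be nonempty and of equal length")
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant true values")
  1 - sum((pred - true)^2) / ss_tot
}

#' Activation functions of the architecture search
#'
#' The four candidate activations evaluated when the architecture was chosen:
#' tanh \eqn{(e^{2x}-1)/(e^{2x}+1)}, ReLU \eqn{\max(0,x)}, SatLU
#' \eqn{\min(1,\max(0,x))} and softplus \eqn{\log(1+e^x)}.
#'
#' @param x numeric vector.
#' @return data.frame with columns `tanh`, `relu`, `satlu`, `softplus`.
#' @export
activation_suite <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  data.frame(
    tanh = ifelse(x > 20, 1, (exp(2 * x) - 1) / (exp(2 * x) + 1)),
    relu = pmax(0, x),
    satlu = pmin(1, pmax(0, x)),
    softplus = ifelse(x > 30, x, log(1 + exp(x)))
  )
}
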