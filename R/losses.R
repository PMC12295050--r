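# Losses operate on per-scale class-probability matrices P (C x V, columns =
# voxels, each column on the simplex) and 0-based integer label vectors y of
# length V. Every loss returns its value together with the analytic gradient
# with respect to the probabilities (dP), so the network backward pass can
# chain through the softmax.

onehot_matrix <- function(y, n_classes) {
  V <- length(y)
  Y <- matrix(0, n_classes, V)
  Y[cbind(y + 1L, seq_len(V))] <- 1
  Y
}

#' Voxel-mean cross-entropy on probabilities
#'
#' Robust variant: probabilities are clamped at `clamp` before the log so
#' that confident wrong predictions cannot produce infinite loss.
#'
#' @param P Class-probability matrix (C x V).
#' @param y Integer labels, 0-based, length V.
#' @param clamp Lower clamp on probabilities.
#' @return List `value`, `dP`.
#' @export
ce_loss <- function(P, y, clamp = 1e-7) {
  ce_loss_cpp(P, as.integer(y), clamp)
}

#' Soft Dice loss on probabilities
#'
#' Mean over the foreground classes of
#' `1 - (2 * sum(p_c * y_c) + eps) / (sum(p_c) + sum(y_c) + eps)`.
#' Background (class 0) is excluded, matching the common convention for
#' lesion segmentation where background dominates the volume.
#'
#' @param P Class-probability matrix (C x V).
#' @param y Integer labels, 0-based.
#' @param eps Smoothing constant.
#' @param fg_classes 0-based class ids counted as foreground.
#' @return List `value`, `dP`; value lies in \[0, 1\].
#' @export
soft_dice_loss <- function(P, y, eps = 1e-5, fg_classes = NULL) {
  if (anyNA(P)) stop("NaN in probabilities")
  C <- nrow(P)
  if (is.null(fg_classes)) fg_classes <- seq_len(C - 1L)  # 1..C-1 (0 = background)
  dice_loss_cpp(P, as.integer(y), eps, as.integer(fg_classes))
}

#' Pyramid supervised loss
#'
#' Deep-supervision objective: the average over scales of
#' `0.5 * (CE + soft Dice)` between each upsampled head and the labels.
#'
#' @param probs List of S class-probability matrices (C x V), all at full
#'   patch resolution.
#' @param y Integer labels, 0-based, length V.
#' @return List `value`, `dP` (list of per-scale gradients).
#' @export
supervised_loss <- function(probs, y) {
  S <- length(probs)
  value <- 0
  dP <- vector("list", S)
  for (s in seq_len(S)) {
    ce <- ce_loss(probs[[s]], y)
    dc <- soft_dice_loss(probs[[s]], y)
    value <- value + 0.5 * (ce$value + dc$value)
    dP[[s]] <- 0.5 * (ce$dP + dc$dP) / S
  }
  list(value = value / S, dP = dP)
}

#' Gaussian warm-up weight for the consistency loss
#'
#' `lambda(t) = wmax * exp(-5 * (1 - t/tmax)^2)`: near-zero early in
#' training, rising monotonically to `wmax` at the final step, so the
#' unsupervised consistency term only takes over once the supervised signal
#' has shaped the predictions.
#'
#' @param t Current training step (0 <= t <= tmax).
#' @param tmax Maximal training step (> 0).
#' @param wmax Final regularization weight.
#' @return The weight, in (0, wmax].
#' @export
warmup_weight <- function(t, tmax, wmax = 0.1) {
  if (tmax <= 0) stop("tmax must be positive")
  if (any(t < 0 | t > tmax)) stop("t must lie in [0, tmax]")
  wmax * exp(-5 * (1 - t / tmax)^2)
}

#' Uncertainty-rectified pyramid consistency loss
#'
#' Multi-scale consistency regularizer: each scale's prediction is pulled
#' toward the pyramid mean `pc = mean_s(p_s)`, with a per-voxel KL
#' discrepancy `D_s = KL(pc || p_s)` acting as an uncertainty estimate.
#' Voxels where a scale disagrees strongly with the consensus are
#' down-weighted by `exp(-D_s)` (rectification), and the mean discrepancy is
#' added as a sharpening term:
#' `Lu = (1/S) * sum_s \[ mean(w_s (p_s - pc)^2) / (mean(w_s) + eps) + mean(D_s) \]`.
#' Zero iff all scales agree exactly.
#'
#' @param probs List of S >= 2 class-probability matrices (C x V).
#' @param eps Stabilizer added to the mean weight.
#' @param clamp Lower clamp on probabilities inside logs.
#' @param kl_dir `"mean_to_scale"` (default, KL(pc || p_s)) or
#'   `"scale_to_mean"` (KL(p_s || pc)).
#' @param grad Also return analytic gradients `dP` per scale.
#' @return List `value` (finite, >= 0) and optionally `dP`.
#' @export
unsupervised_loss <- function(probs, eps = 1e-8, clamp = 1e-8,
                              kl_dir = c("mean_to_scale", "scale_to_mean"),
                              grad = FALSE) {
  kl_dir <- match.arg(kl_dir)
  if (length(probs) < 2) stop("pyramid consistency needs at least 2 scales")
  lu_loss_cpp(probs, eps, clamp, match(kl_dir, c("mean_to_scale", "scale_to_mean")) - 1L,
              grad)
}

#' Combine loss components
#'
#' @param ls Supervised loss value.
#' @param lu Unsupervised loss value.
#' @param lambda_t Warm-up weight at the current step.
#' @return A `loss_breakdown` list with `ls`, `lu`, `lambda_t`, `ltotal`
#'   satisfying `ltotal = ls + lambda_t * lu`.
#' @export
loss_breakdown <- function(ls, lu, lambda_t) {
  stopifnot(is.finite(ls), is.finite(lu), is.finite(lambda_t))
  structure(list(ls = ls, lu = lu, lambda_t = lambda_t,
                 ltotal = ls + lambda_t * lu), class = "loss_breakdown")
}
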