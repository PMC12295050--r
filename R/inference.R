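#' Sliding-window whole-volume prediction
#'
#' Tiles the volume with overlapping patches, predicts each with the
#' highest-resolution head, averages class probabilities where patches
#' overlap, and takes the per-voxel argmax (ties broken toward the lower
#' class index). Volumes smaller than the patch are zero-padded and the
#' prediction cropped back.
#'
#' @param params A trained `pyramid_net` (see [train_ucppa()]).
#' @param vol An [intensity_volume()].
#' @param patch_size Patch (Ph, Pw, Pd); defaults to the network's configured
#'   patch size.
#' @param overlap Fractional overlap between neighboring patches in [0, 1).
#' @param normalize Apply [normalize_zmuv()] first (the preprocessing used in
#'   training).
#' @return A [label_volume()] on the input grid.
#' @export
sliding_window_predict <- function(params, vol, patch_size = NULL, overlap = 0.25,
                                   normalize = TRUE) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (is.null(patch_size)) patch_size <- params$config$patch_size
  p <- as.integer(patch_size)
  if (normalize) vol <- normalize_zmuv(vol)
  x <- vol$data
  orig_dim <- dim(x)
  pad <- pmax(p - orig_dim, 0L)
  if (any(pad > 0L)) {
    xp <- array(0, dim = pmax(orig_dim, p))
    xp[seq_len(orig_dim[1]), seq_len(orig_dim[2]), seq_len(orig_dim[3])] <- x
    x <- xp
  }
  dm <- dim(x)
  C <- params$config$n_classes
  starts <- function(n, w) {
    stride <- max(1L, as.integer(round(w * (1 - overlap))))
    s <- seq(0L, n - w, by = stride)
    if (s[length(s)] != n - w) s <- c(s, n - w)
    unique(s)
  }
  sh <- starts(dm[1], p[1]); sw <- starts(dm[2], p[2]); sd <- starts(dm[3], p[3])
  acc <- array(0, dim = c(C, dm))
  cnt <- array(0, dim = dm)
  for (h0 in sh) for (w0 in sw) for (d0 in sd) {
    hi <- (h0 + 1L):(h0 + p[1]); wi <- (w0 + 1L):(w0 + p[2]); di <- (d0 + 1L):(d0 + p[3])
    patch <- x[hi, wi, di, drop = FALSE]
    pr <- pyramid_forward(params, patch)
    acc[, hi, wi, di] <- acc[, hi, wi, di] + pr$probs[[1]]
    cnt[hi, wi, di] <- cnt[hi, wi, di] + 1
  }
  probs <- sweep(acc, 2:4, cnt, "/")
  lab <- apply(probs, 2:4, which.max) - 1L   # ties: first (lowest class) wins
  lab <- lab[seq_len(orig_dim[1]), seq_len(orig_dim[2]), seq_len(orig_dim[3]), drop = FALSE]
  label_volume(lab, spacing = vol$spacing, origin = vol$origin)
}

as_label_array <- function(x) if (inherits(x, "label_volume")) x$labels else x

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` for the voxel sets of one class (or of all
#' foreground). Two empty masks score 1 by convention.
#'
#' @param pred,truth [label_volume()]s (or integer arrays) on the same grid.
#' @param class_id Class to score (1 = tumor, 2 = SNFH), or `"foreground"`
#'   for the union of nonzero labels.
#' @return Dice in \[0, 1\].
#' @export
dice_score <- function(pred, truth, class_id = 1L) {
  a <- as_label_array(pred); b <- as_label_array(truth)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  A <- if (identical(class_id, "foreground")) a > 0L else a == class_id
  B <- if (identical(class_id, "foreground")) b > 0L else b == class_id
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

surface_points <- function(mask, spacing) {
  dm <- dim(mask)
  interior <- array(TRUE, dm)
  shift_and <- function(m, ax, dir) {
    out <- array(FALSE, dm)
    idx_src <- lapply(dm, seq_len); idx_dst <- idx_src
    if (dir > 0) { idx_dst[[ax]] <- 2:dm[ax]; idx_src[[ax]] <- 1:(dm[ax] - 1) }
    else { idx_dst[[ax]] <- 1:(dm[ax] - 1); idx_src[[ax]] <- 2:dm[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_and(mask, ax, dir)
  surf <- mask & !interior
  w <- which(surf, arr.ind = TRUE)
  sweep(w - 1, 2, spacing, "*")
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Surface voxels of each mask (6-connectivity; volume borders count as
#' surface) are converted to physical coordinates using the voxel spacing,
#' and the 95th percentile of the pooled directed nearest-surface distances
#' (A to B and B to A) is returned in millimetres. Two empty masks give 0;
#' one empty mask gives the sentinel `Inf` (no surface to measure against).
#'
#' @inheritParams dice_score
#' @param spacing Voxel spacing in mm (default from `truth` when it is a
#'   [label_volume()], else 1 mm isotropic).
#' @return HD95 in mm (possibly `Inf`).
#' @export
hd95 <- function(pred, truth, class_id = 1L, spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(truth, "label_volume")) truth$spacing else c(1, 1, 1)
  a <- as_label_array(pred); b <- as_label_array(truth)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  A <- if (identical(class_id, "foreground")) a > 0L else a == class_id
  B <- if (identical(class_id, "foreground")) b > 0L else b == class_id
  ea <- sum(A) == 0; eb <- sum(B) == 0
  if (ea && eb) return(0)
  if (ea || eb) return(Inf)
  pa <- surface_points(A, spacing); pb <- surface_points(B, spacing)
  d_ab <- directed_min_dists(pa, pb)
  d_ba <- directed_min_dists(pb, pa)
  as.numeric(stats::quantile(c(d_ab, d_ba), 0.95))
}
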