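#' Training configuration
#'
#' Hyper-parameters of the semi-supervised training loop. Defaults follow
#' the published recipe where one exists: initial learning rate 0.001, SGD,
#' batches of 2 labeled + 2 unlabeled patches, crop threshold k = 50,
#' learning rate adapted by a reduce-on-plateau rule.
#'
#' @param steps Total number of SGD steps.
#' @param tmax Maximal training step for the Gaussian warm-up (defaults to
#'   `steps`).
#' @param wmax Final consistency regularization weight; 0 disables the
#'   unsupervised loss entirely (supervised-only training).
#' @param k Foreground threshold of the weighted cropping.
#' @param lr Initial learning rate.
#' @param momentum,weight_decay SGD companions.
#' @param batch_labeled,batch_unlabeled Patches per step from each pool.
#' @param lu_on_labeled Include labeled patches in the consistency loss;
#'   by default only unlabeled patches are regularized, matching the
#'   semi-supervised reading that unlabeled data carry the consistency
#'   signal while labeled data are driven by supervision.
#' @param kl_dir KL direction of the uncertainty estimate (see
#'   [unsupervised_loss()]).
#' @param weighted_crop Use the probability-aware crop distribution; FALSE
#'   falls back to uniform depth starts (ablation mode).
#' @param augment Apply random flip/rotation augmentation.
#' @param plateau_window Steps per plateau-monitoring window.
#' @param plateau_patience Windows without improvement before the learning
#'   rate is multiplied by `plateau_factor`.
#' @param plateau_factor Learning-rate reduction factor.
#' @param seed Master RNG seed (controls cropping, augmentation and batching;
#'   initialization takes its own seed in [init_pyramid_net()]).
#' @return Object of class `training_config`.
#' @export
training_config <- function(steps = 500L, tmax = steps, wmax = 0.1, k = 50L,
                            lr = 0.001, momentum = 0.9, weight_decay = 1e-4,
                            batch_labeled = 2L, batch_unlabeled = 2L,
                            lu_on_labeled = FALSE,
                            kl_dir = "mean_to_scale",
                            weighted_crop = TRUE, augment = TRUE,
                            plateau_window = 50L, plateau_patience = 20L,
                            plateau_factor = 0.5, seed = 1L) {
  if (wmax < 0) stop("wmax must be >= 0")
  if (tmax < 1) stop("tmax must be >= 1")
  structure(list(steps = as.integer(steps), tmax = as.integer(tmax), wmax = wmax,
                 k = as.integer(k), lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_labeled = as.integer(batch_labeled),
                 batch_unlabeled = as.integer(batch_unlabeled),
                 lu_on_labeled = lu_on_labeled, kl_dir = kl_dir,
                 weighted_crop = weighted_crop, augment = augment,
                 plateau_window = as.integer(plateau_window),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, seed = as.integer(seed)),
            class = "training_config")
}

load_training_volumes <- function(manifest) {
  lab <- lapply(manifest$labeled, function(e) {
    iv <- normalize_zmuv(read_nifti(e$image))
    lv <- read_nifti(e$labels, type = "label")
    if (!identical(dim(iv$data), dim(lv$labels))) stop("image/label shape mismatch")
    list(x = iv$data, y = lv$labels)
  })
  unl <- lapply(manifest$unlabeled, function(p) {
    list(x = normalize_zmuv(read_nifti(p))$data, y = NULL)
  })
  depths <- vapply(c(lab, unl), function(v) dim(v$x)[3], integer(1))
  if (length(depths) && length(unique(depths)) != 1L)
    stop("all training volumes must share the same depth D")
  list(labeled = lab, unlabeled = unl)
}

sample_training_patch <- function(vol, dist, patch_size, weighted, augment) {
  D <- dim(vol$x)[3]
  j <- if (weighted) sample_crop_start(dist)
       else sample.int(D - patch_size[3] + 1L, 1L) - 1L
  cr <- crop_patch(vol$x, vol$y, j, patch_size)
  if (augment) {
    au <- augment_flip_rotate(cr$patch, cr$labels)
    cr$patch <- au$patch; cr$labels <- au$labels
  }
  cr
}

#' Train the semi-supervised pyramid-consistency segmentation model
#'
#' The full training procedure: a probability-aware aggregate crop
#' distribution is built once from the labeled masks and drives the depth
#' starts of every crop, labeled and unlabeled alike; each step draws a mixed
#' batch, computes the deep-supervision loss on the labeled patches and the
#' pyramid-consistency loss on the batch, combines them with the Gaussian
#' warm-up weight, and takes an SGD step. Fully deterministic given the seeds.
#'
#' @param manifest A `dataset_manifest` (see [generate_dataset()],
#'   [read_manifest()]) with at least one labeled volume.
#' @param net_config A [pyramid_net_config()].
#' @param train_config A [training_config()].
#' @param params Optional warm-start parameters (resume training).
#' @param init_seed Seed for weight initialization when `params` is NULL.
#' @param log_csv Optional path; when given, the loss history is written as
#'   CSV (columns step, ls, lu, lambda, ltotal, lr).
#' @param verbose Print progress every 50 steps.
#' @return List with `params` (trained network), `history` (data frame of
#'   per-step [loss_breakdown()] components), `crop_dist` (the aggregate
#'   distribution), `net_config`, `train_config`.
#' @export
train_ucppa <- function(manifest, net_config, train_config = training_config(),
                        params = NULL, init_seed = 100L, log_csv = NULL,
                        verbose = FALSE) {
  if (manifest$n_labeled < 1) stop("need at least one labeled volume")
  vols <- load_training_volumes(manifest)
  patch <- net_config$patch_size
  lists <- lapply(vols$labeled, function(v)
    build_crop_list(v$y, window_depth = patch[3], k = train_config$k))
  dist <- aggregate_crop_lists(lists)
  if (is.null(params)) params <- init_pyramid_net(net_config, seed = init_seed)
  set.seed(train_config$seed)

  Bl <- train_config$batch_labeled
  Bu <- if (length(vols$unlabeled) > 0 && train_config$wmax > 0)
    train_config$batch_unlabeled else 0L
  B <- Bl + Bu
  V <- prod(patch)
  S <- net_config$n_scales
  state <- NULL
  lr <- train_config$lr
  hist <- vector("list", train_config$steps)
  best_window <- Inf; bad_windows <- 0L; window_acc <- numeric(0)

  for (t in seq_len(train_config$steps)) {
    il <- sample.int(length(vols$labeled), Bl, replace = TRUE)
    iu <- if (Bu > 0) sample.int(length(vols$unlabeled), Bu, replace = TRUE) else integer(0)
    crops <- c(lapply(il, function(i) sample_training_patch(vols$labeled[[i]], dist, patch,
                                                            train_config$weighted_crop,
                                                            train_config$augment)),
               lapply(iu, function(i) sample_training_patch(vols$unlabeled[[i]], dist, patch,
                                                            train_config$weighted_crop,
                                                            train_config$augment)))
    X <- matrix(unlist(lapply(crops, function(cr) as.numeric(cr$patch))), nrow = 1)
    y <- unlist(lapply(crops[seq_len(Bl)], function(cr) as.integer(cr$labels)))

    fw <- net_forward(params, X, c(patch, B), training = TRUE)
    params <- fw$params
    lab_cols <- seq_len(Bl * V)
    probs_lab <- lapply(fw$probs, function(P) P[, lab_cols, drop = FALSE])
    sl <- supervised_loss(probs_lab, y)

    lambda_t <- warmup_weight(min(t, train_config$tmax), train_config$tmax,
                              train_config$wmax)
    lu_val <- 0
    dP <- lapply(seq_len(S), function(s) {
      G <- matrix(0, net_config$n_classes, V * B)
      G[, lab_cols] <- sl$dP[[s]]
      G
    })
    if (Bu > 0) {
      lu_cols <- if (train_config$lu_on_labeled) seq_len(V * B) else (Bl * V + 1L):(V * B)
      probs_lu <- lapply(fw$probs, function(P) P[, lu_cols, drop = FALSE])
      lu <- unsupervised_loss(probs_lu, kl_dir = train_config$kl_dir, grad = TRUE)
      lu_val <- lu$value
      for (s in seq_len(S)) dP[[s]][, lu_cols] <- dP[[s]][, lu_cols] + lambda_t * lu$dP[[s]]
    }
    g <- net_backward(params, fw$cache, dP)
    up <- sgd_update(params, g, state, lr = lr, momentum = train_config$momentum,
                     weight_decay = train_config$weight_decay)
    params <- up$params; state <- up$state

    lb <- loss_breakdown(sl$value, lu_val, lambda_t)
    hist[[t]] <- data.frame(step = t, ls = lb$ls, lu = lb$lu, lambda = lb$lambda_t,
                            ltotal = lb$ltotal, lr = lr)
    if (!all(is.finite(c(lb$ls, lb$lu, lb$ltotal)))) stop("non-finite loss at step ", t)

    # reduce-on-plateau on the windowed mean supervised loss
    window_acc <- c(window_acc, sl$value)
    if (length(window_acc) >= train_config$plateau_window) {
      m <- mean(window_acc); window_acc <- numeric(0)
      if (m < best_window - 1e-6) { best_window <- m; bad_windows <- 0L }
      else {
        bad_windows <- bad_windows + 1L
        if (bad_windows >= train_config$plateau_patience) {
          lr <- lr * train_config$plateau_factor; bad_windows <- 0L
        }
      }
    }
    if (verbose && t %% 50L == 0L)
      message(sprintf("step %d: ls=%.4f lu=%.4f lambda=%.4g ltotal=%.4f",
                      t, lb$ls, lb$lu, lb$lambda_t, lb$ltotal))
  }
  history <- do.call(rbind, hist)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  list(params = params, history = history, crop_dist = dist,
       net_config = net_config, train_config = train_config)
}

#' Save / load a training checkpoint
#'
#' The checkpoint is a single serialized parameter blob; a JSON sidecar
#' (`<path>.json`) records the network and training configuration for
#' provenance.
#'
#' @param fit Result of [train_ucppa()] (or a list with `params`,
#'   `net_config`).
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `save_checkpoint`: invisibly `path`; `load_checkpoint`: a list
#'   with `params` and `net_config`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params, net_config = fit$net_config), path)
  cfg <- fit$net_config
  jsonlite::write_json(list(net_config = unclass(cfg),
                            train_config = if (!is.null(fit$train_config))
                              unclass(fit$train_config) else NULL),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$params)) stop("not a checkpoint file: ", path)
  ck
}
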