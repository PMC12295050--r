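# Pyramid deep-supervision segmentation network (V-Net style encoder/decoder
# with one conv-BN-ReLU block per stage, 2x2x2 max pooling, trilinear
# decoder upsampling, skip concatenation, and auxiliary 1x1x1 prediction
# heads at the S highest decoder resolutions, each upsampled to full patch
# resolution). Activations are (C x V*B) matrices (see src/nn_ops.cpp);
# the backward pass is hand-derived and verified against finite differences
# in the test suite.

#' Network configuration
#'
#' @param in_channels Input channels (1 for single-modality MRI).
#' @param n_classes Output classes (3: background, tumor, SNFH).
#' @param base_filters Channels of the first stage; stages use
#'   `base_filters * c(1, 2, 4, 8, 16)`. 16 for the full-size model,
#'   4 for fast desk-scale runs.
#' @param n_scales Number of deep-supervision heads S (2..4).
#' @param patch_size Training patch (Ph, Pw, Pd); every component must be
#'   divisible by 16 (four pooling stages).
#' @param depth_multiplier Conv blocks per stage (1 reproduces the printed
#'   architecture; >1 approaches a full V-Net stage).
#' @return Object of class `pyramid_net_config`.
#' @export
pyramid_net_config <- function(in_channels = 1L, n_classes = 3L, base_filters = 16L,
                               n_scales = 4L, patch_size = c(128L, 128L, 32L),
                               depth_multiplier = 1L) {
  if (n_scales < 2 || n_scales > 4) stop("n_scales must be in 2..4")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (any(patch_size %% 16L != 0L)) stop("patch_size components must be divisible by 16")
  structure(list(in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
                 base_filters = as.integer(base_filters), n_scales = as.integer(n_scales),
                 patch_size = as.integer(patch_size),
                 depth_multiplier = as.integer(depth_multiplier)),
            class = "pyramid_net_config")
}

new_conv_block <- function(cin, cout) {
  fan <- cin * 27
  list(W = matrix(stats::rnorm(cout * fan, 0, sqrt(2 / fan)), cout, fan),
       b = numeric(cout),
       bn = list(gamma = rep(1, cout), beta = numeric(cout),
                 rm = numeric(cout), rv = rep(1, cout)))
}

#' Initialize network parameters
#'
#' He-normal conv weights, unit-gamma batch norm, zero-initialized heads.
#'
#' @param config A [pyramid_net_config()].
#' @param seed RNG seed for the initialization.
#' @return Parameter list (class `pyramid_net`), with `config` attached.
#' @export
init_pyramid_net <- function(config = pyramid_net_config(), seed = 1L) {
  set.seed(seed)
  f <- config$base_filters
  ch <- f * c(1L, 2L, 4L, 8L, 16L)
  dm <- config$depth_multiplier
  enc <- vector("list", 5)
  for (i in 1:5) {
    cin <- if (i == 1) config$in_channels else ch[i - 1]
    enc[[i]] <- lapply(seq_len(dm), function(j)
      new_conv_block(if (j == 1) cin else ch[i], ch[i]))
  }
  dec <- vector("list", 4)
  for (i in 1:4) {
    cin <- ch[i + 1] + ch[i]
    dec[[i]] <- lapply(seq_len(dm), function(j)
      new_conv_block(if (j == 1) cin else ch[i], ch[i]))
  }
  dsv <- lapply(seq_len(config$n_scales), function(s)
    list(W = matrix(stats::rnorm(config$n_classes * ch[s], 0, sqrt(2 / ch[s])),
                    config$n_classes, ch[s]),
         b = numeric(config$n_classes)))
  structure(list(enc = enc, dec = dec, dsv = dsv, config = config, channels = ch),
            class = "pyramid_net")
}

bn_eps <- 1e-5

bn_forward <- function(X, bn, training, momentum = 0.1) {
  if (training) {
    mu <- rowMeans(X)
    v <- rowMeans(X^2) - mu^2
    v <- pmax(v, 0)
    bn_new <- bn
    bn_new$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn_new$rv <- (1 - momentum) * bn$rv + momentum * v
  } else {
    mu <- bn$rm; v <- bn$rv; bn_new <- bn
  }
  istd <- 1 / sqrt(v + bn_eps)
  xhat <- (X - mu) * istd          # length-C vectors recycle down columns
  Y <- xhat * bn$gamma + bn$beta
  list(Y = Y, cache = list(xhat = xhat, istd = istd, gamma = bn$gamma), bn = bn_new)
}

bn_backward <- function(dY, cache) {
  xhat <- cache$xhat; istd <- cache$istd; gamma <- cache$gamma
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  Vn <- ncol(dY)
  dX <- (gamma * istd) * (dY - dbeta / Vn - xhat * (dgamma / Vn))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

conv_block_forward <- function(X, blk, dims, training) {
  Z <- conv3d_forward(X, blk$W, blk$b, dims)
  bnf <- bn_forward(Z, blk$bn, training)
  mask <- bnf$Y > 0
  A <- bnf$Y * mask
  list(A = A, cache = list(X = X, bn = bnf$cache, mask = mask, dims = dims),
       bn = bnf$bn)
}

conv_block_backward <- function(dA, blk, cache) {
  dZbn <- dA * cache$mask
  bnb <- bn_backward(dZbn, cache$bn)
  g <- conv3d_backward(cache$X, blk$W, bnb$dX, cache$dims)
  list(dX = g$dX,
       grads = list(W = g$dW, b = as.numeric(g$db),
                    bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
}

stage_forward <- function(X, blocks, dims, training) {
  caches <- vector("list", length(blocks))
  bns <- vector("list", length(blocks))
  A <- X
  for (j in seq_along(blocks)) {
    r <- conv_block_forward(A, blocks[[j]], dims, training)
    A <- r$A; caches[[j]] <- r$cache; bns[[j]] <- r$bn
  }
  list(A = A, caches = caches, bns = bns)
}

stage_backward <- function(dA, blocks, caches) {
  grads <- vector("list", length(blocks))
  for (j in rev(seq_along(blocks))) {
    r <- conv_block_backward(dA, blocks[[j]], caches[[j]])
    dA <- r$dX; grads[[j]] <- r$grads
  }
  list(dX = dA, grads = grads)
}

softmax_cols <- function(Z) softmax_cols_cpp(Z)

# dL/dZ from dL/dP through the softmax: p * (dp - <p, dp>).
softmax_backward_cols <- function(P, dP) softmax_backward_cpp(P, dP)

#' Batched network forward pass
#'
#' @param params A `pyramid_net`.
#' @param X Input matrix (in_channels x H*W*D*B).
#' @param dims Integer (H, W, D, B).
#' @param training Use batch statistics (and collect caches for backward).
#' @return List `probs` (S class-probability matrices at full resolution,
#'   highest-resolution head first), `cache` (when training), `params`
#'   (with updated batch-norm running statistics when training).
#' @export
net_forward <- function(params, X, dims, training = FALSE) {
  cfg <- params$config
  S <- cfg$n_scales
  dlist <- list(dims)
  for (k in 2:5) dlist[[k]] <- c(dlist[[k - 1]][1:3] %/% 2L, dims[4])
  acts <- vector("list", 5)       # encoder outputs per level
  ecache <- vector("list", 5); pcache <- vector("list", 4)
  A <- X
  for (i in 1:5) {
    r <- stage_forward(A, params$enc[[i]], dlist[[i]], training)
    params$enc[[i]] <- Map(function(b, bn) { b$bn <- bn; b }, params$enc[[i]], r$bns)
    acts[[i]] <- r$A; ecache[[i]] <- r$caches
    if (i < 5) {
      mp <- maxpool3d_forward(r$A, dlist[[i]])
      pcache[[i]] <- list(argmax = mp$argmax, Vin = ncol(r$A), C = nrow(r$A))
      A <- mp$Y
    }
  }
  dec_out <- vector("list", 4); dcache <- vector("list", 4)
  up_in <- acts[[5]]; up_dims <- dlist[[5]]
  for (i in 4:1) {
    U <- upsample3d_forward(up_in, up_dims, dlist[[i]])
    Xcat <- rbind(U, acts[[i]])
    r <- stage_forward(Xcat, params$dec[[i]], dlist[[i]], training)
    params$dec[[i]] <- Map(function(b, bn) { b$bn <- bn; b }, params$dec[[i]], r$bns)
    dec_out[[i]] <- r$A
    dcache[[i]] <- list(caches = r$caches, cu = nrow(up_in), up_dims = up_dims)
    up_in <- r$A; up_dims <- dlist[[i]]
  }
  probs <- vector("list", S); zcache <- vector("list", S)
  for (s in seq_len(S)) {
    Zs <- params$dsv[[s]]$W %*% dec_out[[s]] + params$dsv[[s]]$b
    Zf <- if (s == 1) Zs else upsample3d_forward(Zs, dlist[[s]], dlist[[1]])
    P <- softmax_cols(Zf)
    probs[[s]] <- P
    zcache[[s]] <- list(din = dec_out[[s]])
  }
  cache <- if (training) list(ecache = ecache, pcache = pcache, dcache = dcache,
                              zcache = zcache, probs = probs, dlist = dlist) else NULL
  list(probs = probs, cache = cache, params = params)
}

#' Batched network backward pass
#'
#' @param params A `pyramid_net`.
#' @param cache Cache returned by [net_forward()] with `training = TRUE`.
#' @param dProbs List of S gradients of the loss w.r.t. the per-scale
#'   probabilities (same shapes as `probs`).
#' @return Gradient structure parallel to `params` (fields `enc`, `dec`, `dsv`).
#' @export
net_backward <- function(params, cache, dProbs) {
  cfg <- params$config
  S <- cfg$n_scales
  dlist <- cache$dlist
  ddec <- vector("list", 4)       # accumulated gradients into decoder outputs
  gdsv <- vector("list", S)
  for (s in seq_len(S)) {
    dZf <- softmax_backward_cpp(cache$probs[[s]], dProbs[[s]])
    dZs <- if (s == 1) dZf else upsample3d_backward(dZf, dlist[[s]], dlist[[1]])
    din <- cache$zcache[[s]]$din
    gdsv[[s]] <- list(W = tcrossprod(dZs, din), b = rowSums(dZs))
    dd <- crossprod(params$dsv[[s]]$W, dZs)
    ddec[[s]] <- if (is.null(ddec[[s]])) dd else ddec[[s]] + dd
  }
  gdec <- vector("list", 4)
  denc_extra <- vector("list", 5) # gradient flowing into encoder skip activations
  dup <- NULL                     # gradient into the upsampled deeper feature
  for (i in 1:4) {
    dA <- if (!is.null(ddec[[i]])) ddec[[i]] else matrix(0, params$channels[i], ncol(cache$dcache[[i]]$caches[[1]]$X))
    if (!is.null(dup)) dA <- dA + dup
    r <- stage_backward(dA, params$dec[[i]], cache$dcache[[i]]$caches)
    gdec[[i]] <- r$grads
    cu <- cache$dcache[[i]]$cu
    dU <- r$dX[seq_len(cu), , drop = FALSE]
    denc_extra[[i]] <- r$dX[(cu + 1):nrow(r$dX), , drop = FALSE]
    dup <- upsample3d_backward(dU, cache$dcache[[i]]$up_dims, dlist[[i]])
  }
  genc <- vector("list", 5)
  dA <- dup                        # gradient into center (level 5) output
  for (i in 5:1) {
    r <- stage_backward(dA, params$enc[[i]], cache$ecache[[i]])
    genc[[i]] <- r$grads
    if (i > 1) {
      pc <- cache$pcache[[i - 1]]
      dA <- maxpool3d_backward(r$dX, pc$argmax, pc$C, pc$Vin)
      dA <- dA + denc_extra[[i - 1]]
    }
  }
  list(enc = genc, dec = gdec, dsv = gdsv)
}

#' One SGD step with momentum and weight decay
#'
#' @param params A `pyramid_net`.
#' @param grads Gradients from [net_backward()].
#' @param state Momentum buffers (NULL on the first step).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty on conv/head weights (not on BN or biases).
#' @return List `params`, `state`.
#' @export
sgd_update <- function(params, grads, state = NULL, lr = 0.001,
                       momentum = 0.9, weight_decay = 1e-4) {
  upd <- function(p, g, st, decay) {
    if (is.null(st)) st <- p * 0
    g <- g + decay * p
    st <- momentum * st + g
    list(p = p - lr * st, st = st)
  }
  if (is.null(state)) state <- list(enc = vector("list", 5), dec = vector("list", 4),
                                    dsv = vector("list", length(params$dsv)))
  walk_stage <- function(blocks, gstage, sstage) {
    if (is.null(sstage)) sstage <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      if (is.null(sstage[[j]])) sstage[[j]] <- list()
      for (nm in c("W", "b")) {
        r <- upd(blocks[[j]][[nm]], gstage[[j]][[nm]], sstage[[j]][[nm]],
                 if (nm == "W") weight_decay else 0)
        blocks[[j]][[nm]] <- r$p; sstage[[j]][[nm]] <- r$st
      }
      for (nm in c("gamma", "beta")) {
        r <- upd(blocks[[j]]$bn[[nm]], gstage[[j]]$bn[[nm]], sstage[[j]][[nm]], 0)
        blocks[[j]]$bn[[nm]] <- r$p; sstage[[j]][[nm]] <- r$st
      }
    }
    list(blocks = blocks, sstage = sstage)
  }
  for (i in 1:5) {
    r <- walk_stage(params$enc[[i]], grads$enc[[i]], state$enc[[i]])
    params$enc[[i]] <- r$blocks; state$enc[[i]] <- r$sstage
  }
  for (i in 1:4) {
    r <- walk_stage(params$dec[[i]], grads$dec[[i]], state$dec[[i]])
    params$dec[[i]] <- r$blocks; state$dec[[i]] <- r$sstage
  }
  for (s in seq_along(params$dsv)) {
    if (is.null(state$dsv[[s]])) state$dsv[[s]] <- list()
    for (nm in c("W", "b")) {
      r <- upd(params$dsv[[s]][[nm]], grads$dsv[[s]][[nm]], state$dsv[[s]][[nm]],
               if (nm == "W") weight_decay else 0)
      params$dsv[[s]][[nm]] <- r$p; state$dsv[[s]][[nm]] <- r$st
    }
  }
  list(params = params, state = state)
}

#' Forward pass on a single patch
#'
#' Convenience wrapper around [net_forward()] for one unbatched patch in
#' evaluation mode (deterministic: batch-norm uses running statistics).
#'
#' @param params A `pyramid_net`.
#' @param patch 3D array matching the configured patch size (or any size
#'   divisible by 16).
#' @return Object of class `pyramid_prediction`: list `probs` of S arrays
#'   `(n_classes, H, W, D)`, each voxel's class probabilities summing to 1.
#' @export
pyramid_forward <- function(params, patch) {
  dm <- dim(patch)
  if (any(dm %% 16L != 0L)) stop("patch dims must be divisible by 16")
  X <- matrix(as.numeric(patch), nrow = 1)
  r <- net_forward(params, X, c(dm, 1L), training = FALSE)
  C <- params$config$n_classes
  probs <- lapply(r$probs, function(P) array(P, c(C, dm)))
  structure(list(probs = probs), class = "pyramid_prediction")
}
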