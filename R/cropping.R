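#' Per-volume crop-start probability list
#'
#' For a labeled volume, marks every depth-axis start index `j` (0-based)
#' whose crop window `[j, j + window_depth)` contains strictly more than `k`
#' foreground voxels (labels 1 or 2, counted over the full H x W extent).
#' Start indices for which the window would overrun the volume get weight 0.
#'
#' @param labels A [label_volume()] (or integer 3D array).
#' @param window_depth Crop depth in voxels (<= D).
#' @param k Foreground-count threshold (window kept iff count > k).
#' @return Object of class `crop_probability_list` with fields `weights`
#'   (integer, length D, indexed by 0-based start `j` at position `j + 1`),
#'   `window_depth`, `k`.
#' @export
build_crop_list <- function(labels, window_depth, k = 50) {
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  D <- dim(arr)[3]
  window_depth <- as.integer(window_depth)
  if (window_depth > D) stop("window_depth exceeds volume depth")
  if (k < 0) stop("k must be >= 0")
  per_slice <- apply(arr > 0L, 3, sum)
  cs <- c(0, cumsum(per_slice))
  nvalid <- D - window_depth + 1L
  slab <- cs[(1:nvalid) + window_depth] - cs[1:nvalid]   # count in [j, j+wd), j = 0..D-wd
  weights <- integer(D)
  weights[seq_len(nvalid)] <- as.integer(slab > k)
  structure(list(weights = weights, window_depth = window_depth, k = k,
                 depth = D), class = "crop_probability_list")
}

#' Aggregate crop lists over labeled volumes
#'
#' Elementwise integer sum of per-volume crop lists; the result is the
#' sampling weight vector shared by labeled and unlabeled volumes during
#' training.
#'
#' @param lists List of [build_crop_list()] results sharing depth,
#'   window_depth and k.
#' @return Object of class `aggregate_crop_distribution` (same fields; the
#'   weights are counts, not just 0/1).
#' @export
aggregate_crop_lists <- function(lists) {
  if (length(lists) == 0) stop("cannot aggregate an empty list of crop lists")
  ref <- lists[[1]]
  w <- integer(ref$depth)
  for (l in lists) {
    if (!inherits(l, "crop_probability_list")) stop("inputs must be crop_probability_list")
    if (l$depth != ref$depth || l$window_depth != ref$window_depth || l$k != ref$k)
      stop("crop lists disagree on depth, window_depth or k")
    w <- w + l$weights
  }
  structure(list(weights = w, window_depth = ref$window_depth, k = ref$k,
                 depth = ref$depth), class = "aggregate_crop_distribution")
}

#' Sample a depth-axis crop start
#'
#' Draws a 0-based start index with probability proportional to the aggregate
#' weights. When all weights are zero (no labeled slab exceeds the
#' threshold), falls back to uniform sampling over all valid starts.
#'
#' @param dist An `aggregate_crop_distribution` (a single
#'   `crop_probability_list` is also accepted).
#' @param n Number of draws.
#' @return Integer vector of 0-based depth start indices.
#' @export
sample_crop_start <- function(dist, n = 1L) {
  valid_max <- dist$depth - dist$window_depth   # last valid 0-based start
  w <- dist$weights[seq_len(valid_max + 1L)]
  if (sum(w) == 0) {
    sample.int(valid_max + 1L, n, replace = TRUE) - 1L
  } else {
    sample.int(valid_max + 1L, n, replace = TRUE, prob = w) - 1L
  }
}

#' Extract a training patch
#'
#' Cuts the half-open window `[h0, h0+Ph) x [w0, w0+Pw) x [j, j+Pd)` from an
#' intensity volume (and, when given, the identically placed window from its
#' label volume). The depth start comes from [sample_crop_start()]; the H and
#' W starts are uniform random unless supplied.
#'
#' @param vol [intensity_volume()] (or 3D array).
#' @param labels Optional [label_volume()] (or array) on the same grid.
#' @param start_j 0-based depth start.
#' @param patch_size Integer (Ph, Pw, Pd).
#' @param h0,w0 Optional 0-based H/W starts; uniform random when NULL.
#' @return List with `patch` (array), `labels` (array or NULL), and the
#'   0-based `offsets` actually used.
#' @export
crop_patch <- function(vol, labels = NULL, start_j, patch_size, h0 = NULL, w0 = NULL) {
  arr <- if (inherits(vol, "intensity_volume")) vol$data else vol
  dm <- dim(arr)
  p <- as.integer(patch_size)
  if (any(p > dm)) stop("patch larger than volume")
  if (start_j < 0 || start_j + p[3] > dm[3]) stop("depth start out of range")
  if (is.null(h0)) h0 <- sample.int(dm[1] - p[1] + 1L, 1L) - 1L
  if (is.null(w0)) w0 <- sample.int(dm[2] - p[2] + 1L, 1L) - 1L
  hi <- (h0 + 1L):(h0 + p[1]); wi <- (w0 + 1L):(w0 + p[2]); di <- (start_j + 1L):(start_j + p[3])
  lab <- NULL
  if (!is.null(labels)) {
    larr <- if (inherits(labels, "label_volume")) labels$labels else labels
    if (!identical(dim(larr), dm)) stop("label shape differs from volume shape")
    lab <- larr[hi, wi, di, drop = FALSE]
  }
  list(patch = arr[hi, wi, di, drop = FALSE], labels = lab,
       offsets = c(h = h0, w = w0, d = start_j))
}

#' Random flip / in-plane rotation augmentation
#'
#' Applies the same random axis flips and 90-degree in-plane (H-W) rotations
#' to an image patch and its label patch. Rotations by 90/270 degrees are
#' only drawn when the patch is square in H and W.
#'
#' @param patch 3D array.
#' @param label_patch Optional matching 3D array.
#' @param moves Optional list `list(flips = logical(3), rot = k)` (k quarter
#'   turns); drawn at random when NULL. `moves = identity_moves()` is a no-op.
#' @return List `patch`, `labels`, `moves` (the draws actually applied).
#' @export
augment_flip_rotate <- function(patch, label_patch = NULL, moves = NULL) {
  dm <- dim(patch)
  if (is.null(moves)) {
    rots <- if (dm[1] == dm[2]) 0:3 else c(0L, 2L)
    moves <- list(flips = stats::runif(3) < 0.5, rot = sample(rots, 1L))
  }
  apply_one <- function(a) {
    if (is.null(a)) return(NULL)
    idx <- lapply(dim(a), seq_len)
    for (ax in 1:3) if (moves$flips[ax]) idx[[ax]] <- rev(idx[[ax]])
    a <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    r <- moves$rot %% 4L
    for (i in seq_len(r)) {  # one quarter turn in the H-W plane
      a <- aperm(a, c(2, 1, 3))
      a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    }
    a
  }
  list(patch = apply_one(patch), labels = apply_one(label_patch), moves = moves)
}

#' Identity augmentation draw
#' @return A `moves` list that makes [augment_flip_rotate()] a no-op.
#' @export
identity_moves <- function() list(flips = c(FALSE, FALSE, FALSE), rot = 0L)
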