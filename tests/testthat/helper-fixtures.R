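# Shared fixtures and independent oracles used across test files.

tiny_phantom <- function(seed = 1L, shape = c(64L, 64L, 48L)) {
  generate_phantom(phantom_config(shape = shape, seed = seed))
}

# Brute-force slab-counting oracle for the crop probability list: counts
# foreground voxels in every depth window directly.
brute_crop_list <- function(labels, window_depth, k) {
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  D <- dim(arr)[3]
  w <- integer(D)
  for (j in 0:(D - window_depth)) {
    cnt <- sum(arr[, , (j + 1):(j + window_depth)] > 0)
    w[j + 1] <- as.integer(cnt > k)
  }
  w
}

# A label cube fixture: 8^3 volume with a 4x4x4 foreground block at depth
# slices 3..6 (0-based depth index 2..5).
cube_labels <- function() {
  lab <- array(0L, c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 1L
  lab
}

# Random probability pyramids on the simplex.
random_probs <- function(S, C, V, seed = 1) {
  set.seed(seed)
  lapply(seq_len(S), function(s) {
    m <- matrix(stats::runif(C * V, 0.05, 1), C, V)
    sweep(m, 2, colSums(m), "/")
  })
}

# Uniform-intensity scene of a homogeneous slab with known extinction sigma:
# constant intensity mapped by a 2-point flat TF to a given opacity.
homogeneous_scene <- function(sigma, dims = c(16L, 16L, 16L), density_scale = 1) {
  opac <- sigma / density_scale
  stopifnot(opac <= 1)
  iv <- intensity_volume(array(0.5, dims))
  lv <- label_volume(array(1L, dims))
  nsv <- non_scalar_volume(iv, lv, label_importance = c(`0` = 1, `1` = 1, `2` = 1))
  pts <- data.frame(intensity = c(0, 1), opacity = c(opac, opac),
                    r = 1, g = 1, b = 1, smoothness = 0, phase_g = 0)
  tf <- transfer_function_2d(pts, suppressWarnings(importance_params(a = 4)),
                             density_scale = density_scale)
  render_scene(nsv, tf)
}

expect_identical_arrays <- function(a, b) expect_true(identical(as.numeric(a), as.numeric(b)))
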