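#' Pinhole camera
#'
#' @param position,look_at,up World-space vectors in mm; `position` must
#'   differ from `look_at`.
#' @param fov Vertical field of view in degrees, in (0, 180).
#' @param width,height Image size in pixels.
#' @return Object of class `camera`.
#' @export
camera <- function(position, look_at, up = c(0, 0, 1), fov = 45,
                   width = 128L, height = 128L) {
  if (all(position == look_at)) stop("camera position must differ from look_at")
  if (fov <= 0 || fov >= 180) stop("fov must be in (0, 180)")
  structure(list(position = as.numeric(position), look_at = as.numeric(look_at),
                 up = as.numeric(up), fov = fov,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera")
}

#' Renderer settings
#'
#' @param spp Samples per pixel (>= 1).
#' @param max_bounces Path length cap (>= 1); Russian roulette starts after
#'   bounce 3.
#' @param seed Base seed of the counter-based per-pixel RNG streams.
#' @param light_dir Direction TOWARD the directional light (world mm).
#' @param light_radiance RGB radiance of the directional light.
#' @param ambient Constant environment radiance collected by escaping rays.
#' @param grad_threshold Gradient magnitude at which the surface-ness weight
#'   saturates; NULL = the 60th percentile of the volume's gradient
#'   magnitudes, computed per scene.
#' @param exposure,gamma Tonemapping applied when resolving to 8-bit.
#' @param cell_size Macrocell edge length in voxels.
#' @return Object of class `render_settings`.
#' @export
render_settings <- function(spp = 32L, max_bounces = 8L, seed = 1L,
                            light_dir = c(1, 0.6, 1.2),
                            light_radiance = c(3.2, 3.1, 3.0),
                            ambient = c(0.10, 0.11, 0.13),
                            grad_threshold = NULL,
                            exposure = 1.0, gamma = 2.2, cell_size = 8L) {
  if (spp < 1) stop("spp must be >= 1")
  if (max_bounces < 1) stop("max_bounces must be >= 1")
  structure(list(spp = as.integer(spp), max_bounces = as.integer(max_bounces),
                 seed = as.integer(seed), light_dir = as.numeric(light_dir),
                 light_radiance = as.numeric(light_radiance),
                 ambient = as.numeric(ambient), grad_threshold = grad_threshold,
                 exposure = exposure, gamma = gamma,
                 cell_size = as.integer(cell_size)),
            class = "render_settings")
}

#' Renderable scene
#'
#' Pairs a [non_scalar_volume()] with a [transfer_function_2d()]. The mask
#' channel holds continuous importance inputs g; the transfer function's
#' label map is already folded in when the non-scalar volume is built.
#'
#' @param volume A [non_scalar_volume()].
#' @param tf A [transfer_function_2d()].
#' @return Object of class `render_scene`.
#' @export
render_scene <- function(volume, tf = default_tf()) {
  stopifnot(inherits(volume, "non_scalar_volume"), inherits(tf, "transfer_function_2d"))
  structure(list(volume = volume, tf = tf), class = "render_scene")
}

tf_points_matrix <- function(tf) {
  as.matrix(tf$points[, c("intensity", "opacity", "r", "g", "b", "smoothness", "phase_g")])
}

scene_arrays <- function(scene) {
  list(inten = as.numeric(scene$volume$intensity$data),
       mask = as.numeric(scene$volume$mask),
       dims = as.integer(dim(scene$volume$intensity$data)),
       spacing = as.numeric(scene$volume$intensity$spacing),
       pts = tf_points_matrix(scene$tf),
       a = scene$tf$importance$a,
       density = scene$tf$density_scale)
}

#' Build the macrocell majorant grid of a scene
#'
#' Each cell stores a conservative upper bound (majorant) on the extinction
#' of every point inside it, accounting for trilinear intensity
#' interpolation (one-voxel neighbourhood expansion) and for interior
#' control points of the piecewise-linear opacity map.
#'
#' @param scene A [render_scene()].
#' @param cell_size Cell edge in voxels (>= 1).
#' @return List: `majorants` (3D array), `n_cells`, `cell_size`, `cell_mm`,
#'   `global_majorant`.
#' @export
build_macrocell_grid <- function(scene, cell_size = 8L) {
  if (cell_size < 1) stop("cell_size must be >= 1")
  sa <- scene_arrays(scene)
  build_macrocell_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a,
                      sa$density, as.integer(cell_size))
}

#' Enumerate the macrocells pierced by a ray
#'
#' 3D digital-differential-analyzer traversal: cells are reported in
#' visitation order with contiguous, non-overlapping `[t_enter, t_exit)`
#' parameter intervals covering the ray-grid intersection.
#'
#' @param origin,dir Ray origin and direction (world mm; direction nonzero).
#' @param grid A grid from [build_macrocell_grid()].
#' @return Matrix with columns ix, iy, iz (0-based cell indices), t_enter,
#'   t_exit; zero rows when the ray misses the grid.
#' @export
dda_traverse <- function(origin, dir, grid) {
  dda_traverse_cpp(as.numeric(origin), as.numeric(dir),
                   as.integer(grid$n_cells), as.numeric(grid$cell_mm))
}

default_grad_threshold <- function(scene) {
  x <- scene$volume$intensity$data
  sp <- scene$volume$intensity$spacing
  dm <- dim(x)
  d1 <- (x[-1, , , drop = FALSE] - x[-dm[1], , , drop = FALSE]) / sp[1]
  d2 <- (x[, -1, , drop = FALSE] - x[, -dm[2], , drop = FALSE]) / sp[2]
  d3 <- (x[, , -1, drop = FALSE] - x[, , -dm[3], drop = FALSE]) / sp[3]
  n <- min(length(d1), length(d2), length(d3))
  gm <- sqrt(d1[seq_len(n)]^2 + d2[seq_len(n)]^2 + d3[seq_len(n)]^2)
  q <- stats::quantile(gm, 0.60, names = FALSE)
  max(q, 1e-8)
}

#' Progressive Monte Carlo rendering
#'
#' Accumulates `settings$spp` null-scattering path-traced samples per pixel
#' (optionally across several calls via `fb`); per-pixel, per-sample
#' counter-based RNG streams make the accumulation independent of pass
#' structure and bit-reproducible for a fixed seed.
#'
#' @param scene A [render_scene()].
#' @param cam A [camera()].
#' @param settings A [render_settings()].
#' @param fb Optional framebuffer from a previous pass to continue.
#' @return Object of class `framebuffer`: `accum` (H x W x 3 linear radiance
#'   sums), `spp` (samples accumulated), plus the settings for resolving.
#' @export
render_progressive <- function(scene, cam, settings = render_settings(), fb = NULL) {
  sa <- scene_arrays(scene)
  gt <- if (is.null(settings$grad_threshold)) default_grad_threshold(scene)
        else settings$grad_threshold
  spp_start <- if (is.null(fb)) 0L else fb$spp
  acc <- render_pt_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a,
                       sa$density, settings$cell_size,
                       cam$position, cam$look_at, cam$up, cam$fov,
                       cam$width, cam$height,
                       settings$light_dir, settings$light_radiance,
                       settings$ambient, gt, settings$max_bounces,
                       settings$spp, spp_start, settings$seed)
  if (!is.null(fb)) acc <- acc + fb$accum
  stopifnot(all(is.finite(acc)), all(acc >= 0))
  structure(list(accum = acc, spp = spp_start + settings$spp,
                 exposure = settings$exposure, gamma = settings$gamma),
            class = "framebuffer")
}

#' Resolve a framebuffer to a displayable image
#'
#' Averages the accumulated radiance, applies exposure and gamma, and clamps
#' to \[0, 1\].
#'
#' @param fb A `framebuffer` from [render_progressive()].
#' @param exposure,gamma Overrides; default from the framebuffer.
#' @return H x W x 3 array in \[0, 1\].
#' @export
resolve_framebuffer <- function(fb, exposure = fb$exposure, gamma = fb$gamma) {
  img <- fb$accum / fb$spp * exposure
  pmin(pmax(img, 0), 1)^(1 / gamma)
}

#' Deterministic emission-absorption ray-march oracle
#'
#' Front-to-back alpha compositing with the same transfer function and
#' importance modulation as the path tracer but no scattering: a fast,
#' noise-free reference for silhouettes and importance behaviour.
#'
#' @param scene A [render_scene()].
#' @param cam A [camera()].
#' @param step March step in mm (> 0).
#' @param settings A [render_settings()] (light/ambient are used; sampling
#'   settings are ignored).
#' @return H x W x 3 array of linear radiance.
#' @export
reference_ray_march <- function(scene, cam, step = 0.5, settings = render_settings()) {
  if (step <= 0) stop("step must be > 0")
  sa <- scene_arrays(scene)
  render_rm_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a, sa$density,
                cam$position, cam$look_at, cam$up, cam$fov, cam$width, cam$height,
                settings$light_dir, settings$light_radiance, settings$ambient, step)
}

#' Write an image to PNG or PPM
#'
#' @param img H x W x 3 array in \[0, 1\] (e.g. from [resolve_framebuffer()];
#'   linear radiance images should be resolved/clamped first).
#' @param path Output path; `.png` or `.ppm` (plain-text P3).
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, target = path)
  } else if (grepl("\\.ppm$", path, ignore.case = TRUE)) {
    q <- round(img * 255)
    h <- dim(img)[1]; w <- dim(img)[2]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    for (i in seq_len(h))
      writeLines(paste(as.integer(t(cbind(q[i, , 1], q[i, , 2], q[i, , 3]))),
                       collapse = " "), con)
  } else stop("unsupported image extension (use .png or .ppm): ", path)
  invisible(path)
}

#' Default camera framing a volume
#'
#' Places the camera on a diagonal outside the volume, looking at its
#' centre.
#'
#' @param volume A [non_scalar_volume()] (or [intensity_volume()]).
#' @param width,height Image size in pixels.
#' @param distance_scale Camera distance as a multiple of the largest extent.
#' @return A [camera()].
#' @export
default_camera <- function(volume, width = 128L, height = 128L, distance_scale = 1.8) {
  iv <- if (inherits(volume, "non_scalar_volume")) volume$intensity else volume
  ext <- dim(iv$data) * iv$spacing
  ctr <- ext / 2
  pos <- ctr + distance_scale * max(ext) * c(1.0, 0.7, 0.45) / sqrt(sum(c(1, 0.7, 0.45)^2))
  camera(position = pos, look_at = ctr, up = c(0, 0, 1),
         width = width, height = height)
}

#' Free-flight distance sampling experiment
#'
#' Draws null-scattering free-flight distances for rays entering the scene
#' at `origin` along `dir`; returns the collision distance in mm, or `Inf`
#' for rays that escape. Used to check the exponential free-path law and
#' Beer-Lambert escape probabilities.
#'
#' @param scene A [render_scene()].
#' @param origin,dir Ray origin/direction (world mm).
#' @param n Number of rays.
#' @param seed RNG seed.
#' @param cell_size Macrocell size in voxels.
#' @return Numeric vector of length n.
#' @export
sample_free_flight <- function(scene, origin, dir, n = 10000L, seed = 1L,
                               cell_size = 8L) {
  sa <- scene_arrays(scene)
  free_flight_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a, sa$density,
                  as.integer(cell_size), as.numeric(origin), as.numeric(dir),
                  as.integer(n), as.integer(seed))
}

#' Henyey-Greenstein direction sampling experiment
#'
#' @param g Asymmetry parameter in (-1, 1); the mean sampled cosine equals g.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Sampled cosines relative to the incoming direction.
#' @export
sample_hg_cosines <- function(g, n = 10000L, seed = 1L) {
  hg_sample_cpp(g, as.integer(n), as.integer(seed))
}

#' Ratio-tracking transmittance estimates along a ray
#'
#' @param scene A [render_scene()].
#' @param origin,dir Ray origin/direction (world mm).
#' @param n Number of independent estimates.
#' @param seed RNG seed.
#' @param cell_size Macrocell size in voxels.
#' @return Numeric vector of unbiased transmittance estimates.
#' @export
estimate_transmittance <- function(scene, origin, dir, n = 10000L, seed = 1L,
                                   cell_size = 8L) {
  sa <- scene_arrays(scene)
  transmittance_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a, sa$density,
                    as.integer(cell_size), as.numeric(origin), as.numeric(dir),
                    as.integer(n), as.integer(seed))
}

#' Sample scattering events at a point
#'
#' Draws hybrid shading events at a world position: the local gradient
#' decides stochastically between the surface branch (cosine-power lobe
#' around the gradient normal, sharpness from the material smoothness) and
#' the volumetric branch (Henyey-Greenstein around the incoming direction);
#' the returned throughput is the single-scattering albedo at the point.
#'
#' @param scene A [render_scene()].
#' @param x World position in mm.
#' @param dir Incoming propagation direction.
#' @param n Number of events to draw.
#' @param seed RNG seed.
#' @param grad_threshold Surface-ness saturation threshold; NULL = the
#'   scene default (60th percentile of gradient magnitudes).
#' @return List: `dir` (n x 3 outgoing directions), `throughput` (n x 3 RGB),
#'   `branch` (0 = volumetric, 1 = surface).
#' @export
shade_event <- function(scene, x, dir, n = 1L, seed = 1L, grad_threshold = NULL) {
  sa <- scene_arrays(scene)
  gt <- if (is.null(grad_threshold)) default_grad_threshold(scene) else grad_threshold
  shade_event_cpp(sa$inten, sa$mask, sa$dims, sa$spacing, sa$pts, sa$a, sa$density,
                  as.numeric(x), as.numeric(dir), gt, as.integer(n), as.integer(seed))
}
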