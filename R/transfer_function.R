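#' Material attributes
#'
#' The optical attributes a voxel maps to under the transfer function:
#' opacity (converted to extinction by the renderer's density scale), RGB
#' single-scattering albedo, surface smoothness in \[0,1\], and the
#' Henyey-Greenstein phase asymmetry in (-1,1).
#'
#' @param opacity Opacity in \[0, 1\].
#' @param albedo RGB vector, each channel in \[0, 1\].
#' @param smoothness Smoothness in \[0, 1\] (1 = mirror-like surface response).
#' @param phase_g HG asymmetry in (-1, 1).
#' @return Object of class `material`.
#' @export
material <- function(opacity, albedo = c(1, 1, 1), smoothness = 0, phase_g = 0) {
  if (opacity < 0 || opacity > 1) stop("opacity must be in [0,1]")
  if (length(albedo) != 3 || any(albedo < 0) || any(albedo > 1)) stop("albedo must be RGB in [0,1]")
  if (smoothness < 0 || smoothness > 1) stop("smoothness must be in [0,1]")
  if (phase_g <= -1 || phase_g >= 1) stop("phase_g must be in (-1,1)")
  structure(list(opacity = opacity, albedo = as.numeric(albedo),
                 smoothness = smoothness, phase_g = phase_g), class = "material")
}

#' Importance transfer function
#'
#' Maps a mask value \eqn{g} (in \eqn{[0,1]}) to an importance value
#' \deqn{I(g; a) = \frac{(1 - e^{-ag})(1 + e^{-a})}{(1 + e^{-ag})(1 - e^{-a})}
#'              = \frac{\tanh(ag/2)}{\tanh(a/2)},}
#' a normalized sigmoid with I(0) = 0 and I(1) = 1, strictly increasing in g.
#' The precision parameter `a > 0` controls how sharply low-importance
#' regions are suppressed: as a grows, intermediate g are pushed toward 1,
#' concentrating visual contrast in the truly unimportant (g near 0)
#' regions; as a tends to 0 the map degrades to the identity I = g. Values
#' a > 1 give the intended sharpening; smaller values are allowed but warn.
#'
#' @param g Mask value(s) in \[0, 1\] (vectorized).
#' @param a Precision parameter, > 0.
#' @return Importance value(s) in \[0, 1\].
#' @export
importance_value <- function(g, a) {
  if (a <= 0) stop("precision parameter a must be > 0")
  if (any(g < 0 | g > 1)) stop("g must lie in [0,1]")
  (1 - exp(-a * g)) * (1 + exp(-a)) / ((1 + exp(-a * g)) * (1 - exp(-a)))
}

#' Importance parameters
#'
#' @param a Precision parameter (> 0; values <= 1 warn, since the intended
#'   sharpening behaviour needs a > 1).
#' @param label_importance Named numeric mapping discrete labels "0","1","2"
#'   to mask values g in \[0, 1\]. Defaults: background 0.15, tumor 1.0,
#'   SNFH 0.6.
#' @return Object of class `importance_params`.
#' @export
importance_params <- function(a = 4,
                              label_importance = c(`0` = 0.15, `1` = 1.0, `2` = 0.6)) {
  if (a <= 0) stop("a must be > 0")
  if (a <= 1) warning("a <= 1 gives little sharpening; a > 1 recommended")
  if (any(label_importance < 0) || any(label_importance > 1))
    stop("label importance values must lie in [0,1]")
  structure(list(a = a, label_importance = label_importance),
            class = "importance_params")
}

#' Modulate a material by an importance value
#'
#' Opacity, smoothness and every albedo channel are multiplied by I; the
#' phase asymmetry is left untouched. With I = 1 the material is unchanged;
#' with I = 0 the region becomes invisible.
#'
#' @param base A [material()].
#' @param I Importance value in \[0, 1\].
#' @return Modulated [material()].
#' @export
modulate_material <- function(base, I) {
  if (I < 0 || I > 1) stop("I must be in [0,1]")
  material(opacity = base$opacity * I, albedo = base$albedo * I,
           smoothness = base$smoothness * I, phase_g = base$phase_g)
}

#' 2D transfer function (intensity x importance)
#'
#' The first dimension is a piecewise-linear map from normalized intensity
#' to a base material (control points sorted by intensity; intensities
#' outside the covered range are clamped to the endpoints). The second
#' dimension is the importance transfer function applied to the mask value.
#' `density_scale` converts opacity to extinction (units 1/mm) for the
#' renderer.
#'
#' @param points Data frame with columns `intensity`, `opacity`, `r`, `g`,
#'   `b`, `smoothness`, `phase_g`; >= 2 rows.
#' @param importance An [importance_params()].
#' @param density_scale Extinction per unit opacity, 1/mm.
#' @return Object of class `transfer_function_2d`.
#' @export
transfer_function_2d <- function(points, importance = importance_params(),
                                 density_scale = 0.25) {
  req <- c("intensity", "opacity", "r", "g", "b", "smoothness", "phase_g")
  if (!all(req %in% names(points))) stop("points must have columns: ", paste(req, collapse = ", "))
  if (nrow(points) < 2) stop("need at least 2 control points")
  points <- points[order(points$intensity), , drop = FALSE]
  if (density_scale <= 0) stop("density_scale must be > 0")
  structure(list(points = points, importance = importance,
                 density_scale = density_scale), class = "transfer_function_2d")
}

#' Default transfer function for normalized (zero-mean unit-variance) volumes
#'
#' Low intensities (air / CSF) are transparent; tissue ramps up in opacity
#' with a warm albedo; hyperintense voxels become bright and slightly glossy.
#'
#' @param importance An [importance_params()].
#' @param density_scale Extinction per unit opacity, 1/mm.
#' @return A [transfer_function_2d()].
#' @export
default_tf <- function(importance = importance_params(), density_scale = 0.25) {
  pts <- data.frame(
    intensity  = c(-2.0, -0.5,  0.3,  1.2,  2.5),
    opacity    = c( 0.0,  0.02, 0.35, 0.75, 0.95),
    r          = c( 0.2,  0.45, 0.85, 0.95, 1.0),
    g          = c( 0.2,  0.40, 0.65, 0.75, 0.95),
    b          = c( 0.25, 0.40, 0.55, 0.55, 0.8),
    smoothness = c( 0.0,  0.05, 0.3,  0.55, 0.7),
    phase_g    = c( 0.0,  0.2,  0.4,  0.5,  0.5))
  transfer_function_2d(pts, importance, density_scale)
}

# Piecewise-linear lookup of the base material at a (clamped) intensity.
interp_base_material <- function(tf, intensity) {
  p <- tf$points
  x <- pmin(pmax(intensity, p$intensity[1]), p$intensity[nrow(p)])
  cols <- c("opacity", "r", "g", "b", "smoothness", "phase_g")
  vals <- vapply(cols, function(cn) stats::approx(p$intensity, p[[cn]], xout = x,
                                                  ties = "ordered")$y, numeric(length(x)))
  if (length(x) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, cols))
  vals
}

#' Evaluate the 2D transfer function at one voxel value
#'
#' Looks up the base material at the intensity, converts the voxel's mask
#' label to g via the importance map, and modulates the material by
#' I = importance_value(g, a).
#'
#' @param intensity Normalized intensity (scalar).
#' @param mask_label Discrete label in {0,1,2}, or a continuous mask value g
#'   in \[0,1\] when `continuous = TRUE`.
#' @param tf A [transfer_function_2d()].
#' @param continuous Interpret `mask_label` as g directly.
#' @return A [material()].
#' @export
evaluate_tf <- function(intensity, mask_label, tf, continuous = FALSE) {
  m <- interp_base_material(tf, intensity)[1, ]
  base <- material(opacity = m[["opacity"]], albedo = m[c("r", "g", "b")],
                   smoothness = m[["smoothness"]],
                   phase_g = min(max(m[["phase_g"]], -0.999), 0.999))
  g <- if (continuous) mask_label else {
    gi <- tf$importance$label_importance[as.character(mask_label)]
    if (is.na(gi)) stop("label ", mask_label, " not in importance map")
    gi
  }
  modulate_material(base, importance_value(as.numeric(g), tf$importance$a))
}

#' Serialize / load a transfer function as JSON
#' @param tf A [transfer_function_2d()].
#' @param path Output (input) path.
#' @return `write_tf`: invisibly `path`; `read_tf`: the transfer function.
#' @export
write_tf <- function(tf, path) {
  jsonlite::write_json(list(points = tf$points,
                            importance = list(a = tf$importance$a,
                                              labels = as.list(tf$importance$label_importance)),
                            density_scale = tf$density_scale),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tf
#' @export
read_tf <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  li <- unlist(j$importance$labels)
  imp <- suppressWarnings(importance_params(a = j$importance$a, label_importance = li))
  transfer_function_2d(as.data.frame(j$points), imp, j$density_scale)
}
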