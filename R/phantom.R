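#' Phantom configuration
#'
#' Parameters of the synthetic brain phantom: a smooth ellipsoidal "brain"
#' with a textured interior, one or more superellipsoidal tumor blobs and a
#' hyperintense shell (SNFH-like ring) around each tumor. Intensity means are
#' chosen so that the tumor and brain histograms overlap substantially, the
#' situation that makes purely intensity-based transfer functions fail and
#' motivates mask-aware rendering.
#'
#' @param shape Volume dimensions (H, W, D) in voxels; each >= 8.
#' @param spacing Voxel size in mm.
#' @param brain_semiaxes Ellipsoid semi-axes as fractions of the half-shape.
#' @param n_lesions Number of tumor blobs.
#' @param lesion_radius_range Min/max tumor semi-axis in voxels.
#' @param lesion_exponent_range Superellipsoid exponent range (2 = ellipsoid).
#' @param shell_thickness Thickness of the hyperintense ring in voxels.
#' @param tumor_mean,tumor_sd Tumor intensity mean and extra jitter sd.
#' @param shell_mean,shell_sd Shell (SNFH) intensity mean and jitter sd.
#' @param brain_mean,brain_sd Brain tissue mean and texture field sd.
#' @param noise_sd Additive voxelwise noise sd.
#' @param noise_type `"gaussian"` (default) or `"rician"`.
#' @param texture_smoothness Gaussian blur sigma (voxels) of the background
#'   random field; larger = smoother tissue texture.
#' @param seed RNG seed; the phantom is a deterministic function of the config.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 48),
                           spacing = c(1, 1, 1),
                           brain_semiaxes = c(0.85, 0.8, 0.78),
                           n_lesions = 1L,
                           lesion_radius_range = c(4, 7.5),
                           lesion_exponent_range = c(2, 4),
                           shell_thickness = 2.5,
                           tumor_mean = 1.35, tumor_sd = 0.05,
                           shell_mean = 1.75, shell_sd = 0.05,
                           brain_mean = 1.0, brain_sd = 0.15,
                           noise_sd = 0.06,
                           noise_type = c("gaussian", "rician"),
                           texture_smoothness = 2.0,
                           seed = 1L) {
  noise_type <- match.arg(noise_type)
  if (any(shape < 8)) stop("shape components must be >= 8")
  if (any(c(tumor_sd, shell_sd, brain_sd, noise_sd) < 0)) stop("sds must be >= 0")
  if (lesion_radius_range[1] > lesion_radius_range[2]) stop("bad radius range")
  max_r <- lesion_radius_range[2] + shell_thickness
  if (max_r >= min(brain_semiaxes * shape / 2)) stop("lesion radius does not fit inside brain")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 brain_semiaxes = brain_semiaxes, n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 lesion_exponent_range = lesion_exponent_range,
                 shell_thickness = shell_thickness,
                 tumor_mean = tumor_mean, tumor_sd = tumor_sd,
                 shell_mean = shell_mean, shell_sd = shell_sd,
                 brain_mean = brain_mean, brain_sd = brain_sd,
                 noise_sd = noise_sd, noise_type = noise_type,
                 texture_smoothness = texture_smoothness, seed = as.integer(seed)),
            class = "phantom_config")
}

# Separable Gaussian blur of a 3D array via per-axis Toeplitz multiplication.
gauss_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  blur_axis1 <- function(a) {
    n <- dim(a)[1]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n); j <- pmin(pmax(i + o, 1L), n)  # clamp at borders
      K[cbind(i, j)] <- K[cbind(i, j)] + k[o + r + 1]
    }
    array(K %*% matrix(a, n), dim = dim(a))
  }
  x <- blur_axis1(x)
  x <- aperm(blur_axis1(aperm(x, c(2, 1, 3))), c(2, 1, 3))
  aperm(blur_axis1(aperm(x, c(3, 2, 1))), c(3, 2, 1))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Implicit superellipsoid membership: sum |R'(x-c)/a|^n <= 1.
superellipsoid_mask <- function(shape, center, semiaxes, rot, expo) {
  h <- seq_len(shape[1]); w <- seq_len(shape[2]); d <- seq_len(shape[3])
  g <- as.matrix(expand.grid(h = h, w = w, d = d))
  u <- sweep(g, 2, center) %*% rot
  v <- abs(sweep(u, 2, semiaxes, "/"))^expo
  array(rowSums(v) <= 1, dim = shape)
}

#' Generate a synthetic brain phantom
#'
#' Produces a paired intensity/label volume according to a [phantom_config()].
#' Tumor voxels get label 1, the surrounding shell label 2; both lie strictly
#' inside the brain ellipsoid. The intensity is a smoothed random field plus
#' per-class mean offsets plus voxelwise noise, so tumor and healthy-tissue
#' intensity histograms overlap.
#'
#' @param config A [phantom_config()].
#' @return List with elements `intensity` ([intensity_volume()]) and
#'   `labels` ([label_volume()]).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shp <- config$shape
  center <- (shp + 1) / 2
  semi <- config$brain_semiaxes * shp / 2

  h <- seq_len(shp[1]); w <- seq_len(shp[2]); d <- seq_len(shp[3])
  ell <- outer(outer(((h - center[1]) / semi[1])^2, ((w - center[2]) / semi[2])^2, "+"),
               ((d - center[3]) / semi[3])^2, "+")
  brain <- ell <= 1

  field <- array(stats::rnorm(prod(shp)), dim = shp)
  field <- gauss_blur3(field, config$texture_smoothness)
  sdf <- stats::sd(as.numeric(field))
  if (sdf > 0) field <- field / sdf * config$brain_sd

  labels <- array(0L, dim = shp)
  margin_fit <- function(c0, a_out) {
    # require the enlarged (shell) superellipsoid's bounding sphere inside the brain
    sum(((c0 - center) / (semi - max(a_out)))^2) <= 1 && all(semi > max(a_out))
  }
  for (i in seq_len(config$n_lesions)) {
    placed <- FALSE
    for (try in 1:200) {
      a <- stats::runif(3, config$lesion_radius_range[1], config$lesion_radius_range[2])
      expo <- stats::runif(1, config$lesion_exponent_range[1], config$lesion_exponent_range[2])
      rot <- random_rotation()
      c0 <- center + (stats::runif(3, -1, 1) * (semi - max(a) - config$shell_thickness - 1))
      if (!margin_fit(c0, a + config$shell_thickness + 1)) next
      tum <- superellipsoid_mask(shp, c0, a, rot, expo)
      if (!any(tum)) next
      shell <- superellipsoid_mask(shp, c0, a + config$shell_thickness, rot, expo) & !tum
      labels[shell & brain & labels == 0L] <- 2L
      labels[tum] <- 1L
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place lesion ", i, " inside the brain")
  }

  intens <- array(0, dim = shp)
  intens[brain] <- config$brain_mean + field[brain]
  t1 <- labels == 1L; t2 <- labels == 2L
  intens[t1] <- config$tumor_mean + field[t1] +
    stats::rnorm(sum(t1), 0, config$tumor_sd)
  intens[t2] <- config$shell_mean + field[t2] +
    stats::rnorm(sum(t2), 0, config$shell_sd)
  if (config$noise_sd > 0) {
    if (config$noise_type == "gaussian") {
      intens <- intens + array(stats::rnorm(prod(shp), 0, config$noise_sd), dim = shp)
    } else {
      # Rician: magnitude of the complex signal under iid Gaussian channel noise
      re <- intens + stats::rnorm(prod(shp), 0, config$noise_sd)
      im <- stats::rnorm(prod(shp), 0, config$noise_sd)
      intens <- array(sqrt(re^2 + im^2), dim = shp)
    }
  }

  list(intensity = intensity_volume(intens, spacing = config$spacing),
       labels = label_volume(labels, spacing = config$spacing))
}

#' Histogram overlap coefficient between two samples
#'
#' Shared-bin overlap coefficient: sum over bins of the minimum of the two
#' relative frequencies. Used to verify that tumor and brain intensities
#' genuinely overlap in generated phantoms.
#'
#' @param a,b Numeric vectors.
#' @param nbins Number of shared histogram bins.
#' @return Overlap coefficient in \[0, 1\].
#' @export
histogram_overlap <- function(a, b, nbins = 50) {
  rng <- range(c(a, b))
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  ha <- graphics::hist(a, breaks = brk, plot = FALSE)$counts / length(a)
  hb <- graphics::hist(b, breaks = brk, plot = FALSE)$counts / length(b)
  sum(pmin(ha, hb))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_labeled` intensity/label NIfTI pairs and `n_unlabeled` intensity
#' volumes (their labels are withheld, emulating unannotated scans) plus a
#' JSON manifest describing the split.
#'
#' @param n_labeled,n_unlabeled Number of labeled / unlabeled volumes.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-volume seeds are derived deterministically.
#' @param config Base [phantom_config()]; its seed field is overridden per volume.
#' @return The manifest as a list (classes `dataset_manifest`): fields
#'   `labeled` (list of `list(image=, labels=)`), `unlabeled` (paths),
#'   `n_labeled`, `n_unlabeled`.
#' @export
generate_dataset <- function(n_labeled, n_unlabeled, out_dir, seed = 1L,
                             config = phantom_config()) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- n_labeled + n_unlabeled
  sub_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
  labeled <- list(); unlabeled <- character(0)
  for (i in seq_len(n_labeled)) {
    cfg <- config; cfg$seed <- sub_seeds[i]
    ph <- generate_phantom(cfg)
    ip <- file.path(out_dir, sprintf("img_%03d.nii.gz", i))
    lp <- file.path(out_dir, sprintf("lab_%03d.nii.gz", i))
    write_nifti(ph$intensity, ip); write_nifti(ph$labels, lp)
    labeled[[i]] <- list(image = ip, labels = lp)
  }
  for (i in seq_len(n_unlabeled)) {
    cfg <- config; cfg$seed <- sub_seeds[n_labeled + i]
    ph <- generate_phantom(cfg)
    ip <- file.path(out_dir, sprintf("uimg_%03d.nii.gz", i))
    write_nifti(ph$intensity, ip)
    unlabeled <- c(unlabeled, ip)
  }
  manifest <- structure(list(labeled = labeled, unlabeled = as.list(unlabeled),
                             n_labeled = n_labeled, n_unlabeled = n_unlabeled),
                        class = "dataset_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param path Path to `manifest.json` or the directory containing it.
#' @return A `dataset_manifest` list.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path)
  m$n_labeled <- as.integer(m$n_labeled); m$n_unlabeled <- as.integer(m$n_unlabeled)
  structure(m, class = "dataset_manifest")
}
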