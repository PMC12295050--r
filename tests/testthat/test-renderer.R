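test_that("macrocell majorants are conservative upper bounds", {
  ph <- tiny_phantom(seed = 2, shape = c(32L, 32L, 32L))
  nsv <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
  sc <- render_scene(nsv, default_tf())
  grid <- build_macrocell_grid(sc, cell_size = 4L)
  x <- nsv$intensity$data
  dm <- dim(x)
  # brute-force: per-voxel extinction from the TF, compared against its cell
  sig <- array(0, dm)
  for (lab in 0:2) {
    sel <- ph$labels$labels == lab
    vals <- x[sel]
    g <- sc$tf$importance$label_importance[as.character(lab)]
    I <- importance_value(g, sc$tf$importance$a)
    op <- segvis3d:::interp_base_material(sc$tf, vals)[, "opacity"]
    sig[sel] <- op * I * sc$tf$density_scale
  }
  cells <- grid$n_cells
  ok <- TRUE
  for (i in 0:(cells[1] - 1)) for (j in 0:(cells[2] - 1)) for (k in 0:(cells[3] - 1)) {
    hi <- (i * 4 + 1):min((i + 1) * 4, dm[1])
    wi <- (j * 4 + 1):min((j + 1) * 4, dm[2])
    di <- (k * 4 + 1):min((k + 1) * 4, dm[3])
    ok <- ok && max(sig[hi, wi, di]) <= grid$majorants[i + 1, j + 1, k + 1] + 1e-12
  }
  expect_true(ok)
  # homogeneous volume: every majorant equals the single extinction value
  hs <- homogeneous_scene(sigma = 0.5)
  gh <- build_macrocell_grid(hs, 4L)
  expect_lt(max(abs(gh$majorants - 0.5)), 1e-12)
  # one cell spanning the whole volume holds the global max
  g1 <- build_macrocell_grid(sc, cell_size = 32L)
  expect_equal(length(g1$majorants), 1L)
  expect_equal(as.numeric(g1$majorants[1]), grid$global_majorant,
               tolerance = 1e-12)
})

test_that("DDA traversal matches geometry and a dense-sampling oracle", {
  hs <- homogeneous_scene(0.2, dims = c(16L, 16L, 16L))
  grid <- build_macrocell_grid(hs, 4L)   # 4x4x4 cells of 4 mm
  tr <- dda_traverse(c(-3, 6.1, 6.1), c(1, 0, 0), grid)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr[, "ix"], 0:3, ignore_attr = TRUE)
  expect_true(all(tr[, "iy"] == 1L) && all(tr[, "iz"] == 1L))
  # contiguous non-overlapping intervals
  expect_equal(tr[-1, "t_enter"], tr[-4, "t_exit"], ignore_attr = TRUE)
  # miss
  expect_equal(nrow(dda_traverse(c(-3, 50, 50), c(1, 0, 0), grid)), 0L)
  expect_error(dda_traverse(c(0, 0, 0), c(0, 0, 0), grid), "nonzero")

  # dense-sampling oracle on random rays
  set.seed(9)
  ext <- 16
  for (r in 1:100) {
    o <- runif(3, -20, 36)
    d <- rnorm(3); if (all(d == 0)) d <- c(1, 0, 0); d <- d / sqrt(sum(d^2))
    got <- dda_traverse(o, d, grid)
    # oracle: sample the ray densely, record entered cells in order; runs
    # shorter than the comparison cutoff (grazing corners) are dropped on
    # both sides
    cutoff <- 6e-3
    tt <- seq(0, 80, by = 1e-3)
    p <- cbind(o[1] + tt * d[1], o[2] + tt * d[2], o[3] + tt * d[3])
    inside <- p[, 1] >= 0 & p[, 1] < ext & p[, 2] >= 0 & p[, 2] < ext &
              p[, 3] >= 0 & p[, 3] < ext
    cid <- floor(p[inside, , drop = FALSE] / 4)
    key <- cid[, 1] + 4 * cid[, 2] + 16 * cid[, 3]
    runs <- rle(as.numeric(key))
    oracle <- runs$values[runs$lengths * 1e-3 > cutoff]
    keep <- got[, "t_exit"] - got[, "t_enter"] > cutoff
    gotkey <- (got[, "ix"] + 4 * got[, "iy"] + 16 * got[, "iz"])[keep]
    expect_equal(as.numeric(gotkey), as.numeric(oracle), tolerance = 0)
  }
})

test_that("free-flight sampling follows exponential statistics", {
  # zero extinction: everything escapes
  empty <- homogeneous_scene(0)
  t0 <- sample_free_flight(empty, c(-1, 8, 8), c(1, 0, 0), n = 200, seed = 1)
  expect_true(all(is.infinite(t0)))

  # homogeneous sigma: free paths exponential(sigma), censored at the exit
  sigma <- 0.5
  hs <- homogeneous_scene(sigma)
  tt <- sample_free_flight(hs, c(-1e-7, 8, 8), c(1, 0, 0), n = 1e4, seed = 2)
  inside <- tt[is.finite(tt)]
  # escape frequency matches Beer-Lambert through d = 16 mm
  p_esc <- mean(is.infinite(tt))
  p_true <- exp(-sigma * 16)
  se <- sqrt(p_true * (1 - p_true) / 1e4)
  expect_lt(abs(p_esc - p_true), 3 * se + 1e-4)
  # conditional mean of a censored exponential
  d <- 16
  m_true <- (1 / sigma) - d * exp(-sigma * d) / (1 - exp(-sigma * d))
  se_m <- sd(inside) / sqrt(length(inside))
  expect_lt(abs(mean(inside) - m_true), 3 * se_m)
})

test_that("Henyey-Greenstein sampling has the right moments", {
  iso <- sample_hg_cosines(0, n = 1e4, seed = 3)
  ks <- suppressWarnings(ks.test(iso, "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)              # g = 0 is isotropic in cos(theta)
  for (g in c(0.6, -0.3)) {
    ct <- sample_hg_cosines(g, n = 1e4, seed = 4)
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)    # first moment of HG equals g
    expect_true(all(ct >= -1 & ct <= 1))
  }
})

test_that("ratio-tracked transmittance is unbiased on closed-form media", {
  sigma <- 0.3
  hs <- homogeneous_scene(sigma)
  est <- estimate_transmittance(hs, c(-1e-7, 8, 8), c(1, 0, 0), n = 1e4, seed = 5)
  t_true <- exp(-sigma * 16)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - t_true), 3 * se + 1e-6)

  # linear ramp along x: sigma(x) = 0.5 * x / 16, integrated optical depth 4
  dims <- c(16L, 16L, 16L)
  ramp <- array(rep((0:15) / 15, times = 16 * 16), dims)  # h-axis ramp
  iv <- intensity_volume(ramp)
  lv <- label_volume(array(1L, dims))
  nsv <- non_scalar_volume(iv, lv, label_importance = c(`0` = 1, `1` = 1, `2` = 1))
  pts <- data.frame(intensity = c(0, 1), opacity = c(0, 1),
                    r = 1, g = 1, b = 1, smoothness = 0, phase_g = 0)
  tf <- transfer_function_2d(pts, suppressWarnings(importance_params(a = 4)),
                             density_scale = 0.5)
  rs <- render_scene(nsv, tf)
  est2 <- estimate_transmittance(rs, c(-1e-7, 8, 8), c(1, 0, 0), n = 2e4, seed = 6)
  # true optical depth: integral of 0.5 * clamped trilinear ramp over [0,16]
  f <- function(x) 0.5 * pmin(pmax((x / 1 - 0.5) / 15, 0), 1)
  tau <- integrate(f, 0, 16)$value
  se2 <- sd(est2) / sqrt(length(est2))
  expect_lt(abs(mean(est2) - exp(-tau)), 3 * se2 + 1e-6)
})

test_that("macrocell acceleration does not change the rendered estimate", {
  ph <- tiny_phantom(seed = 4, shape = c(32L, 32L, 32L))
  nsv <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
  sc <- render_scene(nsv, default_tf())
  cam <- default_camera(nsv, 24, 24)
  f_small <- render_progressive(sc, cam, render_settings(spp = 24, seed = 9, cell_size = 4L))
  f_global <- render_progressive(sc, cam, render_settings(spp = 24, seed = 10, cell_size = 32L))
  a <- f_small$accum / f_small$spp
  b <- f_global$accum / f_global$spp
  # same estimator mean within Monte Carlo noise: paired t-test on pixels
  tt <- t.test(as.numeric(a), as.numeric(b), paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})

test_that("path-traced radiance is finite, non-negative and energy-sane", {
  ph <- tiny_phantom(seed = 5, shape = c(32L, 32L, 32L))
  nsv <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
  sc <- render_scene(nsv, default_tf())
  cam <- default_camera(nsv, 32, 32)
  st <- render_settings(spp = 16, seed = 2)
  fb <- render_progressive(sc, cam, st)
  img <- fb$accum / fb$spp
  expect_true(all(is.finite(img)) && all(img >= 0))
  # empty volume: every pixel is exactly the ambient term
  empty <- homogeneous_scene(0)
  came <- default_camera(empty$volume, 16, 16)
  fbe <- render_progressive(empty, came, st)
  ime <- fbe$accum / fbe$spp
  for (ch in 1:3) expect_lt(max(abs(ime[, , ch] - st$ambient[ch])), 1e-12)
})

test_that("progressive accumulation is order-independent and seed-reproducible", {
  ph <- tiny_phantom(seed = 6, shape = c(32L, 32L, 32L))
  nsv <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
  sc <- render_scene(nsv, default_tf())
  cam <- default_camera(nsv, 24, 24)
  one <- render_progressive(sc, cam, render_settings(spp = 16, seed = 3))
  p1 <- render_progressive(sc, cam, render_settings(spp = 8, seed = 3))
  p2 <- render_progressive(sc, cam, render_settings(spp = 8, seed = 3), fb = p1)
  expect_equal(p2$accum, one$accum, tolerance = 1e-12)
  expect_identical(round(resolve_framebuffer(p2) * 255),
                   round(resolve_framebuffer(one) * 255))
  again <- render_progressive(sc, cam, render_settings(spp = 16, seed = 3))
  expect_identical(one$accum, again$accum)
  # doubling spp shrinks the per-pixel standard error roughly as 1/sqrt(2)
  reps <- 24
  err <- function(spp) {
    imgs <- sapply(seq_len(reps), function(r) {
      f <- render_progressive(sc, cam, render_settings(spp = spp, seed = 100 + r))
      as.numeric(f$accum / f$spp)
    })
    mean(apply(imgs, 1, sd))
  }
  e1 <- err(4); e2 <- err(8)
  expect_lt(abs(e1 / e2 - sqrt(2)), 0.2 * sqrt(2))
})

test_that("the ray-march oracle responds correctly to importance", {
  # empty volume renders the (ambient) background
  empty <- homogeneous_scene(0)
  came <- default_camera(empty$volume, 16, 16)
  st <- render_settings()
  im <- reference_ray_march(empty, came, step = 0.5, settings = st)
  for (ch in 1:3) expect_lt(max(abs(im[, , ch] - st$ambient[ch])), 1e-12)

  # halving the step changes pixels by < 1% on a smooth phantom
  ph <- tiny_phantom(seed = 7, shape = c(32L, 32L, 32L))
  nsv <- non_scalar_volume(normalize_zmuv(ph$intensity), ph$labels)
  sc <- render_scene(nsv, default_tf())
  cam <- default_camera(nsv, 24, 24)
  a <- reference_ray_march(sc, cam, step = 0.1, settings = st)
  b <- reference_ray_march(sc, cam, step = 0.05, settings = st)
  expect_lt(max(abs(a - b)) / max(b), 0.01)

  # a region with importance 0 disappears: rays through it hit background
  iv <- intensity_volume(array(2, c(16, 16, 16)))   # uniformly opaque tissue
  lab <- label_volume(array(1L, c(16, 16, 16)))
  vis <- non_scalar_volume(iv, lab, label_importance = c(`0` = 0.2, `1` = 1, `2` = 0.6))
  hid <- non_scalar_volume(iv, lab, label_importance = c(`0` = 0.2, `1` = 0, `2` = 0.6))
  camv <- default_camera(vis, 16, 16)
  iv1 <- reference_ray_march(render_scene(vis, default_tf()), camv, 0.5, st)
  iv0 <- reference_ray_march(render_scene(hid, default_tf()), camv, 0.5, st)
  for (ch in 1:3) expect_lt(max(abs(iv0[, , ch] - st$ambient[ch])), 1e-12)
  expect_gt(max(abs(iv1 - iv0)), 0.05)

  # lowering g never increases silhouette opacity (monotone importance)
  mid <- non_scalar_volume(iv, lab, label_importance = c(`0` = 0.2, `1` = 0.5, `2` = 0.6))
  ivm <- reference_ray_march(render_scene(mid, default_tf()), camv, 0.5, st)
  # compare total attenuation via distance from background
  d1 <- sum(abs(iv1 - rep(st$ambient, each = 16 * 16)))
  dm <- sum(abs(ivm - rep(st$ambient, each = 16 * 16)))
  d0 <- sum(abs(iv0 - rep(st$ambient, each = 16 * 16)))
  expect_gte(d1, dm); expect_gte(dm, d0)
})

test_that("scattering events respect albedo, gradients and phase settings", {
  # zero-gradient homogeneous scene: always the volumetric branch; with
  # phase_g = 0 the outgoing cosines are isotropic
  hs <- homogeneous_scene(0.5)
  ev <- shade_event(hs, x = c(8, 8, 8), dir = c(0, 0, 1), n = 5000, seed = 2,
                    grad_threshold = 1)
  expect_true(all(ev$branch == 0L))
  expect_gt(suppressWarnings(ks.test(ev$dir[, 3], "punif", -1, 1))$p.value, 0.001)
  expect_true(all(abs(sqrt(rowSums(ev$dir^2)) - 1) < 1e-12))
  # albedo scales the throughput; importance 0 kills it entirely
  expect_lt(max(abs(ev$throughput - 1)), 1e-12)
  iv <- intensity_volume(array(0.5, c(16, 16, 16)))
  lv <- label_volume(array(0L, c(16, 16, 16)))
  dark <- non_scalar_volume(iv, lv, label_importance = c(`0` = 0, `1` = 1, `2` = 1))
  pts <- data.frame(intensity = c(0, 1), opacity = 0.5, r = 1, g = 1, b = 1,
                    smoothness = 0, phase_g = 0)
  sc0 <- render_scene(dark, transfer_function_2d(pts,
                      suppressWarnings(importance_params(a = 4)), 1))
  ev0 <- shade_event(sc0, c(8, 8, 8), c(0, 0, 1), n = 10, seed = 3,
                     grad_threshold = 1)
  expect_true(all(ev0$throughput == 0))       # path terminates
  # a strong gradient with a saturating threshold forces the surface branch,
  # and the outgoing direction leaves the surface (positive along the normal)
  ramp <- array(rep((0:15) / 15, times = 256), c(16, 16, 16))
  rv <- non_scalar_volume(intensity_volume(ramp), label_volume(array(1L, c(16, 16, 16))),
                          label_importance = c(`0` = 1, `1` = 1, `2` = 1))
  scr <- render_scene(rv, transfer_function_2d(pts,
                      suppressWarnings(importance_params(a = 4)), 1))
  evs <- shade_event(scr, c(8, 8, 8), c(1, 0, 0), n = 2000, seed = 4,
                     grad_threshold = 1e-6)
  expect_true(all(evs$branch == 1L))
  expect_true(all(evs$dir[, 1] < 1e-12))      # reflected against the +x gradient
})
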