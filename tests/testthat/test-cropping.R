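test_that("crop list matches the worked cube example", {
  lab <- cube_labels()   # 64 foreground voxels in depth slab [2, 6)
  l50 <- build_crop_list(lab, window_depth = 4, k = 50)
  expect_equal(which(l50$weights == 1L) - 1L, 2L)
  l40 <- build_crop_list(lab, window_depth = 4, k = 40)
  expect_equal(which(l40$weights == 1L) - 1L, c(1L, 2L, 3L))
  # invalid starts (window would overrun) carry weight zero
  expect_true(all(l50$weights[(8 - 4 + 2):8] == 0L))
  expect_true(all(build_crop_list(array(0L, c(8, 8, 8)), 4, 50)$weights == 0L))
  expect_error(build_crop_list(lab, window_depth = 9, k = 0), "exceeds")
})

test_that("crop list equals the brute-force slab-counting oracle", {
  set.seed(11)
  for (rep in 1:20) {
    dm <- sample(8:16, 3, replace = TRUE)
    lab <- array(sample(0:2, prod(dm), TRUE, prob = c(0.9, 0.05, 0.05)), dm)
    wd <- sample(4:8, 1); k <- sample(c(0L, 10L, 50L), 1)
    got <- build_crop_list(lab, wd, k)$weights
    expect_identical(got, brute_crop_list(lab, wd, k))
  }
})

test_that("aggregation is an elementwise integer sum", {
  lab <- cube_labels()
  l <- build_crop_list(lab, 4, 50)
  agg <- aggregate_crop_lists(list(l, l))
  expect_identical(agg$weights, l$weights * 2L)
  set.seed(3)
  ls <- lapply(1:3, function(i) {
    lab <- array(sample(0:1, 8^3, TRUE), c(8, 8, 8))
    build_crop_list(lab, 4, 10)
  })
  agg3 <- aggregate_crop_lists(ls)
  expect_identical(agg3$weights, ls[[1]]$weights + ls[[2]]$weights + ls[[3]]$weights)
  expect_error(aggregate_crop_lists(list()), "empty")
})

test_that("weighted start sampling follows the aggregate distribution", {
  d <- structure(list(weights = c(0L, 2L, 1L, rep(0L, 7)), window_depth = 4L,
                      k = 50L, depth = 10L), class = "aggregate_crop_distribution")
  set.seed(4)
  draws <- sample_crop_start(d, n = 3e5)
  expect_true(all(draws %in% c(1L, 2L)))
  p <- mean(draws == 1L)
  se <- sqrt(2/3 * 1/3 / 3e5)
  expect_lt(abs(p - 2/3), 3 * se)
  # one-hot always returns its index
  d1 <- d; d1$weights <- c(rep(0L, 5), 1L, rep(0L, 4))
  expect_true(all(sample_crop_start(d1, 100) == 5L))
  # all-zero weights fall back to uniform over valid starts {0..6}
  d0 <- d; d0$weights <- rep(0L, 10)
  u <- sample_crop_start(d0, 1e5)
  expect_setequal(sort(unique(u)), 0:6)
  cs <- chisq.test(table(factor(u, levels = 0:6)))
  expect_gt(cs$p.value, 0.001)
})

test_that("crop_patch slices the half-open window", {
  set.seed(5)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  lab <- array(sample(0:2, 16^3, TRUE), c(16, 16, 16))
  cr <- crop_patch(vol, lab, start_j = 3, patch_size = c(8, 8, 4), h0 = 2, w0 = 5)
  expect_identical(cr$patch, vol[3:10, 6:13, 4:7])
  expect_identical(cr$labels, lab[3:10, 6:13, 4:7])
  # full-volume crop is the identity
  full <- crop_patch(vol, NULL, 0, c(16, 16, 16), h0 = 0, w0 = 0)
  expect_identical(full$patch, vol)
  expect_error(crop_patch(vol, NULL, 0, c(32, 8, 8)), "larger")
})

test_that("sampled crops contain more than k foreground voxels", {
  ph <- tiny_phantom(seed = 6)
  wd <- 16L; k <- 50L
  l <- build_crop_list(ph$labels, wd, k)
  agg <- aggregate_crop_lists(list(l))
  expect_gt(sum(agg$weights), 0)
  set.seed(6)
  for (i in 1:10) {
    j <- sample_crop_start(agg)
    cnt <- sum(ph$labels$labels[, , (j + 1):(j + wd)] > 0)
    expect_gt(cnt, k)
  }
})

test_that("flip/rotation augmentation has the expected group structure", {
  set.seed(7)
  p <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  l <- array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4))
  id <- augment_flip_rotate(p, l, moves = identity_moves())
  expect_identical(id$patch, p); expect_identical(id$labels, l)
  # flips are involutions
  mv <- list(flips = c(TRUE, FALSE, TRUE), rot = 0L)
  twice <- augment_flip_rotate(augment_flip_rotate(p, l, mv)$patch, NULL, mv)
  expect_identical(twice$patch, p)
  # four quarter turns are the identity
  r <- list(flips = c(FALSE, FALSE, FALSE), rot = 1L)
  q <- p
  for (i in 1:4) q <- augment_flip_rotate(q, NULL, r)$patch
  expect_identical(q, p)
  # image and labels receive the same transform
  mv2 <- list(flips = c(TRUE, TRUE, FALSE), rot = 2L)
  both <- augment_flip_rotate(p, l, mv2)
  expect_identical(both$labels, augment_flip_rotate(l, NULL, mv2)$patch)
})
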