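make_tiny_dataset <- function(n_lab, n_unl, seed = 21) {
  d <- file.path(tempdir(), paste0("train_ds_", seed, "_", n_lab, "_", n_unl))
  if (!dir.exists(d))
    generate_dataset(n_lab, n_unl, d, seed = seed,
                     config = phantom_config(shape = c(32L, 32L, 32L),
                                             lesion_radius_range = c(4, 6)))
  read_manifest(d)
}

test_that("supervised-only training runs, logs finite losses and learns", {
  man <- make_tiny_dataset(1, 0)
  ncfg <- pyramid_net_config(base_filters = 2L, patch_size = c(16L, 16L, 16L))
  tcfg <- training_config(steps = 60L, wmax = 0, lr = 0.005, seed = 1)
  fit <- train_ucppa(man, ncfg, tcfg)
  h <- fit$history
  expect_equal(nrow(h), 60L)
  expect_true(all(is.finite(h$ls)) && all(is.finite(h$ltotal)))
  expect_true(all(h$lu == 0))                 # no consistency term without wmax
  expect_lt(mean(tail(h$ls, 10)), mean(head(h$ls, 10)))
})

test_that("training is deterministic under a fixed seed and logs the loss identity", {
  man <- make_tiny_dataset(2, 2)
  ncfg <- pyramid_net_config(base_filters = 2L, patch_size = c(16L, 16L, 16L))
  tcfg <- training_config(steps = 12L, wmax = 0.1, seed = 7)
  csv <- tempfile(fileext = ".csv")
  f1 <- train_ucppa(man, ncfg, tcfg, log_csv = csv)
  f2 <- train_ucppa(man, ncfg, tcfg)
  expect_equal(f1$history$ltotal, f2$history$ltotal, tolerance = 1e-14)
  expect_identical(f1$params$enc[[1]][[1]]$W, f2$params$enc[[1]][[1]]$W)
  # the logged rows satisfy ltotal = ls + lambda * lu
  log <- read.csv(csv)
  expect_lt(max(abs(log$ltotal - (log$ls + log$lambda * log$lu))), 1e-6)
  # lambda follows the Gaussian warm-up at the logged steps
  expect_equal(log$lambda, warmup_weight(log$step, tcfg$tmax, tcfg$wmax),
               tolerance = 1e-12)
  expect_gt(mean(f1$history$lu > 0), 0.9)     # consistency loss is active
})

test_that("checkpoints round-trip and resume cleanly", {
  man <- make_tiny_dataset(1, 1)
  ncfg <- pyramid_net_config(base_filters = 2L, patch_size = c(16L, 16L, 16L))
  fit <- train_ucppa(man, ncfg, training_config(steps = 5L, seed = 2))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  expect_true(file.exists(ck) && file.exists(paste0(ck, ".json")))
  back <- load_checkpoint(ck)
  expect_identical(back$params$enc[[1]][[1]]$W, fit$params$enc[[1]][[1]]$W)
  # warm-start accepted
  fit2 <- train_ucppa(man, ncfg, training_config(steps = 3L, seed = 3),
                      params = back$params)
  expect_equal(nrow(fit2$history), 3L)
})

test_that("weighted cropping drives depth starts toward the lesion slab", {
  man <- make_tiny_dataset(3, 0, seed = 31)
  vols <- segvis3d:::load_training_volumes(man)
  lists <- lapply(vols$labeled, function(v) build_crop_list(v$y, 16L, 50L))
  agg <- aggregate_crop_lists(lists)
  expect_gt(sum(agg$weights), 0)
  set.seed(1)
  js <- sample_crop_start(agg, 500)
  expect_true(all(agg$weights[js + 1L] > 0))
})
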