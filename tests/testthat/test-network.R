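test_that("forward pass produces softmax-normalized pyramids of the right shape", {
  cfg <- pyramid_net_config(base_filters = 4L, patch_size = c(32L, 32L, 16L))
  par <- init_pyramid_net(cfg, seed = 1)
  set.seed(1)
  patch <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  pr <- pyramid_forward(par, patch)
  expect_length(pr$probs, 4)
  for (p in pr$probs) {
    expect_equal(dim(p), c(3L, 32L, 32L, 16L))
    sums <- apply(p, 2:4, sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_true(all(p >= 0))
  }
  # eval mode is deterministic
  pr2 <- pyramid_forward(par, patch)
  expect_identical(pr$probs, pr2$probs)
})

test_that("hand-derived network gradients match finite differences", {
  cfg <- pyramid_net_config(base_filters = 2L, patch_size = c(16L, 16L, 16L))
  par <- init_pyramid_net(cfg, seed = 7)
  set.seed(3)
  dims <- c(16L, 16L, 16L, 1L)
  X <- matrix(rnorm(prod(dims)), nrow = 1)
  y <- sample(0:2, prod(dims), replace = TRUE)
  lossval <- function(par) {
    r <- net_forward(par, X, dims, training = TRUE)
    supervised_loss(r$probs, y)$value + 0.3 * unsupervised_loss(r$probs)$value
  }
  r <- net_forward(par, X, dims, training = TRUE)
  sl <- supervised_loss(r$probs, y)
  lu <- unsupervised_loss(r$probs, grad = TRUE)
  dP <- Map(function(a, b) a + 0.3 * b, sl$dP, lu$dP)
  g <- net_backward(r$params, r$cache, dP)
  eps <- 2e-6
  check_one <- function(get, set, gval) {
    i <- sample(length(get(par)), 2)
    for (j in i) {
      pp <- par; v <- get(pp); v[j] <- v[j] + eps; pp <- set(pp, v)
      pm <- par; v <- get(pm); v[j] <- v[j] - eps; pm <- set(pm, v)
      fd <- (lossval(pp) - lossval(pm)) / (2 * eps)
      expect_equal(gval[j], fd, tolerance = 1e-3)
    }
  }
  set.seed(4)
  check_one(function(p) p$enc[[1]][[1]]$W, function(p, v) { p$enc[[1]][[1]]$W[] <- v; p },
            g$enc[[1]][[1]]$W)
  check_one(function(p) p$dec[[4]][[1]]$W, function(p, v) { p$dec[[4]][[1]]$W[] <- v; p },
            g$dec[[4]][[1]]$W)
  check_one(function(p) p$dec[[1]][[1]]$bn$gamma,
            function(p, v) { p$dec[[1]][[1]]$bn$gamma[] <- v; p },
            g$dec[[1]][[1]]$bn$gamma)
  check_one(function(p) p$dsv[[3]]$W, function(p, v) { p$dsv[[3]]$W[] <- v; p },
            g$dsv[[3]]$W)
})

test_that("an SGD step on a fixed batch reduces the loss", {
  cfg <- pyramid_net_config(base_filters = 2L, patch_size = c(16L, 16L, 16L))
  par <- init_pyramid_net(cfg, seed = 2)
  set.seed(5)
  dims <- c(16L, 16L, 16L, 2L)
  X <- matrix(rnorm(prod(dims)), nrow = 1)
  y <- sample(0:2, prod(dims), replace = TRUE)
  state <- NULL
  losses <- numeric(6)
  for (it in 1:6) {
    r <- net_forward(par, X, dims, training = TRUE)
    sl <- supervised_loss(r$probs, y)
    losses[it] <- sl$value
    g <- net_backward(r$params, r$cache, sl$dP)
    up <- sgd_update(r$params, g, state, lr = 0.05)
    par <- up$params; state <- up$state
  }
  expect_lt(losses[6], losses[1])
  expect_true(all(is.finite(losses)))
})
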