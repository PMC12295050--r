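test_that("cross-entropy and Dice losses match direct formulas and gradients", {
  set.seed(1)
  C <- 3; V <- 40
  P <- random_probs(1, C, V, seed = 1)[[1]]
  y <- sample(0:2, V, replace = TRUE)
  ce <- ce_loss(P, y)
  expect_equal(ce$value, -mean(log(P[cbind(y + 1, seq_len(V))])), tolerance = 1e-12)
  dc <- soft_dice_loss(P, y)
  # independent recomputation by direct summation
  val <- mean(sapply(1:2, function(cl) {
    pc <- P[cl + 1, ]; yc <- as.numeric(y == cl)
    1 - (2 * sum(pc * yc) + 1e-5) / (sum(pc) + sum(yc) + 1e-5)
  }))
  expect_equal(dc$value, val, tolerance = 1e-12)
  expect_gte(dc$value, 0); expect_lte(dc$value, 1)
  # finite-difference gradients
  for (f in list(ce_loss, soft_dice_loss)) {
    L <- f(P, y)
    for (i in sample(C * V, 5)) {
      Pp <- P; Pp[i] <- Pp[i] + 1e-7
      Pm <- P; Pm[i] <- Pm[i] - 1e-7
      fd <- (f(Pp, y)$value - f(Pm, y)$value) / 2e-7
      expect_equal(L$dP[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("perfect and maximally wrong predictions bound the Dice loss", {
  V <- 27
  y <- rep(0:2, 9)
  Ph <- onehot <- matrix(0, 3, V); onehot[cbind(y + 1, 1:V)] <- 1
  Ph <- onehot * (1 - 3e-6) + 1e-6
  expect_lt(soft_dice_loss(Ph, y)$value, 1e-4)
  expect_lt(supervised_loss(list(Ph, Ph), y)$value, 1e-4)
  # complement: no overlap at all
  comp <- onehot[c(2, 3, 1), ]
  expect_gt(soft_dice_loss(comp, y)$value, 0.999)
  # uniform prediction on a single-class foreground plane, hand-computed
  V2 <- 16; y2 <- rep(c(1L, 0L), each = 8)
  U <- matrix(1/3, 3, V2)
  hand <- mean(c(1 - (2 * (8/3) + 1e-5) / (16/3 + 8 + 1e-5),
                 1 - (2 * 0 + 1e-5) / (16/3 + 0 + 1e-5)))
  expect_equal(soft_dice_loss(U, y2)$value, hand, tolerance = 1e-12)
})

test_that("supervised pyramid loss averages the per-scale CE+Dice", {
  set.seed(2)
  V <- 8; y <- sample(0:2, V, TRUE)
  ps <- random_probs(2, 3, V, seed = 3)
  # componentwise oracle
  per_scale <- sapply(ps, function(P) 0.5 * (ce_loss(P, y)$value + soft_dice_loss(P, y)$value))
  expect_equal(supervised_loss(ps, y)$value, mean(per_scale), tolerance = 1e-12)
  # S = 1 reduces to the single head
  expect_equal(supervised_loss(ps[1], y)$value, per_scale[1], tolerance = 1e-12)
})

test_that("Gaussian warm-up schedule has the right endpoints and shape", {
  expect_equal(warmup_weight(100, 100, 0.3), 0.3)
  expect_equal(warmup_weight(0, 100, 0.3), 0.3 * exp(-5), tolerance = 1e-12)
  expect_equal(warmup_weight(50, 100, 1), exp(-5/4), tolerance = 1e-12)
  tt <- seq(0, 1000, by = 1)
  lam <- warmup_weight(tt, 1000, 0.1)
  expect_true(all(diff(lam) >= 0))
  expect_true(all(lam <= 0.1 + 1e-15))
  expect_error(warmup_weight(1, 0), "positive")
})

test_that("pyramid consistency loss: zero at agreement, scalar oracle, symmetry", {
  ps <- random_probs(3, 3, 10, seed = 4)
  same <- lapply(1:3, function(s) ps[[1]])
  expect_lt(unsupervised_loss(same)$value, 1e-12)
  # 1-voxel S=2 case against independent scalar arithmetic
  p1 <- matrix(c(0.9, 0.1, 0), 3, 1); p2 <- matrix(c(0.5, 0.3, 0.2), 3, 1)
  pc <- (p1 + p2) / 2
  cl <- function(x) pmax(x, 1e-8)
  D1 <- sum(pc * (log(cl(pc)) - log(cl(p1)))); D2 <- sum(pc * (log(cl(pc)) - log(cl(p2))))
  w1 <- exp(-D1); w2 <- exp(-D2)
  lu_hand <- 0.5 * ((mean(w1 * (p1 - pc)^2) / (w1 + 1e-8)) + D1 +
                    (mean(w2 * (p2 - pc)^2) / (w2 + 1e-8)) + D2)
  expect_equal(unsupervised_loss(list(p1, p2))$value, lu_hand, tolerance = 1e-8)
  # permutation symmetry
  expect_equal(unsupervised_loss(ps)$value,
               unsupervised_loss(ps[c(3, 1, 2)])$value, tolerance = 1e-12)
  expect_error(unsupervised_loss(ps[1]), "at least 2")
})

test_that("consistency-loss gradients agree with finite differences", {
  ps <- random_probs(3, 3, 7, seed = 5)
  for (dir in c("mean_to_scale", "scale_to_mean")) {
    L <- unsupervised_loss(ps, kl_dir = dir, grad = TRUE)
    set.seed(6)
    for (t in 1:3) for (i in sample(21, 3)) {
      pp <- ps; pp[[t]][i] <- pp[[t]][i] + 1e-7
      pm <- ps; pm[[t]][i] <- pm[[t]][i] - 1e-7
      fd <- (unsupervised_loss(pp, kl_dir = dir)$value -
             unsupervised_loss(pm, kl_dir = dir)$value) / 2e-7
      expect_equal(L$dP[[t]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("loss breakdown satisfies the combination identity", {
  lb <- loss_breakdown(ls = 0.8, lu = 0.3, lambda_t = 0.05)
  expect_equal(lb$ltotal, 0.8 + 0.05 * 0.3, tolerance = 1e-12)
  expect_error(loss_breakdown(NaN, 0, 0))
})
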