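test_that("importance transfer function equals its tanh closed form", {
  gs <- seq(0, 1, by = 0.05)
  as <- c(0.5, 1, 2, 4, 8, 16)
  for (a in as) {
    expect_lt(max(abs(importance_value(gs, a) - tanh(a * gs / 2) / tanh(a / 2))), 1e-12)
    expect_identical(importance_value(0, a), 0)
    expect_equal(importance_value(1, a), 1, tolerance = 1e-15)
    expect_true(all(diff(importance_value(gs, a)) > 0))   # strictly increasing in g
  }
  # degenerates to the identity as a -> 0+
  expect_lt(max(abs(importance_value(gs, 1e-4) - gs)), 1e-4)
  # monotone in a for fixed interior g: larger a boosts mid-importance regions
  g <- 0.4
  vals <- sapply(as, function(a) importance_value(g, a))
  expect_true(all(diff(vals) > 0))
  expect_equal(importance_value(0.5, 4), tanh(1) / tanh(2), tolerance = 1e-12)
  expect_error(importance_value(0.5, 0), "> 0")
  expect_error(importance_value(1.5, 2), "\\[0,1\\]")
})

test_that("modulation scales opacity, smoothness and albedo but not phase", {
  m <- material(opacity = 0.8, albedo = c(0.9, 0.5, 0.2), smoothness = 0.6, phase_g = 0.4)
  expect_identical(modulate_material(m, 1), m)
  z <- modulate_material(m, 0)
  expect_equal(z$opacity, 0); expect_equal(z$albedo, c(0, 0, 0)); expect_equal(z$smoothness, 0)
  expect_equal(z$phase_g, 0.4)
  h <- modulate_material(m, 0.5)
  expect_equal(h$opacity, 0.4)
  expect_equal(h$phase_g, m$phase_g)
  # modulation never increases any modulated attribute
  for (I in c(0, 0.3, 0.7, 1)) {
    mm <- modulate_material(m, I)
    expect_lte(mm$opacity, m$opacity)
    expect_lte(mm$smoothness, m$smoothness)
    expect_true(all(mm$albedo <= m$albedo))
  }
})

test_that("2D transfer function evaluation combines both dimensions", {
  tf <- default_tf(suppressWarnings(importance_params(a = 4,
        label_importance = c(`0` = 0, `1` = 1, `2` = 0.6))))
  # importance 1 leaves the intensity TF untouched
  pt <- tf$points[3, ]
  m1 <- evaluate_tf(pt$intensity, 1L, tf)
  expect_equal(m1$opacity, pt$opacity, tolerance = 1e-12)
  expect_equal(m1$albedo, c(pt$r, pt$g, pt$b), tolerance = 1e-12)
  # importance 0 makes the region fully transparent at any intensity
  for (x in c(-3, 0, 1, 5)) {
    m0 <- evaluate_tf(x, 0L, tf)
    expect_equal(m0$opacity, 0)
    expect_equal(m0$albedo, c(0, 0, 0))
  }
  # unknown label errors
  expect_error(evaluate_tf(0, 7L, tf), "not in importance map")
})

test_that("transfer functions survive a JSON round trip", {
  tf <- default_tf(suppressWarnings(importance_params(a = 6)), density_scale = 0.4)
  f <- tempfile(fileext = ".json")
  write_tf(tf, f)
  back <- read_tf(f)
  expect_equal(back$points$opacity, tf$points$opacity, tolerance = 1e-12)
  expect_equal(back$importance$a, 6)
  expect_equal(back$density_scale, 0.4)
  expect_equal(unname(back$importance$label_importance["1"]),
               unname(tf$importance$label_importance["1"]))
})
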