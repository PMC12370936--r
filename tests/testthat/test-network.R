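test_that("the encoder geometry flattens to 2592 at the 224-pixel canvas", {
  d <- dualpath:::net_dims(224L)
  expect_identical(d[["flat"]], 2592L)
  expect_identical(d[["p2"]], 9L)
  # and a real agent produces a scalar from a 224 x 224 image
  ag <- dual_agent(seed = 1L, side = 224L)
  z <- encode(ag, matrix(0.5, 224, 224))
  expect_length(z, 1L)
  expect_true(is.finite(z))
})

test_that("initialization is seeded and bounded by 1/sqrt(fan-in) per layer", {
  a1 <- dual_agent(seed = 42L, side = TEST_SIDE)
  a2 <- dual_agent(seed = 42L, side = TEST_SIDE)
  a3 <- dual_agent(seed = 43L, side = TEST_SIDE)
  expect_identical(a1$par, a2$par)
  expect_false(identical(a1$par, a3$par))

  flat <- a1$dims[["flat"]]
  sizes <- c(16 * 12, 16, 32 * 64, 32, 32 * 288, 32, flat, 1, 1)
  fans <- c(12, 12, 64, 64, 288, 288, flat, flat, 1)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  for (k in seq_along(sizes)) {
    block <- a1$par[starts[k]:ends[k]]
    expect_lte(max(abs(block)), 1 / sqrt(fans[k]))
  }
})

test_that("delta_z is exactly antisymmetric under image swap and zero for identical inputs", {
  ag <- dual_agent(seed = 3L, side = TEST_SIDE)
  p <- tiny_pair(alpha = 0.7, seed = 2)
  swapped <- p
  swapped$left_image <- p$right_image
  swapped$right_image <- p$left_image
  expect_identical(delta_z(ag, swapped), -delta_z(ag, p))

  same <- p
  same$right_image <- p$left_image
  expect_identical(delta_z(ag, same), 0)
})

test_that("the ring loss takes its documented values and is minimized on the ring diagonal", {
  hy <- dual_hyper(lambda = 4, r2 = 0.1)
  expect_equal(ring_loss(0.3, 0.1, hy), 0.04)
  expect_equal(ring_loss(0, 0, hy), 0.04)     # collapse is penalized
  expect_equal(ring_loss(sqrt(0.05), sqrt(0.05), hy), 0)
  expect_true(all(ring_loss(rnorm(50), rnorm(50), hy) >= 0))

  # grid-search oracle: the only global minima are +/- (r/sqrt(2), r/sqrt(2))
  g <- seq(-0.5, 0.5, length.out = 401)
  L <- outer(g, g, function(dz, th) ring_loss(dz, th, hy))
  minima <- which(L <= min(L) + 1e-10, arr.ind = TRUE)
  pts <- cbind(g[minima[, 1]], g[minima[, 2]])
  rstar <- sqrt(0.05)
  d_pos <- sqrt((pts[, 1] - rstar)^2 + (pts[, 2] - rstar)^2)
  d_neg <- sqrt((pts[, 1] + rstar)^2 + (pts[, 2] + rstar)^2)
  expect_true(all(pmin(d_pos, d_neg) < 3e-3))
  expect_true(any(d_pos < 3e-3) && any(d_neg < 3e-3))
})

test_that("order decisions are antisymmetric and ties count as incorrect", {
  ag <- dual_agent(seed = 8L, side = TEST_SIDE)
  p <- tiny_pair(alpha = 0.6, seed = 6)
  swapped <- p
  swapped$left_image <- p$right_image
  swapped$right_image <- p$left_image
  expect_false(order_decision(ag, p) == order_decision(ag, swapped))

  tie <- p
  tie$right_image <- p$left_image  # dz exactly 0: both orders tie
  expect_false(order_decision(ag, tie))
  swapped_tie <- tie
  expect_false(order_decision(ag, swapped_tie))
})

test_that("untrained agents perform at chance on average", {
  set.seed(99)
  cfg <- task_config("size", alpha = 0.5, n_train_pairs = 0L,
                     n_test_pairs = 16L, image_side = TEST_SIDE, seed = 17L)
  ph <- make_phase(cfg)
  accs <- vapply(1:12, function(i) {
    ag <- dual_agent(seed = 200L + i, side = TEST_SIDE)
    evaluate_agent(ag, ph$test)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("agents round-trip through checkpoint files", {
  ag <- dual_agent(seed = 12L, side = TEST_SIDE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_agent(ag, path)
  ag2 <- load_agent(path)
  expect_identical(ag2$par, ag$par)
  expect_identical(ag2$side, ag$side)
  p <- tiny_pair(seed = 3)
  expect_identical(delta_z(ag2, p), delta_z(ag, p))
})
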