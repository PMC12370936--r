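test_that("the realized predictive-feature difference equals alpha and other features are shared", {
  set.seed(11)
  cases <- expand.grid(predictive = c("size", "color", "number"),
                       alpha = c(-0.75, -0.25, 0, 0.5, 1),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    pf <- cases$predictive[i]
    a <- cases$alpha[i]
    cfg <- task_config(pf, alpha = a, image_side = TEST_SIDE)
    for (rep in 1:10) {
      p <- sample_pair(cfg, render = FALSE)
      dl <- dualpath:::predictive_value(p$left_features, pf)
      dr <- dualpath:::predictive_value(p$right_features, pf)
      if (pf == "number") {
        expect_identical(dr - dl, a)
      } else {
        expect_lt(abs((dr - dl) - a), 1e-9)
      }
      expect_true(dl >= 0 && dl <= 1 && dr >= 0 && dr <= 1)
      # non-predictive scalar/categorical features are byte-identical
      for (f in setdiff(c("color", "number", "size", "shape"), pf)) {
        expect_identical(p$left_features[[f]], p$right_features[[f]])
      }
      if (pf != "number") {
        expect_identical(p$left_features$arrangement,
                         p$right_features$arrangement)
      }
      expect_length(p$left_features$arrangement, p$left_features$number)
      expect_length(p$right_features$arrangement, p$right_features$number)
    }
  }
})

test_that("alpha = 0 gives identical feature vectors and pixel-identical images", {
  cfg <- task_config("size", alpha = 0, image_side = TEST_SIDE)
  set.seed(5)
  p <- sample_pair(cfg)
  expect_identical(p$left_features, p$right_features)
  expect_identical(p$left_image, p$right_image)
})

test_that("alpha = 1 on size forces the only feasible pair (0, 1)", {
  cfg <- task_config("size", alpha = 1, image_side = TEST_SIDE)
  set.seed(9)
  p <- sample_pair(cfg, render = FALSE)
  expect_equal(p$left_features$size, 0)
  expect_equal(p$right_features$size, 1)
})

test_that("invalid rules are rejected", {
  expect_error(task_config("size", alpha = 1.2), "\\[-1, 1\\]")
  expect_error(task_config("number", alpha = 0.3), "multiple of 1/8")
})

test_that("the left predictive value is uniform over its feasible interval", {
  alpha <- 0.4
  cfg <- task_config("size", alpha = alpha, image_side = TEST_SIDE)
  set.seed(101)
  left <- replicate(10000, sample_pair(cfg, render = FALSE)$left_features$size)
  expect_gte(min(left), 0)
  expect_lte(max(left), 1 - alpha)
  ks <- suppressWarnings(ks.test(left, "punif", 0, 1 - alpha))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-predictive features are independent across pairs", {
  cfg <- task_config("number", alpha = 0.25, image_side = TEST_SIDE)
  set.seed(77)
  draws <- t(replicate(2000, {
    p <- sample_pair(cfg, render = FALSE)
    c(color = p$left_features$color, size = p$left_features$size)
  }))
  ct <- cor.test(draws[, "color"], draws[, "size"])
  expect_gt(ct$p.value, 0.01)
})

test_that("rendering is deterministic and respects the geometry", {
  f <- list(color = 0.4, number = 9L, size = 0.8, arrangement = 1:9,
            shape = "circle")
  img1 <- render_image(f, side = TEST_SIDE)
  img2 <- render_image(f, side = TEST_SIDE)
  expect_identical(img1, img2)
  # full grid: every cell contains painted (non-background) pixels
  cell <- TEST_SIDE / 3
  for (cx in 0:2) for (cy in 0:2) {
    xs <- floor(cx * cell + 1):ceiling((cx + 1) * cell)
    ys <- floor(cy * cell + 1):ceiling((cy + 1) * cell)
    expect_true(any(img1[ys, xs] < 1),
                label = sprintf("cell (%d, %d) painted", cx, cy))
  }
})

test_that("the maximal size maps to the configured maximal pixel diameter", {
  # reference canvas: size 1 -> enclosing-circle diameter 70 px
  f <- list(color = 0, number = 1L, size = 1, arrangement = 5L,
            shape = "circle")
  img <- render_image(f, side = 224L)
  painted <- which(img < 1, arr.ind = TRUE)
  expect_equal(max(painted[, 1]) - min(painted[, 1]) + 1, 70, tolerance = 0.02)
  expect_equal(max(painted[, 2]) - min(painted[, 2]) + 1, 70, tolerance = 0.02)
})

test_that("all shapes render inside their enclosing circle with the mapped gray level", {
  for (shape in dualpath:::SHAPE_CATALOG) {
    f <- list(color = 0.5, number = 1L, size = 1, arrangement = 5L,
              shape = shape)
    img <- render_image(f, side = 224L)
    painted <- which(img < 1, arr.ind = TRUE)
    expect_gt(nrow(painted), 0)
    centre <- (1.5) * 224 / 3 + 0.5  # pixel-index centre of the middle cell
    rr <- sqrt((painted[, 1] - centre)^2 + (painted[, 2] - centre)^2)
    expect_lte(max(rr), 35 + 1)
    expect_equal(unique(img[painted]), 0.78 * 0.5)
  }
})

test_that("a phase is reproducible from its seed and has the configured counts", {
  cfg <- task_config("size", alpha = 0.5, n_train_pairs = 6L,
                     n_test_pairs = 3L, image_side = TEST_SIDE, seed = 33L)
  ph1 <- make_phase(cfg)
  ph2 <- make_phase(cfg)
  expect_length(ph1$train, 6L)
  expect_length(ph1$test, 3L)
  expect_identical(ph1$train, ph2$train)
  expect_identical(ph1$test, ph2$test)
  # default counts follow the task definition
  expect_identical(task_config("size", 0.5)$n_train_pairs, 160L)
  expect_identical(task_config("size", 0.5)$n_test_pairs, 32L)
})

test_that("phases can be written to PNG with a manifest and a config round-trip", {
  dir <- withr::local_tempdir()
  cfg <- task_config("color", alpha = -0.5, n_train_pairs = 2L,
                     n_test_pairs = 1L, image_side = TEST_SIDE, seed = 4L)
  ph <- make_phase(cfg)
  manifest <- write_phase(ph, dir)
  expect_equal(nrow(manifest), 3L)
  expect_true(all(file.exists(manifest$left_path)))
  img <- png::readPNG(manifest$left_path[1])
  expect_equal(dim(img), c(TEST_SIDE, TEST_SIDE))
  expect_equal(img, ph$train[[1]]$left_image, tolerance = 1 / 255)
  cfg2 <- read_task_config(file.path(dir, "config.json"))
  expect_identical(cfg2[c("predictive", "alpha", "image_side")],
                   cfg[c("predictive", "alpha", "image_side")])
})
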