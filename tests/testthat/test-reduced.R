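r2 <- 0.1
r <- sqrt(r2)
rev_start <- c(-r / sqrt(2), r / sqrt(2))  # post-reversal state

test_that("the flow vanishes at every reported fixed point and matches hand values", {
  for (lambda in c(0.1, 4, 20)) {
    fps <- find_fixed_points(lambda, r2)
    for (i in seq_len(nrow(fps))) {
      v <- reduced_flow(c(fps$dz[i], fps$theta[i]), alpha = 1.3,
                        lambda = lambda, r2 = r2)
      expect_lt(sqrt(sum(v^2)), 1e-10)
    }
  }
  # unregularized flow, literal evaluation at (-a, a) with alpha = 1
  a <- 0.17
  v <- reduced_flow(c(-a, a), alpha = 1, lambda = 0, r2 = r2)
  expect_equal(v, c(2 * a, -2 * a))
  # origin is a fixed point of the full flow
  expect_equal(reduced_flow(c(0, 0), 0.7, 0.1, r2), c(0, 0))
})

test_that("the fixed-point census and stability switch at lambda = 1/r2", {
  weak <- find_fixed_points(0.1, r2)
  expect_equal(nrow(weak), 3L)
  expect_equal(sort(weak$dz[weak$stability == "stable"]),
               c(-r / sqrt(2), r / sqrt(2)))
  expect_identical(weak["origin", "stability"], "unstable")

  strong <- find_fixed_points(20, r2)
  expect_equal(nrow(strong), 5L)
  anti <- strong[grepl("anti", rownames(strong)), ]
  expect_equal(sort(abs(anti$dz)), rep(sqrt((r2 - 1 / 20) / 2), 2))
  expect_equal(anti$dz, -anti$theta)
  expect_true(all(anti$stability == "unstable"))

  # independent oracle: classify stability from a finite-difference Jacobian
  for (i in seq_len(nrow(strong))) {
    p <- c(strong$dz[i], strong$theta[i])
    h <- 1e-6
    J <- cbind((reduced_flow(p + c(h, 0), 1, 20, r2) -
                reduced_flow(p - c(h, 0), 1, 20, r2)) / (2 * h),
               (reduced_flow(p + c(0, h), 1, 20, r2) -
                reduced_flow(p - c(0, h), 1, 20, r2)) / (2 * h))
    stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
    expect_identical(stable, strong$stability[i] == "stable")
  }
})

test_that("integration stays at stable fixed points and converges from the reversal state", {
  at_fp <- reduced_integrate(c(r / sqrt(2), r / sqrt(2)), 1.5, 0.1, r2)
  expect_equal(unname(at_fp$terminal), c(r / sqrt(2), r / sqrt(2)),
               tolerance = 1e-7)
  # alpha = 2: representational pathway, back to the positive fixed point
  up <- reduced_integrate(rev_start, 2, 0.1, r2)
  expect_true(up$converged)
  expect_identical(up$fixed_point, "ring+")
  # alpha = 0.5: relational pathway, theta flips to the negative fixed point
  down <- reduced_integrate(rev_start, 0.5, 0.1, r2)
  expect_identical(down$fixed_point, "ring-")
})

test_that("the unregularized system lands on the line attractor predicted in closed form", {
  set.seed(31)
  for (i in 1:8) {
    s0 <- runif(2, -0.5, 0.5)
    alpha <- exp(runif(1, log(0.1), log(10)))
    tr <- reduced_integrate(s0, alpha, lambda = 0, r2 = r2, t_max = 1e5)
    want <- line_attractor_point(s0[1], s0[2], alpha)
    expect_lt(max(abs(tr$terminal - want)), 1e-6)
    # conservation of dz + alpha^2 * theta along the whole trajectory
    cons <- tr$states[, "dz"] + alpha^2 * tr$states[, "theta"]
    expect_lt(max(abs(cons - cons[1])), 1e-6)
  }
  # already on the line: stays put for any alpha
  expect_equal(line_attractor_point(0.3, 0.3, 2.7), 0.3)
  expect_equal(line_attractor_point(-0.4, 0.4, 1), 0)
})

test_that("the weak-regularization closed forms behave as derived", {
  # symmetric reversal endpoint: (r/sqrt(2)) (alpha^2-1)/(alpha^2+1)
  for (alpha in c(0.3, 1, 2.5)) {
    got <- line_attractor_point(rev_start[1], rev_start[2], alpha)
    expect_equal(got, (r / sqrt(2)) * (alpha^2 - 1) / (alpha^2 + 1))
  }
  expect_equal(line_attractor_point(rev_start[1], rev_start[2], 1), 0)
  # general rule change: zero exactly on alpha1 * alpha2 = 1 ...
  expect_equal(general_endpoint(2, 0.5, r), 0)
  expect_equal(general_endpoint(0.25, 4, r), 0)
  # ... consistent with the symmetric case ...
  for (alpha in c(0.4, 1.7)) {
    expect_equal(general_endpoint(alpha, alpha, r),
                 line_attractor_point(rev_start[1], rev_start[2], alpha))
  }
  # ... and positive (representational) iff alpha1 * alpha2 > 1
  expect_equal(general_endpoint(2, 1, r), 0.0559017, tolerance = 1e-6)
  expect_lt(general_endpoint(0.5, 0.5, r), 0)
})

test_that("the reduced loss is non-increasing along every trajectory", {
  for (alpha in c(0.4, 2.2)) {
    tr <- reduced_integrate(rev_start, alpha, 0.1, r2)
    L <- reduced_loss(tr$states[, "dz"], tr$states[, "theta"], 0.1, r2)
    expect_lte(max(diff(L)), 1e-9)
  }
})

test_that("trajectories obey the alpha <-> 1/alpha swap symmetry", {
  # the image of a trajectory under (dz, theta) -> (-theta, -dz) is the
  # trajectory of the 1/alpha system started from the mapped state
  set.seed(7)
  for (i in 1:4) {
    s0 <- runif(2, -0.4, 0.4)
    alpha <- exp(runif(1, log(0.3), log(3)))
    t1 <- reduced_integrate(s0, alpha, 0.1, r2)
    t2 <- reduced_integrate(c(-s0[2], -s0[1]), 1 / alpha, 0.1, r2)
    mapped <- c(-t1$terminal[2], -t1$terminal[1])
    expect_lt(max(abs(t2$terminal - mapped)), 1e-5)
  }
})

test_that("the weak-regularization product rule predicts the pathway label", {
  expect_identical(predict_pathway(2, 2), "representational")
  expect_identical(predict_pathway(0.5, 0.5), "relational")
  expect_identical(predict_pathway(1, 1), "boundary")
  expect_identical(predict_pathway(c(0.5, 2), c(0.5, 2)),
                   c("relational", "representational"))
})

test_that("the integrated pathway map agrees with the product rule off the boundary band", {
  g <- c(0.3, 0.7, 1.5, 3)
  map <- pathway_map(g, g, lambda = 0.01, r2 = r2)  # weak regularization
  pred <- predict_pathway(map$alpha1, map$alpha2, band = 0.1)
  off_band <- pred != "boundary"
  expect_true(all(map$label[off_band] == pred[off_band]))
})
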