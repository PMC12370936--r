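test_that("the classifier implements the sign table including the dead zone", {
  # relational: theta flips, post-switch dz sign kept
  oc <- classify_pathway(fake_trajectory(0.2, -0.2, -0.2, -0.2))
  expect_identical(oc$label, "relational")
  # representational: dz flips back, theta kept
  oc <- classify_pathway(fake_trajectory(0.2, 0.2, -0.2, 0.2))
  expect_identical(oc$label, "representational")
  # both kept: inconsistent state, excluded
  oc <- classify_pathway(fake_trajectory(0.2, 0.2, -0.2, -0.2))
  expect_identical(oc$label, "excluded")
  # both changed: also excluded
  oc <- classify_pathway(fake_trajectory(0.2, -0.2, -0.2, 0.2))
  expect_identical(oc$label, "excluded")
  # mirrored solution (negative phase-1 theta) classifies symmetrically
  oc <- classify_pathway(fake_trajectory(-0.2, 0.2, 0.2, 0.2))
  expect_identical(oc$label, "relational")
  # dead zone: a vanishing probe has no sign, and the hit is reported
  oc <- classify_pathway(fake_trajectory(0.2, 0.2, -0.2, 1e-9))
  expect_identical(oc$label, "representational")
  expect_true(oc$dead_zone)
  oc <- classify_pathway(fake_trajectory(0.2, 1e-9, -0.2, -0.2))
  expect_identical(oc$label, "relational")
})

test_that("the relational fraction drops excluded outcomes and is order/duplication invariant", {
  labels <- c("representational", "representational", "representational",
              "relational")
  expect_equal(relational_fraction(labels), 0.25)
  expect_equal(relational_fraction(rep("relational", 5)), 1)
  with_excluded <- c(labels, "excluded", "excluded")
  expect_equal(relational_fraction(with_excluded),
               relational_fraction(labels))
  set.seed(1)
  expect_equal(relational_fraction(sample(with_excluded)),
               relational_fraction(with_excluded))
  expect_equal(relational_fraction(rep(with_excluded, 2)),
               relational_fraction(with_excluded))
  expect_error(relational_fraction(c("excluded", "excluded")), "empty cell")
})

test_that("cell summaries count labels and give a binomial CI", {
  ocs <- list(classify_pathway(fake_trajectory(0.2, -0.2, -0.2, -0.2)),
              classify_pathway(fake_trajectory(0.2, 0.2, -0.2, 0.2)),
              classify_pathway(fake_trajectory(0.2, 0.2, -0.2, -0.2)))
  s <- summarize_cell(ocs)
  expect_equal(s$n_relational, 1L)
  expect_equal(s$n_representational, 1L)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$fraction, 0.5)
  expect_true(s$ci_lower < 0.5 && s$ci_upper > 0.5)
})

test_that("the logistic fit recovers a step transition on a fine grid", {
  alphas <- seq(0.2, 0.5, by = 0.02)
  fractions <- as.numeric(alphas < 0.34)
  fit <- fit_inflection(alphas, fractions)
  expect_lt(abs(fit$d - 0.34), 0.02)
  expect_gt(fit$c, 0)
  # midpoint identity: the fitted curve crosses 0.5 exactly at d
  expect_equal(predict(fit, fit$d), 0.5)
})

test_that("degenerate fraction data is an explicit failure, not a silent fit", {
  alphas <- seq(0.1, 0.8, length.out = 6)
  expect_error(fit_inflection(alphas, rep(0.5, 6)), "no transition")
  expect_error(fit_inflection(alphas, rep(0.9, 6)), "no transition")
  expect_error(fit_inflection(alphas[1:3], c(1, 0.5, 0)), "length")
})

test_that("the inflection CI covers the truth for synthetic binomial fractions", {
  # parameter recovery: logistic (c0 = 14, d0 = 0.34) + binomial noise at
  # n = 100 per grid point; d0 must fall inside d +/- ci95 in >= 90% of runs
  c0 <- 14; d0 <- 0.34
  alphas <- seq(0.15, 0.55, by = 0.025)  # grid resolving the transition
  p <- 1 / (1 + exp(c0 * (alphas - d0)))
  set.seed(2024)
  covered <- replicate(150, {
    frac <- rbinom(length(alphas), 100, p) / 100
    fit <- tryCatch(fit_inflection(alphas, frac, n = 100),
                    error = function(e) NULL)
    !is.null(fit) && abs(fit$d - d0) <= fit$ci95_d
  })
  expect_gte(mean(covered), 0.9)
})
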