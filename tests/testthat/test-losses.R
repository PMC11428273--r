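test_that("sigmoid cross-entropy matches its closed forms", {
  expect_equal(sigmoid_cross_entropy(0, 1), log(2), tolerance = 1e-9)
  expect_lte(sigmoid_cross_entropy(30, 1), 1e-12)
  expect_equal(sigmoid_cross_entropy(c(0, 0), c(1, 0)), 2 * log(2),
               tolerance = 1e-9)
  expect_error(sigmoid_cross_entropy(c(0, 0), c(1, 0.5)), "0 or 1")
  expect_error(sigmoid_cross_entropy(0, c(1, 0)), "length")
})

test_that("stabilized cross-entropy agrees with the naive formula", {
  set.seed(3)
  a <- runif(200, -20, 20)
  b <- rbinom(200, 1, 0.5)
  naive <- -sum(b * log(plogis(a)) + (1 - b) * log(1 - plogis(a)))
  expect_equal(sigmoid_cross_entropy(a, b), naive, tolerance = 1e-9)
})

test_that("adversarial losses reward fooling / punish confusion", {
  expect_equal(generator_adv_loss(0), log(2), tolerance = 1e-9)
  expect_lt(generator_adv_loss(30), 1e-12)
  # monotone: raising any fake logit lowers the generator loss
  l <- runif(5, -2, 2)
  for (i in seq_along(l)) {
    l2 <- l
    l2[i] <- l2[i] + 0.5
    expect_lt(generator_adv_loss(l2), generator_adv_loss(l))
  }

  expect_equal(discriminator_loss(0, 0), 2 * log(2), tolerance = 1e-9)
  expect_lt(discriminator_loss(-30, 30), 1e-12)
  # symmetric under swapping roles with flipped logits
  f <- rnorm(4); r <- rnorm(4)
  expect_equal(discriminator_loss(f, r), discriminator_loss(-r, -f),
               tolerance = 1e-9)
})

test_that("absolute-error loss is the per-window Euclidean norm", {
  expect_equal(absolute_error_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(absolute_error_loss(c(1, 2, 3), c(2, 2, 2)), sqrt(2))
  y <- matrix(rnorm(12), 3)
  yh <- matrix(rnorm(12), 3)
  expect_equal(absolute_error_loss(3 * y, 3 * yh),
               3 * absolute_error_loss(y, yh), tolerance = 1e-9)
  expect_equal(absolute_error_loss(y, yh),
               mean(sqrt(rowSums((y - yh)^2))))
  expect_error(absolute_error_loss(1:3, 1:4), "mismatch")
})

test_that("the pairwise sign function is three-valued", {
  expect_identical(sign_pair(3, 1), 1)
  expect_identical(sign_pair(2, 2), 0)
  expect_identical(sign_pair(1, 4), -1)
  expect_error(sign_pair(NaN, 1), "finite")
})

test_that("trend loss hits 0 / 1 / 2 on the canonical direction cases", {
  expect_equal(trend_loss(c(1, 3, 2), c(1, 3, 2), anchor = 0), 0)
  # strictly increasing truth vs strictly decreasing forecast
  expect_equal(trend_loss(c(1, 2, 3), c(-1, -2, -3), anchor = 0), 2)
  # increasing truth vs flat forecast (anchored at the flat level)
  expect_equal(trend_loss(c(1, 2, 3), c(0, 0, 0), anchor = 0), 1)
  expect_true(trend_loss(rnorm(6), rnorm(6), anchor = 0) >= 0)
})

test_that("trend loss is invariant to shared strictly monotone transforms", {
  set.seed(12)
  for (rep in 1:10) {
    anchor <- rnorm(1)
    y <- rnorm(5)
    yh <- rnorm(5)
    f <- function(v) exp(v)  # strictly increasing
    expect_equal(trend_loss(y, yh, anchor),
                 trend_loss(f(y), f(yh), f(anchor)))
  }
})

test_that("distribution loss is the absolute gap between window means", {
  expect_equal(distribution_loss(c(1, 1, 1, 1), c(0.25, 0.25, 0.25, 0.25)),
               0.75)
  expect_equal(distribution_loss(c(0, 2), c(1, 1)), 0)
  y <- rnorm(8)
  yh <- rnorm(8)
  expect_equal(distribution_loss(y, yh + 0.3),
               abs(mean(y) - mean(yh) - 0.3), tolerance = 1e-12)
})

test_that("the total generator loss is the lambda-weighted sum", {
  # engineered window: ||y - yh|| = 0.1 exactly; other components fall out
  y <- c(0.1, 0.2)
  yh <- y - c(0.1 / sqrt(2), -0.1 / sqrt(2))
  expect_equal(absolute_error_loss(y, yh), 0.1)
  gt <- generator_total_loss(y, yh, disc_logits_fake = 0,
                             weights = loss_weights(), anchor = 0)
  expect_equal(gt$components$adv, log(2), tolerance = 1e-9)
  expect_equal(gt$total,
               50 * gt$components$ae + 3 * gt$components$trend +
                 1 * gt$components$dist + 1 * gt$components$adv)
  # the printed worked example: weighted sum of (0.1, 2, 0.3, 0.6931)
  expect_equal(50 * 0.1 + 3 * 2 + 1 * 0.3 + 1 * 0.6931, 11.9931)

  # all-zero components give zero
  z <- generator_total_loss(y, y, disc_logits_fake = 30,
                            weights = loss_weights(), anchor = 0)
  expect_lt(z$total, 1e-10)
  # lambda_t = 0 removes exactly the trend contribution
  ab <- generator_total_loss(y, yh, 0, loss_weights(lambda_t = 0), anchor = 0)
  expect_equal(gt$total - ab$total, 3 * gt$components$trend)
})
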