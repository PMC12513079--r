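test_that("dice loss matches hand computations", {
  g <- matrix(0, 4, 4); g[1:2, 1:2] <- 1
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)

  p_disjoint <- matrix(0, 4, 4); p_disjoint[3:4, 3:4] <- 1
  expect_equal(dice_loss(p_disjoint, g), 1, tolerance = 1e-6)

  # P covers exactly half of G with nothing extra: 1 - 2(|G|/2)/(3|G|/2)
  p_half <- matrix(0, 4, 4); p_half[1:2, 1] <- 1
  expect_equal(dice_loss(p_half, g), 1 / 3, tolerance = 1e-5)
})

test_that("focal loss reduces to its closed forms", {
  g <- matrix(1, 3, 3)
  expect_equal(focal_loss(g, g), 0, tolerance = 1e-5)

  # gamma_f = 0, alpha_t = 1 recovers cross-entropy
  set.seed(3)
  p <- matrix(runif(9, 0.05, 0.95), 3, 3)
  gb <- matrix(rbinom(9, 1, 0.5), 3, 3)
  expect_equal(focal_loss(p, gb, alpha_t = 1, gamma_f = 0), ce_loss(p, gb))

  # single pixel p_t = 0.5: 0.25 * 0.25 * ln 2
  expect_equal(focal_loss(matrix(0.5), matrix(1)),
               0.25 * 0.25 * log(2), tolerance = 1e-10)
})

test_that("cross-entropy matches closed forms and is monotone in error", {
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(ce_loss(g, g), 1e-5)
  expect_equal(ce_loss(matrix(0.5, 2, 2), g), log(2), tolerance = 1e-10)

  p <- matrix(c(0.8, 0.3, 0.6, 0.4), 2, 2)
  base <- ce_loss(p, g)
  for (i in 1:4) {
    worse <- p
    worse[i] <- worse[i] + (if (g[i] == 1) -0.1 else 0.1)
    expect_gt(ce_loss(worse, g), base)
  }
  # literal single-term form keeps only the foreground term
  expect_equal(ce_loss(p, g, literal = TRUE), mean(-g * log(p)))
})

test_that("hybrid loss is the stated weighted combination", {
  g <- matrix(0, 4, 4); g[2:3, 2:3] <- 1
  expect_lt(hybrid_loss(g, g), 1e-4)

  set.seed(9)
  p <- matrix(runif(16, 0.01, 0.99), 4, 4)
  only_dice <- hybrid_loss_config(alpha = 1, beta = 0, gamma_w = 0)
  expect_equal(hybrid_loss(p, g, only_dice), dice_loss(p, g))

  cfg <- hybrid_loss_config()
  expect_equal(cfg$alpha, 0.1)
  expect_equal(cfg$beta, 0.45)
  expect_equal(cfg$gamma_w, 0.45)
  d <- dice_loss(p, g)
  f <- focal_loss(p, g, cfg$focal_alpha_t, cfg$focal_gamma_f)
  ce <- ce_loss(p, g)
  expect_equal(hybrid_loss(p, g, cfg), 0.1 * d + 0.45 * f + 0.45 * ce)

  expect_error(hybrid_loss_config(alpha = 0.5, beta = 0.5, gamma_w = 0.5),
               "sum to 1")
  expect_error(hybrid_loss_config(alpha = -0.1, beta = 0.6, gamma_w = 0.5),
               "non-negative")
})

test_that("the training engine computes the same hybrid loss as the R reference", {
  set.seed(21)
  m <- build_model(model_config(levels = 2, filter_widths = c(2, 3)),
                   quiet = TRUE)
  x <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2))
  g <- array(rbinom(8 * 8 * 2, 1, 0.3), dim = c(8, 8, 2))
  # lr = 0: the reported loss is the batch loss at the current weights,
  # under training-mode batch statistics
  l_engine <- ovseg:::.unetpp_train_batch(m$ptr, x, g, 0,
                                          0.1, 0.45, 0.45, 0.25, 2)
  p <- ovseg:::.unetpp_forward(m$ptr, x, TRUE)
  l_ref <- 0.1 * mean(vapply(1:2, function(b)
    dice_loss(p[, , b], g[, , b]), numeric(1))) +
    0.45 * focal_loss(p, g) + 0.45 * ce_loss(p, g)
  expect_equal(l_engine, l_ref, tolerance = 1e-4)
})
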