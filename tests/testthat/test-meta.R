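three_study <- data.frame(theta = c(0.2, 0, 0.4), se = 0.1)

test_that("fixed-effect pooling matches the hand-computed example", {
  fe <- fixed_effect_pool(three_study)
  expect_equal(fe$theta_hat, 0.2)
  expect_equal(fe$se_hat, 1 / sqrt(300), tolerance = 1e-12)
  expect_equal(fe$Q, 8)
  expect_equal(fe$df, 2L)
  expect_equal(fe$i2, 75)
  expect_equal(fe$model, "fixed")

  dup <- fixed_effect_pool(data.frame(theta = c(0.1, 0.1), se = 0.1))
  expect_equal(dup$theta_hat, 0.1)
  expect_equal(dup$Q, 0)
  expect_equal(dup$i2, 0)

  single <- fixed_effect_pool(data.frame(theta = 0.3, se = 0.1))
  expect_equal(single$model, "not_pooled")
  expect_equal(single$theta_hat, 0.3)
  expect_true(is.na(single$Q))
})

test_that("DerSimonian-Laird tau2 is the truncated method-of-moments value", {
  expect_equal(dl_tau2(three_study), 0.03, tolerance = 1e-12)  # C = 200, (8-2)/200
  expect_equal(dl_tau2(data.frame(theta = c(0.1, 0.1, 0.1), se = 0.1)), 0)
  # Q < df truncates at exactly zero
  expect_identical(dl_tau2(data.frame(theta = c(0.1, 0.11, 0.09), se = 0.3)), 0)
})

test_that("random-effects pooling reweights by se^2 + tau2", {
  re <- random_effects_pool(three_study)
  expect_equal(re$theta_hat, 0.2)
  expect_equal(re$se_hat, 1 / sqrt(75), tolerance = 1e-12)  # w* = 25 each
  expect_equal(re$model, "random")
  # homogeneous limit reduces to fixed effect
  hom <- data.frame(theta = c(0.1, 0.12, 0.11), se = c(0.2, 0.25, 0.22))
  expect_equal(random_effects_pool(hom)$theta_hat, fixed_effect_pool(hom)$theta_hat)
  expect_equal(random_effects_pool(hom)$se_hat, fixed_effect_pool(hom)$se_hat)
  # a study with enormous se carries vanishing weight
  infl <- rbind(three_study, data.frame(theta = 50, se = 1e6))
  expect_equal(random_effects_pool(infl)$theta_hat,
               random_effects_pool(three_study)$theta_hat, tolerance = 1e-4)
})

test_that("the I-squared switch selects the model, inclusively at 50", {
  expect_equal(select_and_pool(three_study)$model, "random")        # I2 = 75
  expect_equal(select_and_pool(data.frame(theta = c(0.1, 0.1), se = 0.1))$model,
               "fixed")                                             # I2 = 0
  boundary <- data.frame(theta = c(0, 2), se = 1)                   # Q = 2, I2 = 50
  expect_equal(fixed_effect_pool(boundary)$i2, 50)
  expect_equal(select_and_pool(boundary)$model, "random")
})

test_that("random-effects se never falls below the fixed-effect se", {
  set.seed(55)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    d <- data.frame(theta = rnorm(k, 0, 0.3), se = runif(k, 0.05, 0.5))
    expect_gte(random_effects_pool(d)$se_hat, fixed_effect_pool(d)$se_hat - 1e-12)
  }
})

test_that("pooling matches an exact-fraction oracle to 12 decimals", {
  instances <- list(
    list(theta = list(frac(1, 5), frac(0), frac(2, 5)), w = c(100, 100, 100)),
    list(theta = list(frac(3, 10), frac(-1, 10), frac(1, 2), frac(1, 4)),
         w = c(25, 100, 4, 16)),
    list(theta = list(frac(1, 3), frac(1, 7)), w = c(9, 49)),
    list(theta = list(frac(-2, 5), frac(-1, 5), frac(0), frac(1, 5)),
         w = c(400, 100, 50, 25))
  )
  for (inst in instances) {
    oracle <- dl_oracle(inst$theta, inst$w)
    d <- data.frame(theta = vapply(inst$theta, f_num, 1), se = 1 / sqrt(inst$w))
    fe <- fixed_effect_pool(d)
    re <- random_effects_pool(d)
    expect_equal(fe$theta_hat, oracle$theta_fe, tolerance = 1e-12)
    expect_equal(fe$se_hat, oracle$se_fe, tolerance = 1e-12)
    expect_equal(fe$Q, oracle$Q, tolerance = 1e-12)
    expect_equal(fe$i2, oracle$i2, tolerance = 1e-12)
    expect_equal(dl_tau2(d), oracle$tau2, tolerance = 1e-12)
    expect_equal(re$theta_hat, oracle$theta_re, tolerance = 1e-12)
    expect_equal(re$se_hat, oracle$se_re, tolerance = 1e-12)
  }
})

test_that("pooling agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (rep in 1:8) {
    k <- sample(3:9, 1)
    theta <- rnorm(k, 0.1, 0.3)
    se <- runif(k, 0.05, 0.5)
    d <- data.frame(theta = theta, se = se)
    fe <- fixed_effect_pool(d)
    ref_fe <- metafor::rma(yi = theta, sei = se, method = "FE")
    expect_equal(fe$theta_hat, as.numeric(ref_fe$beta), tolerance = 1e-10)
    expect_equal(fe$se_hat, ref_fe$se, tolerance = 1e-10)
    expect_equal(fe$Q, ref_fe$QE, tolerance = 1e-10)
    re <- random_effects_pool(d)
    ref_re <- metafor::rma(yi = theta, sei = se, method = "DL")
    expect_equal(re$theta_hat, as.numeric(ref_re$beta), tolerance = 1e-10)
    expect_equal(re$se_hat, ref_re$se, tolerance = 1e-10)
    expect_equal(re$tau2, ref_re$tau2, tolerance = 1e-10)
    expect_equal(re$i2, ref_re$I2, tolerance = 1e-8)
  }
})

test_that("pooled CI is exponentiated on the ratio scale only", {
  d <- data.frame(theta = c(0.2, 0.1, 0.3), se = 0.1)
  or_scale <- select_and_pool(d)
  expect_equal(or_scale$ci_low, exp(or_scale$theta_hat - qnorm(0.975) * or_scale$se_hat))
  d$effect_scale <- "smd"
  smd_scale <- select_and_pool(d)
  expect_equal(smd_scale$ci_low, smd_scale$theta_hat - qnorm(0.975) * smd_scale$se_hat)
})
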