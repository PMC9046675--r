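test_that("log-scale effect and SE are recovered from a ratio CI", {
  est <- theta_from_ratio_ci(0.954, 0.932, 0.977)
  expect_equal(est$theta, -0.0470916075, tolerance = 1e-8)
  expect_equal(est$se, 0.0120292612, tolerance = 1e-8)

  sym <- theta_from_ratio_ci(1.0, 0.5, 2.0)
  expect_equal(sym$theta, 0)
  expect_equal(sym$se, 0.3536530192, tolerance = 1e-8)

  expect_error(theta_from_ratio_ci(1.0, -0.1, 2.0), class = "metasynopsis_error_domain")
  expect_warning(theta_from_ratio_ci(3.0, 0.5, 2.0), "outside")
})

test_that("CI round-trips through (theta, se) to six decimals", {
  z <- qnorm(0.975)
  grid <- expand.grid(or = c(0.7, 0.954, 1.05, 2.4), width = c(1.1, 1.5, 3))
  for (i in seq_len(nrow(grid))) {
    or <- grid$or[i]
    lo <- or / grid$width[i]
    hi <- or * grid$width[i]
    est <- theta_from_ratio_ci(or, lo, hi)
    expect_equal(exp(est$theta - z * est$se), lo, tolerance = 1e-6)
    expect_equal(exp(est$theta + z * est$se), hi, tolerance = 1e-6)
  }
})

test_that("additive odds ratio collapses genotypes to allele counts", {
  est <- additive_or_from_counts(c(85, 30, 0), c(90, 20, 0))
  expect_equal(est$or, 1.5, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 30 + 1 / 200 + 1 / 20 + 1 / 200), tolerance = 1e-12)

  same <- additive_or_from_counts(c(50, 40, 10), c(50, 40, 10))
  expect_equal(same$theta, 0, tolerance = 1e-12)

  # a zero allele cell stays finite through the continuity correction
  cc <- additive_or_from_counts(c(100, 0, 0), c(80, 20, 0))
  expect_true(is.finite(cc$theta) && is.finite(cc$se))

  expect_error(additive_or_from_counts(c(0, 0, 0), c(10, 10, 10)),
               class = "metasynopsis_error_degenerate")
})

test_that("swapping case and control groups inverts the odds ratio", {
  set.seed(101)
  for (rep in 1:10) {
    ca <- as.integer(rmultinom(1, 500, c(0.5, 0.4, 0.1)))
    co <- as.integer(rmultinom(1, 400, c(0.45, 0.45, 0.1)))
    a <- additive_or_from_counts(ca, co)
    b <- additive_or_from_counts(co, ca)
    expect_equal(a$theta, -b$theta, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
})

test_that("standardized mean difference uses the pooled SD", {
  est <- smd_from_group_stats(c(12, 2, 50), c(10, 2, 50))
  expect_equal(est$d, 1)
  expect_equal(est$se, sqrt(0.04 + 1 / 200), tolerance = 1e-12)
  expect_equal(smd_from_group_stats(c(5, 1.3, 20), c(5, 1.1, 25))$d, 0)
  # Hedges correction shrinks towards zero
  expect_lt(abs(smd_from_group_stats(c(12, 2, 10), c(10, 2, 10), hedges = TRUE)$d), 1)
  expect_error(smd_from_group_stats(c(1, 0, 10), c(0, 0, 10)),
               class = "metasynopsis_error_degenerate")
})

test_that("chi-square HWE test matches hand-computed expectations", {
  perfect <- hwe_test(c(25, 50, 25), method = "chisq")
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)

  skew <- hwe_test(c(10, 10, 10), method = "chisq")
  expect_equal(skew$chi2, 10 / 3, tolerance = 1e-10)
  expect_equal(skew$expected, c(7.5, 15, 7.5))
  expect_equal(skew$p, pchisq(10 / 3, 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_warning(mono <- hwe_test(c(0, 0, 40)), "monomorphic")
  expect_equal(mono$p, 1)
})

test_that("exact HWE test matches a brute-force conditional enumeration", {
  # independent oracle: enumerate every genotype assignment of n subjects,
  # weight by HWE probabilities, condition on the observed allele count
  exact_oracle <- function(g, q = 0.37) {
    n <- sum(g)
    m <- 2 * g[3] + g[2]
    probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    grid <- expand.grid(rep(list(0:2), n))        # per-subject minor-allele dose
    keep <- rowSums(grid) == m
    w <- apply(grid[keep, , drop = FALSE], 1, function(r) prod(probs[r + 1]))
    hets <- rowSums(grid[keep, , drop = FALSE] == 1)
    cond <- tapply(w, hets, sum)
    cond <- cond / sum(cond)
    qhat <- m / (2 * n)
    ex <- n * c((1 - qhat)^2, 2 * qhat * (1 - qhat), qhat^2)
    chi_of <- function(h) { aa <- (m - h) / 2; sum((c(n - aa - h, h, aa) - ex)^2 / ex) }
    chi <- vapply(as.integer(names(cond)), chi_of, numeric(1))
    sum(cond[chi >= chi_of(g[2]) - 1e-9])
  }
  for (g in list(c(3, 1, 2), c(2, 2, 2), c(4, 0, 2))) {
    expect_equal(hwe_test(g, method = "exact")$p, exact_oracle(g), tolerance = 1e-9)
  }
  # mid-p never exceeds the conservative p
  expect_lte(hwe_test(c(10, 10, 10), method = "exact")$p_mid,
             hwe_test(c(10, 10, 10), method = "exact")$p)
})

test_that("exact and asymptotic HWE p-values agree on large samples", {
  # mid-p variant vs chi-square, totals of 500 drawn under HWE
  set.seed(90)
  diffs <- replicate(150, {
    g <- as.integer(rmultinom(1, 500, c(0.49, 0.42, 0.09)))
    abs(hwe_test(g, "exact")$p_mid - hwe_test(g, "chisq")$p)
  })
  expect_lte(mean(diffs), 0.02)
})
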