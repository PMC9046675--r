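test_that("Venice letter triplets map to categories as stated", {
  expect_equal(venice_category("AAA"), "strong")
  expect_equal(venice_category("ABA"), "moderate")
  expect_equal(venice_category("ABC"), "weak")
  expect_equal(venice_category("ACA"), "weak")
  expect_equal(venice_category("BCC"), "weak")
  expect_equal(venice_category("B-C"), "weak")      # any C is weak
  expect_equal(venice_category("AA-"), "moderate")  # unavailable blocks all-A
  expect_equal(format(parse_grade_triplet("B-C")), "B-C")
  expect_error(parse_grade_triplet("AAX"), class = "metasynopsis_error_domain")
})

test_that("grade_venice applies the amount / replication / bias rules", {
  meta_stub <- function(i2, k = 5) {
    structure(list(i2 = i2, k = k), class = "meta_result")
  }
  bias_stub <- function(egger_p = 0.5, begg_p = 0.5) {
    structure(list(egger = list(p = egger_p), begg = list(p = begg_p)),
              class = "bias_result")
  }
  sens_stub <- function(robust = TRUE) {
    structure(list(robust = robust), class = "sensitivity_report")
  }
  clean <- grade_venice(meta_stub(0), bias_stub(), sens_stub(),
                        minor_allele_count = 40000)
  expect_equal(format(clean), "AAA")
  expect_equal(format(grade_venice(meta_stub(40), bias_stub(), sens_stub(),
                                   minor_allele_count = 40000)), "ABA")
  expect_equal(format(grade_venice(meta_stub(0), bias_stub(egger_p = 0.02),
                                   sens_stub(), minor_allele_count = 40000)), "AAC")
  expect_equal(format(grade_venice(meta_stub(0), bias_stub(), sens_stub(FALSE),
                                   minor_allele_count = 40000)), "AAC")
  # amount thresholds: boundaries fall to B, below 100 to C
  expect_equal(grade_venice(meta_stub(0), bias_stub(), sens_stub(),
                            minor_allele_count = 1000)$amount, "B")
  expect_equal(grade_venice(meta_stub(0), bias_stub(), sens_stub(),
                            minor_allele_count = 99)$amount, "C")
  # missing inputs grade unavailable
  missing <- grade_venice(meta_stub(NA_real_))
  expect_equal(format(missing), "---")
})

test_that("minor-allele counts come from genotype counts or maf fallback", {
  df <- make_studies(3, case_AA = c(50, 60, 70), case_Aa = c(30, 20, 25),
                     case_aa = c(5, 4, 6), ctrl_AA = c(55, 65, 75),
                     ctrl_Aa = c(35, 25, 20), ctrl_aa = c(6, 3, 2),
                     n_cases = c(85, 84, 101), n_controls = c(96, 93, 97))
  ds <- group_into_datasets(derive_effects(df))[[1]]
  mac <- metasynopsis:::dataset_minor_alleles(ds)
  expect_equal(mac, sum(30, 20, 25, 35, 25, 20) + 2 * sum(5, 4, 6, 6, 3, 2))
  # without counts, 2 * N * maf
  df2 <- make_studies(2, beta = c(0.1, 0.2), se = c(0.05, 0.05),
                      n_cases = c(500, 500), n_controls = c(500, 500))
  ds2 <- group_into_datasets(derive_effects(df2))[[1]]
  expect_equal(metasynopsis:::dataset_minor_alleles(ds2, maf = 0.3), 2 * 2000 * 0.3)
})

test_that("power against a target odds ratio behaves at its limits", {
  expect_equal(power_at_or(1e-6, 0.05, 1.2), 1, tolerance = 1e-9)
  expect_equal(power_at_or(0.1, 0.05, 1 + 1e-9), 0.05, tolerance = 1e-5)
  expect_equal(power_at_or(0.0922, 0.05, 1.2), 0.5070196, tolerance = 1e-6)
  # reciprocal targets give identical power
  expect_equal(power_at_or(0.1, 0.05, 1.2), power_at_or(0.1, 0.05, 1 / 1.2))
  # monotone: decreasing in se, increasing in |log or1|
  se_grid <- seq(0.02, 0.5, by = 0.02)
  expect_true(all(diff(power_at_or(se_grid, 0.05, 1.2)) < 0))
  or_grid <- seq(1.05, 2, by = 0.05)
  expect_true(all(diff(vapply(or_grid, function(o) power_at_or(0.1, 0.05, o), 1)) > 0))
  expect_error(power_at_or(0.1, 0.05, 1), class = "metasynopsis_error_domain")
})

test_that("FPRP follows its closed form and monotonicities", {
  expect_equal(fprp(0.05, 1)$value, 0.05 * 0.95 / (0.05 * 0.95 + 0.05),
               tolerance = 1e-12)
  expect_equal(fprp(0.05, 1)$value, 0.4871795, tolerance = 1e-6)
  expect_gt(fprp(0.05, 1e-10)$value, 0.999)  # power -> 0 drives FPRP -> 1
  alpha_grid <- seq(0.001, 0.2, by = 0.001)
  vals <- vapply(alpha_grid, function(a) fprp(a, 0.5)$value, 1)
  expect_true(all(diff(vals) > 0))
  power_grid <- seq(0.05, 1, by = 0.05)
  vals <- vapply(power_grid, function(p) fprp(0.01, p)$value, 1)
  expect_true(all(diff(vals) < 0))
  pi_grid <- seq(0.01, 0.5, by = 0.01)
  vals <- vapply(pi_grid, function(pi) fprp(0.01, 0.5, pi)$value, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("FPRP categories split at 0.05 and 0.20, boundaries falling down", {
  expect_equal(fprp_category(0.040), "strong")
  expect_equal(fprp_category(0.150), "moderate")
  expect_equal(fprp_category(0.254), "weak")
  expect_equal(fprp_category(0.05), "moderate")
  expect_equal(fprp_category(0.20), "weak")
})

test_that("evidence combination shifts one level and saturates", {
  expect_equal(combine_evidence("weak", "strong")$final, "moderate")
  expect_equal(combine_evidence("strong", "weak")$final, "moderate")
  expect_equal(combine_evidence("moderate", "strong")$final, "strong")
  expect_equal(combine_evidence("strong", "strong")$final, "strong")
  expect_equal(combine_evidence("weak", "weak")$final, "weak")
  expect_equal(combine_evidence("moderate", "moderate")$final, "moderate")
  expect_error(combine_evidence("strong", "none"), class = "metasynopsis_error_domain")
})

test_that("fprp_from_pooled derives alpha from the printed p or the CI", {
  rep_p <- fprp_from_pooled(0.9, 0.85, 0.95, p = 0.001)
  expect_equal(rep_p$alpha, 0.001)
  est <- theta_from_ratio_ci(0.9, 0.85, 0.95)
  ci_p <- fprp_from_pooled(0.9, 0.85, 0.95, alpha_source = "ci_implied")
  expect_equal(ci_p$alpha, 2 * pnorm(-abs(est$theta) / est$se), tolerance = 1e-12)
  # protective effects use the reciprocal target
  expect_equal(rep_p$or1, 1 / 1.2)
  expect_equal(fprp_from_pooled(1.1, 1.05, 1.16, p = 0.001)$or1, 1.2)
  expect_error(fprp_from_pooled(0.9, 0.85, 0.95), class = "metasynopsis_error_domain")
})
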