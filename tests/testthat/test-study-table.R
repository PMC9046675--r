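write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

test_that("a well-formed table reads with no problems", {
  df <- make_studies(3, or = c(0.954, 1.1, 0.8),
                     ci_low = c(0.932, 1.0, 0.7), ci_high = c(0.977, 1.2, 0.95),
                     p = c(1e-4, 0.05, 0.01))
  x <- read_study_table(write_tsv(df))
  expect_equal(nrow(x), 3)
  expect_equal(nrow(attr(x, "problems")), 0)
  expect_true(all(x$analyzable))
  expect_equal(x$or[1], 0.954)
  expect_equal(x$ci_low[1], 0.932)
  expect_equal(x$ci_high[1], 0.977)
})

test_that("a combined '(L, U)' CI cell is normalized on read", {
  df <- make_studies(1, or = 0.954)
  df$ci_low <- NULL; df$ci_high <- NULL
  df$ci <- "(0.932, 0.977)"
  x <- read_study_table(write_tsv(df))
  expect_equal(x$ci_low, 0.932)
  expect_equal(x$ci_high, 0.977)
})

test_that("invalid rows are dropped and reported with line numbers", {
  df <- make_studies(3, case_AA = c(100, 90, 80), case_Aa = c(40, -5, 30),
                     case_aa = c(5, 5, 5), ctrl_AA = c(100, 100, 100),
                     ctrl_Aa = c(40, 40, 40), ctrl_aa = c(5, 5, 5))
  expect_warning(x <- read_study_table(write_tsv(df)), "dropped")
  expect_equal(nrow(x), 2)
  probs <- attr(x, "problems")
  expect_equal(probs$line, 3L)  # header is line 1
  expect_match(probs$message, "negative genotype count")
})

test_that("a missing mandatory column is a schema error naming it", {
  df <- make_studies(2)
  df$hwe_p_controls <- NULL
  expect_error(read_study_table(write_tsv(df)), "hwe_p_controls",
               class = "metasynopsis_error_schema")
})

test_that("p-only records are kept but marked non-analyzable", {
  df <- make_studies(2, p = c(0.01, 0.02), or = c(1.2, NA),
                     ci_low = c(1.1, NA), ci_high = c(1.3, NA))
  x <- read_study_table(write_tsv(df))
  expect_equal(x$analyzable, c(TRUE, FALSE))
})

test_that("write/read round-trips the table", {
  df <- make_studies(4, or = c(1.2, 0.8, 1.05, 0.9),
                     ci_low = c(1.05, 0.7, 0.95, 0.8),
                     ci_high = c(1.4, 0.95, 1.18, 1.02),
                     n_cases = c(100, 250, 310, 90), n_controls = c(200, 300, 400, 100))
  x <- read_study_table(write_tsv(df))
  path2 <- tempfile(fileext = ".tsv")
  write_study_table(x, path2)
  y <- read_study_table(path2)
  expect_equal(y[study_table_columns()], x[study_table_columns()])
})

test_that("allele reorientation flips effects and is an involution", {
  df <- make_studies(1, or = 2.0, ci_low = 1.5, ci_high = 2.5,
                     beta = log(2), se = 0.1, p = 0.001,
                     case_AA = 10, case_Aa = 20, case_aa = 70,
                     ctrl_AA = 30, ctrl_Aa = 40, ctrl_aa = 30,
                     effect_allele = "A", other_allele = "C")
  flipped <- orient_to_effect_allele(df, "C")
  expect_equal(flipped$or, 0.5)
  expect_equal(flipped$ci_low, 0.4)
  expect_equal(flipped$ci_high, 1 / 1.5, tolerance = 1e-12)
  expect_equal(flipped$beta, -log(2))
  expect_equal(flipped$effect_allele, "C")
  expect_equal(flipped$case_AA, 70)
  expect_equal(flipped$case_aa, 10)
  # invariants: |beta|, se, p, and totals preserved
  expect_equal(abs(flipped$beta), abs(df$beta))
  expect_equal(flipped$se, df$se)
  expect_equal(flipped$p, df$p)
  expect_equal(flipped$case_AA + flipped$case_Aa + flipped$case_aa,
               df$case_AA + df$case_Aa + df$case_aa)
  # involution
  twice <- orient_to_effect_allele(flipped, "A")
  expect_equal(twice, df)
  # identity when already oriented
  expect_equal(orient_to_effect_allele(df, "A"), df)
  # unknown allele is an error
  expect_error(orient_to_effect_allele(df, "G"), class = "metasynopsis_error_allele")
})

test_that("records partition into datasets keyed by variant and outcome", {
  df <- dplyr::bind_rows(
    make_studies(5, or = 1.1, ci_low = 1.0, ci_high = 1.21,
                 variant_id = "rs2228145", outcome_name = "asthma"),
    make_studies(3, or = 0.9, ci_low = 0.8, ci_high = 1.01,
                 variant_id = "rs2228145", outcome_name = "ulcerative colitis"))
  df$study_id <- paste0("s", seq_len(nrow(df)))
  df <- derive_effects(df)
  ds <- group_into_datasets(df)
  expect_length(ds, 2)
  ks <- unname(sort(vapply(ds, function(d) d$k, integer(1))))
  expect_equal(ks, c(3L, 5L))
  expect_true(all(vapply(ds, function(d) d$eligible, logical(1))))
  # every record lands in exactly one dataset
  ids <- unlist(lapply(ds, function(d) d$records$study_id))
  expect_setequal(ids, df$study_id)
  expect_equal(length(ids), nrow(df))
})

test_that("small datasets are flagged ineligible and duplicates rejected", {
  small <- derive_effects(make_studies(2, or = c(1.2, 1.3),
                                       ci_low = c(1.0, 1.1), ci_high = c(1.44, 1.54)))
  ds <- group_into_datasets(small)
  expect_length(ds, 1)
  expect_false(ds[[1]]$eligible)

  expect_equal(group_into_datasets(small[0, ]), list())

  dup <- derive_effects(make_studies(2, study_id = c("s1", "s1"),
                                     or = c(1.2, 1.3), ci_low = c(1.0, 1.1),
                                     ci_high = c(1.44, 1.54)))
  expect_error(group_into_datasets(dup), class = "metasynopsis_error_duplicate")
})
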