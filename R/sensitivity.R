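#' Sensitivity re-analyses for a significant association
#'
#' Re-pools the dataset (i) leaving each study out in turn, (ii) without
#' the first positive report, and (iii) without studies whose control
#' genotypes deviate from Hardy-Weinberg equilibrium at `hwe_alpha`. An
#' association is `robust` when every evaluable re-analysis stays
#' significant at `alpha` with an unchanged effect direction. Arms left
#' with fewer than two studies are marked not-evaluable and excluded from
#' the verdict.
#'
#' @param dataset An `association_dataset`.
#' @param alpha Significance level guarding the verdict (default 0.05).
#' @param hwe_alpha Control-HWE exclusion threshold (default 0.05).
#' @param switch_i2 I2 switch forwarded to [select_and_pool()].
#' @return A `sensitivity_report`: `leave_one_out` (tibble of excluded
#'   study, estimate, p, significance), `drop_first_positive` and
#'   `drop_hwe_violations` (each a `meta_result` or `NULL` when
#'   not-evaluable), `robust`, and `driver` (the excluded study that breaks
#'   significance, if any).
#' @export
sensitivity_suite <- function(dataset, alpha = 0.05, hwe_alpha = 0.05,
                              switch_i2 = 50) {
  stopifnot(inherits(dataset, "association_dataset"))
  rec <- dataset$records
  rec <- rec[!is.na(rec$theta) & !is.na(rec$se), , drop = FALSE]
  k <- nrow(rec)
  if (k < 2) {
    rlang::abort("sensitivity analyses need at least two poolable studies",
                 class = "metasynopsis_error_domain")
  }
  full <- select_and_pool(rec, switch_i2)
  direction <- sign(full$theta_hat)

  repool <- function(subset_rec) {
    if (nrow(subset_rec) < 2) return(NULL)
    select_and_pool(subset_rec, switch_i2)
  }
  arm_ok <- function(m) {
    if (is.null(m)) return(NA)
    m$p < alpha && sign(m$theta_hat) == direction
  }

  loo <- lapply(seq_len(k), function(i) repool(rec[-i, , drop = FALSE]))
  loo_tbl <- tibble::tibble(
    excluded = rec$study_id,
    theta_hat = vapply(loo, function(m) if (is.null(m)) NA_real_ else m$theta_hat, 1),
    p = vapply(loo, function(m) if (is.null(m)) NA_real_ else m$p, 1),
    model = vapply(loo, function(m) if (is.null(m)) NA_character_ else m$model, ""),
    significant = vapply(loo, arm_ok, NA)
  )

  first_arm <- if (!any(rec$is_first_report %||% FALSE)) {
    NULL
  } else {
    repool(rec[!rec$is_first_report, , drop = FALSE])
  }
  first_evaluable <- any(rec$is_first_report %||% FALSE) && !is.null(first_arm)

  hwe_known <- !is.na(rec$hwe_p_controls)
  hwe_arm <- if (!any(hwe_known)) {
    NULL
  } else {
    keep <- !hwe_known | rec$hwe_p_controls >= hwe_alpha
    repool(rec[keep, , drop = FALSE])
  }
  hwe_evaluable <- any(hwe_known) && !is.null(hwe_arm)

  verdicts <- c(loo_tbl$significant,
                if (first_evaluable) arm_ok(first_arm),
                if (hwe_evaluable) arm_ok(hwe_arm))
  robust <- all(verdicts, na.rm = TRUE) && any(!is.na(verdicts))
  driver <- loo_tbl$excluded[which(!loo_tbl$significant)]

  out <- list(
    full = full,
    leave_one_out = loo_tbl,
    drop_first_positive = first_arm,
    first_positive_evaluable = first_evaluable,
    drop_hwe_violations = hwe_arm,
    hwe_evaluable = hwe_evaluable,
    alpha = alpha, hwe_alpha = hwe_alpha,
    robust = robust,
    driver = if (length(driver)) driver else character()
  )
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity over %d leave-one-out re-pools: robust = %s\n",
              nrow(x$leave_one_out), x$robust))
  if (length(x$driver)) {
    cat("  significance lost when excluding:", paste(x$driver, collapse = ", "), "\n")
  }
  if (!x$first_positive_evaluable) cat("  first-positive arm not evaluable\n")
  if (!x$hwe_evaluable) cat("  HWE-exclusion arm not evaluable\n")
  invisible(x)
}
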