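#' @title Cumulative evidence grading
#' @description
#' Significant pooled associations are graded twice and the two verdicts
#' are combined. The Venice criteria assign letters A/B/C to (i) the
#' amount of evidence (total minor-allele count among cases and controls),
#' (ii) replication (between-study heterogeneity), and (iii) protection
#' from bias (Egger/Begg screens and sensitivity robustness); all-A is
#' strong, all A/B moderate, any C weak. The false-positive report
#' probability (FPRP) weighs the observed significance level against the
#' power to detect a target odds ratio under a prior probability of true
#' association; FPRP below 0.05 is strong, up to 0.20 moderate, above
#' weak. The final cumulative evidence is the Venice category moved up one
#' level when the FPRP evidence is strong and down one when it is weak.
#' @name evidence_grading
NULL

evidence_levels <- c("weak", "moderate", "strong")

#' Default Venice grading thresholds
#'
#' @param amount_a,amount_b Minor-allele counts: grade A above `amount_a`
#'   (default 1000), C below `amount_b` (default 100), B between.
#' @param repl_a_i2,repl_b_i2 I2 percentages: replication grade A below
#'   `repl_a_i2` (default 25, requiring at least `repl_min_k` datasets),
#'   C above `repl_b_i2` (default 50), B between.
#' @param repl_min_k Minimum dataset count for replication grade A.
#' @param bias_alpha Two-tailed level at which a bias test forces grade C
#'   (default 0.10).
#' @return A named list of thresholds.
#' @export
venice_thresholds <- function(amount_a = 1000, amount_b = 100,
                              repl_a_i2 = 25, repl_b_i2 = 50,
                              repl_min_k = 3, bias_alpha = 0.10) {
  list(amount_a = amount_a, amount_b = amount_b,
       repl_a_i2 = repl_a_i2, repl_b_i2 = repl_b_i2,
       repl_min_k = repl_min_k, bias_alpha = bias_alpha)
}

new_grade_triplet <- function(amount, replication, bias_protection) {
  letters_ok <- c("A", "B", "C", "unavailable")
  stopifnot(amount %in% letters_ok, replication %in% letters_ok,
            bias_protection %in% letters_ok)
  out <- list(amount = amount, replication = replication,
              bias_protection = bias_protection)
  class(out) <- "grade_triplet"
  out
}

#' @export
format.grade_triplet <- function(x, ...) {
  paste0(vapply(c(x$amount, x$replication, x$bias_protection),
                function(l) if (l == "unavailable") "-" else l, ""), collapse = "")
}

#' @export
print.grade_triplet <- function(x, ...) {
  cat("Venice grade:", format(x), "\n")
  invisible(x)
}

#' Parse a rendered Venice grade such as "AAA" or "B-C"
#'
#' @param x Character vector of three-character grades; `-` marks an
#'   unavailable criterion.
#' @return A `grade_triplet` (or list of them when `length(x) > 1`).
#' @export
parse_grade_triplet <- function(x) {
  one <- function(s) {
    s <- trimws(s)
    if (nchar(s) != 3L || grepl("[^ABC-]", s)) {
      rlang::abort(sprintf("cannot parse Venice grade '%s'", s),
                   class = "metasynopsis_error_domain")
    }
    lt <- strsplit(s, "")[[1]]
    lt <- ifelse(lt == "-", "unavailable", lt)
    new_grade_triplet(lt[1], lt[2], lt[3])
  }
  if (length(x) == 1L) one(x) else lapply(x, one)
}

#' Venice category from a letter triplet
#'
#' Strong when all three grades are A, moderate when all are A or B, weak
#' when any grade is C. An unavailable letter blocks both the all-A and
#' the any-C routes, so e.g. `"AA-"` maps to moderate.
#'
#' @param triplet A `grade_triplet` (or a string parseable by
#'   [parse_grade_triplet()]).
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
#' @examples
#' venice_category("AAA")
#' venice_category("ABC")
venice_category <- function(triplet) {
  if (is.character(triplet)) triplet <- parse_grade_triplet(triplet)
  lt <- c(triplet$amount, triplet$replication, triplet$bias_protection)
  if (any(lt == "C")) "weak"
  else if (all(lt == "A")) "strong"
  else "moderate"
}

#' Grade a pooled association by the Venice criteria
#'
#' Amount of evidence is graded on the aggregate minor-allele count among
#' cases and controls (computed from genotype counts when present,
#' otherwise `2 * N * maf` when a minor-allele frequency is supplied);
#' replication on the pooled I2; protection from bias on the Egger/Begg
#' screens and the sensitivity verdict. A criterion whose inputs are
#' missing grades `unavailable`.
#'
#' @param meta A `meta_result`.
#' @param bias A `bias_result`, or `NULL`.
#' @param sens A `sensitivity_report`, or `NULL`.
#' @param dataset The `association_dataset` (for allele counts), or `NULL`.
#' @param thresholds See [venice_thresholds()].
#' @param minor_allele_count Optional explicit override for the amount
#'   criterion.
#' @param maf Optional minor-allele frequency used with the dataset's
#'   sample sizes when genotype counts are absent.
#' @return A `grade_triplet`.
#' @export
grade_venice <- function(meta, bias = NULL, sens = NULL, dataset = NULL,
                         thresholds = venice_thresholds(),
                         minor_allele_count = NULL, maf = NULL) {
  mac <- minor_allele_count %||% dataset_minor_alleles(dataset, maf)
  amount <- if (is.na(mac)) "unavailable"
  else if (mac > thresholds$amount_a) "A"
  else if (mac >= thresholds$amount_b) "B"
  else "C"

  replication <- if (is.na(meta$i2)) "unavailable"
  else if (meta$i2 > thresholds$repl_b_i2) "C"
  else if (meta$i2 < thresholds$repl_a_i2 && meta$k >= thresholds$repl_min_k) "A"
  else "B"

  bias_ps <- c(if (!is.null(bias)) c(bias$egger$p, bias$begg$p))
  robust <- if (!is.null(sens)) sens$robust else NA
  bias_protection <- if (is.null(bias) && is.null(sens)) {
    "unavailable"
  } else if (any(bias_ps < thresholds$bias_alpha, na.rm = TRUE) ||
             isFALSE(robust)) {
    "C"
  } else if (length(bias_ps) && !anyNA(bias_ps) && isTRUE(robust)) {
    "A"
  } else {
    "B"
  }
  new_grade_triplet(amount, replication, bias_protection)
}

dataset_minor_alleles <- function(dataset, maf = NULL) {
  if (is.null(dataset)) return(NA_real_)
  rec <- dataset$records
  counts <- cbind(rec$case_Aa, rec$ctrl_Aa) |> rowSums()
  hom <- cbind(rec$case_aa, rec$ctrl_aa) |> rowSums()
  if (!anyNA(counts) && !anyNA(hom)) return(sum(counts + 2 * hom))
  if (!is.null(maf)) {
    n <- sum(rec$n_cases, rec$n_controls, na.rm = TRUE)
    if (n > 0) return(2 * n * maf)
  }
  NA_real_
}

#' Power to detect a target odds ratio at level alpha
#'
#' Two-sided Wald power `Phi(|log or1| / se - z) + Phi(-|log or1| / se - z)`
#' with `z` the upper `alpha / 2` normal quantile; the far-tail term is
#' included. As `se -> 0` the power tends to 1; as `or1 -> 1` it tends to
#' `alpha`.
#'
#' @param se Standard error of the pooled log ratio.
#' @param alpha Observed (or nominal) significance level in (0, 1).
#' @param or1 Target ratio, not equal to 1; the direction is immaterial
#'   (only `|log or1|` enters).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_at_or(0.0922, 0.05, 1.2)
power_at_or <- function(se, alpha, or1) {
  if (any(se <= 0) || any(alpha <= 0 | alpha >= 1) || any(or1 == 1) || any(or1 <= 0)) {
    rlang::abort("need se > 0, alpha in (0, 1), positive or1 != 1",
                 class = "metasynopsis_error_domain")
  }
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)  # stable for tiny alpha
  m <- abs(log(or1)) / se
  stats::pnorm(m - z) + stats::pnorm(-m - z)
}

#' False-positive report probability
#'
#' `FPRP = alpha (1 - pi) / (alpha (1 - pi) + power * pi)`: the posterior
#' probability that a finding significant at level `alpha` is a false
#' positive, given power `1 - beta` against the target effect and a prior
#' probability `pi` of true association.
#'
#' @param alpha Observed significance level in (0, 1).
#' @param power Power against the target ratio, in (0, 1].
#' @param pi Prior probability of true association (default 0.05).
#' @return An `fprp_result` with `alpha`, `power`, `pi`, `value` and
#'   `category`.
#' @export
#' @examples
#' fprp(0.05, 1)
fprp <- function(alpha, power, pi = 0.05) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power > 1 || pi <= 0 || pi >= 1) {
    rlang::abort("alpha, power and pi must lie in (0, 1)",
                 class = "metasynopsis_error_domain")
  }
  value <- alpha * (1 - pi) / (alpha * (1 - pi) + power * pi)
  out <- list(alpha = alpha, power = power, pi = pi, value = value,
              category = fprp_category(value))
  class(out) <- "fprp_result"
  out
}

#' @export
print.fprp_result <- function(x, ...) {
  cat(sprintf("FPRP = %.4g (alpha = %.3g, power = %.3f, prior = %.2f): %s evidence\n",
              x$value, x$alpha, x$power, x$pi, x$category))
  invisible(x)
}

#' FPRP noteworthiness category
#'
#' Below 0.05 strong, up to 0.20 moderate, above weak; values exactly on a
#' boundary fall to the less-noteworthy side.
#'
#' @param value FPRP in \[0, 1\] (vectorised).
#' @return Character vector of categories.
#' @export
#' @examples
#' fprp_category(c(0.040, 0.150, 0.254))
fprp_category <- function(value) {
  if (any(value < 0 | value > 1)) {
    rlang::abort("FPRP values must lie in [0, 1]", class = "metasynopsis_error_domain")
  }
  ifelse(value < 0.05, "strong", ifelse(value < 0.20, "moderate", "weak"))
}

#' FPRP from a pooled ratio, its CI and p-value
#'
#' The standard error is back-derived from the CI via
#' [theta_from_ratio_ci()]. `alpha_source = "reported_p"` uses the printed
#' pooled p-value as the observed significance level;
#' `"ci_implied"` recomputes it as `2 (1 - Phi(|log or| / se))`. The power
#' target is `or1` for risk effects and its reciprocal for protective ones
#' (equivalent, since only `|log or1|` enters the power).
#'
#' @param or,ci_low,ci_high Pooled ratio and its confidence bounds.
#' @param p Reported pooled p-value (required for `"reported_p"`).
#' @param alpha_source `"reported_p"` or `"ci_implied"`.
#' @param or1 Target detectable ratio (default 1.2).
#' @param pi Prior probability of true association (default 0.05).
#' @param level Confidence level of the interval.
#' @return An `fprp_result` with the extra fields `or1` and `se`.
#' @export
#' @examples
#' fprp_from_pooled(0.977, 0.957, 0.996, p = 0.018)
fprp_from_pooled <- function(or, ci_low, ci_high, p = NULL,
                             alpha_source = c("reported_p", "ci_implied"),
                             or1 = 1.2, pi = 0.05, level = 0.95) {
  alpha_source <- match.arg(alpha_source)
  est <- theta_from_ratio_ci(or, ci_low, ci_high, level)
  alpha <- if (alpha_source == "reported_p") {
    if (is.null(p) || is.na(p)) {
      rlang::abort("alpha_source = 'reported_p' needs a p-value",
                   class = "metasynopsis_error_domain")
    }
    p
  } else {
    2 * stats::pnorm(-abs(est$theta) / est$se)
  }
  target <- if (or < 1) 1 / or1 else or1
  out <- fprp(alpha, power_at_or(est$se, alpha, target), pi)
  out$or1 <- target
  out$se <- est$se
  out$alpha_source <- alpha_source
  out
}

#' Combine Venice and FPRP categories into final cumulative evidence
#'
#' The Venice category moves up one level when the FPRP evidence is strong
#' and down one when it is weak; moderate FPRP leaves it unchanged. Shifts
#' saturate at strong and weak.
#'
#' @param venice_cat,fprp_cat `"strong"`, `"moderate"` or `"weak"`.
#' @return A `cumulative_evidence` list with `venice`, `fprp` and `final`.
#' @export
#' @examples
#' combine_evidence("weak", "strong")
#' combine_evidence("strong", "weak")
combine_evidence <- function(venice_cat, fprp_cat) {
  v <- match(venice_cat, evidence_levels)
  f <- match(fprp_cat, evidence_levels)
  if (anyNA(c(v, f))) {
    rlang::abort("categories must be weak/moderate/strong",
                 class = "metasynopsis_error_domain")
  }
  shift <- c(-1L, 0L, 1L)[f]
  final <- evidence_levels[pmin(3L, pmax(1L, v + shift))]
  out <- list(venice = venice_cat, fprp = fprp_cat, final = final)
  class(out) <- "cumulative_evidence"
  out
}

#' @export
print.cumulative_evidence <- function(x, ...) {
  cat(sprintf("cumulative evidence: %s (Venice %s, FPRP %s)\n",
              x$final, x$venice, x$fprp))
  invisible(x)
}
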