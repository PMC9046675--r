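#' Back-derive a log-scale effect and its standard error from a ratio CI
#'
#' Converts a reported odds/risk/hazard ratio with a symmetric (on the log
#' scale) confidence interval into the analysis-scale pair `(theta, se)`,
#' where `theta = log(or)` and `se = (log(ci_high) - log(ci_low)) / (2 z)`.
#' The normal quantile `z` is evaluated at full double precision
#' (1.959964 at the default 95% level), so a CI rebuilt from the returned
#' pair reproduces the inputs to at least six decimals.
#'
#' @param or Reported ratio (vectorised).
#' @param ci_low,ci_high Lower and upper confidence bounds (ratios).
#' @param level Confidence level of the interval, default 0.95.
#' @return A list with numeric components `theta` and `se`.
#' @export
#' @examples
#' theta_from_ratio_ci(0.954, 0.932, 0.977)
theta_from_ratio_ci <- function(or, ci_low, ci_high, level = 0.95) {
  if (any(!is.finite(or) | !is.finite(ci_low) | !is.finite(ci_high))) {
    rlang::abort("or, ci_low and ci_high must be finite", class = "metasynopsis_error_domain")
  }
  if (any(or <= 0 | ci_low <= 0 | ci_high <= 0)) {
    rlang::abort("ratios and confidence bounds must be positive",
                 class = "metasynopsis_error_domain")
  }
  if (any(ci_low >= ci_high)) {
    rlang::abort("ci_low must be below ci_high", class = "metasynopsis_error_domain")
  }
  outside <- or < ci_low | or > ci_high
  if (any(outside)) {
    rlang::warn("reported ratio lies outside its CI; using the CI-derived standard error")
  }
  z <- z_level(level)
  list(theta = log(or), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Per-allele (additive-model) odds ratio from genotype counts
#'
#' Collapses case and control genotype counts to allele counts (each
#' minor-allele homozygote contributes two minor alleles, each heterozygote
#' one) and computes the cross-product odds ratio with its usual
#' `sqrt(1/a + 1/b + 1/c + 1/d)` log-scale standard error. When any cell of
#' the 2x2 allele table is zero, 0.5 is added to all four cells.
#'
#' @param case_genotypes,ctrl_genotypes Length-3 non-negative integer vectors
#'   of genotype counts ordered (major hom, het, minor hom).
#' @return A list with `theta` (log OR), `se`, and `or`.
#' @export
#' @examples
#' additive_or_from_counts(c(85, 30, 0), c(90, 20, 0))
additive_or_from_counts <- function(case_genotypes, ctrl_genotypes) {
  for (g in list(case_genotypes, ctrl_genotypes)) {
    if (length(g) != 3L || any(!is.finite(g)) || any(g < 0)) {
      rlang::abort("genotype counts must be three non-negative numbers",
                   class = "metasynopsis_error_domain")
    }
  }
  if (sum(case_genotypes) == 0 || sum(ctrl_genotypes) == 0) {
    rlang::abort("each group needs at least one genotyped subject",
                 class = "metasynopsis_error_degenerate")
  }
  allele_counts <- function(g) {
    minor <- 2 * g[3] + g[2]
    c(minor = minor, major = 2 * sum(g) - minor)
  }
  ca <- allele_counts(case_genotypes)
  co <- allele_counts(ctrl_genotypes)
  cells <- c(ca["minor"], ca["major"], co["minor"], co["major"])
  if (all(cells[c(1, 3)] == 0) || all(cells[c(2, 4)] == 0)) {
    rlang::abort("degenerate allele table: an allele is absent from both groups",
                 class = "metasynopsis_error_degenerate")
  }
  if (any(cells == 0)) cells <- cells + 0.5
  theta <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  list(theta = unname(theta), se = unname(se), or = exp(unname(theta)))
}

#' Standardized mean difference between two genotype groups
#'
#' Cohen's d with the pooled (n-weighted) standard deviation, and the usual
#' large-sample standard error
#' `sqrt((n1 + n0) / (n1 n0) + d^2 / (2 (n1 + n0)))`. The small-sample
#' Hedges correction is available behind `hedges = TRUE` but is off by
#' default.
#'
#' @param g1,g0 Length-3 numeric vectors `(mean, sd, n)` for the contrast
#'   group and the reference (wild-type homozygote) group.
#' @param hedges Apply the Hedges small-sample correction factor.
#' @return A list with `d` and `se`.
#' @export
#' @examples
#' smd_from_group_stats(c(12, 2, 50), c(10, 2, 50))
smd_from_group_stats <- function(g1, g0, hedges = FALSE) {
  for (g in list(g1, g0)) {
    if (length(g) != 3L || any(!is.finite(g))) {
      rlang::abort("group stats must be (mean, sd, n)", class = "metasynopsis_error_domain")
    }
    if (g[2] < 0 || g[3] < 2) {
      rlang::abort("need sd >= 0 and n >= 2 in both groups",
                   class = "metasynopsis_error_domain")
    }
  }
  n1 <- g1[3]; n0 <- g0[3]
  s_pooled <- sqrt(((n1 - 1) * g1[2]^2 + (n0 - 1) * g0[2]^2) / (n1 + n0 - 2))
  if (s_pooled == 0) {
    rlang::abort("zero pooled standard deviation", class = "metasynopsis_error_degenerate")
  }
  d <- (g1[1] - g0[1]) / s_pooled
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n0 - 2) - 1))
  se <- sqrt((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0)))
  list(d = unname(d), se = unname(se))
}

#' Hardy-Weinberg equilibrium test on control genotype counts
#'
#' The chi-square method compares observed genotype counts with the
#' `p^2 / 2pq / q^2` expectations implied by the sample allele frequency
#' (1 df, no continuity correction). The exact method enumerates the
#' conditional distribution of the heterozygote count given the allele
#' counts and sums the probabilities of all configurations whose
#' chi-square statistic is at least the observed one — the small-sample
#' version of the asymptotic test, so the two flavors converge as the
#' sample grows. The result also carries `p_mid`, the mid-p variant
#' (half the boundary mass), which tracks nominal significance levels
#' more closely on discrete support. `method = "auto"` uses chi-square
#' for samples of at least 200 and the exact test below that.
#'
#' @param genotypes Length-3 non-negative counts (major hom, het, minor hom).
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @return An object of class `hwe_result`: a list with `chi2`, `p`,
#'   `p_mid` (exact method only), `expected` and `method`. A monomorphic
#'   sample returns `p = 1` with a warning.
#' @export
#' @examples
#' hwe_test(c(10, 10, 10))
hwe_test <- function(genotypes, method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  if (length(genotypes) != 3L || any(!is.finite(genotypes)) || any(genotypes < 0)) {
    rlang::abort("genotype counts must be three non-negative numbers",
                 class = "metasynopsis_error_domain")
  }
  n <- sum(genotypes)
  if (n == 0) {
    rlang::abort("no genotyped subjects", class = "metasynopsis_error_domain")
  }
  n_minor <- 2 * genotypes[3] + genotypes[2]
  if (n_minor == 0 || n_minor == 2 * n) {
    rlang::warn("monomorphic sample: HWE test is uninformative, returning p = 1")
    out <- list(chi2 = 0, p = 1, expected = as.numeric(genotypes), method = "monomorphic")
    class(out) <- "hwe_result"
    return(out)
  }
  if (method == "auto") method <- if (n >= 200) "chisq" else "exact"
  q <- n_minor / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((genotypes - expected)^2 / expected)
  if (method == "chisq") {
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    p_mid <- NA_real_
  } else {
    ex <- hwe_exact_p(genotypes, expected)
    p <- ex$p
    p_mid <- ex$p_mid
  }
  out <- list(chi2 = unname(chi2), p = unname(p), p_mid = unname(p_mid),
              expected = unname(expected), method = method)
  class(out) <- "hwe_result"
  out
}

# Exact HWE p-value: conditional on the observed allele counts, heterozygote
# counts have probability proportional to n! / (nAA! nAa! naa!) * 2^nAa; the
# two-sided p sums configurations whose chi-square statistic is at least the
# observed one (small tolerances absorb float round-off). p_mid counts the
# boundary configurations at half weight.
hwe_exact_p <- function(genotypes, expected) {
  n <- sum(genotypes)
  n_minor <- 2 * genotypes[3] + genotypes[2]
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  log_prob <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- n - aa - h
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) + h * log(2)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  chi <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- n - aa - h
    sum((c(AA, h, aa) - expected)^2 / expected)
  }, numeric(1))
  chi_obs <- chi[match(genotypes[2], hets)]
  tol <- 1e-8 * max(1, chi_obs)
  beyond <- chi > chi_obs + tol
  boundary <- abs(chi - chi_obs) <= tol
  list(p = sum(prob[beyond | boundary]),
       p_mid = sum(prob[beyond]) + 0.5 * sum(prob[boundary]))
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test: chi2 = %.4f, p = %.4g\n", x$method, x$chi2, x$p))
  invisible(x)
}
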