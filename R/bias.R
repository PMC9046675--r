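#' @title Small-study and publication bias tests
#' @description
#' Egger's regression test regresses the standardized effect
#' `theta_i / se_i` on the precision `1 / se_i` by ordinary least squares
#' and tests the intercept against zero (t, k - 2 df): under a common true
#' effect the line passes through the origin, so a non-zero intercept
#' signals funnel-plot asymmetry from small-study effects. Begg's test
#' rank-correlates the standardized deviates
#' `v_i = (theta_i - theta_FE) / sqrt(se_i^2 - se_FE^2)` with the study
#' variances (Kendall's tau); both are evaluated two-tailed at the 0.10
#' level conventional for bias screens.
#' @name bias_tests
NULL

#' Egger's regression test for small-study bias
#'
#' @param x An `association_dataset` or data frame with `theta`/`se`.
#' @return A list with `intercept`, `se`, `t`, `df`, `p` and `k`;
#'   `computable = FALSE` (all statistics `NA`) when `k < 3`.
#' @export
#' @examples
#' egger_test(data.frame(theta = c(0.1, 0.2, 0.4, 0.8), se = c(0.1, 0.2, 0.4, 0.8)))
egger_test <- function(x) {
  inp <- pool_inputs(x)
  check_se(inp$se)
  k <- length(inp$theta)
  if (k < 3) {
    return(list(computable = FALSE, intercept = NA_real_, se = NA_real_,
                t = NA_real_, df = NA_integer_, p = NA_real_, k = k))
  }
  fit <- stats::lm(I(inp$theta / inp$se) ~ I(1 / inp$se))
  # a constant true effect gives a zero-residual fit; the intercept is exact
  sm <- suppressWarnings(summary(fit))$coefficients
  list(computable = TRUE,
       intercept = unname(sm[1, 1]), se = unname(sm[1, 2]),
       t = unname(sm[1, 3]), df = k - 2L, p = unname(sm[1, 4]), k = k)
}

#' Begg's rank-correlation test for publication bias
#'
#' Kendall correlation (tau-b tie correction when needed) between the
#' fixed-effect standardized deviates and the study variances. The p-value
#' uses the exact permutation null of the Kendall S statistic for `k <= 8`
#' without ties, and the normal approximation (with tie-corrected variance)
#' otherwise.
#'
#' @param x An `association_dataset` or data frame with `theta`/`se`.
#' @return A list with `tau`, `S`, `p`, `method` (`"exact"` or `"normal"`),
#'   `ties` flag and `k`; `computable = FALSE` when `k < 3`.
#' @export
begg_test <- function(x) {
  inp <- pool_inputs(x)
  check_se(inp$se)
  k <- length(inp$theta)
  if (k < 3) {
    return(list(computable = FALSE, tau = NA_real_, S = NA_real_, p = NA_real_,
                method = NA_character_, ties = NA, k = k))
  }
  w <- 1 / inp$se^2
  theta_fe <- sum(w * inp$theta) / sum(w)
  var_fe <- 1 / sum(w)
  v <- (inp$theta - theta_fe) / sqrt(pmax(inp$se^2 - var_fe, .Machine$double.eps))
  v[abs(v) < 1e-8 * max(1, abs(theta_fe))] <- 0  # constant effects: true zeros, not float dust
  kendall_tau_test(v, inp$se^2)
}

# Kendall tau-b with exact permutation p (no ties, n <= 8) or normal
# approximation. The exact null of the S statistic is built from the
# Mahonian inversion-count distribution.
kendall_tau_test <- function(x, y, exact_max = 8L) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  dx <- sign(x[pairs[1, ]] - x[pairs[2, ]])
  dy <- sign(y[pairs[1, ]] - y[pairs[2, ]])
  S <- sum(dx * dy)
  ties <- any(dx == 0) || any(dy == 0)
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {  # a fully tied margin: no ordering information
    return(list(computable = TRUE, tau = 0, S = S, p = 1,
                method = "degenerate", ties = TRUE, k = n))
  }
  tau <- S / denom
  if (!ties && n <= exact_max) {
    counts <- mahonian_counts(n)                       # counts[d + 1] = #perms with d inversions
    s_values <- n0 - 2 * (seq_along(counts) - 1)       # S = n0 - 2 * inversions
    p <- sum(counts[abs(s_values) >= abs(S)]) / sum(counts)
    method <- "exact"
  } else {
    # tie-corrected variance of S (no continuity correction)
    var_s <- n * (n - 1) * (2 * n + 5) / 18
    adj <- function(v) {
      t <- as.numeric(table(v))
      sum(t * (t - 1) * (2 * t + 5))
    }
    var_s <- var_s - (adj(x) + adj(y)) / 18
    p <- if (var_s <= 0) 1 else 2 * stats::pnorm(-abs(S) / sqrt(var_s))
    method <- "normal"
  }
  list(computable = TRUE, tau = tau, S = S, p = min(1, p),
       method = method, ties = ties, k = n)
}

# number of permutations of n elements by inversion count (Mahonian numbers)
mahonian_counts <- function(n) {
  counts <- 1
  for (m in 2:n) {
    new_len <- length(counts) + (m - 1)
    cum <- cumsum(counts)
    counts <- vapply(seq_len(new_len) - 1L, function(d) {
      hi <- min(d, length(counts) - 1L)
      lo <- max(0L, d - (m - 1L))
      cum[hi + 1L] - if (lo > 0) cum[lo] else 0
    }, numeric(1))
  }
  counts
}

#' Run both bias tests on a dataset
#'
#' @param x An `association_dataset` or data frame with `theta`/`se`.
#' @param alpha Two-tailed level at which either test flags bias
#'   (default 0.10).
#' @return A `bias_result` list with `egger`, `begg`, `significant_at` and
#'   a `flagged` verdict (`NA` when neither test is computable).
#' @export
bias_tests <- function(x, alpha = 0.10) {
  egger <- egger_test(x)
  begg <- begg_test(x)
  ps <- c(egger$p, begg$p)
  flagged <- if (all(is.na(ps))) NA else any(ps < alpha, na.rm = TRUE)
  out <- list(egger = egger, begg = begg, significant_at = alpha, flagged = flagged)
  class(out) <- "bias_result"
  out
}

#' @export
print.bias_result <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "not computable" else sprintf("p = %.3g", p)
  cat(sprintf("Egger intercept %s (%s); Begg tau %s (%s); flagged at %.2f: %s\n",
              ifelse(is.na(x$egger$intercept), "NA", sprintf("%.3f", x$egger$intercept)),
              fmt(x$egger$p),
              ifelse(is.na(x$begg$tau), "NA", sprintf("%.3f", x$begg$tau)),
              fmt(x$begg$p), x$significant_at,
              ifelse(is.na(x$flagged), "NA", x$flagged)))
  invisible(x)
}
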