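#' @title Inverse-variance pooling with DerSimonian-Laird heterogeneity
#' @description
#' The engine pools study-level effects (log odds ratios or standardized
#' mean differences) by inverse-variance weighting. Heterogeneity is
#' quantified by Cochran's Q on fixed-effect weights, Higgins'
#' `I2 = max(0, (Q - df) / Q) * 100`, and the DerSimonian-Laird
#' method-of-moments `tau2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2) / sum(w)`. [select_and_pool()] applies the model
#' switch used throughout the synopsis: random effects when `I2 >= 50`,
#' fixed effects otherwise.
#' @name meta_engine
NULL

new_meta_result <- function(k, theta_hat, se_hat, Q, df, i2, tau2, model,
                            scale = c("log_odds", "smd"), level = 0.95) {
  scale <- match.arg(scale)
  z <- z_level(level)
  lo <- theta_hat - z * se_hat
  hi <- theta_hat + z * se_hat
  p <- 2 * stats::pnorm(-abs(theta_hat) / se_hat)
  q_p <- if (is.na(Q) || df < 1) NA_real_ else stats::pchisq(Q, df, lower.tail = FALSE)
  out <- list(
    k = k, theta_hat = theta_hat, se_hat = se_hat,
    ci_low = if (scale == "log_odds") exp(lo) else lo,
    ci_high = if (scale == "log_odds") exp(hi) else hi,
    p = p, Q = Q, df = df, q_p = q_p, i2 = i2, tau2 = tau2,
    model = model, scale = scale, level = level
  )
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  est <- if (x$scale == "log_odds") exp(x$theta_hat) else x$theta_hat
  lab <- if (x$scale == "log_odds") "OR" else "SMD"
  cat(sprintf("%s-effects pool of %d studies: %s = %.3f (%.3f, %.3f), p = %.3g\n",
              x$model, x$k, lab, est, x$ci_low, x$ci_high, x$p))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
                x$Q, x$df, x$q_p, x$i2, x$tau2))
  }
  invisible(x)
}

pool_inputs <- function(x) {
  if (inherits(x, "association_dataset")) {
    rec <- x$records
    keep <- !is.na(rec$theta) & !is.na(rec$se)
    list(theta = rec$theta[keep], se = rec$se[keep], scale = x$effect_scale)
  } else if (is.data.frame(x)) {
    list(theta = x$theta, se = x$se,
         scale = if (!is.null(x$effect_scale)) x$effect_scale[1] else "log_odds")
  } else {
    rlang::abort("expected an association_dataset or a data frame with theta/se columns",
                 class = "metasynopsis_error_domain")
  }
}

check_se <- function(se) {
  if (length(se) == 0 || any(!is.finite(se)) || any(se <= 0)) {
    rlang::abort("every poolable record needs a finite positive standard error",
                 class = "metasynopsis_error_domain")
  }
}

#' Fixed-effect (inverse-variance) pool
#'
#' @param x An `association_dataset`, or a data frame with `theta` and `se`
#'   columns.
#' @param level Confidence level for the pooled interval.
#' @return A `meta_result`. With a single study the estimate is passed
#'   through unpooled (`model = "not_pooled"`, no Q/I2).
#' @export
#' @examples
#' fixed_effect_pool(data.frame(theta = c(0.2, 0, 0.4), se = 0.1))
fixed_effect_pool <- function(x, level = 0.95) {
  inp <- pool_inputs(x)
  check_se(inp$se)
  k <- length(inp$theta)
  if (k == 1L) {
    return(new_meta_result(1L, inp$theta, inp$se, NA_real_, 0L, NA_real_, 0,
                           "not_pooled", inp$scale, level))
  }
  w <- 1 / inp$se^2
  theta_hat <- sum(w * inp$theta) / sum(w)
  se_hat <- 1 / sqrt(sum(w))
  Q <- sum(w * (inp$theta - theta_hat)^2)
  df <- k - 1L
  i2 <- max(0, (Q - df) / Q) * 100
  new_meta_result(k, theta_hat, se_hat, Q, df, i2,
                  dl_tau2_core(inp$theta, inp$se), "fixed", inp$scale, level)
}

# method-of-moments tau2 from fixed-effect weights
dl_tau2_core <- function(theta, se) {
  k <- length(theta)
  w <- 1 / se^2
  theta_fe <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / C)
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator `max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)` computed on fixed-effect weights.
#'
#' @inheritParams fixed_effect_pool
#' @return A non-negative scalar.
#' @export
#' @examples
#' dl_tau2(data.frame(theta = c(0.2, 0, 0.4), se = 0.1))
dl_tau2 <- function(x) {
  inp <- pool_inputs(x)
  check_se(inp$se)
  if (length(inp$theta) < 2L) {
    rlang::abort("tau2 needs at least two studies", class = "metasynopsis_error_domain")
  }
  dl_tau2_core(inp$theta, inp$se)
}

#' Random-effects (DerSimonian-Laird) pool
#'
#' Re-weights by `1 / (se^2 + tau2)`. Q, I2 and tau2 are reported from the
#' fixed-weight computation; in the homogeneous limit (`tau2 = 0`) the
#' result coincides with [fixed_effect_pool()].
#'
#' @inheritParams fixed_effect_pool
#' @return A `meta_result`.
#' @export
random_effects_pool <- function(x, level = 0.95) {
  fe <- fixed_effect_pool(x, level)
  if (fe$k == 1L) return(fe)
  inp <- pool_inputs(x)
  w <- 1 / (inp$se^2 + fe$tau2)
  theta_hat <- sum(w * inp$theta) / sum(w)
  se_hat <- 1 / sqrt(sum(w))
  new_meta_result(fe$k, theta_hat, se_hat, fe$Q, fe$df, fe$i2, fe$tau2,
                  "random", inp$scale, level)
}

#' Pool with the I-squared model switch
#'
#' Random effects when `I2 >= switch_i2` (the inclusive inequality used
#' throughout the synopsis), fixed effects otherwise. Single-study inputs
#' pass through unpooled.
#'
#' @inheritParams fixed_effect_pool
#' @param switch_i2 I2 percentage at or above which the random-effects
#'   model is selected; default 50.
#' @return A `meta_result`.
#' @export
#' @examples
#' select_and_pool(data.frame(theta = c(0.2, 0, 0.4), se = 0.1))
select_and_pool <- function(x, switch_i2 = 50, level = 0.95) {
  fe <- fixed_effect_pool(x, level)
  if (fe$k == 1L || is.na(fe$i2) || fe$i2 < switch_i2) fe else random_effects_pool(x, level)
}
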