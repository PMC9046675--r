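#' @title Synthetic study collections
#' @description
#' Generates collections of case-control (or quantitative-trait) studies
#' with the structure the pipeline assumes: control genotypes in
#' Hardy-Weinberg proportions at a given minor-allele frequency, case
#' genotype probabilities tilted multiplicatively per minor-allele copy by
#' `exp(theta_i)` (logistic-consistent with the additive per-allele odds
#' ratio the pipeline estimates), and study-level true effects
#' `theta_i ~ N(theta, tau2)`. Optional suppression of small null-direction
#' studies produces funnel asymmetry for stressing the bias tests.
#' @name synthetic_data
NULL

#' Configuration for a synthetic study collection
#'
#' @param k Number of studies.
#' @param theta True per-allele log odds ratio (or, for quantitative
#'   collections, ignored in favour of `smd`).
#' @param tau2 Between-study variance of the true effects.
#' @param maf Minor-allele frequency in controls, in (0, 0.5).
#' @param n_cases_range,n_controls_range Integer ranges that study sample
#'   sizes are drawn from uniformly.
#' @param bias_gamma Suppression strength for [inject_small_study_bias()],
#'   in \[0, 1\].
#' @param outcome_kind `"disease"` or `"continuous_phenotype"`.
#' @param smd True standardized mean difference of the minor-homozygote
#'   contrast (heterozygote shift is half of it).
#' @param residual_sd Residual standard deviation of the quantitative
#'   trait.
#' @param seed Optional integer seed; fixing it makes the draw
#'   reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(k = 10, theta = 0, tau2 = 0, maf = 0.30,
                       n_cases_range = c(200, 2000),
                       n_controls_range = c(200, 2000),
                       bias_gamma = 0, outcome_kind = "disease",
                       smd = 0, residual_sd = 1, seed = NULL) {
  if (k < 1) rlang::abort("k must be at least 1", class = "metasynopsis_error_domain")
  if (tau2 < 0) rlang::abort("tau2 must be non-negative", class = "metasynopsis_error_domain")
  if (maf <= 0 || maf >= 0.5) {
    rlang::abort("maf must lie strictly between 0 and 0.5",
                 class = "metasynopsis_error_domain")
  }
  for (r in list(n_cases_range, n_controls_range)) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
      rlang::abort("sample-size ranges must be positive and increasing",
                   class = "metasynopsis_error_domain")
    }
  }
  if (bias_gamma < 0 || bias_gamma > 1) {
    rlang::abort("bias_gamma must lie in [0, 1]", class = "metasynopsis_error_domain")
  }
  if (residual_sd <= 0) {
    rlang::abort("residual_sd must be positive", class = "metasynopsis_error_domain")
  }
  out <- list(k = as.integer(k), theta = theta, tau2 = tau2, maf = maf,
              n_cases_range = as.integer(n_cases_range),
              n_controls_range = as.integer(n_controls_range),
              bias_gamma = bias_gamma, outcome_kind = outcome_kind,
              smd = smd, residual_sd = residual_sd, seed = seed)
  class(out) <- "sim_config"
  out
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

case_probs <- function(maf, theta_i) {
  w <- hwe_probs(maf) * exp(theta_i * 0:2)
  w / sum(w)
}

# study sizes span orders of magnitude in genetic-association literature,
# so sizes are drawn log-uniformly within the configured range
draw_sizes <- function(k, range) {
  if (range[1] == range[2]) return(rep(range[1], k))
  as.integer(round(exp(stats::runif(k, log(range[1]), log(range[2])))))
}

sim_binary_rows <- function(theta_i, cfg) {
  k <- length(theta_i)
  n_ca <- draw_sizes(k, cfg$n_cases_range)
  n_co <- draw_sizes(k, cfg$n_controls_range)
  gc <- vapply(seq_len(k), function(i) {
    as.integer(stats::rmultinom(1, n_ca[i], case_probs(cfg$maf, theta_i[i])))
  }, integer(3))
  gn <- vapply(seq_len(k), function(i) {
    as.integer(stats::rmultinom(1, n_co[i], hwe_probs(cfg$maf)))
  }, integer(3))
  hwe_p <- vapply(seq_len(k), function(i) {
    suppressWarnings(hwe_test(gn[, i])$p)
  }, numeric(1))
  tibble::tibble(
    study_id = sprintf("sim%03d", seq_len(k)), pmid = NA_character_,
    year = 2003L + seq_len(k),
    variant_id = "rsSIM", effect_allele = "C", other_allele = "A",
    outcome_name = "simulated outcome", outcome_kind = cfg$outcome_kind,
    design = "case_control", ancestry = "synthetic",
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    beta = NA_real_, se = NA_real_, p = NA_real_,
    n_cases = n_ca, n_controls = n_co,
    case_AA = gc[1, ], case_Aa = gc[2, ], case_aa = gc[3, ],
    ctrl_AA = gn[1, ], ctrl_Aa = gn[2, ], ctrl_aa = gn[3, ],
    mean_AA = NA_real_, sd_AA = NA_real_, n_AA = NA_real_,
    mean_Aa = NA_real_, sd_Aa = NA_real_, n_Aa = NA_real_,
    mean_aa = NA_real_, sd_aa = NA_real_, n_aa = NA_real_,
    hwe_p_controls = hwe_p, is_first_report = seq_len(k) == 1L
  )
}

#' Simulate a case-control meta-analysis dataset
#'
#' Per study, a true effect `theta_i ~ N(theta, tau2)` is drawn, control
#' genotype counts are multinomial under Hardy-Weinberg proportions at
#' `maf`, and case genotype probabilities are the HWE weights tilted by
#' `exp(theta_i)` per minor-allele copy. Genotype counts are emitted so
#' the effect-size stage can rebuild per-allele odds ratios; the first
#' study carries the first-report flag.
#'
#' @param cfg A [sim_config()].
#' @return An `association_dataset` with the generating config attached as
#'   attribute `"sim_config"`.
#' @export
#' @examples
#' simulate_binary_meta(sim_config(k = 5, theta = 0.2, seed = 1))
simulate_binary_meta <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  theta_i <- stats::rnorm(cfg$k, cfg$theta, sqrt(cfg$tau2))
  rows <- derive_effects(sim_binary_rows(theta_i, cfg))
  ds <- new_association_dataset(rows, contrast = "additive")
  attr(ds, "sim_config") <- cfg
  attr(ds, "theta_i") <- theta_i
  ds
}

#' Simulate a quantitative-trait meta-analysis dataset
#'
#' Genotype group sizes are multinomial under Hardy-Weinberg proportions;
#' group means are shifted from the wild-type baseline by
#' `smd_i * residual_sd` for minor homozygotes and half that for
#' heterozygotes, with `smd_i ~ N(smd, tau2)`. Per-genotype summary
#' statistics are emitted so the effect-size stage can rebuild
#' standardized mean differences under the co-dominant contrasts.
#'
#' @param cfg A [sim_config()] with `outcome_kind = "continuous_phenotype"`.
#' @param contrast Which co-dominant contrast to derive.
#' @return An `association_dataset` on the SMD scale.
#' @export
simulate_quantitative_meta <- function(cfg,
                                       contrast = c("codominant_hom", "codominant_het")) {
  stopifnot(inherits(cfg, "sim_config"))
  contrast <- match.arg(contrast)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  smd_i <- stats::rnorm(cfg$k, cfg$smd, sqrt(cfg$tau2))
  sizes_all <- draw_sizes(cfg$k, cfg$n_controls_range)
  rows <- dplyr::bind_rows(lapply(seq_len(cfg$k), function(i) {
    n <- sizes_all[i]
    sizes <- as.integer(stats::rmultinom(1, n, hwe_probs(cfg$maf)))
    sizes <- pmax(sizes, 2L)  # degenerate tiny groups would have no variance
    shift <- c(0, 0.5, 1) * smd_i[i] * cfg$residual_sd
    grp <- lapply(1:3, function(g) stats::rnorm(sizes[g], shift[g], cfg$residual_sd))
    tibble::tibble(
      study_id = sprintf("sim%03d", i), pmid = NA_character_, year = 2003L + i,
      variant_id = "rsSIM", effect_allele = "C", other_allele = "A",
      outcome_name = "simulated trait", outcome_kind = "continuous_phenotype",
      design = "cross_sectional", ancestry = "synthetic",
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      beta = NA_real_, se = NA_real_, p = NA_real_,
      n_cases = NA_integer_, n_controls = n,
      case_AA = NA_real_, case_Aa = NA_real_, case_aa = NA_real_,
      ctrl_AA = NA_real_, ctrl_Aa = NA_real_, ctrl_aa = NA_real_,
      mean_AA = mean(grp[[1]]), sd_AA = stats::sd(grp[[1]]), n_AA = sizes[1],
      mean_Aa = mean(grp[[2]]), sd_Aa = stats::sd(grp[[2]]), n_Aa = sizes[2],
      mean_aa = mean(grp[[3]]), sd_aa = stats::sd(grp[[3]]), n_aa = sizes[3],
      hwe_p_controls = NA_real_, is_first_report = i == 1L
    )
  }))
  rows <- derive_effects(rows, smd_contrast = contrast)
  ds <- new_association_dataset(rows, contrast = contrast)
  attr(ds, "sim_config") <- cfg
  attr(ds, "smd_i") <- smd_i
  ds
}

#' Inject small-study suppression bias into a simulated dataset
#'
#' Emulates the selective non-publication of null small studies: studies
#' in the top tercile of standard error whose estimate is not nominally
#' significant in the generating direction (one-sided z below 1.645) are,
#' with probability `gamma`, redrawn — keeping their sample sizes and
#' study-level true effects — until a publishable draw appears. The
#' resulting excess of significant small-study estimates produces the
#' funnel asymmetry that Egger's and Begg's tests are designed to detect.
#' `gamma = 0` returns the dataset unchanged.
#'
#' @param dataset An `association_dataset` from [simulate_binary_meta()].
#' @param gamma Suppression probability in \[0, 1\].
#' @param max_redraws Safety cap on redraws per study.
#' @return The biased `association_dataset`.
#' @export
inject_small_study_bias <- function(dataset, gamma, max_redraws = 100L) {
  stopifnot(inherits(dataset, "association_dataset"))
  if (gamma < 0 || gamma > 1) {
    rlang::abort("gamma must lie in [0, 1]", class = "metasynopsis_error_domain")
  }
  cfg <- attr(dataset, "sim_config")
  if (is.null(cfg)) {
    rlang::abort("bias injection needs the generating sim_config attribute",
                 class = "metasynopsis_error_domain")
  }
  rec <- dataset$records
  if (gamma == 0 || nrow(rec) == 0) return(dataset)
  direction <- if (cfg$theta == 0) 1 else sign(cfg$theta)
  theta_i <- attr(dataset, "theta_i")
  z_pub <- stats::qnorm(0.95)  # one-sided nominal significance gate
  publishable <- function(theta, se) direction * theta / se >= z_pub
  small <- rec$se >= stats::quantile(rec$se, 2 / 3, na.rm = TRUE)
  for (i in which(small)) {
    if (publishable(rec$theta[i], rec$se[i])) next
    if (stats::runif(1) > gamma) next
    for (draw in seq_len(max_redraws)) {
      gc <- as.integer(stats::rmultinom(1, rec$n_cases[i], case_probs(cfg$maf, theta_i[i])))
      gn <- as.integer(stats::rmultinom(1, rec$n_controls[i], hwe_probs(cfg$maf)))
      est <- tryCatch(additive_or_from_counts(gc, gn), error = function(e) NULL)
      if (!is.null(est) && publishable(est$theta, est$se)) {
        rec$case_AA[i] <- gc[1]; rec$case_Aa[i] <- gc[2]; rec$case_aa[i] <- gc[3]
        rec$ctrl_AA[i] <- gn[1]; rec$ctrl_Aa[i] <- gn[2]; rec$ctrl_aa[i] <- gn[3]
        rec$theta[i] <- est$theta; rec$se[i] <- est$se
        rec$hwe_p_controls[i] <- suppressWarnings(hwe_test(gn)$p)
        break
      }
    }
  }
  dataset$records <- rec
  dataset
}

#' Convert a simulated dataset back to the study-table schema
#'
#' @param dataset An `association_dataset`.
#' @return A tibble in [study_table_columns()] order.
#' @export
as_study_table <- function(dataset) {
  stopifnot(inherits(dataset, "association_dataset"))
  rec <- dataset$records
  if ("se_raw" %in% names(rec)) rec$se <- rec$se_raw
  rec[intersect(study_table_columns(), names(rec))]
}
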