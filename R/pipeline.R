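#' Default configuration for the synopsis pipeline
#'
#' Every threshold used by the pipeline stages, overridable individually
#' or loaded from YAML with [read_synopsis_config()]. Defaults: two-sided
#' significance 0.05; bias tests at 0.10; random-effects switch at
#' I2 = 50; control-HWE exclusion at 0.05; FPRP prior 0.05, target OR 1.2
#' (reciprocal for protective effects), categories split at 0.05 / 0.20.
#'
#' @param alpha Two-sided significance level gating the grading stages.
#' @param bias_alpha Level of the Egger/Begg screens.
#' @param switch_i2 I2 switch for [select_and_pool()].
#' @param hwe_alpha Control-HWE exclusion threshold in the sensitivity
#'   suite.
#' @param pi FPRP prior probability of true association.
#' @param or1 FPRP power target ratio.
#' @param min_k Minimum poolable studies for an eligible main
#'   meta-analysis.
#' @param venice Venice letter thresholds, see [venice_thresholds()].
#' @param effect_alleles Optional named character vector mapping
#'   variant id to the designated (minor) effect allele; records are
#'   reoriented to it before grouping.
#' @param maf Optional named numeric vector of per-variant minor-allele
#'   frequencies, used for the Venice amount criterion when genotype
#'   counts are absent.
#' @return A `synopsis_config` list.
#' @export
synopsis_config <- function(alpha = 0.05, bias_alpha = 0.10, switch_i2 = 50,
                            hwe_alpha = 0.05, pi = 0.05, or1 = 1.2, min_k = 3,
                            venice = venice_thresholds(bias_alpha = bias_alpha),
                            effect_alleles = NULL, maf = NULL) {
  out <- list(alpha = alpha, bias_alpha = bias_alpha, switch_i2 = switch_i2,
              hwe_alpha = hwe_alpha, pi = pi, or1 = or1, min_k = min_k,
              venice = venice, effect_alleles = effect_alleles, maf = maf)
  class(out) <- "synopsis_config"
  out
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [synopsis_config()]; `venice`
#' may be a mapping of [venice_thresholds()] arguments, and
#' `effect_alleles` / `maf` mappings keyed by variant id.
#'
#' @param path Path to a YAML file.
#' @return A `synopsis_config`.
#' @export
read_synopsis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(synopsis_config)))]
  if (!is.null(args$venice)) args$venice <- do.call(venice_thresholds, args$venice)
  if (!is.null(args$effect_alleles)) args$effect_alleles <- unlist(args$effect_alleles)
  if (!is.null(args$maf)) args$maf <- unlist(args$maf)
  do.call(synopsis_config, args)
}

#' Run the full synopsis pipeline over a study table
#'
#' Reads (or accepts) study-level records, reorients them to the
#' designated effect alleles, derives the common effect representation,
#' partitions into association datasets, pools each eligible dataset with
#' the I2 model switch, and — for associations significant at
#' `config$alpha` — runs the bias tests, the sensitivity suite, Venice
#' grading, FPRP, and the evidence combination. Deterministic given
#' inputs and config.
#'
#' @param studies Path to a study TSV, or a tibble from
#'   [read_study_table()].
#' @param config A [synopsis_config()].
#' @return A list of `association_report` objects (one per dataset with at
#'   least one poolable record).
#' @export
run_pipeline <- function(studies, config = synopsis_config()) {
  if (is.character(studies)) studies <- read_study_table(studies)
  if (!is.null(config$effect_alleles)) {
    hit <- studies$variant_id %in% names(config$effect_alleles)
    studies[hit, ] <- orient_to_effect_allele(
      studies[hit, , drop = FALSE],
      unname(config$effect_alleles[studies$variant_id[hit]]))
  }
  if (!"theta" %in% names(studies)) studies <- derive_effects(studies)
  datasets <- group_into_datasets(studies)
  datasets <- Filter(function(d) d$k >= 1, datasets)
  if (!length(datasets)) {
    rlang::warn("no datasets with poolable records; empty report")
    return(list())
  }
  lapply(datasets, function(ds) associate_report(ds, config))
}

associate_report <- function(ds, config) {
  meta <- select_and_pool(ds, config$switch_i2)
  eligible <- ds$k >= config$min_k
  report <- list(
    variant_id = ds$variant_id,
    outcome_name = ds$outcome_name,
    contrast = ds$contrast,
    k = ds$k,
    n_cases = sum(ds$records$n_cases, na.rm = TRUE),
    n_controls = sum(ds$records$n_controls, na.rm = TRUE),
    eligible = eligible,
    meta = meta,
    bias = NULL, sensitivity = NULL, venice = NULL, fprp = NULL, cumulative = NULL
  )
  graded <- eligible && !is.na(meta$p) && meta$p < config$alpha && ds$k >= 2
  if (graded) {
    report$bias <- bias_tests(ds, config$bias_alpha)
    report$sensitivity <- sensitivity_suite(ds, config$alpha, config$hwe_alpha,
                                            config$switch_i2)
    maf <- if (!is.null(config$maf)) unname(config$maf[ds$variant_id]) else NULL
    report$venice <- grade_venice(meta, report$bias, report$sensitivity, ds,
                                  thresholds = config$venice, maf = maf)
    if (meta$scale == "log_odds") {
      est <- exp(meta$theta_hat)
      # a Wald p can underflow to zero for overwhelming effects; floor it
      report$fprp <- fprp_from_pooled(est, meta$ci_low, meta$ci_high,
                                      p = max(meta$p, 1e-300),
                                      alpha_source = "reported_p",
                                      or1 = config$or1, pi = config$pi)
      report$cumulative <- combine_evidence(venice_category(report$venice),
                                            report$fprp$category)
    }
  }
  class(report) <- "association_report"
  report
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("%s / %s (k = %d%s)\n", x$variant_id, x$outcome_name, x$k,
              if (x$eligible) "" else ", ineligible"))
  print(x$meta)
  if (!is.null(x$cumulative)) print(x$cumulative)
  invisible(x)
}

#' Flatten association reports into a pooled-results table
#'
#' One row per association, mirroring the pooled-table layout: variant,
#' outcome, dataset and subject counts, pooled estimate with CI and p,
#' I2, heterogeneity p, model, Venice grade, FPRP and cumulative
#' evidence.
#'
#' @param reports A list of `association_report`s from [run_pipeline()].
#' @return A tibble.
#' @export
report_table <- function(reports) {
  dplyr::bind_rows(lapply(reports, function(r) {
    m <- r$meta
    est <- if (m$scale == "log_odds") exp(m$theta_hat) else m$theta_hat
    tibble::tibble(
      variant = r$variant_id, outcome = r$outcome_name, datasets = r$k,
      cases = r$n_cases, controls = r$n_controls,
      estimate = est, ci_low = m$ci_low, ci_high = m$ci_high,
      p = m$p, i2 = m$i2, het_p = m$q_p, tau2 = m$tau2, model = m$model,
      venice = if (is.null(r$venice)) NA_character_ else format(r$venice),
      fprp = if (is.null(r$fprp)) NA_real_ else r$fprp$value,
      cumulative = if (is.null(r$cumulative)) NA_character_ else r$cumulative$final
    )
  }))
}

#' Serialize association reports to JSON
#'
#' Each association becomes an object holding its meta, bias, sensitivity
#' and grading blocks; re-serializing identical inputs is byte-identical.
#'
#' @param reports A list of `association_report`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  strip <- function(x) {
    if (inherits(x, "meta_result") || inherits(x, "bias_result") ||
        inherits(x, "fprp_result") || inherits(x, "cumulative_evidence") ||
        inherits(x, "grade_triplet")) {
      x <- unclass(x)
    }
    if (inherits(x, "sensitivity_report")) {
      x <- list(robust = x$robust, driver = x$driver,
                leave_one_out = x$leave_one_out,
                first_positive_evaluable = x$first_positive_evaluable,
                hwe_evaluable = x$hwe_evaluable)
    }
    if (is.list(x) && !is.data.frame(x)) lapply(x, strip) else x
  }
  payload <- lapply(reports, function(r) {
    strip(r[setdiff(names(r), "sensitivity")] |>
            c(list(sensitivity = strip(r$sensitivity))))
  })
  names(payload) <- vapply(reports, function(r) {
    paste(r$variant_id, r$outcome_name, sep = " / ")
  }, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}
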