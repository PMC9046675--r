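#' @title Study-level record tables
#' @description
#' Study-level association records travel as one row per study x variant x
#' outcome in a tab-separated table with a fixed header (see
#' [study_table_columns()]). A row is *analyzable* when it carries at least
#' one complete effect source: a coefficient with its standard error, a
#' ratio with both confidence bounds, the six genotype counts, or
#' per-genotype group statistics. Rows with only a p-value are kept but
#' marked non-poolable.
#' @name study_table
NULL

#' Column order of the study table schema
#'
#' @return Character vector of the 34 column names, in file order.
#' @export
study_table_columns <- function() {
  c("study_id", "pmid", "year", "variant_id", "effect_allele", "other_allele",
    "outcome_name", "outcome_kind", "design", "ancestry",
    "or", "ci_low", "ci_high", "beta", "se", "p",
    "n_cases", "n_controls",
    "case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa",
    "mean_AA", "sd_AA", "n_AA", "mean_Aa", "sd_Aa", "n_Aa",
    "mean_aa", "sd_aa", "n_aa", "hwe_p_controls", "is_first_report")
}

study_table_numeric <- function() {
  setdiff(study_table_columns(),
          c("study_id", "pmid", "variant_id", "effect_allele", "other_allele",
            "outcome_name", "outcome_kind", "design", "ancestry", "is_first_report"))
}

#' Read a study-level association table
#'
#' Reads the tab-separated schema of [study_table_columns()]. A combined
#' confidence-interval column `ci` holding `"(L, U)"` cells is accepted in
#' place of (or alongside) `ci_low`/`ci_high` and is normalized on read.
#' Rows that fail type or range checks (unparsable numerics, negative
#' genotype counts, inverted CIs, non-positive standard errors) are dropped
#' with a warning; the offending line numbers and messages are attached as
#' the `"problems"` attribute.
#'
#' @param path Path to a TSV file.
#' @return A tibble of study records with a logical `analyzable` column and
#'   a `"problems"` attribute (zero-row tibble when the file is clean).
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "metasynopsis_error_io")
  }
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (!is.null(raw$ci) && is.null(raw$ci_low)) {
    bounds <- parse_ci_cell(raw$ci)
    raw$ci_low <- bounds$low
    raw$ci_high <- bounds$high
    raw$ci <- NULL
  }
  missing_cols <- setdiff(study_table_columns(), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("study table is missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "metasynopsis_error_schema")
  }
  raw <- raw[study_table_columns()]
  problems <- tibble::tibble(line = integer(), column = character(), message = character())
  for (col in study_table_numeric()) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad)) {
      problems <- dplyr::bind_rows(problems, tibble::tibble(
        line = bad + 1L, column = col,
        message = sprintf("unparsable numeric '%s'", raw[[col]][bad])))
    }
    raw[[col]] <- vals
  }
  raw$is_first_report <- tolower(trimws(ifelse(is.na(raw$is_first_report), "",
                                               raw$is_first_report))) %in%
    c("true", "t", "1", "yes")
  raw$year <- as.integer(raw$year)

  count_cols <- c("case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa")
  for (col in count_cols) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad)) {
      problems <- dplyr::bind_rows(problems, tibble::tibble(
        line = bad + 1L, column = col, message = "negative genotype count"))
    }
  }
  bad_ci <- which(!is.na(raw$ci_low) & !is.na(raw$ci_high) & raw$ci_low >= raw$ci_high)
  if (length(bad_ci)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = bad_ci + 1L, column = "ci_low", message = "ci_low not below ci_high"))
  }
  bad_se <- which(!is.na(raw$se) & raw$se <= 0)
  if (length(bad_se)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = bad_se + 1L, column = "se", message = "non-positive standard error"))
  }
  if (nrow(problems)) {
    rlang::warn(sprintf("%d row(s) failed validation and were dropped (see attr(x, 'problems'))",
                        length(unique(problems$line))))
    raw <- raw[-(unique(problems$line) - 1L), , drop = FALSE]
  }
  out <- tibble::as_tibble(raw)
  out$analyzable <- record_analyzable(out)
  attr(out, "problems") <- problems
  out
}

# "(0.932, 0.977)" or "0.932-0.977" -> two numeric columns
parse_ci_cell <- function(x) {
  x <- gsub("[()]", "", x)
  parts <- strsplit(x, "\\s*[,–-]\\s*")
  list(low = vapply(parts, function(p) p[1] %||% NA_character_, character(1)),
       high = vapply(parts, function(p) p[2] %||% NA_character_, character(1)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

record_analyzable <- function(x) {
  has_beta <- !is.na(x$beta) & !is.na(x$se)
  has_or <- !is.na(x$or) & !is.na(x$ci_low) & !is.na(x$ci_high)
  counts <- cbind(x$case_AA, x$case_Aa, x$case_aa, x$ctrl_AA, x$ctrl_Aa, x$ctrl_aa)
  has_counts <- rowSums(is.na(counts)) == 0
  stats_cols <- cbind(x$mean_AA, x$sd_AA, x$n_AA, x$mean_aa, x$sd_aa, x$n_aa)
  has_stats <- rowSums(is.na(stats_cols)) == 0
  has_beta | has_or | has_counts | has_stats
}

#' Write a study table back to disk
#'
#' Inverse of [read_study_table()] up to whitespace and float formatting.
#'
#' @param x A study-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  out <- x[intersect(study_table_columns(), names(x))]
  out$is_first_report <- ifelse(out$is_first_report, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-express a study record per copy of a designated effect allele
#'
#' If the record already reports its effect for `target_allele` it is
#' returned unchanged. Otherwise the effect is flipped: `beta` is negated,
#' the ratio and its bounds are replaced by reciprocals (bounds swapped),
#' genotype counts and per-genotype group statistics are reversed
#' (`AA` and `aa` exchanged), and the two allele labels are swapped. The
#' operation is an involution and preserves `|beta|`, `se`, `p` and all
#' totals exactly.
#'
#' @param record A one-or-more-row study tibble.
#' @param target_allele Single base, or one per row.
#' @return The reoriented tibble.
#' @export
orient_to_effect_allele <- function(record, target_allele) {
  target_allele <- rep_len(target_allele, nrow(record))
  mismatch <- target_allele != record$effect_allele &
    target_allele != record$other_allele
  if (any(mismatch)) {
    rlang::abort(sprintf("target allele not among record alleles for study %s",
                         paste(record$study_id[mismatch], collapse = ", ")),
                 class = "metasynopsis_error_allele")
  }
  flip <- which(target_allele == record$other_allele)
  if (!length(flip)) return(record)
  swap <- function(x, a, b) { tmp <- x[[a]][flip]; x[[a]][flip] <- x[[b]][flip]; x[[b]][flip] <- tmp; x }
  record$beta[flip] <- -record$beta[flip]
  old_or <- record$or[flip]
  old_lo <- record$ci_low[flip]
  old_hi <- record$ci_high[flip]
  record$or[flip] <- 1 / old_or
  record$ci_low[flip] <- 1 / old_hi
  record$ci_high[flip] <- 1 / old_lo
  record <- swap(record, "effect_allele", "other_allele")
  record <- swap(record, "case_AA", "case_aa")
  record <- swap(record, "ctrl_AA", "ctrl_aa")
  for (pair in list(c("mean_AA", "mean_aa"), c("sd_AA", "sd_aa"), c("n_AA", "n_aa"))) {
    record <- swap(record, pair[1], pair[2])
  }
  record
}

#' Derive the common (theta, se) effect representation for each record
#'
#' Fills `theta`, `se_theta` and `effect_scale` from the best available
#' source, in priority order: coefficient + SE, ratio + CI
#' ([theta_from_ratio_ci()]), genotype counts
#' ([additive_or_from_counts()]), then per-genotype group statistics
#' ([smd_from_group_stats()], contrast controlled by `smd_contrast`).
#'
#' @param x A study tibble from [read_study_table()].
#' @param smd_contrast `"codominant_hom"` (minor homozygote vs wild-type)
#'   or `"codominant_het"`.
#' @return `x` with `theta`, `se_theta` (renamed to `se` in pooled use),
#'   `effect_scale` and `poolable` columns.
#' @export
derive_effects <- function(x, smd_contrast = c("codominant_hom", "codominant_het")) {
  smd_contrast <- match.arg(smd_contrast)
  n <- nrow(x)
  theta <- se <- rep(NA_real_, n)
  scale <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(x$beta[i]) && !is.na(x$se[i])) {
      theta[i] <- x$beta[i]; se[i] <- x$se[i]
      scale[i] <- if (!is.na(x$outcome_kind[i]) &&
                      x$outcome_kind[i] == "continuous_phenotype") "smd" else "log_odds"
    } else if (!is.na(x$or[i]) && !is.na(x$ci_low[i]) && !is.na(x$ci_high[i])) {
      est <- theta_from_ratio_ci(x$or[i], x$ci_low[i], x$ci_high[i])
      theta[i] <- est$theta; se[i] <- est$se; scale[i] <- "log_odds"
    } else if (!anyNA(c(x$case_AA[i], x$case_Aa[i], x$case_aa[i],
                        x$ctrl_AA[i], x$ctrl_Aa[i], x$ctrl_aa[i]))) {
      est <- additive_or_from_counts(
        c(x$case_AA[i], x$case_Aa[i], x$case_aa[i]),
        c(x$ctrl_AA[i], x$ctrl_Aa[i], x$ctrl_aa[i]))
      theta[i] <- est$theta; se[i] <- est$se; scale[i] <- "log_odds"
    } else if (!anyNA(c(x$mean_AA[i], x$sd_AA[i], x$n_AA[i],
                        x$mean_aa[i], x$sd_aa[i], x$n_aa[i]))) {
      g1 <- if (smd_contrast == "codominant_hom") {
        c(x$mean_aa[i], x$sd_aa[i], x$n_aa[i])
      } else {
        c(x$mean_Aa[i], x$sd_Aa[i], x$n_Aa[i])
      }
      if (!anyNA(g1)) {
        est <- smd_from_group_stats(g1, c(x$mean_AA[i], x$sd_AA[i], x$n_AA[i]))
        theta[i] <- est$d; se[i] <- est$se; scale[i] <- "smd"
      }
    }
  }
  x$theta <- theta
  x$se_theta <- se
  x$effect_scale <- scale
  x$poolable <- !is.na(theta) & !is.na(se) & se > 0
  x
}

#' Partition harmonized records into association datasets
#'
#' Groups records by (variant, outcome, contrast). Datasets with fewer than
#' three studies are flagged `eligible = FALSE` for the main meta-analysis
#' but retained for reporting. Duplicate (study, variant, outcome) keys are
#' an error listing the collisions.
#'
#' @param records A study tibble with derived effects (see
#'   [derive_effects()]).
#' @param contrast Contrast label stored on each dataset.
#' @return A list of `association_dataset` objects.
#' @export
group_into_datasets <- function(records, contrast = "additive") {
  if (nrow(records) == 0) return(list())
  key <- paste(records$study_id, records$variant_id, records$outcome_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    rlang::abort(paste0("duplicate (study, variant, outcome) record(s): ",
                        paste(gsub("\r", "/", dup), collapse = "; ")),
                 class = "metasynopsis_error_duplicate")
  }
  split_key <- paste(records$variant_id, records$outcome_name, sep = "\r")
  lapply(split(seq_len(nrow(records)), split_key), function(idx) {
    rec <- records[idx, , drop = FALSE]
    new_association_dataset(rec, contrast)
  })
}

new_association_dataset <- function(records, contrast = "additive") {
  pool <- if ("poolable" %in% names(records)) {
    records[records$poolable, , drop = FALSE]
  } else {
    records
  }
  scale <- unique(stats::na.omit(records$effect_scale))
  if (length(scale) > 1) {
    rlang::abort("records in one dataset must share an effect scale",
                 class = "metasynopsis_error_domain")
  }
  out <- list(
    variant_id = records$variant_id[1],
    outcome_name = records$outcome_name[1],
    outcome_kind = records$outcome_kind[1],
    contrast = contrast,
    effect_scale = if (length(scale)) scale else "log_odds",
    records = dplyr::rename(records, se_raw = dplyr::any_of("se")) |>
      dplyr::rename(se = dplyr::any_of("se_theta")),
    k = nrow(pool),
    eligible = nrow(pool) >= 3
  )
  class(out) <- "association_dataset"
  out
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("association dataset %s / %s: k = %d poolable record(s)%s\n",
              x$variant_id, x$outcome_name, x$k,
              if (x$eligible) "" else " (ineligible, k < 3)"))
  invisible(x)
}
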