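#' Load a packaged pooled-association table
#'
#' The packaged fixtures transcribe published pooled results — one row per
#' meta-analysis with the pooled OR and CI, p-value, I2, heterogeneity p,
#' Venice grade, FPRP and cumulative-evidence label. Censored cells such
#' as `<0.001` are split into a numeric bound and a censoring flag.
#'
#' @param which `"table1"` (disease outcomes), `"table2"` (categorical
#'   phenotypes), or a path to a TSV in the same layout.
#' @return A tibble with numeric `p`, `i2`, `fprp_value` (+ logical
#'   `fprp_censored`), `het_p_value` (+ `het_p_censored`), and the printed
#'   `venice`/`cumulative` strings (empty for ungraded rows).
#' @export
#' @examples
#' load_pooled_table("table1")
load_pooled_table <- function(which = c("table1", "table2")) {
  path <- if (file.exists(which[1])) {
    which[1]
  } else {
    which <- match.arg(which)
    synopsis_example(paste0(which, "_pooled.tsv"))
  }
  x <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                         colClasses = "character", fileEncoding = "UTF-8")
  num <- function(v) suppressWarnings(as.numeric(v))
  censored <- function(v) {
    v <- trimws(ifelse(is.na(v), "", v))
    list(value = num(sub("^<", "", v)), censored = grepl("^<", v))
  }
  fp <- censored(x$fprp)
  hp <- censored(x$het_p)
  tibble::tibble(
    variant = x$variant,
    major_allele = x$major_allele, minor_allele = x$minor_allele,
    maf = num(x$maf), outcome = x$outcome,
    datasets = as.integer(x$datasets),
    cases = num(x$cases), controls = num(x$controls), n_total = num(x$n_total),
    or = num(x$or), ci_low = num(x$ci_low), ci_high = num(x$ci_high),
    p = num(x$p), i2 = num(x$i2),
    het_p_value = hp$value, het_p_censored = hp$censored,
    venice = trimws(ifelse(is.na(x$venice), "", x$venice)),
    fprp_value = fp$value, fprp_censored = fp$censored,
    cumulative = trimws(ifelse(is.na(x$cumulative), "", x$cumulative))
  )
}

#' Count significant pooled associations
#'
#' @param x A pooled table (from [load_pooled_table()]), a report table, or
#'   a list of `association_report`s — anything carrying a pooled p per
#'   association.
#' @param alpha Two-sided significance level, default 0.05.
#' @return A named vector `c(n_total, n_significant)`.
#' @export
#' @examples
#' count_significant(load_pooled_table("table1"))
count_significant <- function(x, alpha = 0.05) {
  p <- if (is.data.frame(x)) {
    x$p
  } else if (is.list(x)) {
    vapply(x, function(r) r$meta$p, numeric(1))
  } else {
    rlang::abort("cannot extract p-values", class = "metasynopsis_error_domain")
  }
  c(n_total = length(p), n_significant = sum(p < alpha, na.rm = TRUE))
}

#' Regrade the printed evidence columns of a pooled table
#'
#' For every graded row, re-derives the Venice category from the printed
#' letter triplet, the FPRP category from the printed FPRP value
#' (a censored `<0.001` is strong by construction), combines them with
#' [combine_evidence()], and compares against the printed cumulative
#' label.
#'
#' @param pooled A tibble from [load_pooled_table()], or several bound
#'   together.
#' @return The graded rows with `venice_category`, `fprp_category`,
#'   `final` and logical `matches_printed` columns.
#' @export
replay_cumulative <- function(pooled) {
  graded <- pooled[nzchar(pooled$venice) & !is.na(pooled$fprp_value), , drop = FALSE]
  graded$venice_category <- vapply(graded$venice,
                                   function(v) venice_category(parse_grade_triplet(v)),
                                   character(1))
  graded$fprp_category <- fprp_category(graded$fprp_value)
  graded$final <- vapply(seq_len(nrow(graded)), function(i) {
    combine_evidence(graded$venice_category[i], graded$fprp_category[i])$final
  }, character(1))
  graded$matches_printed <- graded$final == tolower(graded$cumulative)
  graded
}

#' Recompute FPRP for every graded row of a pooled table
#'
#' Applies [fprp_from_pooled()] to the printed OR, CI and p of each graded
#' row.
#'
#' @param pooled A tibble from [load_pooled_table()].
#' @param alpha_source,or1,pi Forwarded to [fprp_from_pooled()].
#' @return The graded rows with a numeric `fprp_recomputed` column.
#' @export
recompute_fprp <- function(pooled, alpha_source = "reported_p", or1 = 1.2, pi = 0.05) {
  graded <- pooled[nzchar(pooled$venice), , drop = FALSE]
  graded$fprp_recomputed <- vapply(seq_len(nrow(graded)), function(i) {
    fprp_from_pooled(graded$or[i], graded$ci_low[i], graded$ci_high[i],
                     p = graded$p[i], alpha_source = alpha_source,
                     or1 = or1, pi = pi)$value
  }, numeric(1))
  graded
}
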