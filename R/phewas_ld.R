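#' Bonferroni family-wise threshold
#'
#' @param m Number of tests (at least 1).
#' @param fwer Family-wise error rate, default 0.05.
#' @return `fwer / m`.
#' @export
#' @examples
#' bonferroni_threshold(778)
bonferroni_threshold <- function(m, fwer = 0.05) {
  if (length(m) != 1 || !is.finite(m) || m < 1) {
    rlang::abort("m must be a single count >= 1", class = "metasynopsis_error_domain")
  }
  if (fwer <= 0 || fwer > 1) {
    rlang::abort("fwer must lie in (0, 1]", class = "metasynopsis_error_domain")
  }
  fwer / m
}

#' Read a phenome-wide summary table
#'
#' Tab-separated with columns phenotype, code, effect, ci_low, ci_high, p,
#' n_cases.
#'
#' @param path Path to a TSV file.
#' @return A tibble of phenome-wide rows.
#' @export
read_phewas_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "metasynopsis_error_io")
  }
  x <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                         colClasses = c(phenotype = "character", code = "character"))
  needed <- c("phenotype", "p")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    rlang::abort(paste0("phenome-wide table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "metasynopsis_error_schema")
  }
  bad <- which(!is.na(x$p) & (x$p < 0 | x$p > 1))
  if (length(bad)) {
    rlang::abort("p-values outside [0, 1]", class = "metasynopsis_error_domain")
  }
  tibble::as_tibble(x)
}

#' Phenome-wide scan at a Bonferroni threshold
#'
#' Returns the rows with `p < fwer / m`, sorted by ascending p. The number
#' of tests `m` defaults to the number of rows scanned, so a table padded
#' to the full phenotype panel is thresholded at the panel-wide level.
#'
#' @param rows A tibble of phenome-wide rows (see [read_phewas_table()]).
#' @param fwer Family-wise error rate, default 0.05.
#' @param m Number of tests; defaults to `nrow(rows)`.
#' @return The significant rows, ascending in p, with the threshold
#'   attached as attribute `"threshold"`.
#' @export
phewas_scan <- function(rows, fwer = 0.05, m = nrow(rows)) {
  if (nrow(rows) == 0) {
    rlang::abort("empty phenome-wide table", class = "metasynopsis_error_domain")
  }
  thr <- bonferroni_threshold(m, fwer)
  hit <- rows[!is.na(rows$p) & rows$p < thr, , drop = FALSE]
  hit <- hit[order(hit$p), , drop = FALSE]
  attr(hit, "threshold") <- thr
  hit
}

#' Read a square r-squared matrix keyed by variant id
#'
#' Expects a header row of variant ids and a leading id column; validates
#' symmetry, a unit diagonal and values in \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A named square matrix of class `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "metasynopsis_error_io")
  }
  x <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as_ld_matrix(as.matrix(x))
}

#' Validate a square r-squared matrix
#'
#' @param r2 A square numeric matrix with matching row and column names.
#' @return The matrix with class `ld_matrix`.
#' @export
as_ld_matrix <- function(r2) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) {
    rlang::abort("r2 must be a square matrix", class = "metasynopsis_error_domain")
  }
  if (is.null(rownames(r2)) || !identical(rownames(r2), colnames(r2))) {
    rlang::abort("r2 needs matching row and column variant ids",
                 class = "metasynopsis_error_domain")
  }
  if (any(r2 < 0 | r2 > 1)) {
    rlang::abort("r2 values must lie in [0, 1]", class = "metasynopsis_error_domain")
  }
  if (any(abs(r2 - t(r2)) > 1e-8)) {
    rlang::abort("r2 matrix must be symmetric", class = "metasynopsis_error_domain")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    rlang::abort("r2 diagonal must be 1", class = "metasynopsis_error_domain")
  }
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Prune variants into linkage-disequilibrium clusters
#'
#' Builds the graph with an edge wherever `r2 > cutoff` (strict) and
#' returns its connected components in order of first appearance. Each
#' cluster's representative is its first member in input order, unless a
#' variant named in `prefer` belongs to the cluster.
#'
#' @param r2 An `ld_matrix` (see [as_ld_matrix()] / [read_ld_matrix()]).
#' @param cutoff Strict r-squared threshold, default 0.8.
#' @param prefer Character vector of variants to favour as representatives.
#' @return A list of character-vector clusters with attribute
#'   `"representatives"`.
#' @export
#' @examples
#' ld <- as_ld_matrix(diag(1, 3, 3) |>
#'   `dimnames<-`(list(paste0("rs", 1:3), paste0("rs", 1:3))))
#' ld_prune(ld)
ld_prune <- function(r2, cutoff = 0.8, prefer = NULL) {
  if (!inherits(r2, "ld_matrix")) r2 <- as_ld_matrix(r2)
  ids <- rownames(r2)
  n <- length(ids)
  adj <- r2 > cutoff
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  next_comp <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    next_comp <- next_comp + 1L
    queue <- i
    comp[i] <- next_comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- next_comp
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(seq_len(next_comp), function(cid) ids[comp == cid])
  reps <- vapply(clusters, function(cl) {
    hit <- intersect(prefer, cl)
    if (length(hit)) hit[1] else cl[1]
  }, character(1))
  attr(clusters, "representatives") <- reps
  clusters
}
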