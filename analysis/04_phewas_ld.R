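#!/usr/bin/env Rscript

# Offline phenome-wide stage: prune the variant panel to independent
# signals by linkage disequilibrium, then scan each representative's
# phenotype summary table at the panel-wide Bonferroni threshold.

suppressPackageStartupMessages({
  library(metasynopsis)
  library(dplyr)
})
dir.create("results", showWarnings = FALSE)
set.seed(778)

ld <- read_ld_matrix(synopsis_example("ld_blocks_synthetic.tsv"))
clusters <- ld_prune(ld, cutoff = 0.8,
                     prefer = c("rs2228145", "rs4845625"))
reps <- attr(clusters, "representatives")
for (i in seq_along(clusters)) {
  message(sprintf("LD cluster %d (r2 > 0.8): %s -> representative %s",
                  i, paste(clusters[[i]], collapse = ", "), reps[i]))
}
writeLines(vapply(seq_along(clusters), function(i) {
  sprintf("%s\t%s", reps[i], paste(clusters[[i]], collapse = ","))
}, ""), "results/ld_clusters.tsv")

panel_size <- 778
thr <- bonferroni_threshold(panel_size, 0.05)
message(sprintf("Bonferroni threshold for %d phenotypes: %.3g", panel_size, thr))

hits <- bind_rows(lapply(reps, function(v) {
  known <- read_phewas_table(synopsis_example(sprintf("phewas_%s.tsv", v)))
  # pad the summary table with null phenotypes to the full panel size
  nulls <- tibble::tibble(
    phenotype = sprintf("null phenotype %03d", seq_len(panel_size - nrow(known))),
    code = NA_character_, effect = 1, ci_low = NA_real_, ci_high = NA_real_,
    p = runif(panel_size - nrow(known), 0.01, 1), n_cases = NA_integer_)
  phewas_scan(bind_rows(known, nulls), fwer = 0.05) |>
    mutate(variant = v, .before = 1)
}))
message(sprintf("%d phenome-wide associations below the threshold", nrow(hits)))
print(as.data.frame(hits[, c("variant", "phenotype", "effect", "p")]), digits = 3)
write.table(hits, "results/phewas_hits.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/ld_clusters.tsv and results/phewas_hits.tsv")
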