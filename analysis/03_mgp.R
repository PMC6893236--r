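#!/usr/bin/env Rscript
# Estimate marker gene profiles (relative cell-type abundance surrogates) on
# the integrated matrices and test case-control differences per cell type
# (Wilcoxon rank-sum, BH-adjusted). Late phase should show neuronal MGPs
# down and astrocyte/microglia MGPs up; early phase should show no change.
#
# Reads results/integrated/<phase>/ and the marker GMT from
# results/synthetic/<phase>/; writes results/mgp/<phase>/.

library(admega)

for (phase in c("late", "early")) {
  expr <- read_expression_tsv(
    file.path("results/integrated", phase, "expression.tsv"))
  meta <- read_sample_table(
    file.path("results/integrated", phase, "samples.tsv"))
  markers <- load_gmt(file.path("results/synthetic", phase, "markers.gmt"))

  corrected <- correct_study_effects(
    expr, meta$study_id[match(colnames(expr), meta$sample_id)])
  mgp <- estimate_mgp(corrected, markers$sets)
  tests <- test_mgp_difference(mgp, meta)

  out <- file.path("results/mgp", phase)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  scores <- data.frame(sample_id = rownames(mgp$scores), mgp$scores,
                       check.names = FALSE)
  write.table(scores, file.path(out, "mgp_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tests, file.path(out, "mgp_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(phase, ": cell types at FDR < 0.05: ",
          paste(sprintf("%s (%s)", tests$celltype[tests$fdr < 0.05],
                        tests$direction[tests$fdr < 0.05]), collapse = ", "))
}
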