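#!/usr/bin/env Rscript
# Simulate the two synthetic multi-study cohorts the analysis runs on: a
# late-phase cohort (neuron loss + gliosis shifts the cellular composition of
# case samples) and an early-phase cohort (no composition change, 30 genes
# up-regulated by one log2 unit within pyramidal cells). Three studies on
# three platforms with overlapping gene sets, 10 controls and 10 cases each.
#
# Writes per-study expression TSVs, sample tables, marker GMTs and ground
# truth under results/synthetic/<phase>/.

library(admega)

seed <- 1L
out_root <- "results/synthetic"

late <- generate_cohort(cohort_config(phase = "late"), seed = seed)
write_cohort(late, file.path(out_root, "late"))
message("late cohort: ", length(late$studies), " studies, ",
        length(late$profiles$gene_ids), " genes -> ",
        file.path(out_root, "late"))

early <- generate_cohort(
  cohort_config(phase = "early",
                regulated = list(n = 30, celltype = "pyramidal",
                                 log2fc = 1)),
  seed = seed + 1L)
write_cohort(early, file.path(out_root, "early"))
message("early cohort: 30 regulated pyramidal genes, no composition shift -> ",
        file.path(out_root, "early"))
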