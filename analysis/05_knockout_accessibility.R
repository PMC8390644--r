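#!/usr/bin/env Rscript
# Step 5: differential accessibility in the knockout condition
# (CPM/log2 normalization, moderated t, FDR < 0.05), the loss-direction
# fraction, and per-chromatin-state enrichment of the losses against
# the expected counts from cluster proportions.

suppressMessages(library(statepipe))

counts <- read_matrix_tsv("results/data/atac_counts.tsv")
truth <- utils::read.table("results/data/atac_truth.tsv", header = TRUE,
                           sep = "\t")
states <- utils::read.table("results/chromatin_states.tsv", header = TRUE,
                            sep = "\t")
groups <- list(WT = grep("^WT_", colnames(counts), value = TRUE),
               KO = grep("^KO_", colnames(counts), value = TRUE))

dars <- call_dars(counts, groups$WT, groups$KO)
utils::write.table(dars, "results/dars_ko_vs_wt.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

down <- dars$significant & dars$direction == "down"
cat(sprintf("DARs at FDR < 0.05: %d, of which %d reduced (%.1f%%)\n",
            sum(dars$significant), sum(down),
            dar_direction_fraction(sum(down), sum(dars$significant))))
cat(sprintf("planted-loss sensitivity: %.2f\n",
            mean(down[truth$dar == "down"])))

# enrichment of losses across the chromatin-state clusters of step 3
cls <- states$class[match(dars$peak_id, states$peak_id)]
obs <- tapply(down, cls, sum)
sizes <- table(cls)[names(obs)]
enr <- expected_cluster_dars(
  stats::setNames(as.integer(obs), names(obs)),
  stats::setNames(as.integer(sizes), names(obs)))
enr <- enr[order(enr$p_value), ]
print(as.data.frame(enr))
utils::write.table(enr, "results/dar_cluster_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("classes enriched for accessibility loss (p < 1e-6):",
    paste(enr$cluster[enr$p_value < 1e-6 & enr$observed > enr$expected],
          collapse = ", "), "\n")
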