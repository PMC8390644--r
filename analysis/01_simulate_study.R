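#!/usr/bin/env Rscript
# Step 1: generate the synthetic two-state study that the downstream
# analysis scripts consume. Emulates the structure of a naive/primed
# pluripotency study: replicated bait AP-MS in both states with a
# contaminant-frequency table, a planted chromatin-state peak landscape
# with eight (mark, state) tracks and a TSS annotation, a two-condition
# expression matrix, and a knockout ATAC count matrix in which the
# planted primed-specific and shared enhancers lose accessibility.

suppressMessages(library(statepipe))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260926

## AP-MS arm: one 4-replicate IP study per state, shared protein space
for (state in c("naive", "primed")) {
  cfg <- apms_sim_config(n_proteins = 1200, n_true_interactors = 30,
                         enrichment_fold = 10, dropout_rate = 0.1,
                         seed = seed + (state == "primed"))
  sim <- simulate_apms(cfg)
  write_spectral_counts(sim$records,
                        sprintf("results/data/apms_%s.tsv", state))
  utils::write.table(sim$truth,
                     sprintf("results/data/apms_%s_truth.tsv", state),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (state == "naive") {
    crap <- simulate_crapome(cfg, sim$truth)
    utils::write.table(crap, "results/data/crapome.tsv", sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
}
cat("AP-MS tables: 2 states x 4 replicate IPs, 1200 proteins each\n")

## chromatin arm: planted six-class landscape
land <- simulate_peak_landscape(genome_sim_config(seed = seed + 2))
write_bed(land$peaks, "results/data/baf_peaks.bed")
for (tr in names(land$track_peaks))
  write_bed(land$track_peaks[[tr]],
            sprintf("results/data/track_%s.bed", tr))
write_matrix_tsv(land$intensity, "results/data/track_intensity.tsv",
                 id_column = "peak_id")
utils::write.table(land$tss, "results/data/tss.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(land$truth, "results/data/landscape_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Peak landscape: %d peaks over %d tracks, %d TSS\n",
            length(land$peaks), length(land$track_peaks),
            nrow(land$tss)))

## expression arm: naive (A) vs primed (B), 3 replicates each
e <- simulate_expression(expr_sim_config(n_genes = 5000, n_deg_up = 150,
                                         n_deg_down = 150,
                                         effect_log2fc = 3,
                                         n_replicates = 3,
                                         seed = seed + 3))
write_matrix_tsv(e$matrix, "results/data/expression_fpkm.tsv",
                 id_column = "gene_id")
utils::write.table(e$truth, "results/data/expression_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Expression: %d genes, %d planted DEGs\n", nrow(e$matrix),
            sum(e$truth$deg != "null")))

## knockout ATAC arm: accessibility loss planted at primed/shared enhancers
lost <- land$truth$class %in% c("primed_enhancer", "shared_enhancer")
acfg <- atac_sim_config(n_peaks = length(land$peaks),
                        n_dar_down = sum(lost), seed = seed + 4)
atac <- simulate_atac_counts(acfg, peak_ids = land$truth$peak_id,
                             dar_labels = ifelse(lost, "down", "null"))
write_matrix_tsv(atac$counts, "results/data/atac_counts.tsv",
                 id_column = "peak_id")
utils::write.table(atac$truth, "results/data/atac_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("ATAC: %d peaks, %d planted accessibility losses\n",
            nrow(atac$counts), sum(lost)))
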