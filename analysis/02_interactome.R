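#!/usr/bin/env Rscript
# Step 2: call bait interactors per state from the simulated AP-MS
# tables — identification filtering (score > 10, peptides > 2),
# detection in >= 3 of 4 IPs, CRAPome frequency <= 20%, modified
# enrichment statistic, per-experiment empirical p, CCP combination and
# BH FDR at 0.1 — then compare the two state interactomes.

suppressMessages(library(statepipe))
dir.create("results", showWarnings = FALSE)

crap <- tibble::as_tibble(utils::read.table("results/data/crapome.tsv",
                                            header = TRUE, sep = "\t"))
calls <- list()
for (state in c("naive", "primed")) {
  rec <- read_spectral_counts(sprintf("results/data/apms_%s.tsv", state))
  calls[[state]] <- call_interactors(rec, crap)
  flat <- dplyr::select(calls[[state]], -dplyr::where(is.list))
  utils::write.table(flat,
                     sprintf("results/interactors_%s.tsv", state),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- utils::read.table(
    sprintf("results/data/apms_%s_truth.tsv", state), header = TRUE)
  hit <- calls[[state]]$protein_id[calls[[state]]$called]
  tru <- truth$protein_id[truth$is_true_interactor]
  cat(sprintf(
    "%s: %d candidates scored, %d called (sensitivity %.2f, FDR %.2f)\n",
    state, nrow(calls[[state]]), length(hit),
    mean(tru %in% hit), mean(!hit %in% tru)))
}

ov <- interactome_overlap(calls$naive, calls$primed)
cat(sprintf("state overlap: %d naive-only, %d primed-only, %d shared\n",
            length(ov$a_only), length(ov$b_only), length(ov$shared)))
overlap_tab <- tibble::tibble(
  protein_id = c(ov$a_only, ov$shared, ov$b_only),
  set = rep(c("naive_only", "shared", "primed_only"),
            c(length(ov$a_only), length(ov$shared), length(ov$b_only))))
utils::write.table(overlap_tab, "results/interactome_overlap.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
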