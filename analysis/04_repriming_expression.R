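#!/usr/bin/env Rscript
# Step 4: differential expression between the two states (pseudocounted
# FPKM, unpaired two-sided t-test, p < 0.05 and fold change > 2) and the
# response-fraction arithmetic used for repriming time courses.

suppressMessages(library(statepipe))

fpkm <- read_matrix_tsv("results/data/expression_fpkm.tsv")
truth <- utils::read.table("results/data/expression_truth.tsv",
                           header = TRUE, sep = "\t")
groups <- list(A = grep("^A_", colnames(fpkm), value = TRUE),
               B = grep("^B_", colnames(fpkm), value = TRUE))

x <- add_pseudocount(expression_matrix(fpkm, "paired_end_FPKM"))
degs <- call_degs(x, groups$A, groups$B)
utils::write.table(degs, "results/degs_naive_vs_primed.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

n_up <- sum(degs$significant & degs$direction == "up")
n_down <- sum(degs$significant & degs$direction == "down")
cat(sprintf("DEGs: %d up / %d down in condition B (of %d genes)\n",
            n_up, n_down, nrow(degs)))
cat(sprintf("planted-effect sensitivity %.2f, null false-positive rate %.4f\n",
            mean(degs$significant[truth$deg != "null"]),
            mean(degs$significant[truth$deg == "null"])))

# response-fraction arithmetic of a repriming time course: what share of
# the state-specific DEGs respond in the expected direction
resp_down <- repriming_response_fraction(n_down, round(0.9 * n_down))
cat(sprintf(
  "example response fraction: %d of %d state genes responding = %.1f%%\n",
  resp_down$n_responding, resp_down$n_total, resp_down$percent))
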