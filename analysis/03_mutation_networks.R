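#!/usr/bin/env Rscript
# Stage 3 — gene frequencies, the DNA-repair panel contrast, and the
# per-group co-occurrence / mutual-exclusivity networks.
#
# Genes above 5% frequency are compared between CR and ICR by Fisher's exact
# test; the repair-panel fraction contrast uses the Yates-corrected
# chi-squared test; pairwise interactions are tested separately within the CR
# and ICR subsets (top 25 mutated genes, raw p < 0.05), mirroring the
# group-specific network analysis. Group-specific significance classification
# (classify_group_specific) consumes per-gene q-value tables from an external
# significance caller and is exercised in the test suite.

suppressMessages(library(rectalCR))

data_dir <- Sys.getenv("RECTALCR_DATA_DIR", "results/fixtures")
clinical <- read_clinical(file.path(data_dir, "clinical.tsv"))
maf <- read_maf(file.path(data_dir, "mutations.maf"))
kept <- filter_variants(maf, filter_config())
mat <- build_mutation_matrix(kept, clinical$sample_id)

freq <- compare_gene_frequencies(mat, clinical$response)
message("top differential genes:")
print(head(freq, 8), digits = 3)

panel <- repair_panel_fraction(mat, clinical$response)
message(sprintf("DNA-repair panel mutated: CR %.0f%% vs ICR %.0f%% (chi-squared p = %.3g)",
                100 * panel$fractions[["CR"]], 100 * panel$fractions[["ICR"]],
                panel$test$p_value))

dir.create("results", showWarnings = FALSE)
edges <- list()
for (grp in c("CR", "ICR")) {
  sub <- mat[clinical$response == grp, , drop = FALSE]
  cand <- top_mutated_genes(sub, min_freq = 0.05, top = 25)
  ints <- pairwise_interactions(sub, cand, alpha = 0.05)
  message(sprintf("%s tumors: %d co-occurring and %d mutually exclusive pairs (of %d tested)",
                  grp, count_significant_pairs(ints, "co-occurring"),
                  count_significant_pairs(ints, "mutually exclusive"), nrow(ints)))
  write.table(ints, sprintf("results/interactions_%s.tsv", grp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig <- ints[ints$label != "none", ]
  if (nrow(sig)) {
    edges[[grp]] <- data.frame(source = sig$gene_a, target = sig$gene_b,
                               sign = ifelse(sig$label == "co-occurring", "+", "-"),
                               group = grp)
  }
}
if (length(edges)) {
  write.table(do.call(rbind, edges), "results/interaction_edges.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
write.table(freq, "results/gene_frequencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/gene_frequencies.tsv, results/interactions_{CR,ICR}.tsv, results/interaction_edges.tsv")
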