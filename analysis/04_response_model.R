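#!/usr/bin/env Rscript
# Stage 4 — the logistic complete-response prediction pipeline.
#
# Bivariate screen of gene and co-occurring-pair indicators against response
# (Fisher, p < 0.1, CR-enriched as in the published analysis), construction of
# the network-gene indicator and the 0 / 1-2 / 3-or-more co-occurrence count
# category, logistic fits with the count as categorical and as continuous,
# selection by lowest AIC (Tjur R2 tie-break), and training-set metrics.
# Note: screening and fitting share the training cohort, which overstates the
# metrics; see the methods vignette.

suppressMessages(library(rectalCR))

data_dir <- Sys.getenv("RECTALCR_DATA_DIR", "results/fixtures")
clinical <- read_clinical(file.path(data_dir, "clinical.tsv"))
maf <- read_maf(file.path(data_dir, "mutations.maf"))
kept <- filter_variants(maf, filter_config())
mat <- build_mutation_matrix(kept, clinical$sample_id)

ints <- pairwise_interactions(mat, top_mutated_genes(mat), adjust = TRUE)
cooc <- ints[ints$label == "co-occurring", ]
screening <- screen_predictors(mat, cooc, clinical$response,
                               alpha_screen = 0.1, direction = "CR")
message(sprintf("screen: %d genes and %d co-occurring pairs at p < 0.1",
                nrow(screening$genes), nrow(screening$pairs)))

features <- build_features(clinical, mat, screening)
candidates <- list(fit_response_model(features, "categorical"),
                   fit_response_model(features, "continuous"))
final <- select_model(candidates)
print(attr(final, "candidate_summary"), digits = 4)
print(final)

dir.create("results", showWarnings = FALSE)
write.table(final$coef_table, "results/response_model.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(metric = names(final$metrics), value = unname(final$metrics)),
            "results/response_metrics.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(attr(final, "candidate_summary"), "results/model_candidates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/response_model.tsv, results/response_metrics.tsv, results/model_candidates.tsv")
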