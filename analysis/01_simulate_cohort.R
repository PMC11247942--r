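#!/usr/bin/env Rscript
# Stage 1 — cohort input.
#
# Without an external dataset this builds the study-scale synthetic cohort
# (104 CR / 260 ICR, confounded group assignment, CR-enriched DNA-repair
# genes, planted co-occurring pairs, age-dependent mutation burden) and
# writes the fixture bundle the later stages consume. Point RECTALCR_DATA_DIR
# at a directory holding clinical.tsv and mutations.maf (e.g. a reformatted
# cBioPortal rectal_msk_2022 export) to run the downstream stages on real
# data instead; the published cohort-level numbers (see
# rectalCR::replication_targets()) are only reproducible that way.

suppressMessages(library(rectalCR))

real_dir <- Sys.getenv("RECTALCR_DATA_DIR", "")
out_dir <- "results/fixtures"

if (nzchar(real_dir)) {
  message("External data directory supplied (", real_dir, "); nothing to simulate.")
  quit(save = "no")
}

params <- simulation_preset("paperlike", seed = 20260928)
files <- write_fixture_bundle(out_dir, params, overwrite = TRUE)

sim <- simulate_cohort(params)
message(sprintf("wrote %s: %d patients (%d CR / %d ICR), %d MAF rows (%d below-threshold decoys)",
                out_dir, nrow(sim$clinical), sum(sim$clinical$response == "CR"),
                sum(sim$clinical$response == "ICR"), nrow(sim$maf),
                sum(sim$truth$maf_decoy)))
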