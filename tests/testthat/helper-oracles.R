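# Independent oracles and small fixture builders shared across the suite.

# Brute-force two-sided Fisher p: enumerate the full hypergeometric support
# with log-binomial-coefficient arithmetic (no dhyper), summing probabilities
# not exceeding the observed table's (same 1e-7 relative tie guard).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  logp <- function(x) lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- exp(logp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random 2x2 table with N between 4 and max_n and no fixed structure.
random_table <- function(max_n = 60) {
  n <- sample(4:max_n, 1)
  as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
}

# Plain binary matrix dressed as a mutation matrix (tests that only need
# incidence structure, not the MAF path).
as_mutmat <- function(m, samples = sprintf("S%03d", seq_len(nrow(m))),
                      genes = sprintf("G%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(samples, genes)
  m
}

# Minimal MAF text on disk; rows is a data.frame with MAF column names.
write_tiny_maf <- function(rows, path = tempfile(fileext = ".maf"),
                           comment = TRUE) {
  con <- file(path, "w")
  if (comment) writeLines("#version synthetic", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

tiny_maf_rows <- function(n = 2) {
  data.frame(
    Hugo_Symbol = rep(c("TP53", "APC"), length.out = n),
    Chromosome = "chr1",
    Start_Position = seq_len(n) * 100L,
    Reference_Allele = "A",
    Tumor_Seq_Allele2 = "G",
    Variant_Classification = "Missense_Mutation",
    Tumor_Sample_Barcode = rep(c("S1", "S2"), length.out = n),
    t_depth = 100L,
    t_alt_count = 40L,
    stringsAsFactors = FALSE
  )
}
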