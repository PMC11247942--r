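#' Gene frequencies, co-occurrence networks, and group-specific calls
#'
#' Group-stratified gene-level mutation frequency comparison, pairwise
#' co-occurrence / mutual-exclusivity detection by Fisher's exact test, the
#' CR-/ICR-specific classification of externally supplied q-values, and the
#' DNA-repair panel mutation fraction contrast.
#'
#' @name mutnet
#' @keywords internal
NULL

#' DNA damage repair gene panel
#'
#' Mismatch repair, homologous recombination and polymerase proofreading genes
#' used for the repair-panel mutation fraction contrast. Extend or replace via
#' a plain-text panel file (one HUGO symbol per line, [read_gene_panel()]).
#'
#' @return Character vector of HUGO symbols.
#' @export
dna_repair_panel <- function() {
  c("MSH3", "MLH1", "PMS1", "BRCA1", "BARD1", "POLD1", "POLE")
}

#' Read a gene panel file (one HUGO symbol per line)
#' @param path Path to the panel file; `#` comments and blank lines ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Compare per-gene mutation frequencies between CR and ICR
#'
#' Genes whose mutation frequency exceeds `min_freq` in at least one group are
#' tested with Fisher's exact test on the mutated/not-mutated by CR/ICR table.
#' The odds ratio is oriented so OR > 1 means enrichment in the treated (CR)
#' group.
#'
#' @param matrix Binary `mutation_matrix` (samples x genes).
#' @param group Group labels aligned with the matrix rows.
#' @param min_freq Frequency threshold, strict (default 0.05 per the > 5% rule).
#' @param treated Treated-group label (default `"CR"`).
#' @return Data.frame (gene, n_mutated_CR, n_total_CR, n_mutated_ICR,
#'   n_total_ICR, freq_CR, freq_ICR, odds_ratio, p_value), sorted by p then gene.
#' @export
compare_gene_frequencies <- function(matrix, group, min_freq = 0.05,
                                     treated = "CR") {
  if (length(group) != nrow(matrix)) stop("group must align with matrix samples")
  t_idx <- group == treated
  n1 <- sum(t_idx)
  n0 <- sum(!t_idx)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  m1 <- colSums(matrix[t_idx, , drop = FALSE])
  m0 <- colSums(matrix[!t_idx, , drop = FALSE])
  f1 <- m1 / n1
  f0 <- m0 / n0
  keep <- f1 > min_freq | f0 > min_freq
  genes <- colnames(matrix)[keep]
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), n_mutated_CR = integer(0),
                      n_total_CR = integer(0), n_mutated_ICR = integer(0),
                      n_total_ICR = integer(0), freq_CR = numeric(0),
                      freq_ICR = numeric(0), odds_ratio = numeric(0),
                      p_value = numeric(0)))
  }
  res <- lapply(genes, function(g) {
    tab <- c(m1[g], m0[g], n1 - m1[g], n0 - m0[g])
    fisher_exact_2x2(tab)
  })
  out <- data.frame(
    gene = genes,
    n_mutated_CR = as.integer(m1[genes]), n_total_CR = n1,
    n_mutated_ICR = as.integer(m0[genes]), n_total_ICR = n0,
    freq_CR = as.numeric(f1[genes]), freq_ICR = as.numeric(f0[genes]),
    odds_ratio = vapply(res, `[[`, 0, "estimate"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top mutated genes of a matrix
#'
#' Candidate genes for pairwise interaction testing: frequency above
#' `min_freq` (strict), capped at the `top` most frequently mutated.
#'
#' @param matrix Binary `mutation_matrix`.
#' @param min_freq Frequency threshold (default 0.05).
#' @param top Cap on the number of genes (default 25).
#' @return Character vector of gene symbols (matrix order, i.e. frequency rank).
#' @export
top_mutated_genes <- function(matrix, min_freq = 0.05, top = 25L) {
  freq <- colMeans(matrix)
  genes <- colnames(matrix)[freq > min_freq]
  utils::head(genes, top)
}

#' Pairwise co-occurrence / mutual-exclusivity testing
#'
#' For every unordered pair of candidate genes, builds the both / a-only /
#' b-only / neither table across samples, runs Fisher's exact test, and labels
#' the pair co-occurring (p < alpha and OR > 1), mutually exclusive (p < alpha
#' and OR < 1), or none. Pairs are emitted in canonical order
#' (`gene_a` < `gene_b` lexicographically).
#'
#' @param matrix Binary `mutation_matrix`.
#' @param genes Candidate genes (default [top_mutated_genes()] of the matrix).
#' @param alpha Significance level for the label (default 0.05, raw p).
#' @param adjust If TRUE, apply Benjamini-Hochberg across the pairs and label
#'   on the adjusted values (off by default, mirroring raw-p stars).
#' @return Data.frame (gene_a, gene_b, both, a_only, b_only, neither,
#'   odds_ratio, p_value, label).
#' @export
pairwise_interactions <- function(matrix, genes = top_mutated_genes(matrix),
                                  alpha = 0.05, adjust = FALSE) {
  missing_genes <- setdiff(genes, colnames(matrix))
  if (length(missing_genes)) {
    stop("gene(s) absent from the matrix: ", paste(missing_genes, collapse = ", "))
  }
  if (length(genes) < 2) stop("need at least 2 candidate genes")
  pairs <- utils::combn(sort(genes), 2)
  n_pairs <- ncol(pairs)
  both <- a_only <- b_only <- neither <- integer(n_pairs)
  or <- p <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    ga <- matrix[, pairs[1, i]]
    gb <- matrix[, pairs[2, i]]
    both[i] <- sum(ga == 1 & gb == 1)
    a_only[i] <- sum(ga == 1 & gb == 0)
    b_only[i] <- sum(ga == 0 & gb == 1)
    neither[i] <- sum(ga == 0 & gb == 0)
    res <- fisher_exact_2x2(c(both[i], a_only[i], b_only[i], neither[i]))
    or[i] <- res$estimate
    p[i] <- res$p_value
  }
  p_label <- if (adjust) bh_adjust(p) else p
  label <- ifelse(p_label < alpha & or > 1, "co-occurring",
                  ifelse(p_label < alpha & or < 1, "mutually exclusive", "none"))
  data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
             both = both, a_only = a_only, b_only = b_only, neither = neither,
             odds_ratio = or, p_value = p, label = label,
             stringsAsFactors = FALSE)
}

#' Count interaction pairs with a given label
#' @param interactions Output of [pairwise_interactions()].
#' @param label One of `"co-occurring"`, `"mutually exclusive"`, `"none"`.
#' @return Integer count.
#' @export
count_significant_pairs <- function(interactions, label = "co-occurring") {
  if (nrow(interactions) == 0) return(0L)
  sum(interactions$label == label)
}

#' Classify genes as CR-specific, ICR-specific, shared, or neither
#'
#' A gene is CR-specific iff its q-value is below `alpha` in CR tumors and
#' above `alpha` in ICR tumors; ICR-specific by symmetry; shared iff below in
#' both. Inequalities are strict, so q equal to `alpha` on either side falls
#' into "neither". Genes missing from one table are treated as q = 1 there.
#'
#' @param q_cr,q_icr Named numeric vectors of q-values keyed by gene, or
#'   data.frames with columns `gene` and `q`.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame (gene, q_CR, q_ICR, category); every gene falls into
#'   exactly one category.
#' @export
classify_group_specific <- function(q_cr, q_icr, alpha = 0.05) {
  as_qvec <- function(q, label) {
    if (is.data.frame(q)) {
      if (!all(c("gene", "q") %in% names(q))) {
        stop(label, " must have columns gene and q")
      }
      q <- stats::setNames(q$q, q$gene)
    }
    if (anyNA(q) || any(q < 0 | q > 1)) stop(label, " q-values must lie in [0, 1]")
    q
  }
  q_cr <- as_qvec(q_cr, "q_cr")
  q_icr <- as_qvec(q_icr, "q_icr")
  genes <- sort(union(names(q_cr), names(q_icr)))
  qc <- ifelse(genes %in% names(q_cr), q_cr[genes], 1)
  qi <- ifelse(genes %in% names(q_icr), q_icr[genes], 1)
  category <- ifelse(qc < alpha & qi > alpha, "CR-specific",
              ifelse(qi < alpha & qc > alpha, "ICR-specific",
              ifelse(qc < alpha & qi < alpha, "shared", "neither")))
  data.frame(gene = genes, q_CR = as.numeric(qc), q_ICR = as.numeric(qi),
             category = category, stringsAsFactors = FALSE)
}

#' Per-group fraction of samples mutated in a gene panel
#'
#' Fraction of samples in each group carrying at least one mutation in any
#' panel gene, plus the Yates-corrected chi-squared test of the induced 2x2
#' table (mutated/not by group).
#'
#' @param matrix Binary `mutation_matrix`.
#' @param group Aligned group labels.
#' @param panel Gene set (default [dna_repair_panel()]).
#' @param treated Treated-group label (default `"CR"`).
#' @return List with `fractions` (named, treated first), `counts` (mutated and
#'   total per group), and `test` (a `cr_test_result`, or NULL when the panel
#'   does not overlap the matrix genes — flagged with a warning).
#' @export
repair_panel_fraction <- function(matrix, group, panel = dna_repair_panel(),
                                  treated = "CR") {
  if (length(panel) == 0) stop("panel must be non-empty")
  if (length(group) != nrow(matrix)) stop("group must align with matrix samples")
  present <- intersect(panel, colnames(matrix))
  t_idx <- group == treated
  other <- setdiff(unique(group), treated)[1]
  n1 <- sum(t_idx)
  n0 <- sum(!t_idx)
  if (length(present) == 0) {
    warning("panel has no overlap with the matrix genes; fractions are 0 and no test is run")
    fr <- stats::setNames(c(0, 0), c(treated, other))
    return(list(fractions = fr,
                counts = data.frame(group = c(treated, other),
                                    mutated = c(0L, 0L), total = c(n1, n0)),
                test = NULL))
  }
  hit <- rowSums(matrix[, present, drop = FALSE]) >= 1
  m1 <- sum(hit[t_idx])
  m0 <- sum(hit[!t_idx])
  test <- tryCatch(chi2_yates(c(m1, m0, n1 - m1, n0 - m0)),
                   error = function(e) {
                     warning("panel fraction test degenerate: ", conditionMessage(e))
                     NULL
                   })
  list(
    fractions = stats::setNames(c(m1 / n1, m0 / n0), c(treated, other)),
    counts = data.frame(group = c(treated, other), mutated = c(m1, m0),
                        total = c(n1, n0), stringsAsFactors = FALSE),
    test = test
  )
}
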