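#' Synthetic rectal-cancer cohort generator
#'
#' Generates clinical tables and MAF-style mutation records with the
#' statistical structure the analysis pipeline assumes: confounded CR/ICR
#' assignment through a covariate logit, group-differential gene mutation
#' probabilities, planted co-occurring gene pairs induced by shared latent
#' Bernoulli factors calibrated to a requested dependence odds ratio,
#' age-dependent passenger mutation burden, below-threshold decoy variants
#' that the filter stage must remove, and an optional closed-loop mode in
#' which the response is regenerated from a known logistic model for
#' end-to-end coefficient recovery. Every realized quantity is recorded in a
#' truth object.
#'
#' @name synthetic_cohort
#' @keywords internal
NULL

#' Default simulated gene panel
#'
#' DNA-repair genes enriched in complete responders, common colorectal driver
#' genes enriched in incomplete responders, and group-neutral genes.
#' `base_freq` is the ICR mutation probability and `log_or` the CR shift on
#' the log-odds scale.
#'
#' @return Data.frame with columns `gene`, `base_freq`, `log_or`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("MSH3", "MLH1", "PMS1", "BRCA1", "BARD1", "POLD1", "POLE",
             "APC", "TP53", "KRAS", "PIK3CA", "FBXW7",
             "TTN", "SYNE1", "MUC16", "ARID1A", "SMAD4", "ATM", "KMT2D",
             "PTEN", "NRAS", "RNF43", "SOX9", "TCF7L2", "BRAF"),
    base_freq = c(0.10, 0.07, 0.05, 0.07, 0.04, 0.05, 0.06,
                  0.65, 0.60, 0.40, 0.20, 0.12,
                  0.50, 0.25, 0.22, 0.15, 0.12, 0.10, 0.10,
                  0.08, 0.06, 0.06, 0.08, 0.07, 0.06),
    log_or = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6,
               -0.4, -0.3, -0.3, -0.3, -0.3,
               0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Default planted co-occurring pairs
#'
#' Disjoint DNA-repair and chromatin gene pairs with a within-pair dependence
#' odds ratio of 8.
#'
#' @return Data.frame with columns `gene_a`, `gene_b`, `log_or`.
#' @export
default_planted_pairs <- function() {
  data.frame(
    gene_a = c("BRCA1", "MLH1", "POLD1", "ATM", "KMT2D"),
    gene_b = c("BARD1", "PMS1", "POLE", "MSH3", "PTEN"),
    log_or = rep(log(8), 5),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' Defaults emulate the study cohort: 104 CR and 260 ICR patients, age
#' ~ Normal(60, 10) years, BMI ~ Normal(27, 5), 35% female, log-normal tumor
#' size matched to group medians 4.2 cm (CR) and 4.7 cm (ICR), AJCC stage 3
#' probabilities echoing the node-positive fractions (70.2% CR, 79.4% ICR),
#' confounded assignment through a covariate logit, CR-enriched repair genes
#' and ICR-enriched drivers, five planted co-occurring pairs at dependence
#' OR 8, and an age-dependent passenger burden giving CR tumors a higher mean
#' mutation count.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_cr,n_icr Group sizes.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,p_female Covariate distributions.
#' @param size_meanlog,size_sdlog Log-normal tumor-size latent (cm).
#' @param size_median_cr,size_median_icr Target group medians (cm); the latent
#'   size is rescaled per group to these medians after assignment.
#' @param p_stage3 Named probabilities of AJCC stage 3 per group.
#' @param assignment_coefficients Logit weights of standardized age, bmi,
#'   gender, tumor_size on CR membership (confounding strength).
#' @param assignment_quadratic Logit weights on the squared standardized
#'   covariates (nonlinear confounding; zero by default).
#' @param gene_panel Data.frame gene/base_freq/log_or.
#' @param planted_pairs Data.frame gene_a/gene_b/log_or (positive dependence);
#'   genes must be panel members and may appear in at most one pair.
#' @param tmb_means Named per-group mean passenger mutation counts.
#' @param tmb_age_coef Log-linear effect of standardized age on the passenger
#'   mean (makes confounded assignment bias the naive TMB contrast).
#' @param n_passenger_genes Size of the passenger gene pool.
#' @param coding_length_mb Coding territory for rate conversion.
#' @param response_coefficients Optional named vector (`intercept`,
#'   `tumor_size`, `ajcc_stage3`, `network_gene`, `cat_1_2`, `cat_3plus`)
#'   switching on closed-loop mode: the response is regenerated from this
#'   logistic model instead of the confounded assignment.
#' @param network_genes Genes defining the closed-loop network indicator
#'   (default: panel genes with positive `log_or`).
#' @param decoy_fraction Fraction of extra below-threshold variants (depth or
#'   allele fraction under the filter cutoffs) added to the MAF.
#' @param depth_mean Poisson mean of retained-variant depth (floored at 30).
#' @param af_shape1,af_shape2 Beta parameters of the allele fraction
#'   (truncated to >= 0.1 for retained variants).
#' @param p_msi_h MSI-high probability (about 2% in both groups).
#' @param p_recurrence Named per-group recurrence probabilities.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(seed,
                              n_cr = 104L, n_icr = 260L,
                              age_mean = 60, age_sd = 10,
                              bmi_mean = 27, bmi_sd = 5,
                              p_female = 0.35,
                              size_meanlog = log(4.45), size_sdlog = 0.35,
                              size_median_cr = 4.2, size_median_icr = 4.7,
                              p_stage3 = c(CR = 0.702, ICR = 0.794),
                              assignment_coefficients = c(age = 0.4, bmi = -0.3,
                                                          gender = 0.25,
                                                          tumor_size = -0.4),
                              assignment_quadratic = c(age = 0, bmi = 0,
                                                       gender = 0, tumor_size = 0),
                              gene_panel = default_gene_panel(),
                              planted_pairs = default_planted_pairs(),
                              tmb_means = c(CR = 14, ICR = 10),
                              tmb_age_coef = 0.4,
                              n_passenger_genes = 400L,
                              coding_length_mb = 38,
                              response_coefficients = NULL,
                              network_genes = NULL,
                              decoy_fraction = 0.2,
                              depth_mean = 80,
                              af_shape1 = 5, af_shape2 = 5,
                              p_msi_h = 0.02,
                              p_recurrence = c(CR = 0.10, ICR = 0.33)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for reproducibility")
  if (n_cr < 2 || n_icr < 2) stop("need at least 2 samples per group")
  if (any(gene_panel$base_freq <= 0 | gene_panel$base_freq >= 1)) {
    stop("gene base frequencies must lie strictly inside (0, 1)")
  }
  if (anyDuplicated(gene_panel$gene)) stop("duplicate gene in panel")
  if (nrow(planted_pairs)) {
    pg <- c(planted_pairs$gene_a, planted_pairs$gene_b)
    unknown <- setdiff(pg, gene_panel$gene)
    if (length(unknown)) {
      stop("planted pair references unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(pg)) stop("a gene may appear in at most one planted pair")
    if (any(planted_pairs$log_or <= 0)) stop("planted pair dependence must be positive (co-occurrence)")
  }
  if (is.null(network_genes)) {
    network_genes <- gene_panel$gene[gene_panel$log_or > 0]
  }
  structure(
    list(seed = as.integer(seed), n_cr = as.integer(n_cr), n_icr = as.integer(n_icr),
         age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         p_female = p_female, size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         size_median_cr = size_median_cr, size_median_icr = size_median_icr,
         p_stage3 = p_stage3,
         assignment_coefficients = assignment_coefficients,
         assignment_quadratic = assignment_quadratic,
         gene_panel = gene_panel, planted_pairs = planted_pairs,
         tmb_means = tmb_means, tmb_age_coef = tmb_age_coef,
         n_passenger_genes = as.integer(n_passenger_genes),
         coding_length_mb = coding_length_mb,
         response_coefficients = response_coefficients,
         network_genes = network_genes,
         decoy_fraction = decoy_fraction, depth_mean = depth_mean,
         af_shape1 = af_shape1, af_shape2 = af_shape2,
         p_msi_h = p_msi_h, p_recurrence = p_recurrence),
    class = "simulation_params"
  )
}

#' Named simulation presets
#'
#' * `paperlike` — the defaults: study-scale cohort (104/260), confounded
#'   assignment, CR-enriched repair genes, planted pairs, higher CR burden.
#' * `null` — every effect zeroed: randomized assignment, group-neutral
#'   genes, no planted pairs, equal burden and tumor size.
#' * `strong-confounding` — n = 400 (114 CR / 286 ICR) with strong covariate
#'   logit weights; the balancing stage must undo a large naive TMB bias.
#' * `planted-pairs` — n = 300 (86 CR / 214 ICR), group-neutral genes, five
#'   pairs planted at dependence OR 8; only the pair structure remains.
#' * `closed-loop` — response regenerated from a known logistic model (tumor
#'   size, stage, network-gene indicator, co-occurrence categories at the
#'   published OR scale: 0.79 / 0.71 / 2.57 / 1.57 / 8.47) over a 20-gene
#'   panel with eight planted pairs; for end-to-end recovery.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_params()].
#' @return A `simulation_params` list.
#' @export
simulation_preset <- function(name = c("paperlike", "null", "strong-confounding",
                                       "planted-pairs", "closed-loop"),
                              seed, ...) {
  name <- match.arg(name)
  zero_assign <- c(age = 0, bmi = 0, gender = 0, tumor_size = 0)
  args <- switch(
    name,
    "paperlike" = list(),
    "null" = {
      panel <- default_gene_panel()
      panel$log_or <- 0
      list(assignment_coefficients = zero_assign,
           gene_panel = panel,
           planted_pairs = default_planted_pairs()[0, ],
           tmb_means = c(CR = 12, ICR = 12), tmb_age_coef = 0,
           size_median_cr = 4.45, size_median_icr = 4.45,
           p_stage3 = c(CR = 0.75, ICR = 0.75))
    },
    "strong-confounding" = list(
      n_cr = 114L, n_icr = 286L,
      assignment_coefficients = c(age = 0.8, bmi = -0.7, gender = 0.5,
                                  tumor_size = -0.7)),
    "planted-pairs" = {
      panel <- data.frame(gene = sprintf("G%02d", 1:20), base_freq = 0.2,
                          log_or = 0, stringsAsFactors = FALSE)
      pairs <- data.frame(gene_a = sprintf("G%02d", seq(1, 9, by = 2)),
                          gene_b = sprintf("G%02d", seq(2, 10, by = 2)),
                          log_or = rep(log(8), 5), stringsAsFactors = FALSE)
      list(n_cr = 86L, n_icr = 214L,
           assignment_coefficients = zero_assign,
           gene_panel = panel, planted_pairs = pairs,
           size_median_cr = 4.45, size_median_icr = 4.45,
           p_stage3 = c(CR = 0.75, ICR = 0.75),
           tmb_means = c(CR = 12, ICR = 12), tmb_age_coef = 0)
    },
    "closed-loop" = {
      panel <- data.frame(
        gene = c(sprintf("NET%02d", 1:4), sprintf("PRG%02d", 1:10)),
        base_freq = c(rep(0.15, 4), rep(0.45, 10)),
        log_or = 0, stringsAsFactors = FALSE)
      pairs <- data.frame(
        gene_a = sprintf("PRG%02d", seq(1, 10, by = 2)),
        gene_b = sprintf("PRG%02d", seq(2, 10, by = 2)),
        log_or = rep(log(14), 5), stringsAsFactors = FALSE)
      list(n_cr = 230L, n_icr = 570L,
           assignment_coefficients = zero_assign,
           gene_panel = panel, planted_pairs = pairs,
           size_median_cr = 4.45, size_median_icr = 4.45,
           p_stage3 = c(CR = 0.5, ICR = 0.5),
           tmb_means = c(CR = 10, ICR = 10), tmb_age_coef = 0,
           network_genes = sprintf("NET%02d", 1:4),
           response_coefficients = c(intercept = -0.9,
                                     tumor_size = log(0.79),
                                     ajcc_stage3 = log(0.71),
                                     network_gene = log(2.57),
                                     cat_1_2 = log(1.57),
                                     cat_3plus = log(8.47)))
    }
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(simulation_params, c(list(seed = seed), args))
}

# Solve the shared-latent probability q so that the pair (p_a, p_b) attains
# the requested dependence odds ratio. The latent L ~ Bern(q) forces both
# genes mutated; residual probabilities (p - q)/(1 - q) preserve marginals.
solve_pair_latent <- function(p_a, p_b, target_log_or) {
  or_at <- function(q) {
    pa <- (p_a - q) / (1 - q)
    pb <- (p_b - q) / (1 - q)
    p11 <- q + (1 - q) * pa * pb
    p10 <- (1 - q) * pa * (1 - pb)
    p01 <- (1 - q) * (1 - pa) * pb
    p00 <- (1 - q) * (1 - pa) * (1 - pb)
    log(p11) + log(p00) - log(p10) - log(p01)
  }
  hi <- min(p_a, p_b) * (1 - 1e-9)
  if (or_at(hi - 1e-12) < target_log_or) return(hi)  # clamp: dependence cap
  stats::uniroot(function(q) or_at(q) - target_log_or,
                 lower = 1e-12, upper = hi, tol = 1e-12)$root
}

rtrunc_beta <- function(n, shape1, shape2, lower) {
  out <- stats::rbeta(n, shape1, shape2)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rbeta(length(bad), shape1, shape2)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Simulate a synthetic CR/ICR cohort
#'
#' Draws covariates, assigns CR/ICR with fixed group sizes by
#' covariate-dependent acceptance (sampling without replacement with logit
#' weights), draws group-shifted gene mutations, plants pair dependence via
#' shared latent factors calibrated to the requested odds ratio, adds
#' age-dependent Poisson passenger mutations, optionally regenerates the
#' response from the known logistic model (closed-loop), and emits MAF rows
#' with synthetic coordinates, depth ~ Poisson(80) floored at 30, allele
#' fraction ~ Beta(5, 5) truncated to >= 0.1, plus a configurable fraction of
#' below-threshold decoy rows.
#'
#' @param params A [simulation_params()] or [simulation_preset()] object.
#' @return List with `clinical` (data.frame), `maf` (variant records in the
#'   [read_maf()] schema), and `truth` (per-sample realized quantities, the
#'   gene incidence matrix, decoy row flags, and the generative parameters).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_cr + params$n_icr
  ids <- sprintf("S%04d", seq_len(n))

  age <- round(stats::rnorm(n, params$age_mean, params$age_sd), 1)
  bmi <- round(stats::rnorm(n, params$bmi_mean, params$bmi_sd), 1)
  gender_female <- stats::rbinom(n, 1, params$p_female)
  size_latent <- stats::rlnorm(n, params$size_meanlog, params$size_sdlog)

  zs <- function(x) (x - mean(x)) / if (stats::sd(x) > 0) stats::sd(x) else 1
  zmat <- cbind(age = zs(age), bmi = zs(bmi), gender = zs(gender_female),
                tumor_size = zs(size_latent))
  ac <- params$assignment_coefficients[colnames(zmat)]
  aq <- params$assignment_quadratic[colnames(zmat)]
  ac[is.na(ac)] <- 0
  aq[is.na(aq)] <- 0
  lp <- drop(zmat %*% ac) + drop((zmat^2) %*% aq)
  accept <- stats::plogis(lp)
  cr_rows <- sample.int(n, params$n_cr, prob = accept)
  group <- rep("ICR", n)
  group[cr_rows] <- "CR"
  is_cr <- group == "CR"

  tumor_size <- round(size_latent *
    ifelse(is_cr, params$size_median_cr, params$size_median_icr) /
    exp(params$size_meanlog), 2)
  stage3 <- stats::rbinom(n, 1, ifelse(is_cr, params$p_stage3[["CR"]],
                                       params$p_stage3[["ICR"]]))
  t_stage <- ifelse(stage3 == 1,
                    sample(c("T2", "T3", "T4"), n, TRUE, c(0.10, 0.60, 0.30)),
                    sample(c("T2", "T3", "T4"), n, TRUE, c(0.50, 0.45, 0.05)))
  n_stage <- ifelse(stage3 == 1,
                    sample(c("N1", "N2"), n, TRUE, c(0.6, 0.4)), "N0")
  msi_status <- ifelse(stats::rbinom(n, 1, params$p_msi_h) == 1, "MSI-H", "MSS")
  recurrence <- ifelse(
    stats::rbinom(n, 1, ifelse(is_cr, params$p_recurrence[["CR"]],
                               params$p_recurrence[["ICR"]])) == 1, "yes", "no")

  # --- gene mutations -------------------------------------------------------
  panel <- params$gene_panel
  pmat <- matrix(NA_real_, n, nrow(panel), dimnames = list(ids, panel$gene))
  for (j in seq_len(nrow(panel))) {
    pmat[, j] <- stats::plogis(stats::qlogis(panel$base_freq[j]) +
                                 panel$log_or[j] * is_cr)
  }
  gmat <- matrix(0L, n, nrow(panel), dimnames = list(ids, panel$gene))
  in_pair <- c(params$planted_pairs$gene_a, params$planted_pairs$gene_b)
  for (g in setdiff(panel$gene, in_pair)) {
    gmat[, g] <- stats::rbinom(n, 1, pmat[, g])
  }
  if (nrow(params$planted_pairs)) {
    for (i in seq_len(nrow(params$planted_pairs))) {
      ga <- params$planted_pairs$gene_a[i]
      gb <- params$planted_pairs$gene_b[i]
      tlo <- params$planted_pairs$log_or[i]
      for (g_lab in c("CR", "ICR")) {
        rows <- which(group == g_lab)
        pa <- pmat[rows[1], ga]
        pb <- pmat[rows[1], gb]
        q <- solve_pair_latent(pa, pb, tlo)
        latent <- stats::rbinom(length(rows), 1, q)
        ra <- stats::rbinom(length(rows), 1, (pa - q) / (1 - q))
        rb <- stats::rbinom(length(rows), 1, (pb - q) / (1 - q))
        gmat[rows, ga] <- pmax(latent, ra)
        gmat[rows, gb] <- pmax(latent, rb)
      }
    }
  }

  # --- passengers: age-dependent Poisson burden -----------------------------
  if (params$n_passenger_genes > 0) {
    pass_pool <- sprintf("PSG%04d", seq_len(params$n_passenger_genes))
    mu <- exp(log(ifelse(is_cr, params$tmb_means[["CR"]], params$tmb_means[["ICR"]])) +
                params$tmb_age_coef * zmat[, "age"])
    pass_counts <- stats::rpois(n, mu)
    pass_counts <- pmin(pass_counts, params$n_passenger_genes)
    pass_genes <- lapply(seq_len(n), function(i) {
      if (pass_counts[i] == 0) character(0) else sample(pass_pool, pass_counts[i])
    })
  } else {
    pass_genes <- rep(list(character(0)), n)
    pass_counts <- integer(n)
  }

  # --- closed-loop response regeneration ------------------------------------
  pair_count <- integer(n)
  if (nrow(params$planted_pairs)) {
    for (i in seq_len(nrow(params$planted_pairs))) {
      pair_count <- pair_count +
        as.integer(gmat[, params$planted_pairs$gene_a[i]] == 1 &
                     gmat[, params$planted_pairs$gene_b[i]] == 1)
    }
  }
  net_genes <- intersect(params$network_genes, colnames(gmat))
  network_mutated <- if (length(net_genes)) {
    as.integer(rowSums(gmat[, net_genes, drop = FALSE]) >= 1)
  } else integer(n)
  response_prob <- rep(NA_real_, n)
  if (!is.null(params$response_coefficients)) {
    rc <- params$response_coefficients
    eta <- rc[["intercept"]] + rc[["tumor_size"]] * tumor_size +
      rc[["ajcc_stage3"]] * stage3 + rc[["network_gene"]] * network_mutated +
      rc[["cat_1_2"]] * as.numeric(pair_count >= 1 & pair_count <= 2) +
      rc[["cat_3plus"]] * as.numeric(pair_count >= 3)
    response_prob <- stats::plogis(eta)
    group <- ifelse(stats::rbinom(n, 1, response_prob) == 1, "CR", "ICR")
    is_cr <- group == "CR"
  }

  clinical <- data.frame(
    sample_id = ids, response = group,
    age = age, gender = ifelse(gender_female == 1, "female", "male"),
    bmi = bmi, tumor_size = tumor_size,
    t_stage = t_stage, n_stage = n_stage,
    ajcc_stage = as.character(2 + stage3),
    recurrence = recurrence, msi_status = msi_status,
    stringsAsFactors = FALSE
  )

  # --- MAF emission ---------------------------------------------------------
  hit_idx <- which(gmat == 1L, arr.ind = TRUE)
  maf_sample <- c(ids[hit_idx[, 1]], rep(ids, lengths(pass_genes)))
  maf_gene <- c(colnames(gmat)[hit_idx[, 2]], unlist(pass_genes, use.names = FALSE))
  ord <- order(maf_sample, maf_gene)
  maf_sample <- maf_sample[ord]
  maf_gene <- maf_gene[ord]
  n_true <- length(maf_gene)

  n_decoy <- round(params$decoy_fraction * n_true)
  decoy_sample <- if (n_decoy > 0) sample(ids, n_decoy, replace = TRUE) else character(0)
  all_genes <- c(colnames(gmat),
                 if (params$n_passenger_genes > 0) sprintf("PSG%04d", seq_len(params$n_passenger_genes)))
  decoy_gene <- if (n_decoy > 0) sample(all_genes, n_decoy, replace = TRUE) else character(0)

  m <- n_true + n_decoy
  depth <- pmax(stats::rpois(m, params$depth_mean), 30)
  af <- rtrunc_beta(m, params$af_shape1, params$af_shape2, 0.1)
  decoy <- rep(FALSE, m)
  if (n_decoy > 0) {
    di <- n_true + seq_len(n_decoy)
    decoy[di] <- TRUE
    low_depth <- di[seq_len(floor(n_decoy / 2))]
    low_af <- setdiff(di, low_depth)
    depth[low_depth] <- sample(5:29, length(low_depth), replace = TRUE)
    af[low_af] <- stats::runif(length(low_af), 0, 0.095)
  }
  genes_all <- c(maf_gene, decoy_gene)
  samples_all <- c(maf_sample, decoy_sample)
  alt <- ifelse(decoy & af < 0.1, floor(af * depth), ceiling(af * depth))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt_base <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  classes <- sample(nonsynonymous_classes(), m, replace = TRUE,
                    prob = c(0.55, 0.10, 0.01, 0.08, 0.06, 0.04, 0.03, 0.10, 0.03))
  maf <- data.frame(
    sample_id = samples_all, gene = genes_all,
    chromosome = paste0("chr_", genes_all),
    position = sample.int(100000L, m, replace = TRUE),
    ref_allele = ref, alt_allele = unname(alt_base),
    variant_classification = classes,
    depth = as.numeric(depth),
    allele_fraction = alt / depth,
    stringsAsFactors = FALSE
  )

  truth <- list(
    params = params,
    samples = data.frame(
      sample_id = ids, group = group, assignment_lp = lp,
      assignment_prob = accept, pair_count = pair_count,
      network_mutated = network_mutated, passenger_count = pass_counts,
      response_prob = response_prob, stringsAsFactors = FALSE),
    gene_matrix = gmat,
    gene_probabilities = pmat,
    maf_decoy = decoy
  )
  list(clinical = clinical, maf = maf, truth = truth)
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the clinical TSV, the MAF, a machine-readable per-sample truth
#' sidecar (TSV), and the parameters as TOML. Re-running with the same seed
#' reproduces byte-identical files.
#'
#' @param path Output directory (created if needed).
#' @param params A [simulation_params()] object.
#' @param overwrite Overwrite existing files (default FALSE; collision errors).
#' @return Named vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(path, params, overwrite = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- c(clinical = file.path(path, "clinical.tsv"),
             maf = file.path(path, "mutations.maf"),
             truth = file.path(path, "truth_samples.tsv"),
             params = file.path(path, "params.toml"))
  exists <- file.exists(files)
  if (any(exists) && !overwrite) {
    stop("output file(s) already exist (use overwrite = TRUE): ",
         paste(files[exists], collapse = ", "))
  }
  sim <- simulate_cohort(params)
  utils::write.table(sim$clinical, files["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_maf(sim$maf, files["maf"])
  utils::write.table(sim$truth$samples, files["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gp <- params$gene_panel
  config <- list(
    cohort = list(seed = params$seed, n_cr = params$n_cr, n_icr = params$n_icr,
                  p_female = params$p_female, age_mean = params$age_mean,
                  age_sd = params$age_sd, bmi_mean = params$bmi_mean,
                  bmi_sd = params$bmi_sd),
    filters = list(min_depth = 30, min_af = 0.1, coding_only = TRUE),
    tmb = list(coding_length_mb = params$coding_length_mb,
               mean_cr = params$tmb_means[["CR"]],
               mean_icr = params$tmb_means[["ICR"]],
               age_coef = params$tmb_age_coef),
    assignment = list(
      coefficients = unname(params$assignment_coefficients),
      covariates = names(params$assignment_coefficients)),
    genes = list(gene = gp$gene, base_freq = gp$base_freq, log_or = gp$log_or)
  )
  if (nrow(params$planted_pairs)) {
    config$pairs <- list(gene_a = params$planted_pairs$gene_a,
                         gene_b = params$planted_pairs$gene_b,
                         log_or = params$planted_pairs$log_or)
  }
  write_run_config(config, files["params"])
  invisible(files)
}
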