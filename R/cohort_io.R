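#' MAF and clinical-table ingestion, variant filtering, mutation matrix, TMB
#'
#' Readers for MAF-style mutation files and clinical tables, the depth /
#' allele-fraction / coding-class variant filter, the binary samples-by-genes
#' incidence matrix, and per-sample tumor mutation burden in mutations per
#' megabase.
#'
#' @name cohort_io
#' @keywords internal
NULL

#' Conventional nonsynonymous MAF variant classes
#' @return Character vector of MAF `Variant_Classification` values counted as
#'   coding nonsynonymous.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Variant filter configuration
#'
#' Defaults follow the study design: exclude variants with depth < 30 or
#' allele fraction < 0.1 (exclusion is strict, so depth 30 / AF 0.1 are kept),
#' and restrict to coding nonsynonymous classes.
#'
#' @param min_depth Minimum read depth retained (default 30).
#' @param min_af Minimum allele fraction retained (default 0.1).
#' @param coding_only Keep only `classes` (default TRUE).
#' @param classes Variant classes counted as coding nonsynonymous.
#' @param strict If TRUE, records with missing depth/AF are dropped instead of
#'   retained-and-tallied.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 30L, min_af = 0.1, coding_only = TRUE,
                          classes = nonsynonymous_classes(), strict = FALSE) {
  stopifnot(min_depth >= 0, min_af >= 0, min_af <= 1)
  structure(list(min_depth = as.integer(min_depth), min_af = min_af,
                 coding_only = isTRUE(coding_only), classes = classes,
                 strict = isTRUE(strict)),
            class = "filter_config")
}

maf_required_columns <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                          "Start_Position", "Reference_Allele",
                          "Tumor_Seq_Allele2", "Variant_Classification")

coerce_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & x != "." & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable numeric value in column '%s' at data row %d: '%s'",
                 column, bad[1], x[bad[1]]))
  }
  out
}

#' Read a MAF-style somatic mutation file
#'
#' Tab-separated with a header; lines starting with `#` are skipped. The
#' allele fraction is taken from an `AF` column when present, otherwise
#' computed as `t_alt_count / t_depth`, otherwise left missing.
#'
#' @param path Path to the MAF file.
#' @return A data.frame of variant records with columns `sample_id`, `gene`,
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `variant_classification`, `depth`, `allele_fraction`.
#' @export
read_maf <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(maf_required_columns, names(raw))
  if (length(missing_cols)) {
    stop("MAF is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  depth <- if ("t_depth" %in% names(raw)) {
    coerce_numeric_column(raw[["t_depth"]], "t_depth")
  } else rep(NA_real_, n)
  af <- if ("AF" %in% names(raw)) {
    coerce_numeric_column(raw[["AF"]], "AF")
  } else if (all(c("t_alt_count", "t_depth") %in% names(raw))) {
    coerce_numeric_column(raw[["t_alt_count"]], "t_alt_count") / depth
  } else rep(NA_real_, n)
  pos <- coerce_numeric_column(raw[["Start_Position"]], "Start_Position")
  if (any(!is.na(pos) & pos < 1)) stop("Start_Position must be >= 1 (1-based MAF coordinates)")
  if (any(!nzchar(raw[["Hugo_Symbol"]]))) stop("empty Hugo_Symbol in MAF")
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("allele fraction outside [0, 1]")
  data.frame(
    sample_id = raw[["Tumor_Sample_Barcode"]],
    gene = raw[["Hugo_Symbol"]],
    chromosome = raw[["Chromosome"]],
    position = as.integer(pos),
    ref_allele = raw[["Reference_Allele"]],
    alt_allele = raw[["Tumor_Seq_Allele2"]],
    variant_classification = raw[["Variant_Classification"]],
    depth = depth,
    allele_fraction = af,
    stringsAsFactors = FALSE
  )
}

#' Write variant records back to MAF format
#'
#' Round-trip companion of [read_maf()]: writes the standard column names,
#' with depth as `t_depth`, alt reads as `t_alt_count`, and the allele
#' fraction as `AF`.
#'
#' @param records Variant record data.frame as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  out <- data.frame(
    Hugo_Symbol = records$gene,
    Chromosome = records$chromosome,
    Start_Position = records$position,
    Reference_Allele = records$ref_allele,
    Tumor_Seq_Allele2 = records$alt_allele,
    Variant_Classification = records$variant_classification,
    Tumor_Sample_Barcode = records$sample_id,
    t_depth = records$depth,
    t_alt_count = ifelse(is.na(records$depth) | is.na(records$allele_fraction),
                         NA_real_, round(records$allele_fraction * records$depth)),
    AF = records$allele_fraction,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the depth / allele-fraction / coding filter
#'
#' Retains records with `depth >= min_depth` and `allele_fraction >= min_af`
#' (so the study's "depth < 30 and AF < 0.1 excluded" rule is strict) and,
#' when `coding_only`, a nonsynonymous coding classification. Records with
#' missing depth/AF are retained and tallied via a message (public panel
#' exports often drop these columns) unless `config$strict`.
#'
#' @param records Variant records from [read_maf()].
#' @param config A [filter_config()].
#' @return The retained records; attribute `n_missing_retained` carries the
#'   tally of records kept despite missing depth/AF.
#' @export
filter_variants <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  depth_ok <- is.na(records$depth) | records$depth >= config$min_depth
  af_ok <- is.na(records$allele_fraction) | records$allele_fraction >= config$min_af
  class_ok <- if (config$coding_only) {
    records$variant_classification %in% config$classes
  } else rep(TRUE, nrow(records))
  missing_da <- is.na(records$depth) | is.na(records$allele_fraction)
  if (config$strict) {
    depth_ok <- depth_ok & !is.na(records$depth)
    af_ok <- af_ok & !is.na(records$allele_fraction)
  }
  keep <- depth_ok & af_ok & class_ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_missing <- sum(missing_da[keep])
  if (n_missing > 0 && !config$strict) {
    message(sprintf("filter_variants: retained %d record(s) with missing depth/AF", n_missing))
  }
  attr(out, "n_missing_retained") <- n_missing
  out
}

#' Build the binary samples-by-genes mutation matrix
#'
#' `incidence[s, g] = 1` iff sample `s` carries at least one retained variant
#' of gene `g`. Genes are ordered by descending mutation frequency, ties
#' broken alphabetically. Samples without variants get all-zero rows, but a
#' record whose sample is absent from `samples` is an error (it would silently
#' shrink the cohort).
#'
#' @param records Filtered variant records.
#' @param samples Ordered character vector of every sample to represent.
#' @return A `mutation_matrix`: binary integer matrix with sample rownames and
#'   gene colnames.
#' @export
build_mutation_matrix <- function(records, samples) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  unknown <- setdiff(unique(records$sample_id), samples)
  if (length(unknown)) {
    stop("variant record(s) for sample(s) absent from the cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  genes <- unique(records$gene)
  mat <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(records) > 0) {
    idx <- cbind(match(records$sample_id, samples), match(records$gene, genes))
    mat[idx] <- 1L
  }
  freq <- colSums(mat)
  ord <- order(-freq, colnames(mat))
  mat <- mat[, ord, drop = FALSE]
  class(mat) <- c("mutation_matrix", class(mat))
  mat
}

#' Per-sample tumor mutation burden (mutations / Mb)
#'
#' Count of retained variants per sample divided by the length of the
#' interrogated coding territory. The default denominator, 38 Mb, is a typical
#' whole-exome capture; targeted panels must override it.
#'
#' @param records Filtered variant records.
#' @param samples Ordered sample ids; every one receives a value (0 allowed).
#' @param coding_length_mb Coding territory in Mb, > 0.
#' @return Named numeric vector of mutation rates, one per sample.
#' @export
compute_tmb <- function(records, samples, coding_length_mb = 38) {
  if (!is.numeric(coding_length_mb) || coding_length_mb <= 0) {
    stop("coding_length_mb must be > 0")
  }
  samples <- as.character(samples)
  counts <- table(factor(records$sample_id, levels = samples))
  stats::setNames(as.numeric(counts) / coding_length_mb, samples)
}

#' Read a clinical table
#'
#' Tab- or comma-separated with a header. Column names can be remapped via
#' `mapping` (names = canonical fields, values = file columns). The response
#' column must contain exactly the two labels CR and ICR.
#'
#' @param path Path to the clinical file.
#' @param mapping Optional named character vector remapping file columns onto
#'   the canonical fields (`sample_id`, `response`, `age`, `gender`, `bmi`,
#'   `tumor_size`, `t_stage`, `n_stage`, `ajcc_stage`, `recurrence`,
#'   `msi_status`).
#' @return A data.frame, one row per patient.
#' @export
read_clinical <- function(path, mapping = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dat <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(dat)) stop("clinical table lacks mapped column: ", src)
      names(dat)[names(dat) == src] <- canon
    }
  }
  for (col in c("sample_id", "response")) {
    if (!col %in% names(dat)) stop("clinical table is missing required column: ", col)
  }
  labs <- sort(unique(dat$response))
  if (!identical(labs, sort(c("CR", "ICR")))) {
    stop("response must contain exactly the labels CR and ICR; found: ",
         paste(labs, collapse = ", "))
  }
  if ("tumor_size" %in% names(dat) &&
      any(!is.na(dat$tumor_size) & dat$tumor_size <= 0)) {
    stop("tumor_size must be positive where present")
  }
  dat
}

# ---- minimal TOML subset (run configs and simulation parameter files) -------

toml_format_value <- function(v) {
  fmt1 <- function(x) {
    if (is.character(x)) sprintf('"%s"', x)
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (length(v) == 1L) fmt1(v)
  else paste0("[", paste(vapply(v, fmt1, ""), collapse = ", "), "]")
}

#' Write a flat run-config as TOML
#'
#' Minimal TOML subset: named sections holding scalar or flat-array values.
#'
#' @param config Named list of named lists (sections of key/value pairs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, sprintf("[%s]", section))
    sec <- config[[section]]
    for (key in names(sec)) {
      lines <- c(lines, sprintf("%s = %s", key, toml_format_value(sec[[key]])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

toml_parse_scalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
  if (tok %in% c("true", "false")) return(tok == "true")
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) return(num)
  tok
}

#' Read a flat TOML run-config
#'
#' Counterpart of [write_run_config()]; supports `[section]` headers, scalar
#' values (string, number, boolean) and flat arrays, plus `#` comments.
#'
#' @param path Path to the TOML file.
#' @return Named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("TOML key outside any [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (grepl("^\\[.*\\]$", val)) {
        toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
        toks <- toks[nzchar(trimws(toks))]
        parsed <- lapply(toks, toml_parse_scalar)
        val <- unlist(parsed)
      } else {
        val <- toml_parse_scalar(val)
      }
      out[[section]][[key]] <- val
    } else {
      stop("unparseable TOML line: ", ln)
    }
  }
  out
}
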