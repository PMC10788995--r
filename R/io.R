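#' Read a gene x sample expression table with biotype annotation
#'
#' Reads a tab-separated expression table (genes in rows, one header row of
#' sample IDs, first column holding gene identifiers) and, when a GTF file is
#' supplied, annotates every gene with its biotype by joining against the
#' GTF's `gene` records. Gene-ID version suffixes (`".N"`) are stripped on
#' both sides before joining, since annotation releases and expression
#' matrices frequently disagree on versioning. Genes absent from the GTF get
#' biotype `"unknown"` (with a warning); without a GTF all genes are
#' `"unknown"`.
#'
#' Expression values are assumed to be already normalised (FPKM/TPM-like).
#' No within-package normalisation is applied: the pair indicator used
#' downstream is invariant to per-sample monotone transforms, so the scale
#' of the input does not matter beyond non-negativity.
#'
#' @param path Path to the tab-separated expression file.
#' @param gtf_path Optional path to a GTF annotation file.
#' @param lnc_biotypes Raw GTF biotypes collapsed into the `"lncRNA"` class.
#'   The default covers current Ensembl (`lncRNA`) plus the legacy split
#'   biotypes (`antisense`, `lincRNA`, `processed_transcript`, ...), because
#'   GTF dialects drifted across releases.
#' @return A tibble with columns `gene_id`, `biotype` (one of `"lncRNA"`,
#'   `"protein_coding"`, `"other"`, `"unknown"`), then one numeric column per
#'   sample, row order as in the file.
#' @export
read_expression <- function(path, gtf_path = NULL,
                            lnc_biotypes = c("lncRNA", "antisense", "lincRNA",
                                             "processed_transcript",
                                             "sense_intronic",
                                             "sense_overlapping")) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  header <- readr::read_lines(path, n_max = 1)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2) {
    abort(sprintf("malformed header (line 1 of %s): expected tab-separated sample IDs.", path))
  }
  if (anyDuplicated(fields[-1])) {
    abort(sprintf("malformed header (line 1 of %s): duplicated sample IDs.", path))
  }
  # base parser: strtod-exact doubles, so written values round-trip bit-for-bit
  tbl <- as_tibble(utils::read.delim(path, check.names = FALSE,
                                     colClasses = c("character", rep(NA, length(fields) - 1))))
  names(tbl)[1] <- "gene_id"
  stop_if_not_expr(tbl, "expression file")
  smp <- setdiff(names(tbl), "gene_id")
  for (s in smp) {
    v <- tbl[[s]]
    if (!is.numeric(v)) abort(sprintf("non-numeric expression values in sample column '%s'.", s))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or non-finite expression at gene '%s', sample '%s'.",
                    tbl$gene_id[bad[1]], s))
    }
  }

  biotype <- rep("unknown", nrow(tbl))
  if (!is.null(gtf_path)) {
    ann <- read_gtf_biotypes(gtf_path)
    idx <- match(strip_gene_version(tbl$gene_id), strip_gene_version(ann$gene_id))
    raw <- ann$raw_biotype[idx]
    biotype <- classify_biotype(raw, lnc_biotypes)
    n_missing <- sum(is.na(idx))
    if (n_missing > 0) {
      warn(sprintf("%d gene(s) absent from the GTF; biotype set to 'unknown'.", n_missing))
    }
  }
  out <- bind_cols(tibble(gene_id = tbl$gene_id, biotype = biotype),
                   tbl[, smp, drop = FALSE])
  as_tibble(out)
}

# Map raw GTF biotypes onto the package's four classes.
classify_biotype <- function(raw, lnc_biotypes) {
  dplyr::case_when(
    is.na(raw) ~ "unknown",
    raw %in% lnc_biotypes ~ "lncRNA",
    raw == "protein_coding" ~ "protein_coding",
    TRUE ~ "other"
  )
}

#' Extract gene biotypes from a GTF file
#'
#' Uses `rtracklayer::import()` when available and otherwise a minimal
#' internal reader of the 9-column GTF format. Only records with feature
#' type `gene` are used; both the `gene_biotype` (Ensembl) and `gene_type`
#' (GENCODE) attribute keys are accepted.
#'
#' @param gtf_path Path to the GTF file.
#' @return A tibble with columns `gene_id` and `raw_biotype`.
#' @export
read_gtf_biotypes <- function(gtf_path) {
  if (!file.exists(gtf_path)) abort(sprintf("GTF file not found: %s", gtf_path))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(gtf_path, format = "gtf")
    meta <- as.data.frame(S4Vectors::mcols(gr))
    keep <- meta$type == "gene"
    bt <- meta$gene_biotype %||% meta$gene_type %||% rep(NA_character_, nrow(meta))
    out <- tibble(gene_id = as.character(meta$gene_id[keep]),
                  raw_biotype = as.character(bt[keep]))
  } else {
    out <- parse_gtf_genes(gtf_path)
  }
  # one record per gene; first wins deterministically
  out[!duplicated(out$gene_id), , drop = FALSE]
}

# Dependency-free GTF gene-record reader (attribute column 'key "value";').
parse_gtf_genes <- function(gtf_path) {
  lines <- readr::read_lines(gtf_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) >= 9
  if (!all(ok)) {
    abort(sprintf("malformed GTF record at line %d: fewer than 9 tab-separated fields.",
                  which(!ok)[1]))
  }
  feat <- vapply(parts, `[[`, character(1), 3)
  parts <- parts[feat == "gene"]
  attr_field <- vapply(parts, `[[`, character(1), 9)
  get_attr <- function(x, key) {
    m <- regmatches(x, regexec(paste0(key, ' "([^"]+)"'), x))
    vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, character(1))
  }
  gene_id <- get_attr(attr_field, "gene_id")
  bt <- get_attr(attr_field, "gene_biotype")
  bt2 <- get_attr(attr_field, "gene_type")
  tibble(gene_id = gene_id,
         raw_biotype = dplyr::coalesce(bt, bt2))
}

#' Write an expression tibble back to TSV
#'
#' Values round-trip bit-identically through [read_expression()] (the writer
#' uses shortest round-trippable decimal representations); row and column
#' order are preserved. The `biotype` column is not written, matching the
#' input format.
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stop_if_not_expr(expr)
  out <- expr[, c("gene_id", sample_ids(expr)), drop = FALSE]
  # %.17g guarantees doubles survive the text round trip bit-identically
  out <- mutate(out, across(-"gene_id", ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated, one row per sample, with columns `sample_id`, `os_time`
#' (overall-survival follow-up in days, > 0), `os_event` (1 = death
#' observed, 0 = censored) and optionally `age`, `sex` (`male`/`female`),
#' `grade` (`G1`-`G4`), `stage` (`I`-`IV`) and `immune_subtype` (`C1`-`C6`).
#'
#' @param path Path to the clinical TSV.
#' @return A validated tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("clinical file not found: %s", path))
  clin <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_not_clinical(clin, "clinical file")
  check_level <- function(col, levels) {
    if (col %in% names(clin)) {
      bad <- stats::na.omit(setdiff(unique(clin[[col]]), levels))
      if (length(bad) > 0) {
        abort(sprintf("clinical column '%s' has values outside {%s}: %s",
                      col, paste(levels, collapse = ", "), paste(bad, collapse = ", ")))
      }
    }
  }
  check_level("sex", c("male", "female"))
  check_level("grade", paste0("G", 1:4))
  check_level("stage", c("I", "II", "III", "IV"))
  check_level("immune_subtype", paste0("C", 1:6))
  as_tibble(clin)
}

#' Read a gene set (GRP or single-set GMT)
#'
#' GRP: one gene symbol per line, `#` comment lines ignored, the set named
#' after the file. GMT: a single line `name <tab> description <tab> genes...`.
#'
#' @param path Path to the gene-set file.
#' @param name Optional set name override.
#' @return A tibble with columns `set_name` and `symbol`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("gene set file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- trimws(lines[!startsWith(lines, "#") & nzchar(trimws(lines))])
  if (length(lines) == 0) abort("gene set file is empty.")
  if (grepl("\t", lines[1], fixed = TRUE)) { # GMT
    if (length(lines) > 1) abort("multi-set GMT files are not supported; supply one set.")
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) abort("malformed GMT line: expected name, description, genes.")
    set_name <- name %||% fields[1]
    symbols <- fields[-(1:2)]
  } else { # GRP
    set_name <- name %||% tools::file_path_sans_ext(basename(path))
    symbols <- lines
  }
  symbols <- unique(symbols[nzchar(symbols)])
  if (length(symbols) == 0) abort("gene set has no members.")
  tibble(set_name = set_name, symbol = symbols)
}

#' Read a drug x sample IC50 matrix
#'
#' Tab-separated with drugs in rows and a sample-ID header; the first column
#' holds drug names. IC50 values may be on any monotone scale (for example
#' log micromolar); downstream comparisons are rank-based.
#'
#' @param path Path to the IC50 TSV.
#' @return A tibble with column `drug` then one numeric column per sample.
#' @export
read_ic50 <- function(path) {
  if (!file.exists(path)) abort(sprintf("IC50 file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "drug"
  tbl$drug <- as.character(tbl$drug)
  if (anyDuplicated(tbl$drug)) abort("duplicated drug names in IC50 table.")
  as_tibble(tbl)
}

#' Restrict an expression table and a clinical table to their common samples
#'
#' Both inputs are reduced to the intersection of their sample IDs, in the
#' expression table's column order, so that downstream per-sample operations
#' line up. The clinical table is taken to describe the tumour cohort, so
#' the intersection is the modelling cohort. Dropped sample counts are
#' reported via a message.
#'
#' @param expr Expression tibble.
#' @param clinical Clinical tibble.
#' @return A list with elements `expression` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  stop_if_not_expr(expr)
  stop_if_not_clinical(clinical)
  smp <- sample_ids(expr)
  common <- smp[smp %in% clinical$sample_id]
  if (length(common) == 0) {
    abort("no samples shared between the expression and clinical tables.")
  }
  dropped_expr <- length(smp) - length(common)
  dropped_clin <- nrow(clinical) - length(common)
  if (dropped_expr > 0 || dropped_clin > 0) {
    inform(sprintf("align_cohort: dropped %d expression sample(s) and %d clinical row(s).",
                   dropped_expr, dropped_clin))
  }
  expr_out <- expr[, c(intersect(.meta_cols, names(expr)), common), drop = FALSE]
  clin_out <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  list(expression = as_tibble(expr_out), clinical = as_tibble(clin_out))
}
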