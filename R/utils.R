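#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange left_join inner_join bind_rows
#'   bind_cols group_by summarise ungroup pull across all_of any_of relocate
#'   rename desc n
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
#' @importFrom stats pchisq pnorm pt cor median quantile rnorm rexp rbinom
#'   runif sd setNames var p.adjust kruskal.test wilcox.test chisq.test
#'   complete.cases uniroot qnorm coef na.omit
#' @importFrom utils combn head read.delim modifyList
NULL

# Columns of an expression/pair tibble that are annotation, not samples.
.meta_cols <- c("gene_id", "biotype", "pair_id", "lnc_a", "lnc_b", "frac_one")

#' Sample identifiers of an expression or pair tibble
#'
#' Expression tables are tibbles with one row per gene (`gene_id`, `biotype`,
#' then one numeric column per sample); pair tables have `pair_id`, `lnc_a`,
#' `lnc_b`, `frac_one`, then one 0/1 column per sample. This helper returns
#' the sample columns in order.
#'
#' @param x An expression or pair-matrix tibble.
#' @return Character vector of sample IDs (column order preserved).
#' @export
sample_ids <- function(x) {
  setdiff(names(x), .meta_cols)
}

# Numeric matrix view of an expression tibble (genes x samples).
expr_matrix <- function(expr) {
  smp <- sample_ids(expr)
  m <- as.matrix(expr[, smp, drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

# Numeric 0/1 matrix view of a pair tibble (pairs x samples).
pair_indicator_matrix <- function(pm) {
  smp <- sample_ids(pm)
  m <- as.matrix(pm[, smp, drop = FALSE])
  rownames(m) <- pm$pair_id
  storage.mode(m) <- "double"
  m
}

stop_if_not_expr <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort(sprintf("`%s` must be an expression tibble with a `gene_id` column.", arg))
  }
  dup <- expr$gene_id[duplicated(expr$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene IDs: %s", paste(unique(dup), collapse = ", ")))
  }
  invisible(expr)
}

stop_if_not_clinical <- function(clin, arg = "clinical") {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(clin))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (anyNA(clin$os_time) || anyNA(clin$os_event)) {
    abort(sprintf("`%s` has missing follow-up time or event indicator.", arg))
  }
  if (any(clin$os_time <= 0)) abort(sprintf("`%s`: follow-up times must be > 0.", arg))
  if (!all(clin$os_event %in% c(0, 1))) {
    abort(sprintf("`%s`: event indicator must be 0 or 1.", arg))
  }
  if (anyDuplicated(clin$sample_id)) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  invisible(clin)
}

# Strip Ensembl-style ".N" version suffixes from gene identifiers.
strip_gene_version <- function(ids) sub("\\.\\d+$", "", ids)

# Correlation p-value by the t transform on n - 2 df (exact for Pearson,
# large-sample approximation for Spearman rank correlation).
cor_t_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}
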