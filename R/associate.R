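#' Rank-sum comparison of a feature between the high- and low-risk groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test with mid-rank tie handling: exact
#' enumeration when the combined sample size is at most 20 and there are no
#' ties, otherwise the normal approximation with tie-corrected variance and
#' continuity correction. The reported direction follows the sign of the
#' median difference.
#'
#' @param values_high,values_low Numeric vectors for the two groups.
#' @param feature Feature name to report.
#' @return One-row tibble: `feature`, `n_high`, `n_low`, `statistic`
#'   (Mann-Whitney U of the high group), `p`, `direction`
#'   (`higher_in_high`, `higher_in_low` or `none`).
#' @export
wilcoxon_rank_sum <- function(values_high, values_low, feature = "feature") {
  if (length(values_high) == 0 || length(values_low) == 0) {
    abort("both groups must be non-empty.")
  }
  n <- length(values_high) + length(values_low)
  has_ties <- anyDuplicated(c(values_high, values_low)) > 0
  exact <- n <= 20 && !has_ties
  if (length(unique(c(values_high, values_low))) == 1) {
    # all observations identical: rank variance is zero, no evidence either way
    return(tibble(feature = feature,
                  n_high = length(values_high), n_low = length(values_low),
                  statistic = length(values_high) * length(values_low) / 2,
                  p = 1, direction = "none"))
  }
  ht <- suppressWarnings(
    wilcox.test(values_high, values_low, exact = exact, correct = TRUE)
  )
  md <- median(values_high) - median(values_low)
  direction <- if (md > 0) "higher_in_high" else if (md < 0) "higher_in_low" else "none"
  tibble(feature = feature,
         n_high = length(values_high), n_low = length(values_low),
         statistic = unname(ht$statistic), p = ht$p.value,
         direction = direction)
}

#' Correlation of the risk score with a feature
#'
#' Spearman (default) or Pearson correlation with a two-sided p-value from
#' the t transform on `n - 2` degrees of freedom (exact for Pearson under
#' normality, the usual large-sample approximation for Spearman).
#'
#' @param scores,values Paired numeric vectors (at least 3 pairs).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble `r`, `p`, `n`, `method`.
#' @export
score_correlation <- function(scores, values, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(scores) != length(values)) abort("`scores` and `values` must be paired.")
  ok <- is.finite(scores) & is.finite(values)
  scores <- scores[ok]; values <- values[ok]
  n <- length(scores)
  if (n < 3) abort("need at least 3 paired observations.")
  if (sd(scores) == 0 || sd(values) == 0) abort("zero variance in one of the vectors.")
  r <- cor(scores, values, method = method)
  tibble(r = r, p = cor_t_pvalue(r, n), n = n, method = method)
}

#' Chi-square test of clinical proportions between risk groups
#'
#' Pearson chi-square without continuity correction on a
#' risk-group x category contingency table, `df = (R - 1)(C - 1)`. A
#' warning is raised when any expected cell count is below 5.
#'
#' @param tab A contingency table (matrix of nonnegative integer counts),
#'   or `NULL` when `strat`/`clinical`/`variable` are given.
#' @param strat,clinical,variable Alternative interface: cross-tabulate the
#'   [stratify()] risk label against clinical column `variable`.
#' @return One-row tibble `chi2`, `df`, `p`.
#' @export
chi_square_proportions <- function(tab = NULL, strat = NULL, clinical = NULL,
                                   variable = NULL) {
  if (is.null(tab)) {
    if (is.null(strat) || is.null(clinical) || is.null(variable)) {
      abort("supply either `tab` or all of `strat`, `clinical`, `variable`.")
    }
    d <- inner_join(strat[, c("sample_id", "risk")], clinical, by = "sample_id")
    tab <- table(d$risk, d[[variable]])
  }
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be nonnegative integers.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has an empty row or column margin.")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warn("expected cell count below 5; chi-square approximation may be poor.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Compare the risk score across immune subtypes
#'
#' Drops subtype levels observed in fewer than `min_n` samples (reported via
#' a message — sparsely represented subtypes such as C5/C6 are typically
#' excluded), then tests the remaining levels by Kruskal-Wallis, followed by
#' pairwise rank-sum tests with Benjamini-Hochberg adjustment.
#'
#' @param scores Numeric risk scores.
#' @param subtype Character/factor subtype labels, parallel to `scores`.
#' @param min_n Minimum samples for a level to be retained (default 3).
#' @return List of class `subtype_comparison`: `retained`, `dropped`,
#'   `kruskal_h`, `df`, `p`, and `pairwise` (tibble `level_a`, `level_b`,
#'   `p`, `p_adj`).
#' @export
subtype_comparison <- function(scores, subtype, min_n = 3) {
  if (length(scores) != length(subtype)) abort("`scores` and `subtype` must be paired.")
  ok <- !is.na(subtype) & is.finite(scores)
  scores <- scores[ok]; subtype <- as.character(subtype[ok])
  counts <- table(subtype)
  retained <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts), retained)
  if (length(dropped) > 0) {
    inform(sprintf("subtype_comparison: excluding sparse level(s): %s",
                   paste(dropped, collapse = ", ")))
  }
  if (length(retained) < 2) abort("fewer than 2 subtype levels with enough samples.")
  keep <- subtype %in% retained
  kw <- kruskal.test(scores[keep], factor(subtype[keep]))
  combs <- combn(sort(retained), 2)
  pw <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    res <- wilcoxon_rank_sum(scores[subtype == a], scores[subtype == b],
                             feature = paste(a, b, sep = " vs "))
    tibble(level_a = a, level_b = b, p = res$p)
  })
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  structure(list(retained = sort(retained), dropped = dropped,
                 kruskal_h = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = pw),
            class = "subtype_comparison")
}

#' @export
print.subtype_comparison <- function(x, ...) {
  cat(sprintf("<subtype_comparison> levels %s: Kruskal-Wallis H = %.3f (df %d), p = %.3g\n",
              paste(x$retained, collapse = "/"), x$kruskal_h, x$df, x$p))
  if (length(x$dropped) > 0) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  print(x$pairwise, ...)
  invisible(x)
}

#' Compare drug IC50 between risk groups
#'
#' One rank-sum test per drug of IC50 in high- versus low-risk samples,
#' Benjamini-Hochberg adjusted across drugs. Higher IC50 in the high-risk
#' group suggests reduced sensitivity of high-risk patients to that drug.
#'
#' @param ic50 Tibble `drug` then one numeric column per sample
#'   ([read_ic50()] format).
#' @param strat Stratification tibble from [stratify()].
#' @return Tibble `drug`, `n_high`, `n_low`, `statistic`, `p`, `p_adj`,
#'   `direction`, one row per drug.
#' @export
drug_sensitivity_compare <- function(ic50, strat) {
  smp <- setdiff(names(ic50), "drug")
  common <- intersect(smp, strat$sample_id)
  if (length(common) == 0) abort("no samples shared between IC50 matrix and stratification.")
  risk <- setNames(as.character(strat$risk), strat$sample_id)[common]
  hi <- common[risk == "high"]; lo <- common[risk == "low"]
  if (length(hi) < 2 || length(lo) < 2) abort("need at least 2 samples per risk group.")
  res <- purrr::map_dfr(seq_len(nrow(ic50)), function(i) {
    vh <- unlist(ic50[i, hi], use.names = FALSE)
    vl <- unlist(ic50[i, lo], use.names = FALSE)
    out <- wilcoxon_rank_sum(vh, vl, feature = ic50$drug[i])
    rename(out, drug = "feature")
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  relocate(res, "p_adj", .after = "p")
}

# Figure labels use protein names; expression matrices use gene symbols.
.gene_aliases <- c(PD1 = "PDCD1", `PD-1` = "PDCD1",
                   PDL1 = "CD274", `PD-L1` = "CD274",
                   TIM3 = "HAVCR2", `TIM-3` = "HAVCR2",
                   CD39 = "ENTPD1")

#' Resolve common immune-checkpoint protein aliases to gene symbols
#'
#' @param symbols Character vector of gene symbols or protein aliases
#'   (e.g. `PD1`, `PDL1`, `TIM3`).
#' @return Character vector of gene symbols.
#' @export
resolve_gene_alias <- function(symbols) {
  hit <- .gene_aliases[symbols]
  ifelse(is.na(hit), symbols, unname(hit))
}

#' Compare gene expression between risk groups
#'
#' For each requested gene (protein aliases such as `PD1`/`PDL1`/`TIM3`
#' resolved via [resolve_gene_alias()]): a rank-sum test of expression in
#' high- versus low-risk samples plus a score-expression correlation, with
#' Benjamini-Hochberg adjustment of the rank-sum p-values across the gene
#' family tested.
#'
#' @param expr Expression tibble.
#' @param strat Stratification tibble from [stratify()].
#' @param genes Character vector of gene symbols or aliases.
#' @param cor_method Correlation method for the score association.
#' @return Tibble `gene`, `n_high`, `n_low`, `statistic`, `p`, `p_adj`,
#'   `direction`, `cor_r`, `cor_p`; genes absent from `expr` are skipped
#'   with a warning.
#' @export
risk_group_expression <- function(expr, strat, genes,
                                  cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  stop_if_not_expr(expr)
  resolved <- resolve_gene_alias(genes)
  missing <- resolved[!resolved %in% expr$gene_id]
  if (length(missing) > 0) {
    warn(sprintf("gene(s) absent from the expression table: %s",
                 paste(missing, collapse = ", ")))
  }
  resolved <- resolved[resolved %in% expr$gene_id]
  if (length(resolved) == 0) abort("none of the requested genes are present.")
  m <- expr_matrix(expr)
  common <- intersect(colnames(m), strat$sample_id)
  if (length(common) == 0) abort("no samples shared between expression and stratification.")
  risk <- setNames(as.character(strat$risk), strat$sample_id)[common]
  score <- setNames(strat$score, strat$sample_id)[common]
  res <- purrr::map_dfr(resolved, function(g) {
    v <- m[g, common]
    out <- wilcoxon_rank_sum(v[risk == "high"], v[risk == "low"], feature = g)
    cc <- score_correlation(score, v, method = cor_method)
    mutate(rename(out, gene = "feature"), cor_r = cc$r, cor_p = cc$p)
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  relocate(res, "p_adj", .after = "p")
}
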