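#' Run the full pair-signature pipeline on a cohort
#'
#' End-to-end convenience wrapper: co-expression screen of lncRNAs against
#' the phenotype gene set, moderated differential expression of the screened
#' lncRNAs (tumour vs normal), pair construction and validity filtering on
#' the tumour cohort, univariate Cox screening, LASSO-Cox signature
#' selection (or a supplied model, e.g. [published_signature()]),
#' exponentiated risk scoring, time-dependent ROC, optimal-cutoff
#' stratification, log-rank comparison and univariate + multivariate Cox of
#' the score against clinical covariates.
#'
#' @param expr Expression tibble (tumour and normal samples, biotypes
#'   assigned).
#' @param clinical Clinical tibble (tumour cohort).
#' @param gene_set Tibble `set_name`, `symbol` ([read_gene_set()] format).
#' @param group Named vector or tibble assigning samples to tumor/normal;
#'   samples absent from it but present in `clinical` are taken as tumour.
#' @param model Optional `pair_signature` to apply instead of fitting one.
#' @param cutoff Optional fixed score cutoff; default: [optimal_cutoff()] of
#'   the ROC at `horizon`.
#' @param horizon ROC horizon in days (default 365).
#' @param r_min,p_max_cor Co-expression screen thresholds.
#' @param fdr_max,lfc_min Differential-expression thresholds.
#' @param min_frac Pair-validity class fraction.
#' @param p_max_cox Univariate Cox screen threshold.
#' @param n_folds,seed Cross-validation parameters for the LASSO fit.
#' @return A list with every intermediate result: `hits`, `de`, `de_lnc`,
#'   `pairs`, `cox_screen`, `model`, `scores`, `roc`, `cutoff`, `strata`,
#'   `logrank`, `cox_univariate`, `cox_multivariate`.
#' @export
run_pair_pipeline <- function(expr, clinical, gene_set, group,
                              model = NULL, cutoff = NULL, horizon = 365,
                              r_min = 0.4, p_max_cor = 0.001,
                              fdr_max = 0.05, lfc_min = 2, min_frac = 0.2,
                              p_max_cox = 0.05, n_folds = 10, seed = 1L) {
  stop_if_not_expr(expr)
  stop_if_not_clinical(clinical)
  if (is.data.frame(group)) group <- setNames(group$group, group$sample_id)

  lnc <- filter(expr, .data$biotype == "lncRNA")
  set_expr <- filter(expr, .data$gene_id %in% gene_set$symbol)
  # screen on the tumour cohort: the phenotype is a tumour property, and
  # mixing groups would confound co-expression with tumour/normal shifts
  tum <- intersect(sample_ids(expr), names(group)[group == "tumor"])
  if (length(tum) < 3) abort("fewer than 3 tumour samples for the co-expression screen.")
  keep_cols <- function(x) x[, c("gene_id", "biotype", tum), drop = FALSE]
  hits <- coexpression_screen(keep_cols(lnc), keep_cols(set_expr),
                              r_min = r_min, p_max = p_max_cor)
  if (nrow(hits) == 0) abort("no lncRNAs pass the co-expression screen.")

  screened <- filter(lnc, .data$gene_id %in% hits$lnc_id)
  de <- moderated_de(screened, group, fdr_max = fdr_max, lfc_min = lfc_min)
  de_lnc <- de$gene_id[de$significant]
  if (length(de_lnc) < 2) abort("fewer than 2 differentially expressed lncRNAs.")

  aligned <- align_cohort(filter(expr, .data$gene_id %in% de_lnc), clinical)
  pm <- build_pair_matrix(aligned$expression)
  pm <- filter_valid_pairs(pm, min_frac = min_frac)
  if (nrow(pm) == 0) abort("no pairs survive the validity filter.")

  cox_screen <- univariate_cox_screen(pm, aligned$clinical, p_max = p_max_cox)
  if (is.null(model)) {
    cand <- pm[pm$pair_id %in% cox_screen$term[cox_screen$significant], , drop = FALSE]
    if (nrow(cand) < 2) abort("fewer than 2 prognostic candidate pairs for LASSO.")
    model <- fit_lasso_cox(cand, aligned$clinical, n_folds = n_folds, seed = seed)
  }
  scores <- compute_risk_score(pm, model)
  roc <- survival_roc(scores, aligned$clinical, horizon = horizon)
  if (is.null(cutoff)) cutoff <- optimal_cutoff(roc)
  strata <- stratify(scores, cutoff)
  lr <- logrank_test(strata, aligned$clinical)
  cox_uni <- multivariate_cox(aligned$clinical, scores, covariates = character(0))
  cov_avail <- intersect(c("age", "sex", "grade", "stage"), names(aligned$clinical))
  cox_multi <- multivariate_cox(aligned$clinical, scores, covariates = cov_avail)

  list(hits = hits, de = de, de_lnc = de_lnc, pairs = pm,
       cox_screen = cox_screen, model = model, scores = scores, roc = roc,
       cutoff = cutoff, strata = strata, logrank = lr,
       cox_univariate = cox_uni, cox_multivariate = cox_multi)
}
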