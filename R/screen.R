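#' Co-expression screen of lncRNAs against a phenotype gene set
#'
#' A lncRNA is called related to the phenotype when its expression correlates
#' with at least one gene-set member at `r > r_min` (or `|r| > r_min` with
#' `use_abs = TRUE`) and `p < p_max`. Correlations are computed on
#' `log2(x + 1)` (FPKM-like inputs are right-skewed; the log is monotone so
#' Spearman results are unchanged and Pearson becomes a sensible linear
#' measure). P-values use the exact t transform for Pearson and the
#' large-sample t approximation for Spearman. Each selected lncRNA reports
#' the partner with the largest qualifying `|r|`. Constant expression
#' vectors have undefined correlation and never qualify.
#'
#' @param expr_lnc Expression tibble restricted to candidate lncRNAs.
#' @param expr_set Expression tibble restricted to gene-set members; must
#'   have the same sample columns as `expr_lnc`.
#' @param r_min Correlation threshold (default 0.4).
#' @param p_max P-value threshold (default 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param use_abs Threshold on `|r|` instead of signed `r`.
#' @return Tibble with one row per selected lncRNA: `lnc_id`,
#'   `best_partner`, `r`, `p`.
#' @export
coexpression_screen <- function(expr_lnc, expr_set, r_min = 0.4, p_max = 0.001,
                                method = c("pearson", "spearman"),
                                use_abs = FALSE) {
  method <- match.arg(method)
  stop_if_not_expr(expr_lnc, "expr_lnc")
  stop_if_not_expr(expr_set, "expr_set")
  smp <- sample_ids(expr_lnc)
  if (!identical(smp, sample_ids(expr_set))) {
    abort("`expr_lnc` and `expr_set` must share identical sample columns.")
  }
  n <- length(smp)
  if (n < 3) abort("co-expression screen needs at least 3 shared samples.")

  lm <- log2(expr_matrix(expr_lnc) + 1)
  sm <- log2(expr_matrix(expr_set) + 1)
  const_lnc <- apply(lm, 1, sd) == 0
  if (any(const_lnc)) {
    warn(sprintf("excluding %d constant lncRNA vector(s): %s",
                 sum(const_lnc), paste(rownames(lm)[const_lnc], collapse = ", ")))
  }
  const_set <- apply(sm, 1, sd) == 0
  lm_use <- lm[!const_lnc, , drop = FALSE]
  sm_use <- sm[!const_set, , drop = FALSE]
  if (nrow(lm_use) == 0 || nrow(sm_use) == 0) {
    return(tibble(lnc_id = character(0), best_partner = character(0),
                  r = numeric(0), p = numeric(0)))
  }
  if (method == "spearman") {
    lm_use <- t(apply(lm_use, 1, rank))
    sm_use <- t(apply(sm_use, 1, rank))
  }
  rmat <- cor(t(lm_use), t(sm_use))
  pmat <- matrix(cor_t_pvalue(rmat, n), nrow(rmat), ncol(rmat),
                 dimnames = dimnames(rmat))
  qual <- (if (use_abs) abs(rmat) > r_min else rmat > r_min) & (pmat < p_max)

  hits <- purrr::map_dfr(seq_len(nrow(rmat)), function(i) {
    q <- which(qual[i, ])
    if (length(q) == 0) return(NULL)
    best <- q[which.max(abs(rmat[i, q]))]
    tibble(lnc_id = rownames(rmat)[i],
           best_partner = colnames(rmat)[best],
           r = unname(rmat[i, best]),
           p = unname(pmat[i, best]))
  })
  if (nrow(hits) == 0) {
    return(tibble(lnc_id = character(0), best_partner = character(0),
                  r = numeric(0), p = numeric(0)))
  }
  as_tibble(hits)
}

#' Moderated two-group differential expression
#'
#' Empirical-Bayes moderated t-tests of tumour versus normal on
#' `log2(x + 1)`. Per gene, the log2 fold change is the difference of group
#' means and the residual variance is pooled over both groups with
#' `d = n_t + n_n - 2` degrees of freedom. The prior (`d0`, `s0^2`) is
#' estimated by moment matching of `log(s^2)` against a scaled-F model
#' (digamma/trigamma method); the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` shrinks per-gene variances toward the
#' prior, and the moderated t has `d0 + d` degrees of freedom. When the
#' trigamma equation has no positive solution the prior is degenerate
#' (`d0 = Inf`, full shrinkage). P-values are Benjamini-Hochberg adjusted
#' across all tested genes.
#'
#' @param expr Expression tibble (any biotypes; filter beforehand if needed).
#' @param group Named character vector or tibble (`sample_id`, `group`)
#'   assigning each expression sample to `"tumor"` or `"normal"`.
#' @param fdr_max Adjusted-p threshold for the significance flag.
#' @param lfc_min log2-fold-change threshold for the significance flag
#'   (applied to `|log2fc|` when `direction = "both"`).
#' @param direction `"both"` (default), `"up"` or `"down"`: sidedness of the
#'   fold-change gate.
#' @param d0,s0_sq Optional overrides of the prior degrees of freedom and
#'   prior variance (both must be given together); mainly for validation —
#'   `d0 = 0` reproduces the ordinary equal-variance t-test.
#' @return Tibble with one row per gene: `gene_id`, `log2fc`, `t_mod`, `p`,
#'   `fdr`, `prior_df`, `prior_var`, `residual_df`, `significant`.
#' @export
moderated_de <- function(expr, group, fdr_max = 0.05, lfc_min = 2,
                         direction = c("both", "up", "down"),
                         d0 = NULL, s0_sq = NULL) {
  direction <- match.arg(direction)
  stop_if_not_expr(expr)
  if (is.data.frame(group)) group <- setNames(group$group, group$sample_id)
  smp <- sample_ids(expr)
  if (!all(smp %in% names(group))) abort("every expression sample needs a group label.")
  g <- group[smp]
  if (!all(g %in% c("tumor", "normal"))) abort("group labels must be 'tumor' or 'normal'.")
  nt <- sum(g == "tumor"); nn <- sum(g == "normal")
  if (nt < 2 || nn < 2) abort("each group needs at least 2 samples.")

  m <- expr_matrix(expr)
  if (any(!is.finite(log2(m + 1)))) {
    bad <- expr$gene_id[which(rowSums(!is.finite(log2(m + 1))) > 0)[1]]
    abort(sprintf("non-finite log expression for gene '%s'.", bad))
  }
  lg <- log2(m + 1)
  mt <- rowMeans(lg[, g == "tumor", drop = FALSE])
  mn <- rowMeans(lg[, g == "normal", drop = FALSE])
  log2fc <- mt - mn
  ss_t <- rowSums((lg[, g == "tumor", drop = FALSE] - mt)^2)
  ss_n <- rowSums((lg[, g == "normal", drop = FALSE] - mn)^2)
  d <- nt + nn - 2
  s2 <- (ss_t + ss_n) / d

  if (is.null(d0) != is.null(s0_sq)) abort("supply `d0` and `s0_sq` together.")
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / nt + 1 / nn))
  t_mod <- log2fc / se
  # total df capped at the pooled residual df across all genes (the prior
  # cannot contribute more information than the data it was estimated from)
  df_total <- min(d0 + d, length(s2) * d)
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df_total)
  fdr <- p.adjust(p, method = "BH")
  lfc_pass <- switch(direction,
                     both = abs(log2fc) > lfc_min,
                     up = log2fc > lfc_min,
                     down = log2fc < -lfc_min)
  tibble(gene_id = expr$gene_id,
         log2fc = unname(log2fc),
         t_mod = unname(t_mod),
         p = unname(p),
         fdr = unname(fdr),
         prior_df = d0,
         prior_var = s0_sq,
         residual_df = d,
         significant = unname(fdr < fdr_max & lfc_pass))
}

# Moment matching of log sample variances against a scaled-F model:
# e_g = log s2_g - digamma(d/2) + log(d/2) has mean log s0^2 + digamma(d0/2)
# - log(d0/2) and excess variance trigamma(d0/2) beyond trigamma(d/2).
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = max(mean(s2), .Machine$double.eps)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess dispersion beyond chi-square sampling noise: degenerate
    # prior, all variances shrunk fully to their plain average
    return(list(d0 = Inf, s0_sq = mean(s2[ok])))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton iteration for trigamma^{-1}(x), monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
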