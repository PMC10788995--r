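#' Configuration for a synthetic survival cohort
#'
#' Describes a cohort with the statistical structure the pair-signature
#' pipeline assumes: a per-sample latent phenotype activity (here, vascular
#' invasion), a curated gene set loading on that activity, lncRNAs that are
#' either linked to the activity or pure noise, tumour-only differential
#' expression of a subset of linked lncRNAs, survival times whose hazard
#' depends on planted pair indicators, independent censoring, categorical
#' clinical covariates, and a drug IC50 matrix with a planted monotone
#' dependence on true risk for half the drugs.
#'
#' Defaults emulate the scale and composition of a TCGA-style liver-cancer
#' cohort: 365 tumours, 50 normals, a male-skewed sex distribution,
#' mostly-G2/G3 grades, mostly stage-I/II tumours, immune subtypes
#' concentrated in C1-C4 with C5/C6 nearly absent, roughly two-thirds
#' censoring, and a baseline hazard giving a median overall survival near
#' four years for an average-risk patient.
#'
#' @param n_tumor,n_normal Sample counts per group.
#' @param n_lnc,n_coding,n_geneset Numbers of lncRNAs, of non-gene-set
#'   protein-coding genes, and of gene-set member genes.
#' @param factor_loading Correlation (on the log scale) of "linked" lncRNAs
#'   with the latent activity, in `[0, 1]`.
#' @param n_linked_lnc Number of lncRNAs linked to the latent activity.
#' @param n_de_lnc Number of linked lncRNAs additionally differentially
#'   expressed in tumours (must be `<= n_linked_lnc`).
#' @param de_log2fc Tumour-only shift, in log2 units, added to the
#'   differentially expressed lncRNAs.
#' @param sigma_noise Standard deviation of the log-scale noise.
#' @param signature_pairs Tibble or data frame with columns `lnc_a`, `lnc_b`,
#'   `beta`: the planted prognostic pairs and their log hazard ratios. Pair
#'   members must name simulated lncRNAs (`LNC001`, ...). The default plants
#'   five pairs among the differentially expressed lncRNAs with the
#'   magnitude pattern of the published five-pair signature.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param censor_rate Target fraction of censored tumours in `[0, 1)`.
#' @param n_drugs Number of drugs in the IC50 matrix; the first half carry a
#'   planted monotone dependence on the true risk score.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_tumor = 365, n_normal = 50,
                       n_lnc = 120, n_coding = 150, n_geneset = 40,
                       factor_loading = 0.7, n_linked_lnc = 25, n_de_lnc = 14,
                       de_log2fc = 3, sigma_noise = 1,
                       signature_pairs = NULL,
                       baseline_hazard = 5e-4, censor_rate = 0.65,
                       n_drugs = 10, seed = 1L) {
  if (is.null(signature_pairs)) {
    signature_pairs <- tibble(
      lnc_a = sprintf("LNC%03d", c(1, 3, 4, 5, 2)),
      lnc_b = sprintf("LNC%03d", c(2, 2, 2, 6, 7)),
      beta  = c(0.38, -0.32, -0.34, -0.36, 0.45)
    )
  }
  signature_pairs <- as_tibble(signature_pairs)
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_coding = n_coding, n_geneset = n_geneset,
              factor_loading = factor_loading, n_linked_lnc = n_linked_lnc,
              n_de_lnc = n_de_lnc, de_log2fc = de_log2fc,
              sigma_noise = sigma_noise, signature_pairs = signature_pairs,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_drugs = n_drugs, seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_coding", "n_geneset",
              "n_linked_lnc", "n_drugs")
  for (k in counts) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1) abort(sprintf("`%s` must be a positive count.", k))
  }
  if (n_de_lnc < 0 || n_de_lnc > n_linked_lnc) abort("`n_de_lnc` must be in [0, n_linked_lnc].")
  if (n_linked_lnc > n_lnc) abort("`n_linked_lnc` must not exceed `n_lnc`.")
  if (factor_loading < 0 || factor_loading > 1) abort("`factor_loading` must be in [0, 1].")
  if (sigma_noise <= 0) abort("`sigma_noise` must be > 0.")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  need <- c("lnc_a", "lnc_b", "beta")
  if (!all(need %in% names(signature_pairs))) {
    abort("`signature_pairs` needs columns lnc_a, lnc_b, beta.")
  }
  lnc_ids <- sprintf("LNC%03d", seq_len(n_lnc))
  unknown <- setdiff(c(signature_pairs$lnc_a, signature_pairs$lnc_b), lnc_ids)
  if (length(unknown) > 0) {
    abort(sprintf("signature pair references unknown lncRNA(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates, reproducibly from `config$seed`:
#' \itemize{
#' \item a latent activity \eqn{v_s \sim N(0,1)} per sample;
#' \item gene-set member genes with log2 expression \eqn{a_g v_s} plus noise
#'   (loadings \eqn{a_g} drawn once, uniform on \eqn{[0.5, 0.9]}), linked
#'   lncRNAs with loading `factor_loading`, and unlinked lncRNAs as pure
#'   noise — all on a unit-variance log2 scale around gene-specific means,
#'   then exponentiated (base 2) onto a positive FPKM-like scale;
#' \item a tumour-only shift of `de_log2fc` log2 units for the first
#'   `n_de_lnc` linked lncRNAs;
#' \item exponential survival times for tumours with hazard
#'   \eqn{h_s = h_0 \exp(\sum_p \beta_p x_p(s))}, where \eqn{x_p(s)} is the
#'   0/1 pair indicator of planted pair \eqn{p} in sample \eqn{s};
#' \item independent exponential censoring whose rate is calibrated
#'   deterministically so that the expected censored fraction equals
#'   `censor_rate` (under the exponential/exponential model the per-sample
#'   censoring probability is \eqn{c/(c + h_s)}; the calibration solves the
#'   cohort average for \eqn{c});
#' \item clinical covariates (age, sex, grade, stage, immune subtype) from
#'   fixed categorical distributions;
#' \item an IC50 matrix in which the first half of the drugs increase
#'   monotonically with the true log risk score plus noise and the rest are
#'   pure noise.
#' }
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expression` (tumour + normal columns),
#'   `clinical` (tumour samples), `samples` (sample_id/group),
#'   `gene_set`, `ic50`, and `truth` (linked and DE lncRNA IDs, the planted
#'   pair table, the per-tumour true risk score, latent activity, planted
#'   drug names, and the calibrated censoring rate).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  nt <- config$n_tumor; nn <- config$n_normal
  n_all <- nt + nn
  tumor_ids <- sprintf("T%03d", seq_len(nt))
  normal_ids <- sprintf("N%03d", seq_len(nn))
  ids <- c(tumor_ids, normal_ids)
  group <- c(rep("tumor", nt), rep("normal", nn))

  v <- rnorm(n_all)

  lnc_ids <- sprintf("LNC%03d", seq_len(config$n_lnc))
  set_ids <- sprintf("VIG%03d", seq_len(config$n_geneset))
  cod_ids <- sprintf("CG%03d", seq_len(config$n_coding))

  # log2-scale factor model; with sigma_noise = 1 the log-scale correlation
  # of a gene with the latent activity equals its loading
  a_g <- runif(config$n_geneset, 0.5, 0.9)
  z_set <- sapply(seq_len(config$n_geneset), function(g) {
    a_g[g] * v + sqrt(1 - a_g[g]^2) * rnorm(n_all, sd = config$sigma_noise)
  })
  z_set <- t(z_set)

  fl <- config$factor_loading
  linked <- lnc_ids[seq_len(config$n_linked_lnc)]
  z_lnc <- matrix(rnorm(config$n_lnc * n_all, sd = config$sigma_noise),
                  config$n_lnc, n_all)
  z_lnc[seq_len(config$n_linked_lnc), ] <-
    fl * matrix(v, config$n_linked_lnc, n_all, byrow = TRUE) +
    sqrt(1 - fl^2) * z_lnc[seq_len(config$n_linked_lnc), , drop = FALSE]

  de_lnc <- character(0)
  if (config$n_de_lnc > 0) {
    de_lnc <- linked[seq_len(config$n_de_lnc)]
    z_lnc[seq_len(config$n_de_lnc), group == "tumor"] <-
      z_lnc[seq_len(config$n_de_lnc), group == "tumor"] + config$de_log2fc
  }

  z_cod <- matrix(rnorm(config$n_coding * n_all, sd = config$sigma_noise),
                  config$n_coding, n_all)

  mu <- rnorm(config$n_geneset + config$n_lnc + config$n_coding, mean = 4, sd = 1)
  # planted pair members share a baseline mean so their indicator is balanced
  # across samples (a pair whose members differ by several log2 units would be
  # nearly constant and uninformative, which the validity filter would remove)
  root <- seq_along(mu)
  find_root <- function(i) { while (root[i] != i) i <- root[i]; i }
  for (i in seq_len(nrow(config$signature_pairs))) {
    ia <- config$n_geneset + match(config$signature_pairs$lnc_a[i], lnc_ids)
    ib <- config$n_geneset + match(config$signature_pairs$lnc_b[i], lnc_ids)
    root[find_root(ib)] <- find_root(ia)
  }
  mu <- mu[vapply(seq_along(mu), function(i) as.integer(find_root(i)), integer(1))]
  z_all <- rbind(z_set, z_lnc, z_cod) + mu
  vals <- 2^z_all
  gene_id <- c(set_ids, lnc_ids, cod_ids)
  biotype <- c(rep("protein_coding", config$n_geneset),
               rep("lncRNA", config$n_lnc),
               rep("protein_coding", config$n_coding))
  expr <- bind_cols(tibble(gene_id = gene_id, biotype = biotype),
                    as_tibble(`colnames<-`(vals, ids)))

  # planted pair indicators on the tumour expression
  tum_vals <- vals[, group == "tumor", drop = FALSE]
  rownames(tum_vals) <- gene_id
  sp <- config$signature_pairs
  x_mat <- t(sapply(seq_len(nrow(sp)), function(i) {
    as.integer(tum_vals[sp$lnc_a[i], ] > tum_vals[sp$lnc_b[i], ])
  }))
  lin_pred <- as.numeric(t(x_mat) %*% sp$beta)
  hazard <- config$baseline_hazard * exp(lin_pred)
  event_time <- rexp(nt, rate = hazard)

  if (config$censor_rate > 0) {
    cens_rate <- calibrate_censoring(hazard, config$censor_rate)
    cens_time <- rexp(nt, rate = cens_rate)
  } else {
    cens_rate <- 0
    cens_time <- rep(Inf, nt)
  }
  os_time <- pmin(event_time, cens_time)
  os_event <- as.integer(event_time <= cens_time)

  clinical <- tibble(
    sample_id = tumor_ids,
    os_time = os_time,
    os_event = os_event,
    age = pmin(pmax(round(rnorm(nt, 61, 11)), 18), 90),
    sex = sample(c("male", "female"), nt, replace = TRUE, prob = c(0.68, 0.32)),
    grade = sample(paste0("G", 1:4), nt, replace = TRUE,
                   prob = c(0.15, 0.48, 0.33, 0.04)),
    stage = sample(c("I", "II", "III", "IV"), nt, replace = TRUE,
                   prob = c(0.47, 0.24, 0.24, 0.05)),
    immune_subtype = sample(paste0("C", 1:6), nt, replace = TRUE,
                            prob = c(0.25, 0.33, 0.27, 0.14, 0.007, 0.003))
  )

  true_score <- exp(lin_pred)
  drugs <- c("sorafenib", "nilotinib", "rapamycin", "cisplatin", "mitomycin_c",
             "erlotinib", "gefitinib", "paclitaxel", "gemcitabine", "docetaxel")
  drugs <- if (config$n_drugs <= length(drugs)) drugs[seq_len(config$n_drugs)] else
    c(drugs, sprintf("drug%02d", seq_len(config$n_drugs - length(drugs))))
  n_planted <- floor(config$n_drugs / 2)
  lp_std <- if (sd(lin_pred) > 0) (lin_pred - mean(lin_pred)) / sd(lin_pred) else lin_pred * 0
  ic50_vals <- t(sapply(seq_len(config$n_drugs), function(d) {
    if (d <= n_planted) 0.8 * lp_std + rnorm(nt, sd = 0.6) else rnorm(nt)
  }))
  ic50 <- bind_cols(tibble(drug = drugs),
                    as_tibble(`colnames<-`(ic50_vals, tumor_ids)))

  list(
    expression = expr,
    clinical = clinical,
    samples = tibble(sample_id = ids, group = group),
    gene_set = tibble(set_name = "vascular_invasion", symbol = set_ids),
    ic50 = ic50,
    truth = list(linked_lnc = linked, de_lnc = de_lnc,
                 signature_pairs = sp, true_score = setNames(true_score, tumor_ids),
                 latent_activity = setNames(v, ids),
                 planted_drugs = drugs[seq_len(n_planted)],
                 censoring_rate = cens_rate)
  )
}

# Solve mean_s c/(c + h_s) = target for the censoring rate c; the left side
# is continuous and strictly increasing in c, so the root is unique.
calibrate_censoring <- function(hazard, target) {
  f <- function(cc) mean(cc / (cc + hazard)) - target
  hi <- max(hazard) * target / (1 - target) * 10 + 1
  while (f(hi) < 0) hi <- hi * 10
  uniroot(f, lower = 0, upper = hi, tol = 1e-12)$root
}
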