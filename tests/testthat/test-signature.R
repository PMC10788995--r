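pm_from_indicator <- function(x, ids = NULL) {
  # wrap a pairs x samples 0/1 matrix as a pair tibble
  if (is.null(rownames(x))) rownames(x) <- paste0("Pa", seq_len(nrow(x)), "|Pb", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  ab <- strsplit(rownames(x), "|", fixed = TRUE)
  dplyr::bind_cols(
    tibble::tibble(pair_id = rownames(x),
                   lnc_a = vapply(ab, `[[`, "", 1),
                   lnc_b = vapply(ab, `[[`, "", 2),
                   frac_one = rowMeans(x)),
    tibble::as_tibble(x)
  )
}

test_that("the published signature carries the five reference pairs", {
  sig <- published_signature()
  expect_equal(nrow(sig$pairs), 5)
  expect_equal(sig$pairs$beta[1], 0.3776)
  expect_equal(sig$pairs$pair_id[1], "AC099850.4|MIR4435-2HG")
  expect_equal(sig$provenance, "published")
  expect_equal(sum(sig$pairs$beta), -0.1827, tolerance = 1e-12)
  # an all-ones sample therefore scores below 1
  x <- matrix(1L, 5, 1, dimnames = list(sig$pairs$pair_id, "S1"))
  expect_equal(compute_risk_score(pm_from_indicator(x), sig)$score,
               exp(-0.1827))
})

test_that("risk scores are exp of the coefficient-weighted indicator sum", {
  sig <- published_signature()
  x <- matrix(c(1, 0, 0, 0, 1,
                0, 0, 0, 0, 0), 5, 2,
              dimnames = list(sig$pairs$pair_id, c("S1", "S2")))
  sc <- compute_risk_score(pm_from_indicator(x), sig)
  expect_equal(sc$score[1], exp(0.3776 + 0.4547), tolerance = 1e-12)
  expect_equal(sc$score[1], exp(0.8323), tolerance = 1e-6)
  expect_identical(sc$score[2], 1) # empty sum -> e^0 exactly
  # raising one positive-coefficient indicator multiplies the score by exp(beta)
  x2 <- x; x2["AC099850.4|MIR4435-2HG", "S2"] <- 1
  sc2 <- compute_risk_score(pm_from_indicator(x2), sig)
  expect_equal(sc2$score[2] / sc$score[2], exp(0.3776), tolerance = 1e-12)
})

test_that("log-score is additive over disjoint-support indicator vectors", {
  sig <- published_signature()
  x <- matrix(c(1, 1, 0, 0, 0,
                0, 0, 1, 0, 1,
                1, 1, 1, 0, 1,
                0, 0, 0, 0, 0), 5, 4,
              dimnames = list(sig$pairs$pair_id, c("X", "Y", "XY", "Z")))
  sc <- compute_risk_score(pm_from_indicator(x), sig)
  expect_equal(sc$score[1] * sc$score[2], sc$score[3] * sc$score[4],
               tolerance = 1e-12)
})

test_that("scoring fails loudly when signature pairs are absent", {
  sig <- published_signature()
  x <- matrix(0L, 2, 2, dimnames = list(sig$pairs$pair_id[1:2], c("S1", "S2")))
  expect_error(compute_risk_score(pm_from_indicator(x), sig),
               "AC048341.2\\|GIHCG")
})

test_that("the univariate Cox beta maximises the partial likelihood (grid oracle)", {
  clin <- make_clinical(time = c(1, 2, 3, 4), event = rep(1, 4))
  x <- matrix(c(1, 0, 1, 0), 1, 4,
              dimnames = list("A|B", clin$sample_id))
  fit <- univariate_cox_screen(pm_from_indicator(x), clin)
  b_grid <- oracle_cox_grid(clin$os_time, clin$os_event, as.numeric(x))
  expect_equal(fit$beta, b_grid, tolerance = 2e-4)
  # larger untied fixture for good measure
  clin2 <- binary_cox_fixture(n = 16, beta = 0.7, seed = 5)
  x2 <- matrix(clin2$x, 1, 16, dimnames = list("A|B", clin2$sample_id))
  fit2 <- univariate_cox_screen(pm_from_indicator(x2), clin2)
  b2 <- oracle_cox_grid(clin2$os_time, clin2$os_event, clin2$x)
  expect_equal(fit2$beta, b2, tolerance = 2e-4)
})

test_that("the Cox score test equals the log-rank chi-square for a binary covariate", {
  clin <- binary_cox_fixture(n = 20, beta = 1, seed = 42)
  fit <- survival::coxph(survival::Surv(os_time, os_event) ~ x, data = clin,
                         ties = "efron")
  sdf <- survival::survdiff(survival::Surv(os_time, os_event) ~ x, data = clin)
  expect_equal(unname(fit$score), unname(sdf$chisq), tolerance = 1e-8)
  orc <- oracle_logrank(clin$os_time, clin$os_event, clin$x)
  expect_equal(unname(fit$score), orc$chi2, tolerance = 1e-8)
})

test_that("a null pair indicator gives a near-unit hazard ratio", {
  set.seed(61)
  n <- 2000
  clin <- make_clinical(time = rexp(n, 0.001), event = rbinom(n, 1, 0.7))
  x <- matrix(rbinom(n, 1, 0.5), 1, n, dimnames = list("A|B", clin$sample_id))
  fit <- univariate_cox_screen(pm_from_indicator(x), clin)
  expect_gt(fit$hr, 0.9)
  expect_lt(fit$hr, 1.1)
})

test_that("LASSO at full shrinkage errors; at zero penalty matches the plain Cox fit", {
  clin <- binary_cox_fixture(n = 40, beta = 1, seed = 8)
  set.seed(88)
  x <- rbind(clin$x, rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  rownames(x) <- c("A|B", "C|D", "E|F")
  colnames(x) <- clin$sample_id
  pm <- pm_from_indicator(x)
  expect_error(fit_lasso_cox(pm, clin, lambda = 10), "empty signature")

  single <- pm_from_indicator(x[1, , drop = FALSE])
  sig0 <- fit_lasso_cox(single, clin, lambda = 0)
  ref <- univariate_cox_screen(single, clin)
  expect_equal(sig0$pairs$beta, ref$beta, tolerance = 1e-4)
})

test_that("cross-validated LASSO keeps planted pairs and is seed-reproducible", {
  hits <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(sim_config(
      n_tumor = 400, n_normal = 10, n_lnc = 30, n_coding = 5, n_geneset = 5,
      n_linked_lnc = 5, n_de_lnc = 0, censor_rate = 0.3,
      signature_pairs = tibble::tibble(lnc_a = c("LNC001", "LNC003"),
                                       lnc_b = c("LNC002", "LNC004"),
                                       beta = c(0.8, 0.8)),
      seed = 700 + s))
    tum <- sim$samples$sample_id[sim$samples$group == "tumor"]
    lnc <- dplyr::filter(sim$expression, biotype == "lncRNA")
    pm <- build_pair_matrix(lnc[, c("gene_id", "biotype", tum)])
    pm <- suppressMessages(filter_valid_pairs(pm))
    planted <- paste(c("LNC001", "LNC003"), c("LNC002", "LNC004"), sep = "|")
    cand <- pm[pm$pair_id %in% c(planted, setdiff(pm$pair_id, planted)[1:10]), ]
    sig <- fit_lasso_cox(cand, sim$clinical, seed = 1)
    sig_again <- fit_lasso_cox(cand, sim$clinical, seed = 1)
    expect_identical(sig$pairs, sig_again$pairs)
    hits <- hits + all(planted %in% sig$pairs$pair_id)
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("non-convergent or degenerate fits are flagged, and no events is an error", {
  clin <- make_clinical(time = c(5, 6, 7, 8), event = rep(0, 4))
  x <- matrix(c(1, 0, 1, 0), 1, 4, dimnames = list("A|B", clin$sample_id))
  expect_error(univariate_cox_screen(pm_from_indicator(x), clin), "no events")
  # monotone likelihood: indicator perfectly separates early deaths
  clin2 <- make_clinical(time = c(1, 2, 3, 100, 200, 300), event = rep(1, 6))
  x2 <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6, dimnames = list("A|B", clin2$sample_id))
  out <- suppressWarnings(univariate_cox_screen(pm_from_indicator(x2), clin2))
  expect_false(out$significant[1])
})
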