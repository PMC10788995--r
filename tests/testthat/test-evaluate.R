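scores_tbl <- function(score, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(score))
  tibble::tibble(sample_id = ids, score = score)
}

test_that("perfectly separating scores give AUC 1 and a separating cutoff", {
  clin <- make_clinical(time = c(100, 150, 200, 800, 900, 1000),
                        event = c(1, 1, 1, 0, 0, 0))
  sc <- scores_tbl(c(5, 6, 7, 1, 2, 3))
  roc <- survival_roc(sc, clin, horizon = 365)
  expect_equal(roc$auc, 1)
  cut <- optimal_cutoff(roc)
  # tie rule: largest threshold attaining J = 1 (fewest high-risk calls)
  expect_equal(cut, 3)
  strat <- suppressMessages(stratify(sc, cut))
  expect_equal(as.character(strat$risk), c(rep("high", 3), rep("low", 3)))
})

test_that("without censoring the ROC reduces to the binary empirical ROC", {
  set.seed(71)
  n <- 30
  clin <- make_clinical(time = sample(c(50:200, 400:600), n), event = rep(1, n))
  sc <- scores_tbl(round(rnorm(n), 1)) # ties on purpose
  roc <- survival_roc(sc, clin, horizon = 365)
  is_case <- clin$os_time <= 365
  expect_equal(roc$auc, oracle_auc(sc$score, is_case), tolerance = 1e-12)
  expect_equal(roc$n_cases, sum(is_case))
  # AUC is invariant under strictly increasing score transforms
  roc2 <- survival_roc(scores_tbl(exp(sc$score)), clin, horizon = 365)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
})

test_that("scores independent of survival give a near-half AUC", {
  set.seed(72)
  n <- 2000
  clin <- make_clinical(time = rexp(n, 1 / 500), event = rbinom(n, 1, 0.7))
  sc <- scores_tbl(exp(rnorm(n)))
  roc <- survival_roc(sc, clin, horizon = 365)
  expect_lt(abs(roc$auc - 0.5), 0.03)
})

test_that("the optimal cutoff maximises Youden J (exhaustive enumeration)", {
  clin <- make_clinical(time = c(100, 120, 900, 910, 920, 930),
                        event = c(1, 1, 0, 0, 0, 0))
  sc <- scores_tbl(c(4, 2, 3, 1, 2.5, 0.5))
  roc <- survival_roc(sc, clin, horizon = 365)
  cv <- roc$curve[is.finite(roc$curve$threshold), ]
  j <- cv$sens + cv$spec - 1
  best <- max(cv$threshold[j == max(j)])
  expect_equal(optimal_cutoff(roc), best)
  # uninformative scores -> warning
  clin2 <- make_clinical(time = c(100, 900, 100, 900), event = c(1, 0, 1, 0))
  roc2 <- survival_roc(scores_tbl(c(2, 2, 1, 1)), clin2, horizon = 365)
  expect_warning(optimal_cutoff(roc2), "Youden")
})

test_that("stratification is strict at the cutoff and rejects empty groups", {
  sc <- scores_tbl(c(0.8, 1.0, 2.0))
  strat <- suppressMessages(stratify(sc, 1.395))
  expect_equal(as.character(strat$risk), c("low", "low", "high"))
  strat2 <- suppressMessages(stratify(scores_tbl(c(1.395, 2)), 1.395))
  expect_equal(as.character(strat2$risk), c("low", "high")) # boundary -> low
  expect_error(stratify(scores_tbl(c(2, 3)), 1.395), "empty")
  expect_error(stratify(sc, -1), "positive")
})

test_that("Kaplan-Meier matches the hand product-limit on the classic fixture", {
  clin <- km_classic()
  km <- kaplan_meier(clin)
  orc <- oracle_km(clin$os_time, clin$os_event)
  got <- km[km$n_event > 0, c("time", "survival")]
  expect_equal(as.data.frame(got), as.data.frame(orc), tolerance = 1e-12)
  # spelled out: 4/7, then *3/4, then *1/2
  expect_equal(orc$survival, c(4 / 7, 4 / 7 * 3 / 4, 4 / 7 * 3 / 4 * 1 / 2))

  all_cens <- make_clinical(time = c(5, 10, 15), event = c(0, 0, 0))
  expect_true(all(kaplan_meier(all_cens)$survival == 1))

  no_cens <- make_clinical(time = 1:4, event = rep(1, 4))
  expect_equal(kaplan_meier(no_cens)$survival, c(0.75, 0.5, 0.25, 0))
})

test_that("log-rank terms match the hypergeometric oracle; label swap is symmetric", {
  clin <- make_clinical(time = c(3, 3, 5, 7, 9, 9, 11, 13, 15, 17),
                        event = c(1, 1, 0, 1, 1, 1, 0, 1, 0, 1))
  grp <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0)
  strat <- tibble::tibble(sample_id = clin$sample_id,
                          score = ifelse(grp == 1, 2, 0.5), cutoff = 1,
                          risk = factor(ifelse(grp == 1, "high", "low"),
                                        levels = c("low", "high")))
  lr <- logrank_test(strat, clin)
  orc <- oracle_logrank(clin$os_time, clin$os_event, grp)
  expect_equal(lr$chi2, orc$chi2, tolerance = 1e-8)
  expect_equal(lr$p, pchisq(orc$chi2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # swapping labels leaves the statistic unchanged
  strat_sw <- strat
  strat_sw$risk <- factor(ifelse(grp == 1, "low", "high"), levels = c("low", "high"))
  expect_equal(logrank_test(strat_sw, clin)$chi2, lr$chi2, tolerance = 1e-12)
  # time rescaling leaves it unchanged too
  clin_scaled <- clin; clin_scaled$os_time <- clin$os_time * 3.7
  expect_equal(logrank_test(strat, clin_scaled)$chi2, lr$chi2, tolerance = 1e-12)
})

test_that("identical groups give a zero log-rank statistic", {
  base_t <- c(3, 5, 8, 13); base_e <- c(1, 1, 0, 1)
  clin <- make_clinical(time = rep(base_t, 2), event = rep(base_e, 2))
  strat <- tibble::tibble(sample_id = clin$sample_id, score = rep(c(2, 0.5), each = 4),
                          cutoff = 1,
                          risk = factor(rep(c("high", "low"), each = 4),
                                        levels = c("low", "high")))
  expect_equal(logrank_test(strat, clin)$chi2, 0, tolerance = 1e-12)
})

test_that("a single-term joint Cox model reproduces the univariate fit", {
  clin <- binary_cox_fixture(n = 30, beta = 0.8, seed = 9)
  sc <- scores_tbl(exp(clin$x), ids = clin$sample_id)
  multi <- multivariate_cox(clin, sc, covariates = character(0))
  x <- matrix(as.numeric(sc$score > 1), 1, 30,
              dimnames = list("A|B", clin$sample_id))
  # same binary covariate on the indicator scale is not identical to the score
  # scale, so compare against coxph on the score itself
  ref <- survival::coxph(survival::Surv(clin$os_time, clin$os_event) ~ sc$score,
                         ties = "efron")
  expect_equal(multi$beta, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(multi$hr, exp(unname(coef(ref))), tolerance = 1e-8)
})

test_that("duplicated covariates raise a collinearity error", {
  clin <- binary_cox_fixture(n = 30, beta = 0.8, seed = 10)
  clin$age <- rnorm(30, 60, 10)
  clin$age2 <- clin$age
  expect_error(multivariate_cox(clin, covariates = c("age", "age2")), "[Cc]ollinear")
})

test_that("the joint model recovers a planted score effect alongside noise covariates", {
  covered <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(900 + s)
    n <- 600
    lp <- rbinom(n, 1, 0.5)
    noise <- rnorm(n)
    time <- rexp(n, rate = 1e-3 * exp(0.5 * lp))
    cens <- rexp(n, rate = 5e-4)
    clin <- make_clinical(time = pmin(time, cens),
                          event = as.integer(time <= cens))
    clin$noise <- noise
    sc <- scores_tbl(lp, ids = clin$sample_id)
    fit <- multivariate_cox(clin, sc, covariates = "noise")
    row <- fit[fit$term == "risk_score", ]
    covered <- covered + (row$ci_low <= exp(0.5) && exp(0.5) <= row$ci_high)
  }
  expect_gte(covered / n_seeds, 0.9)
})

test_that("feature AUC comparison ranks, ties the identity feature, and flips signs", {
  set.seed(73)
  n <- 120
  risk <- exp(rnorm(n))
  time <- rexp(n, rate = 2e-3 * risk)
  clin <- make_clinical(time = pmax(time, 1), event = rep(1, n))
  clin$age <- rnorm(n, 60, 10)
  sc <- scores_tbl(risk, ids = clin$sample_id)
  clin$identity <- risk
  tab <- compare_roc_features(clin, sc, features = c("age", "identity"),
                              horizon = 365)
  expect_equal(tab$auc[tab$feature == "identity"],
               tab$auc[tab$feature == "risk_score"], tolerance = 1e-12)
  clin$neg <- -clin$age
  tab2 <- compare_roc_features(clin, sc, features = c("age", "neg"), horizon = 365)
  expect_equal(tab2$auc[tab2$feature == "neg"],
               1 - tab2$auc[tab2$feature == "age"], tolerance = 1e-12)
})

test_that("ROC preconditions are enforced", {
  clin <- make_clinical(time = c(500, 600, 700), event = c(1, 1, 0))
  sc <- scores_tbl(c(1, 2, 3))
  expect_error(survival_roc(sc, clin, horizon = 365), "no events by the horizon")
  expect_error(survival_roc(sc, clin, horizon = 5000), "within the observed follow-up")
  clin2 <- make_clinical(time = c(100, 200, 300), event = c(1, 1, 1))
  expect_error(survival_roc(sc, clin2, horizon = 300), "event-free beyond")
})
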