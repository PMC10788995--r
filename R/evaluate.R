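#' Time-dependent ROC curve under right censoring
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' samples with an observed event by the horizon, controls are samples
#' still event-free beyond it. Censoring is handled by inverse-probability-
#' of-censoring weights (IPCW) from the Kaplan-Meier estimate of the
#' censoring distribution: a case observed at time `t` gets weight
#' `1 / G(t-)` and every control gets weight `1 / G(horizon)`, where `G` is
#' the censoring survival function. Without censoring all weights are equal
#' and the estimator reduces to the plain empirical ROC of the
#' event-by-horizon indicator. Sensitivity and specificity are evaluated at
#' every observed score threshold (`score > c` calls a sample high-risk) and
#' the AUC is the trapezoidal area over the curve.
#'
#' @param scores Tibble `sample_id`, `score` (higher = worse prognosis).
#' @param clinical Clinical tibble with `sample_id`, `os_time`, `os_event`.
#' @param horizon Evaluation time in days (default 365, i.e. 1-year
#'   survival).
#' @return A `survival_roc` object: `curve` (tibble `threshold`, `sens`,
#'   `spec`, descending thresholds with `Inf`/`-Inf` endpoints), `auc`,
#'   `horizon`, `n_cases`, `n_controls`.
#' @export
survival_roc <- function(scores, clinical, horizon = 365) {
  stop_if_not_clinical(clinical)
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` needs columns sample_id and score.")
  }
  d <- inner_join(scores, clinical[, c("sample_id", "os_time", "os_event")],
                  by = "sample_id")
  if (nrow(d) == 0) abort("no samples shared between scores and clinical.")
  if (horizon <= 0 || horizon > max(d$os_time)) {
    abort("`horizon` must lie within the observed follow-up.")
  }
  is_case <- d$os_time <= horizon & d$os_event == 1
  is_control <- d$os_time > horizon
  if (sum(is_case) == 0) abort("no events by the horizon.")
  if (sum(is_control) == 0) abort("no samples event-free beyond the horizon.")

  # KM of the censoring distribution (censoring is the 'event' here)
  gfit <- survival::survfit(survival::Surv(d$os_time, 1 - d$os_event) ~ 1)
  g_at <- function(t) { # left-continuous survival G(t-)
    vapply(t, function(tt) {
      idx <- gfit$time < tt
      if (!any(idx)) 1 else min(gfit$surv[idx])
    }, numeric(1))
  }
  w <- numeric(nrow(d))
  w[is_case] <- 1 / g_at(d$os_time[is_case])
  w[is_control] <- 1 / g_at(horizon + .Machine$double.eps * horizon)[1]
  if (any(!is.finite(w[is_case | is_control]))) {
    abort("censoring weights degenerate (censoring survival reaches 0 before the horizon).")
  }

  thr <- c(Inf, sort(unique(d$score), decreasing = TRUE), -Inf)
  case_w <- sum(w[is_case]); ctrl_w <- sum(w[is_control])
  sens <- vapply(thr, function(cc) sum(w[is_case & d$score > cc]) / case_w, numeric(1))
  spec <- vapply(thr, function(cc) sum(w[is_control & d$score <= cc]) / ctrl_w, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)

  structure(list(curve = tibble(threshold = thr, sens = sens, spec = spec),
                 auc = auc, horizon = horizon,
                 n_cases = sum(is_case), n_controls = sum(is_control)),
            class = "survival_roc")
}

#' @export
print.survival_roc <- function(x, ...) {
  cat(sprintf("<survival_roc> horizon %g days, AUC %.3f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Optimal risk-score cutoff from a time-dependent ROC curve
#'
#' Returns the finite score threshold maximising Youden's
#' `J = sens + spec - 1`; ties are broken toward the larger threshold,
#' which assigns fewer samples to the high-risk group. When no threshold
#' achieves `J > 0` (an uninformative score) a warning is raised and the
#' maximising threshold is returned regardless.
#'
#' @param roc A `survival_roc` object.
#' @return A single numeric cutoff.
#' @export
optimal_cutoff <- function(roc) {
  if (!inherits(roc, "survival_roc")) abort("`roc` must be a survival_roc.")
  cv <- roc$curve[is.finite(roc$curve$threshold), ]
  if (nrow(cv) == 0) abort("degenerate ROC curve: no finite thresholds.")
  j <- cv$sens + cv$spec - 1
  if (max(j) <= 0) warn("no threshold attains positive Youden J; score looks uninformative.")
  best <- which(j == max(j))
  max(cv$threshold[best])
}

#' Stratify samples into high- and low-risk groups at a score cutoff
#'
#' `risk = "high"` iff `score > cutoff` (strict: a sample scoring exactly
#' the cutoff is low-risk). Errors if either group would be empty.
#'
#' @param scores Tibble `sample_id`, `score`.
#' @param cutoff Positive score threshold (e.g. from [optimal_cutoff()], or
#'   the published 1.395).
#' @return Tibble `sample_id`, `score`, `cutoff`, `risk` (factor low/high).
#' @export
stratify <- function(scores, cutoff) {
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` needs columns sample_id and score.")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("`cutoff` must be a single positive number.")
  }
  risk <- factor(ifelse(scores$score > cutoff, "high", "low"),
                 levels = c("low", "high"))
  if (any(table(risk) == 0)) {
    abort(sprintf("stratification at cutoff %g leaves the %s-risk group empty.",
                  cutoff, names(which(table(risk) == 0))[1]))
  }
  inform(sprintf("stratify: %d high-risk, %d low-risk at cutoff %g.",
                 sum(risk == "high"), sum(risk == "low"), cutoff))
  tibble(sample_id = scores$sample_id, score = scores$score,
         cutoff = cutoff, risk = risk)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit()`. Censored times reduce the risk set without
#' producing a step; survival starts at 1 and is non-increasing.
#'
#' @param clinical Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @param strat Optional stratification tibble from [stratify()]; when
#'   given, one curve per risk group.
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival` (and
#'   `group` when stratified), one row per distinct observed time.
#' @export
kaplan_meier <- function(clinical, strat = NULL) {
  stop_if_not_clinical(clinical)
  if (nrow(clinical) == 0) abort("empty clinical table.")
  if (is.null(strat)) {
    fit <- survival::survfit(survival::Surv(os_time, os_event) ~ 1,
                             data = clinical)
    return(tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv))
  }
  d <- inner_join(clinical, strat[, c("sample_id", "risk")], by = "sample_id")
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ risk, data = d)
  grp <- rep(sub("^risk=", "", names(fit$strata)), fit$strata)
  tibble(group = grp, time = fit$time, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test of a risk stratification
#'
#' Standard log-rank test (`survival::survdiff()`): at each distinct event
#' time the observed events in one group are compared with the
#' hypergeometric expectation given the risk sets; the squared sum of
#' differences over the summed variance is chi-square with 1 df.
#'
#' @param strat Stratification tibble from [stratify()].
#' @param clinical Clinical tibble covering the stratified samples.
#' @return Tibble `chi2`, `df`, `p`, `n_high`, `n_low`.
#' @export
logrank_test <- function(strat, clinical) {
  stop_if_not_clinical(clinical)
  d <- inner_join(clinical, strat[, c("sample_id", "risk")], by = "sample_id")
  if (any(table(d$risk) == 0)) abort("both risk groups must be non-empty.")
  sd_fit <- survival::survdiff(survival::Surv(os_time, os_event) ~ risk, data = d)
  tibble(chi2 = sd_fit$chisq, df = 1, p = pchisq(sd_fit$chisq, 1, lower.tail = FALSE),
         n_high = sum(d$risk == "high"), n_low = sum(d$risk == "low"))
}

# Ordinal/numeric encoding of clinical covariates: grade G1-G4 -> 1-4,
# stage I-IV -> 1-4, sex male = 1 / female = 0.
encode_clinical <- function(clinical, terms) {
  enc <- tibble(sample_id = clinical$sample_id)
  for (term in terms) {
    v <- clinical[[term]]
    if (is.null(v)) abort(sprintf("clinical table has no column '%s'.", term))
    enc[[term]] <- switch(term,
      sex = as.numeric(v == "male"),
      grade = as.numeric(factor(v, levels = paste0("G", 1:4))),
      stage = as.numeric(factor(v, levels = c("I", "II", "III", "IV"))),
      { if (!is.numeric(v)) abort(sprintf("cannot encode non-numeric term '%s'.", term)); v })
  }
  enc
}

#' Joint Cox model of the risk score and clinical covariates
#'
#' Fits one Cox proportional-hazards model (Efron ties) containing the risk
#' score and/or ordinal-encoded clinical covariates, to assess whether the
#' score is prognostic independently of clinical factors. Rows with missing
#' values in any term are dropped listwise (reported via a message).
#' A model with a single term reduces exactly to the univariate fit.
#'
#' @param clinical Clinical tibble.
#' @param scores Optional tibble `sample_id`, `score`; when given, the term
#'   `risk_score` enters the model.
#' @param covariates Character vector of clinical columns to include
#'   (default `c("age", "sex", "grade", "stage")`; `sex`, `grade`, `stage`
#'   are ordinal-encoded).
#' @return Tibble with one row per term: `term`, `beta`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_events`.
#' @export
multivariate_cox <- function(clinical, scores = NULL,
                             covariates = c("age", "sex", "grade", "stage")) {
  stop_if_not_clinical(clinical)
  d <- encode_clinical(clinical, covariates)
  if (!is.null(scores)) {
    d <- inner_join(tibble(sample_id = scores$sample_id, risk_score = scores$score),
                    d, by = "sample_id")
    d <- d[, c("sample_id", "risk_score", covariates)]
  }
  terms <- setdiff(names(d), "sample_id")
  if (length(terms) == 0) abort("no model terms supplied.")
  d <- inner_join(d, clinical[, c("sample_id", "os_time", "os_event")], by = "sample_id")
  ok <- complete.cases(d[, terms])
  if (sum(!ok) > 0) inform(sprintf("multivariate_cox: dropped %d sample(s) with missing covariates.", sum(!ok)))
  d <- d[ok, ]
  mm <- as.matrix(d[, terms, drop = FALSE])
  if (qr(cbind(1, mm))$rank < ncol(mm) + 1) {
    dup <- terms[duplicated(lapply(terms, function(t) unname(mm[, t])))]
    abort(sprintf("collinear model terms%s.",
                  if (length(dup) > 0) paste0(": ", paste(dup, collapse = ", ")) else ""))
  }
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (any(is.na(coef(fit)))) abort("Cox fit failed (NA coefficients).")
  b <- coef(fit)
  se <- sqrt(diag(fit$var))
  tibble(term = terms, beta = unname(b), hr = exp(unname(b)),
         ci_low = exp(unname(b) - qnorm(0.975) * se),
         ci_high = exp(unname(b) + qnorm(0.975) * se),
         p = 2 * pnorm(-abs(unname(b) / se)),
         n = nrow(d), n_events = sum(d$os_event))
}

#' Compare time-dependent AUCs of the risk score and clinical features
#'
#' Computes the [survival_roc()] AUC at a shared horizon for the risk score
#' and each ordinal-encoded clinical feature, sorted by decreasing AUC — the
#' comparison used to argue the score's prognostic value exceeds that of
#' individual clinical characteristics.
#'
#' @param clinical Clinical tibble.
#' @param scores Tibble `sample_id`, `score`.
#' @param features Clinical columns to compare against
#'   (default `c("age", "sex", "grade", "stage")`).
#' @param horizon Evaluation time in days.
#' @return Tibble `feature`, `auc`, sorted descending.
#' @export
compare_roc_features <- function(clinical, scores,
                                 features = c("age", "sex", "grade", "stage"),
                                 horizon = 365) {
  stop_if_not_clinical(clinical)
  enc <- encode_clinical(clinical, features)
  res <- purrr::map_dfr(c("risk_score", features), function(f) {
    vals <- if (f == "risk_score") {
      scores
    } else {
      ok <- !is.na(enc[[f]])
      tibble(sample_id = enc$sample_id[ok], score = enc[[f]][ok])
    }
    roc <- survival_roc(vals, clinical, horizon = horizon)
    tibble(feature = f, auc = roc$auc)
  })
  arrange(res, desc(.data$auc))
}
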