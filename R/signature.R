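#' Univariate Cox screen of pair indicators against overall survival
#'
#' Fits one single-covariate Cox proportional-hazards model per pair
#' indicator (Newton-Raphson on the partial likelihood, Efron handling of
#' tied event times, via `survival::coxph()`), and flags pairs with Wald
#' `p < p_max` as prognostic candidates.
#'
#' @param pm Pair tibble ([build_pair_matrix()], ideally after
#'   [filter_valid_pairs()] so no indicator is constant).
#' @param clinical Clinical tibble with `sample_id`, `os_time`, `os_event`
#'   covering the pair matrix's samples.
#' @param p_max Wald p-value threshold for the `significant` flag.
#' @return Tibble with one row per pair: `term`, `beta`, `hr`, `ci_low`,
#'   `ci_high` (95% Wald bounds on the HR), `p`, `n`, `n_events`,
#'   `converged`, `significant`.
#' @export
univariate_cox_screen <- function(pm, clinical, p_max = 0.05) {
  stop_if_not_clinical(clinical)
  x <- pair_indicator_matrix(pm)
  smp <- colnames(x)
  if (!all(smp %in% clinical$sample_id)) {
    abort("every pair-matrix sample needs a clinical row.")
  }
  cl <- clinical[match(smp, clinical$sample_id), ]
  if (sum(cl$os_event) == 0) abort("no events in the cohort; Cox screening impossible.")
  y <- survival::Surv(cl$os_time, cl$os_event)

  fits <- purrr::map(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    warned <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(y ~ xi, ties = "efron",
                        control = survival::coxph.control(iter.max = 50)),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    conv <- !is.null(fit) && !warned && fit$iter < 50 &&
      all(is.finite(coef(fit))) && all(is.finite(sqrt(diag(fit$var))))
    if (is.null(fit)) {
      return(tibble(term = rownames(x)[i], beta = NA_real_, hr = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    n = length(xi), n_events = sum(cl$os_event),
                    converged = FALSE))
    }
    b <- unname(coef(fit))
    se <- sqrt(fit$var[1, 1])
    tibble(term = rownames(x)[i], beta = b, hr = exp(b),
           ci_low = exp(b - qnorm(0.975) * se),
           ci_high = exp(b + qnorm(0.975) * se),
           p = 2 * pnorm(-abs(b / se)),
           n = length(xi), n_events = sum(cl$os_event),
           converged = conv)
  })
  out <- bind_rows(fits)
  bad <- !out$converged
  if (any(bad)) {
    warn(sprintf("%d pair fit(s) did not converge and are excluded from the significant set: %s",
                 sum(bad), paste(out$term[bad], collapse = ", ")))
  }
  out$significant <- out$converged & !is.na(out$p) & out$p < p_max
  out
}

#' Select a pair signature by cross-validated LASSO-penalised Cox regression
#'
#' Fits the L1-penalised Cox coefficient path over the candidate pairs with
#' `glmnet`, chooses the penalty at the minimum of the `n_folds`-fold
#' cross-validated partial-likelihood deviance (folds stratified by event
#' status and reproducible from `seed`), and returns the pairs with nonzero
#' coefficients at that penalty. Coefficients are on the 0/1 indicator
#' scale (pair indicators are not standardised beyond glmnet's internal
#' standardisation, which is undone in the returned coefficients).
#'
#' @param pm Pair tibble restricted to the screened candidate pairs.
#' @param clinical Clinical tibble covering the pair matrix's samples.
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation. `lambda = 0`
#'   gives the unpenalised fit (with a single candidate pair this reduces to
#'   the plain univariate Cox estimate).
#' @return A `pair_signature` object: ordered pairs, nonzero coefficients,
#'   the penalty used, `provenance = "fitted"`.
#' @export
fit_lasso_cox <- function(pm, clinical, n_folds = 10, seed = 1L, lambda = NULL) {
  stop_if_not_clinical(clinical)
  x <- pair_indicator_matrix(pm)
  smp <- colnames(x)
  if (!all(smp %in% clinical$sample_id)) {
    abort("every pair-matrix sample needs a clinical row.")
  }
  cl <- clinical[match(smp, clinical$sample_id), ]
  y <- survival::Surv(cl$os_time, cl$os_event)
  n_events <- sum(cl$os_event)

  if (nrow(x) == 1) {
    if (!is.null(lambda) && lambda == 0) {
      xi <- x[1, ]
      fit <- survival::coxph(y ~ xi, ties = "efron")
      return(new_pair_signature(pm$pair_id, pm$lnc_a, pm$lnc_b,
                                unname(coef(fit)), lambda = 0,
                                provenance = "fitted"))
    }
    abort("penalised fitting needs at least 2 candidate pairs.")
  }
  xt <- t(x)

  if (is.null(lambda)) {
    if (n_events < n_folds) {
      abort(sprintf("only %d events for %d folds; reduce `n_folds`.", n_events, n_folds))
    }
    set.seed(seed)
    foldid <- integer(ncol(x))
    for (ev in c(0, 1)) { # stratify folds by event status
      idx <- which(cl$os_event == ev)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    cvfit <- glmnet::cv.glmnet(xt, y, family = "cox", foldid = foldid,
                               type.measure = "deviance", thresh = 1e-10)
    lambda <- cvfit$lambda.min
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(xt, y, family = "cox", thresh = 1e-10,
                          lambda = if (lambda > 0) NULL else c(0.1, 0.01, 0))
    beta <- as.numeric(coef(fit, s = lambda, exact = TRUE, x = xt, y = y))
  }
  nz <- which(beta != 0)
  if (length(nz) == 0) {
    abort("empty signature: all coefficients zero at the chosen penalty; use a weaker penalty.")
  }
  new_pair_signature(pm$pair_id[nz], pm$lnc_a[nz], pm$lnc_b[nz], beta[nz],
                     lambda = lambda, provenance = "fitted")
}

new_pair_signature <- function(pair_id, lnc_a, lnc_b, beta, lambda, provenance) {
  stopifnot(length(beta) == length(pair_id), !anyDuplicated(pair_id),
            all(beta != 0))
  structure(list(pairs = tibble(pair_id = pair_id, lnc_a = lnc_a,
                                lnc_b = lnc_b, beta = beta),
                 lambda = lambda, provenance = provenance),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> %d pair(s), provenance: %s, lambda: %s\n",
              nrow(x$pairs), x$provenance,
              if (is.null(x$lambda)) "NA" else format(x$lambda, digits = 4)))
  print(x$pairs, ...)
  invisible(x)
}

#' The published five-pair hepatocellular-carcinoma signature
#'
#' The reference vascular-invasion-related lncRNA-pair signature for
#' hepatocellular carcinoma, with its five published coefficients on the
#' 0/1 pair-indicator scale. The associated published risk-score cutoff is
#' 1.395.
#'
#' @return A `pair_signature` with `provenance = "published"`.
#' @export
published_signature <- function() {
  pairs <- tibble(
    lnc_a = c("AC099850.4", "AC048341.2", "AC048341.2", "AC048341.2", "MIR4435-2HG"),
    lnc_b = c("MIR4435-2HG", "LENG8-AS1", "GIHCG", "LINC01436", "AC110285.2"),
    beta  = c(0.3776, -0.3176, -0.3402, -0.3572, 0.4547)
  )
  new_pair_signature(paste(pairs$lnc_a, pairs$lnc_b, sep = "|"),
                     pairs$lnc_a, pairs$lnc_b, pairs$beta,
                     lambda = NULL, provenance = "published")
}

#' Exponentiated risk score of a pair signature
#'
#' `score_s = exp(sum_i beta_i x_{i,s})` over the signature's pair
#' indicators. Scores are strictly positive; a sample with all indicators 0
#' scores exactly 1. Since the indicators are rank-based, the score inherits
#' their invariance to per-sample monotone transforms of expression.
#'
#' @param pm Pair tibble containing (at least) every signature pair.
#' @param model A `pair_signature`.
#' @return Tibble `sample_id`, `score`.
#' @export
compute_risk_score <- function(pm, model) {
  if (!inherits(model, "pair_signature")) abort("`model` must be a pair_signature.")
  missing <- setdiff(model$pairs$pair_id, pm$pair_id)
  if (length(missing) > 0) {
    abort(sprintf("pair matrix lacks signature pair(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- pair_indicator_matrix(pm[match(model$pairs$pair_id, pm$pair_id), ])
  score <- exp(as.numeric(t(x) %*% model$pairs$beta))
  tibble(sample_id = colnames(x), score = score)
}
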