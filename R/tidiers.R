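#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pair signature into one row per pair
#'
#' @param x A `pair_signature`.
#' @param ... Unused.
#' @return Tibble `pair_id`, `lnc_a`, `lnc_b`, `estimate` (Cox coefficient)
#'   and `hr` (`exp(estimate)`).
#' @method tidy pair_signature
#' @export
tidy.pair_signature <- function(x, ...) {
  mutate(x$pairs, estimate = .data$beta, hr = exp(.data$beta),
         .keep = "unused")
}

#' One-row summary of a pair signature
#'
#' @param x A `pair_signature`.
#' @param ... Unused.
#' @return Tibble `n_pairs`, `lambda`, `provenance`, `beta_sum`.
#' @method glance pair_signature
#' @export
glance.pair_signature <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         lambda = x$lambda %||% NA_real_,
         provenance = x$provenance,
         beta_sum = sum(x$pairs$beta))
}

#' Tidy a time-dependent ROC curve
#'
#' @param x A `survival_roc`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `sens`, `spec`, `fpr`).
#' @method tidy survival_roc
#' @export
tidy.survival_roc <- function(x, ...) {
  mutate(x$curve, fpr = 1 - .data$spec)
}

#' One-row summary of a time-dependent ROC
#'
#' @param x A `survival_roc`.
#' @param ... Unused.
#' @return Tibble `auc`, `horizon`, `n_cases`, `n_controls`.
#' @method glance survival_roc
#' @export
glance.survival_roc <- function(x, ...) {
  tibble(auc = x$auc, horizon = x$horizon,
         n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Tidy a subtype comparison into its pairwise tests
#'
#' @param x A `subtype_comparison`.
#' @param ... Unused.
#' @return The pairwise tibble (`level_a`, `level_b`, `p`, `p_adj`).
#' @method tidy subtype_comparison
#' @export
tidy.subtype_comparison <- function(x, ...) x$pairwise

#' One-row summary of a subtype comparison
#'
#' @param x A `subtype_comparison`.
#' @param ... Unused.
#' @return Tibble `kruskal_h`, `df`, `p`, `n_levels`, `dropped`.
#' @method glance subtype_comparison
#' @export
glance.subtype_comparison <- function(x, ...) {
  tibble(kruskal_h = x$kruskal_h, df = x$df, p = x$p,
         n_levels = length(x$retained),
         dropped = paste(x$dropped, collapse = ","))
}
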