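#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_abline geom_point
#'   geom_vline labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a time-dependent ROC curve
#'
#' @param object A `survival_roc`.
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity with the chance
#'   diagonal, AUC and horizon in the title.
#' @method autoplot survival_roc
#' @export
autoplot.survival_roc <- function(object, ...) {
  cv <- tidy(object)
  ggplot(cv, aes(x = .data$fpr, y = .data$sens)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#b2182b") +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("Time-dependent ROC at %g days (AUC = %.3f)",
                         object$horizon, object$auc)) +
    theme_minimal()
}

#' Kaplan-Meier plot of the risk groups
#'
#' @param clinical Clinical tibble.
#' @param strat Optional stratification tibble from [stratify()].
#' @return A ggplot of the product-limit curves (one per risk group when
#'   stratified).
#' @export
plot_km <- function(clinical, strat = NULL) {
  km <- kaplan_meier(clinical, strat)
  if ("group" %in% names(km)) {
    km_plot <- ggplot(km, aes(x = .data$time, y = .data$survival,
                              colour = .data$group))
  } else {
    km_plot <- ggplot(km, aes(x = .data$time, y = .data$survival))
  }
  km_plot +
    geom_step() +
    labs(x = "Time (days)", y = "Overall survival", colour = "Risk") +
    theme_minimal()
}

#' Risk-score distribution with the stratification cutoff
#'
#' @param strat Stratification tibble from [stratify()].
#' @return A ggplot of ranked scores coloured by risk group, with the
#'   cutoff marked.
#' @export
plot_risk_scores <- function(strat) {
  d <- arrange(strat, .data$score)
  d$rank <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$rank, y = .data$score, colour = .data$risk)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = sum(d$risk == "low") + 0.5, linetype = "dashed") +
    labs(x = "Patients (ranked by score)", y = "Risk score", colour = "Risk") +
    theme_minimal()
}
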