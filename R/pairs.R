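#' Build the 0-or-1 pair-indicator matrix over a set of lncRNAs
#'
#' For every unordered pair of input genes, oriented `(a, b)` with `a`
#' preceding `b` in the input row order, the per-sample indicator is
#' `X_s = 1` if `expr(a, s) > expr(b, s)` and `0` otherwise (ties score 0,
#' or 1 with `ties_high = TRUE`). Because only the within-sample ordering of
#' the two genes enters, the matrix is invariant to any per-sample strictly
#' increasing transform of the expression values — no absolute expression
#' levels are required. `K` input genes yield `K(K-1)/2` candidate pairs.
#'
#' @param expr Expression tibble restricted to the `K >= 2` genes to pair
#'   (for the prognostic pipeline: the differentially expressed lncRNAs,
#'   tumour samples only).
#' @param ties_high Score ties as 1 instead of the default 0.
#' @return A pair tibble: `pair_id` (`"A|B"`), `lnc_a`, `lnc_b`, `frac_one`
#'   (mean indicator over samples), then one 0/1 integer column per sample.
#' @export
build_pair_matrix <- function(expr, ties_high = FALSE) {
  stop_if_not_expr(expr)
  m <- expr_matrix(expr)
  if (any(!is.finite(m))) abort("expression values must be finite.")
  k <- nrow(m)
  if (k < 2) abort("need at least 2 genes to form pairs.")
  idx <- combn(k, 2)
  cmp <- if (ties_high) `>=` else `>`
  x <- matrix(0L, ncol(idx), ncol(m))
  for (j in seq_len(ncol(idx))) {
    x[j, ] <- as.integer(cmp(m[idx[1, j], ], m[idx[2, j], ]))
  }
  colnames(x) <- colnames(m)
  a <- rownames(m)[idx[1, ]]
  b <- rownames(m)[idx[2, ]]
  bind_cols(tibble(pair_id = paste(a, b, sep = "|"),
                   lnc_a = a, lnc_b = b,
                   frac_one = rowMeans(x)),
            as_tibble(x))
}

#' Filter pairs whose indicator is informative across the cohort
#'
#' A pair indicator that is (nearly) constant carries no ranking
#' information. A pair is kept only when each indicator class occupies more
#' than `min_frac` of the samples, i.e. strictly
#' `min_frac < frac_one < 1 - min_frac`. With the default `min_frac = 0.2`
#' a pair survives only when both the 0s and the 1s exceed 20% of samples;
#' pairs exactly on the boundary are dropped (and reported via a message).
#'
#' @param pm Pair tibble from [build_pair_matrix()].
#' @param min_frac Minimum class fraction, in `(0, 0.5)`.
#' @return The surviving rows of `pm`, order preserved.
#' @export
filter_valid_pairs <- function(pm, min_frac = 0.2) {
  if (!is.data.frame(pm) || nrow(pm) == 0) abort("empty pair matrix.")
  if (!all(c("pair_id", "frac_one") %in% names(pm))) {
    abort("`pm` must come from build_pair_matrix().")
  }
  if (min_frac <= 0 || min_frac >= 0.5) abort("`min_frac` must be in (0, 0.5).")
  on_boundary <- pm$frac_one == min_frac | pm$frac_one == 1 - min_frac
  if (any(on_boundary)) {
    inform(sprintf("filter_valid_pairs: %d pair(s) exactly on the %.0f%% boundary dropped: %s",
                   sum(on_boundary), 100 * min_frac,
                   paste(pm$pair_id[on_boundary], collapse = ", ")))
  }
  keep <- pm$frac_one > min_frac & pm$frac_one < 1 - min_frac
  pm[keep, , drop = FALSE]
}
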