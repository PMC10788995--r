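# Fixture builders shared across test files. Everything is generated in code;
# no binary or large data ships with the package.

make_expr <- function(mat, biotype = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  if (is.null(biotype)) biotype <- rep("lncRNA", nrow(mat))
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(mat), biotype = biotype),
    tibble::as_tibble(mat)
  )
}

make_clinical <- function(time, event, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(time))
  tibble::tibble(sample_id = ids, os_time = time, os_event = event, ...)
}

# Classic right-censored fixture: times 6, 6, 6, 7, 10+, 13, 16+
km_classic <- function() {
  make_clinical(time = c(6, 6, 6, 7, 10, 13, 16),
                event = c(1, 1, 1, 1, 0, 1, 0))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Three-gene expression TSV + matching GTF fixture on disk.
tiny_expression_files <- function(env = parent.frame()) {
  expr <- write_tsv_fixture(c(
    "gene_id\tS1\tS2\tS3",
    "ENSG00000100001.5\t1\t2\t3",
    "ENSG00000100002\t4\t0\t6",
    "ENSG00000100003\t7\t8\t9"
  ))
  gtf <- write_tsv_fixture(c(
    "#!genome-build test",
    paste("1", "ens", "gene", "1", "100", ".", "+", ".",
          'gene_id "ENSG00000100002"; gene_biotype "lncRNA";', sep = "\t"),
    paste("1", "ens", "gene", "200", "300", ".", "+", ".",
          'gene_id "ENSG00000100001"; gene_biotype "protein_coding";', sep = "\t"),
    paste("1", "ens", "transcript", "1", "100", ".", "+", ".",
          'gene_id "ENSG00000100002"; gene_biotype "lncRNA";', sep = "\t")
  ), ext = ".gtf")
  list(expr = expr, gtf = gtf)
}

# Small survival cohort with a prognostic binary indicator, no tied times.
binary_cox_fixture <- function(n = 20, beta = 1, seed = 42) {
  set.seed(seed)
  x <- rep(c(0, 1), length.out = n)
  time <- round(rexp(n, rate = 0.01 * exp(beta * x)), 4)
  while (anyDuplicated(time)) time <- time + runif(n, 0, 1e-3)
  make_clinical(time = time, event = rep(1, n), x = x)
}

# Brute-force oracles -------------------------------------------------------

# Pearson r from the explicit covariance formula plus the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Exhaustive double-loop reconstruction of the pair-indicator matrix.
oracle_pair_matrix <- function(mat) {
  k <- nrow(mat)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rows[[length(rows) + 1]] <- as.integer(mat[i, ] > mat[j, ])
    }
  }
  do.call(rbind, rows)
}

# Step-up Benjamini-Hochberg by direct enumeration of the rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Log-rank O/E/V terms by per-time hypergeometric enumeration.
oracle_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  ev_times <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o - e)^2 / v
  list(o = o, e = e, v = v, chi2 = chi2)
}

# Hand product-limit Kaplan-Meier at the distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  tibble::tibble(time = ts, survival = surv)
}

# Cox partial log-likelihood for one binary covariate, Breslow-free (no tied
# event times assumed), maximised over a refined grid.
oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5) {
  loglik <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(lo, hi, by = 0.01)
  b <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  grid <- seq(b - 0.01, b + 0.01, by = 1e-4)
  grid[which.max(vapply(grid, loglik, numeric(1)))]
}

# Pairwise-concordance AUC of a binary outcome (ties count half).
oracle_auc <- function(score, is_case) {
  cs <- score[is_case]; ct <- score[!is_case]
  pairs <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Exact two-sided rank-sum p by enumerating all label assignments.
oracle_ranksum_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}
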