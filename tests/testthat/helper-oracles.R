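# Independent oracles and fixture builders. Each oracle is written as a
# plain double-loop or matrix-algebra re-derivation, deliberately not
# sharing code with the package implementation it checks.

# Zero-intercept weighted least squares by explicit matrix algebra.
wls_origin_oracle <- function(bx, by, sy) {
  w <- diag(1 / sy^2)
  xtwx <- t(bx) %*% w %*% bx
  beta <- solve(xtwx, t(bx) %*% w %*% by)
  list(beta = as.numeric(beta), se = sqrt(1 / as.numeric(xtwx)))
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Hand-computed ssGSEA ECDF walk for one sample (explicit loop).
ssgsea_oracle <- function(expr_vec, gene_ids, set, alpha) {
  ord <- order(-expr_vec, gene_ids)
  ids <- gene_ids[ord]
  n <- length(ids)
  w <- (n:1)^alpha
  inset <- ids %in% set
  m <- sum(inset)
  denom <- sum(w[inset])
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + w[i] / denom
    else p_out <- p_out + 1 / (n - m)
    score <- score + (p_in - p_out)
  }
  score
}

# Plug-in MI recomputed with explicit nested loops over the joint table.
mi_oracle <- function(x, y, bins) {
  n <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") * bins / n)
  by <- ceiling(rank(y, ties.method = "first") * bins / n)
  total <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(bx == i & by == j) / n
      if (pij > 0) {
        pi_ <- sum(bx == i) / n
        pj_ <- sum(by == j) / n
        total <- total + pij * log(pij / (pi_ * pj_))
      }
    }
  }
  total
}

# Random valid harmonized set for estimator checks.
random_harmonized <- function(k, seed) {
  set.seed(seed)
  harmonized_set(sprintf("rs%d", seq_len(k)),
                 beta_exposure = stats::rnorm(k, 0.15, 0.05),
                 se_exposure = stats::runif(k, 0.01, 0.05),
                 beta_outcome = stats::rnorm(k, 0.05, 0.03),
                 se_outcome = stats::runif(k, 0.01, 0.05))
}

# Tiny expression study with explicit values.
tiny_study <- function(n_genes = 10, n_samples = 4, seed = 1,
                       labels = NULL) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("G%d", seq_len(n_genes)),
                                 sprintf("S%d", seq_len(n_samples))))
  labels <- labels %||% rep(c("active", "inactive"),
                            length.out = n_samples)
  expression_study(vals, stats::setNames(labels, colnames(vals)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
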