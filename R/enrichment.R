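# Single-sample GSEA (ECDF-walk) scores, rank-based group comparison, and
# classical two-group GSEA with phenotype-label permutations.

# Per-sample ssGSEA walk over one ranked gene list.
# ord_genes: gene ids in descending expression order; w: positional weights
# (already raised to alpha); set: character vector of in-set genes.
.ssgsea_walk <- function(ord_genes, w, set) {
  ind <- ord_genes %in% set
  m <- sum(ind)
  n <- length(ord_genes)
  if (m == 0L || m == n) return(NA_real_)
  p_in <- cumsum(w * ind) / sum(w[ind])
  p_out <- cumsum(!ind) / (n - m)
  sum(p_in - p_out)
}

# Deterministic descending order of a sample: expression desc, gene id asc.
.rank_order <- function(e, gene_ids) {
  order(-e, gene_ids)
}

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression from largest to
#' smallest (ties broken by gene id for determinism) and the score is the
#' integrated difference between the weighted in-set empirical cumulative
#' distribution function and the uniform out-of-set ECDF. The in-set walk
#' weights each gene by its rank-normalized magnitude (`N` for the top gene
#' down to 1) raised to `alpha`; with `alpha = 0` the score depends on
#' ranks only and is invariant to monotone transforms of a sample.
#'
#' Sets that do not intersect the study's genes are skipped with a warning;
#' genes absent from the study never influence a score.
#'
#' @param study an [expression_study()].
#' @param sets a [gene_set_collection()].
#' @param alpha weighting exponent (>= 0), default 0.25.
#' @return matrix set x sample of scores, class `enrichment_scores`, with
#'   attribute `method = "ssgsea"`.
#' @export
ssgsea_score <- function(study, sets, alpha = 0.25) {
  stopifnot(inherits(study, "expression_study"),
            inherits(sets, "gene_set_collection"))
  if (alpha < 0) stop("alpha must be >= 0")
  genes <- rownames(study$values)
  usable <- list()
  for (nm in names(sets$sets)) {
    inter <- intersect(sets$sets[[nm]], genes)
    if (length(inter) == 0L) {
      warning("set '", nm, "' does not intersect study genes; skipped")
    } else usable[[nm]] <- inter
  }
  if (length(usable) == 0L) stop("no usable gene sets")
  n <- length(genes)
  w <- (n:1)^alpha
  out <- matrix(NA_real_, length(usable), ncol(study$values),
                dimnames = list(names(usable), colnames(study$values)))
  for (j in seq_len(ncol(study$values))) {
    ord <- .rank_order(study$values[, j], genes)
    ord_genes <- genes[ord]
    for (i in seq_along(usable))
      out[i, j] <- .ssgsea_walk(ord_genes, w, usable[[i]])
  }
  structure(out, class = c("enrichment_scores", "matrix", "array"),
            method = "ssgsea")
}

#' Risk and protective ssGSEA scores from a gene MR table
#'
#' Builds the risk (`label == "risk"`) and protective (`label ==
#' "protective"`) gene lists and scores each as a single ssGSEA set over
#' all samples. Labeled genes absent from the study are named in a warning
#' (or an error when an entire list is missing).
#'
#' @param study an [expression_study()].
#' @param gene_table a `gene_mr_table` from [qtl_mr_screen()].
#' @param alpha ssGSEA weighting exponent.
#' @return list with `risk` and `protective` score vectors (named by
#'   sample) and the underlying `enrichment_scores` matrix.
#' @export
risk_protective_scores <- function(study, gene_table, alpha = 0.25) {
  risk <- gene_table$gene_id[gene_table$label == "risk"]
  prot <- gene_table$gene_id[gene_table$label == "protective"]
  if (length(risk) == 0L && length(prot) == 0L)
    stop("gene table has neither risk nor protective genes")
  genes <- rownames(study$values)
  missing <- setdiff(c(risk, prot), genes)
  for (lst in list(risk = risk, protective = prot)) {
    if (length(lst) && length(intersect(lst, genes)) == 0L)
      stop("labeled gene(s) absent from the study: ",
           paste(setdiff(lst, genes), collapse = ", "))
  }
  if (length(missing))
    warning("labeled gene(s) absent from the study (ignored): ",
            paste(missing, collapse = ", "))
  sets <- list()
  if (length(risk)) sets$risk_score <- unique(risk)
  if (length(prot)) sets$protective_score <- unique(prot)
  scores <- ssgsea_score(study, gene_set_collection(sets), alpha = alpha)
  list(risk = if ("risk_score" %in% rownames(scores))
         scores["risk_score", ] else NULL,
       protective = if ("protective_score" %in% rownames(scores))
         scores["protective_score", ] else NULL,
       scores = scores)
}

#' Wilcoxon rank-sum comparison of scores between phenotype groups
#'
#' Two-sided Wilcoxon rank-sum per score row; the exact null distribution
#' is used when `min(n_a, n_b) <= 10` and there are no ties, the normal
#' approximation with continuity correction otherwise.
#'
#' @param scores an `enrichment_scores` matrix (sets x samples) or a named
#'   numeric vector of per-sample scores.
#' @param study the [expression_study()] carrying phenotype labels.
#' @param group_a,group_b phenotype labels to compare.
#' @return data.frame (set_name, median_a, median_b, wilcoxon_stat, pval).
#' @export
compare_groups <- function(scores, study, group_a = "active",
                           group_b = "inactive") {
  if (is.null(dim(scores)))
    scores <- matrix(scores, 1, dimnames = list("score", names(scores)))
  ph <- study$phenotype[colnames(scores)]
  ia <- which(ph == group_a); ib <- which(ph == group_b)
  if (length(ia) == 0L) stop("no samples in group '", group_a, "'")
  if (length(ib) == 0L) stop("no samples in group '", group_b, "'")
  rows <- lapply(rownames(scores), function(nm) {
    a <- scores[nm, ia]; b <- scores[nm, ib]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- min(length(a), length(b)) <= 10 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    pval <- wt$p.value
    if (!is.finite(pval)) pval <- 1  # complete ties degenerate the normal approx
    data.frame(set_name = nm, median_a = stats::median(a),
               median_b = stats::median(b),
               wilcoxon_stat = unname(wt$statistic),
               pval = min(1, pval), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Signal-to-noise ranking metric between two sample groups.
.signal_to_noise <- function(x_a, x_b) {
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  sa <- apply(x_a, 1, stats::sd); sb <- apply(x_b, 1, stats::sd)
  # conventional floors keep the denominator away from zero
  sa <- pmax(sa, 0.2 * abs(ma), 1e-8)
  sb <- pmax(sb, 0.2 * abs(mb), 1e-8)
  (ma - mb) / (sa + sb)
}

# Classical weighted Kolmogorov-Smirnov running-sum enrichment score.
# metric: named stat per gene; set: gene ids. Returns signed max deviation.
.gsea_es <- function(metric, set, p = 1) {
  ord <- order(-metric, names(metric))
  m_sorted <- metric[ord]
  ind <- names(m_sorted) %in% set
  nm <- sum(ind)
  n <- length(metric)
  if (nm == 0L || nm == n) return(NA_real_)
  wt <- abs(m_sorted)^p
  denom <- sum(wt[ind])
  if (denom == 0) wt[ind] <- 1 # degenerate: fall back to unweighted hits
  p_hit <- cumsum(wt * ind) / max(sum(wt[ind]), .Machine$double.eps)
  p_miss <- cumsum(!ind) / (n - nm)
  run <- p_hit - p_miss
  run[which.max(abs(run))]
}

#' Two-group GSEA with phenotype permutations
#'
#' Genes are ranked by the signal-to-noise statistic between the two
#' groups; each set's enrichment score is the signed maximum deviation of
#' the weighted running sum. The null is built by permuting sample labels;
#' the normalized enrichment score divides by the mean of same-signed
#' permuted scores and the p-value is the same-signed permutation tail.
#'
#' @param study an [expression_study()].
#' @param pathway_sets a [gene_set_collection()].
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @param group_a,group_b phenotype labels (each needs >= 2 samples).
#' @return data.frame (set_name, size, es, nes, perm_pval).
#' @export
gsea_two_group <- function(study, pathway_sets, n_perm = 1000, seed = 1,
                           group_a = "active", group_b = "inactive") {
  stopifnot(inherits(study, "expression_study"),
            inherits(pathway_sets, "gene_set_collection"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  ph <- study$phenotype
  ia <- which(ph == group_a); ib <- which(ph == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("signal-to-noise undefined: need >= 2 samples per group")
  set.seed(seed)
  genes <- rownames(study$values)
  x <- study$values[, c(ia, ib), drop = FALSE]
  na <- length(ia)
  usable <- list()
  for (nm in names(pathway_sets$sets)) {
    inter <- intersect(pathway_sets$sets[[nm]], genes)
    if (length(inter) == 0L || length(inter) == length(genes)) {
      warning("set '", nm, "' unusable (empty or whole-universe); skipped")
    } else usable[[nm]] <- inter
  }
  if (length(usable) == 0L) stop("no usable gene sets")
  metric <- .signal_to_noise(x[, seq_len(na), drop = FALSE],
                             x[, -seq_len(na), drop = FALSE])
  names(metric) <- genes
  es_obs <- vapply(usable, function(s) .gsea_es(metric, s), numeric(1))
  es_perm <- matrix(NA_real_, n_perm, length(usable))
  nsamp <- ncol(x)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nsamp)
    mp <- .signal_to_noise(x[, idx[seq_len(na)], drop = FALSE],
                           x[, idx[-seq_len(na)], drop = FALSE])
    names(mp) <- genes
    es_perm[b, ] <- vapply(usable, function(s) .gsea_es(mp, s), numeric(1))
  }
  rows <- lapply(seq_along(usable), function(i) {
    obs <- es_obs[[i]]
    perm <- es_perm[, i]
    same <- if (obs >= 0) perm[perm >= 0] else perm[perm < 0]
    nes <- if (length(same)) obs / mean(abs(same)) else NA_real_
    pval <- if (length(same))
      (1 + sum(abs(same) >= abs(obs))) / (1 + length(same)) else NA_real_
    data.frame(set_name = names(usable)[i], size = length(usable[[i]]),
               es = obs, nes = nes, perm_pval = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
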