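# Transcriptional-network layer: binned mutual information, regulon
# inference (permutation -> bootstrap -> data-processing-inequality
# pruning), per-sample regulon activity, and regulon-phenotype tests.

# Equal-frequency binning; ties broken by first occurrence so every vector
# of the same length gets the identical marginal bin-count profile.
.bin_equal_freq <- function(x, bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * bins / n)
}

.mi_bins <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins) / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  nz <- joint > 0
  outer_p <- as.vector(outer(px, py))
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Plug-in mutual information on equal-frequency bins
#'
#' Both vectors are discretized into `bins` equal-frequency bins and the
#' plug-in estimate `sum p_ij log(p_ij / (p_i p_j))` is returned in nats.
#' The estimator is symmetric and nonnegative; for `y == x` with `n`
#' divisible by `bins` it equals `log(bins)` exactly.
#'
#' The default bin count grows with the cube root of the sample size
#' (`max(2, floor(n^(1/3)))`): a square-root rule makes the joint table
#' have on the order of `n` cells, and the plug-in estimator's upward bias
#' then dominates the signal, while cube-root binning keeps the cell count
#' at `n^(2/3)` and tracks the continuous MI closely at large `n` (see the
#' methods vignette). At typical cohort sizes (tens of samples) this gives
#' a coarse ternary low/mid/high discretization.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param bins bin count, default `max(2, floor(n^(1/3)))`.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  n <- length(x)
  if (n < 8) stop("mutual_information requires length >= 8")
  bins <- bins %||% max(2, floor(n^(1 / 3)))
  stopifnot(bins >= 2, bins <= n)
  .mi_bins(.bin_equal_freq(x, bins), .bin_equal_freq(y, bins), bins)
}

#' Infer TF regulons by mutual information
#'
#' Three pruning steps, in order: (a) permutation significance — each
#' TF-target MI is compared with a permutation null at level `alpha`
#' (with equal-frequency binning all genes share the same marginal bin
#' profile, so one `n_perm`-draw null per TF serves every candidate);
#' (b) bootstrap stability — an edge must exceed the null threshold in at
#' least `boot_consensus` of `n_boot` sample resamples; (c) DPI pruning —
#' in every regulator-regulator-target triangle the weakest edge is
#' removed when its MI is below the smaller of the other two minus
#' `dpi_tol` (so `dpi_tol = Inf` never removes anything). Edge signs come
#' from the Spearman correlation. Deterministic given `seed` and
#' independent of the input order of genes or TFs (everything is keyed on
#' sorted ids).
#'
#' @param study an [expression_study()] with >= 8 samples.
#' @param tf_ids regulator gene ids (must be study genes).
#' @param n_perm permutation draws for the null.
#' @param alpha permutation significance level.
#' @param n_boot bootstrap resamples.
#' @param boot_consensus minimum fraction of resamples supporting an edge.
#' @param dpi_tol DPI tolerance.
#' @param seed integer seed.
#' @param bins MI bin count (see [mutual_information()]).
#' @return list of `regulon` objects: `list(tf_id, targets =`
#'   `data.frame(gene_id, mi, sign))`, named by TF.
#' @export
infer_regulons <- function(study, tf_ids, n_perm = 1000, alpha = 0.01,
                           n_boot = 100, boot_consensus = 0.75,
                           dpi_tol = 0, seed = 1, bins = NULL) {
  stopifnot(inherits(study, "expression_study"))
  genes <- rownames(study$values)
  miss <- setdiff(tf_ids, genes)
  if (length(miss)) stop("tf id(s) not in study: ", paste(miss, collapse = ", "))
  n <- ncol(study$values)
  if (n < 8) stop("infer_regulons requires >= 8 samples (MI unstable below)")
  tf_ids <- sort(unique(tf_ids))
  bins <- bins %||% max(2, floor(n^(1 / 3)))
  set.seed(seed)

  x <- study$values[order(genes), , drop = FALSE]
  genes <- rownames(x)
  binned <- t(apply(x, 1, .bin_equal_freq, bins = bins))

  # shared permutation null: MI(shuffled regulator, equal-frequency template)
  template <- .bin_equal_freq(seq_len(n), bins)
  edges <- list()
  null_q <- numeric(0)
  for (tf in tf_ids) {
    bt <- binned[tf, ]
    null_mi <- vapply(seq_len(n_perm), function(i)
      .mi_bins(sample(bt), template, bins), numeric(1))
    thr <- stats::quantile(null_mi, 1 - alpha, names = FALSE, type = 1)
    cand <- setdiff(genes, tf)
    mi <- vapply(cand, function(g) .mi_bins(bt, binned[g, ], bins), numeric(1))
    pval <- (1 + vapply(mi, function(m) sum(null_mi >= m), numeric(1))) /
      (1 + n_perm)
    surv <- cand[pval < alpha]
    if (length(surv)) {
      # bootstrap stability against the same null threshold
      support <- stats::setNames(integer(length(surv)), surv)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bt_b <- .bin_equal_freq(x[tf, idx], bins)
        for (g in surv) {
          mg <- .mi_bins(bt_b, .bin_equal_freq(x[g, idx], bins), bins)
          if (mg >= thr) support[[g]] <- support[[g]] + 1L
        }
      }
      surv <- surv[support[surv] / n_boot >= boot_consensus]
    }
    if (length(surv))
      edges[[tf]] <- stats::setNames(mi[surv], surv)
    else
      edges[[tf]] <- stats::setNames(numeric(0), character(0))
  }

  # DPI: regulator-regulator-target triangles
  if (length(tf_ids) >= 2 && !is.infinite(dpi_tol)) {
    removed <- list()
    for (i in seq_along(tf_ids)) {
      for (j in seq_along(tf_ids)) {
        if (i >= j) next
        t1 <- tf_ids[[i]]; t2 <- tf_ids[[j]]
        mi_tt <- edges[[t1]][t2]
        if (is.na(mi_tt)) mi_tt <- edges[[t2]][t1]
        if (is.na(mi_tt)) next
        common <- intersect(names(edges[[t1]]), names(edges[[t2]]))
        common <- setdiff(common, c(t1, t2))
        for (g in common) {
          trio <- c(edge1 = unname(edges[[t1]][g]),
                    edge2 = unname(edges[[t2]][g]),
                    tt = unname(mi_tt))
          weakest <- which.min(trio)
          if (trio[weakest] < min(trio[-weakest]) - dpi_tol) {
            if (weakest == 1L) removed[[t1]] <- c(removed[[t1]], g)
            if (weakest == 2L) removed[[t2]] <- c(removed[[t2]], g)
            if (weakest == 3L) {
              removed[[t1]] <- c(removed[[t1]], t2)
              removed[[t2]] <- c(removed[[t2]], t1)
            }
          }
        }
      }
    }
    for (tf in names(removed))
      edges[[tf]] <- edges[[tf]][setdiff(names(edges[[tf]]),
                                         removed[[tf]])]
  }

  regulons <- lapply(tf_ids, function(tf) {
    tg <- edges[[tf]]
    signs <- vapply(names(tg), function(g) {
      s <- sign(stats::cor(x[tf, ], x[g, ], method = "spearman"))
      if (is.na(s) || s == 0) 1 else s
    }, numeric(1))
    structure(list(tf_id = tf,
                   targets = data.frame(gene_id = names(tg),
                                        mi = unname(tg),
                                        sign = unname(signs),
                                        stringsAsFactors = FALSE)),
              class = "regulon")
  })
  names(regulons) <- tf_ids
  regulons
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d targets (%d+, %d-)\n", x$tf_id,
              nrow(x$targets), sum(x$targets$sign > 0),
              sum(x$targets$sign < 0)))
  invisible(x)
}

#' Per-sample regulon activity
#'
#' For each sample and TF, activity is a signed two-arm single-sample
#' enrichment: the ssGSEA walk score of the positively-signed targets
#' minus the walk score of the negatively-signed targets on that sample's
#' ranked expression. A sample over-expressing positive targets and
#' under-expressing negative targets scores high; negating all target
#' signs negates the activity.
#'
#' @param study an [expression_study()].
#' @param regulons list of `regulon` objects from [infer_regulons()].
#' @param alpha ssGSEA weighting exponent.
#' @return matrix TF x sample of activity scores, class
#'   `regulon_activity`.
#' @export
regulon_activity <- function(study, regulons, alpha = 0.25) {
  stopifnot(inherits(study, "expression_study"), length(regulons) > 0)
  genes <- rownames(study$values)
  keep <- vapply(regulons, function(r)
    length(intersect(r$targets$gene_id, genes)) > 0, logical(1))
  if (any(!keep))
    warning("regulon(s) with no targets in study skipped: ",
            paste(vapply(regulons[!keep], `[[`, character(1), "tf_id"),
                  collapse = ", "))
  regulons <- regulons[keep]
  if (length(regulons) == 0L) stop("no regulon has targets in the study")
  n <- length(genes)
  w <- (n:1)^alpha
  out <- matrix(0, length(regulons), ncol(study$values),
                dimnames = list(vapply(regulons, `[[`, character(1), "tf_id"),
                                colnames(study$values)))
  for (j in seq_len(ncol(study$values))) {
    ord_genes <- genes[.rank_order(study$values[, j], genes)]
    for (i in seq_along(regulons)) {
      tg <- regulons[[i]]$targets
      pos <- intersect(tg$gene_id[tg$sign > 0], genes)
      neg <- intersect(tg$gene_id[tg$sign < 0], genes)
      es_pos <- if (length(pos)) .ssgsea_walk(ord_genes, w, pos) else 0
      es_neg <- if (length(neg)) .ssgsea_walk(ord_genes, w, neg) else 0
      out[i, j] <- es_pos - es_neg
    }
  }
  structure(out, class = c("regulon_activity", "matrix", "array"))
}

#' Regulon-phenotype association by one- or two-tailed GSEA
#'
#' Genes are ranked by the signal-to-noise statistic between the two
#' phenotype groups. One-tailed mode tests the whole (unsigned) target set
#' on the ranked list; two-tailed mode tests the positive and negative
#' arms at opposite ends, the statistic being `ES(positive arm) -
#' ES(negative arm)`. P-values come from phenotype-label permutations.
#'
#' @param study an [expression_study()].
#' @param regulons list of `regulon` objects.
#' @param tails `"one"` or `"two"`.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @param group_a,group_b phenotype labels.
#' @return data.frame (tf_id, statistic, pval, direction) — direction is
#'   the sign of the statistic (two-tailed concordance direction).
#' @export
regulon_phenotype_test <- function(study, regulons, tails = c("two", "one"),
                                   n_perm = 1000, seed = 1,
                                   group_a = "active", group_b = "inactive") {
  tails <- match.arg(tails)
  stopifnot(inherits(study, "expression_study"), length(regulons) > 0)
  ph <- study$phenotype
  ia <- which(ph == group_a); ib <- which(ph == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 samples per phenotype group")
  set.seed(seed)
  genes <- rownames(study$values)
  x <- study$values[, c(ia, ib), drop = FALSE]
  na <- length(ia)
  for (r in regulons) {
    if (length(intersect(r$targets$gene_id, genes)) == 0L)
      stop("regulon '", r$tf_id, "' is disjoint from the ranked gene list")
  }
  stat_of <- function(metric) {
    names(metric) <- genes
    vapply(regulons, function(r) {
      tg <- r$targets
      if (tails == "one") {
        .gsea_es(metric, intersect(tg$gene_id, genes))
      } else {
        pos <- intersect(tg$gene_id[tg$sign > 0], genes)
        neg <- intersect(tg$gene_id[tg$sign < 0], genes)
        es_p <- if (length(pos)) .gsea_es(metric, pos) else 0
        es_n <- if (length(neg)) .gsea_es(metric, neg) else 0
        es_p - es_n
      }
    }, numeric(1))
  }
  obs <- stat_of(.signal_to_noise(x[, seq_len(na), drop = FALSE],
                                  x[, -seq_len(na), drop = FALSE]))
  perm <- matrix(NA_real_, n_perm, length(regulons))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(ncol(x))
    perm[b, ] <- stat_of(
      .signal_to_noise(x[, idx[seq_len(na)], drop = FALSE],
                       x[, idx[-seq_len(na)], drop = FALSE]))
  }
  pval <- vapply(seq_along(regulons), function(i)
    (1 + sum(abs(perm[, i]) >= abs(obs[[i]]))) / (1 + n_perm), numeric(1))
  data.frame(tf_id = vapply(regulons, `[[`, character(1), "tf_id"),
             statistic = unname(obs), pval = pval,
             direction = ifelse(obs >= 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}
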