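# Immune-cell layer: signature ssGSEA scores averaged per cell type,
# spillover compensation by linear least squares, univariate logistic
# screening against disease activity, LASSO selection, and risk-gene x
# cell-type correlation.

#' Raw cell-type scores from signature collections
#'
#' ssGSEA score per signature, then the unweighted mean over all
#' signatures mapping to the same cell type. Cell types whose signatures
#' all miss the study's genes are dropped with a warning.
#'
#' @param study an [expression_study()].
#' @param signatures a [signature_collection()].
#' @param alpha ssGSEA weighting exponent.
#' @return matrix cell_type x sample, class `cell_score_matrix`, attribute
#'   `provenance = "raw"`.
#' @export
score_cell_types <- function(study, signatures, alpha = 0.25) {
  stopifnot(inherits(signatures, "signature_collection"))
  gsc <- gene_set_collection(signatures$signatures)
  scores <- ssgsea_score(study, gsc, alpha = alpha)
  cell_of <- signatures$cell_of[rownames(scores)]
  cells <- sort(unique(unname(signatures$cell_of)))
  out <- matrix(NA_real_, length(cells), ncol(scores),
                dimnames = list(cells, colnames(scores)))
  usable <- logical(length(cells))
  for (i in seq_along(cells)) {
    sel <- which(cell_of == cells[[i]])
    if (length(sel) == 0L) next
    usable[i] <- TRUE
    out[i, ] <- colMeans(scores[sel, , drop = FALSE])
  }
  if (any(!usable))
    warning("cell type(s) with no usable signatures dropped: ",
            paste(cells[!usable], collapse = ", "))
  out <- out[usable, , drop = FALSE]
  if (nrow(out) == 0L) stop("no cell type has usable signatures")
  structure(out, class = c("cell_score_matrix", "matrix", "array"),
            provenance = "raw")
}

#' Spillover compensation
#'
#' Signature cross-reactivity is corrected per sample by solving
#' `spillover %*% corrected = raw` in the least-squares sense, clipping
#' negative solutions to zero. With an identity spillover matrix the
#' corrected scores are `max(raw, 0)` elementwise, making the operation a
#' projection (applying it twice equals once).
#'
#' @param raw a `cell_score_matrix` (cell types x samples).
#' @param spillover square matrix keyed by cell type; must cover all
#'   scored cell types and be non-singular.
#' @return corrected `cell_score_matrix` (provenance
#'   `"spillover_corrected"`), entries >= 0.
#' @export
spillover_correct <- function(raw, spillover) {
  cells <- rownames(raw)
  miss <- setdiff(cells, rownames(spillover))
  if (length(miss))
    stop("cell type(s) missing from spillover matrix: ",
         paste(miss, collapse = ", "))
  a <- as.matrix(spillover[cells, cells, drop = FALSE])
  qr_a <- qr(a)
  if (qr_a$rank < length(cells)) stop("spillover matrix is singular")
  corrected <- qr.coef(qr_a, unclass(raw))
  corrected <- pmax(corrected, 0)
  dimnames(corrected) <- dimnames(raw)
  structure(corrected, class = c("cell_score_matrix", "matrix", "array"),
            provenance = "spillover_corrected")
}

#' Univariate screen of cell-type scores against disease activity
#'
#' Per cell type, a logistic regression of the activity indicator
#' (`group_a` = 1) on the score; the reported p is the Wald p of the
#' slope. Complete-separation fits (detected via the glm warning) fall
#' back to a Wilcoxon rank-sum p with a logged notice.
#'
#' @param scores a `cell_score_matrix`.
#' @param study the [expression_study()] carrying phenotype labels (or a
#'   named label vector).
#' @param group_a,group_b labels contrasted (>= 3 samples each).
#' @param sig flag threshold.
#' @return data.frame (cell_type, p, method, flagged) sorted as input.
#' @export
univariate_screen <- function(scores, study, group_a = "active",
                              group_b = "inactive", sig = 0.05) {
  ph <- if (inherits(study, "expression_study")) study$phenotype else study
  common <- intersect(colnames(scores), names(ph))
  ph <- ph[common]
  scores <- scores[, common, drop = FALSE]
  sel <- ph %in% c(group_a, group_b)
  if (sum(ph == group_a, na.rm = TRUE) < 3 ||
      sum(ph == group_b, na.rm = TRUE) < 3)
    stop("need >= 3 samples per group")
  y <- as.integer(ph[sel] == group_a)
  rows <- lapply(rownames(scores), function(ct) {
    s <- scores[ct, sel]
    fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))
    # complete/quasi-separation: fitted probabilities pinned at 0/1 (glm can
    # converge without warning in that regime, with divergent coefficients)
    separated <- any(fit$fitted.values > 1 - 1e-8) ||
      any(fit$fitted.values < 1e-8) ||
      abs(stats::coef(fit)[["s"]]) > 20
    if (separated || !fit$converged) {
      message("univariate_screen: separation for '", ct,
              "', falling back to rank-sum test")
      p <- suppressWarnings(
        stats::wilcox.test(s[y == 1], s[y == 0])$p.value)
      method <- "wilcoxon_fallback"
    } else {
      p <- summary(fit)$coefficients["s", "Pr(>|z|)"]
      method <- "logistic_wald"
    }
    data.frame(cell_type = ct, p = p, method = method, flagged = p < sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' LASSO selection of cell types
#'
#' L1-penalized logistic regression over the (already screened) cell-type
#' scores; lambda chosen by cross-validated deviance with the 1-SE rule.
#' Fold assignment is seeded, so the result is deterministic given `seed`.
#'
#' @param scores `cell_score_matrix` restricted to screened cell types
#'   (>= 2 rows).
#' @param study [expression_study()] or named label vector.
#' @param group_a,group_b labels (samples outside them are ignored).
#' @param n_folds cross-validation folds (reduced with a warning when
#'   there are fewer samples than folds).
#' @param seed integer seed.
#' @param lambda optional fixed penalty bypassing cross-validation.
#' @return list (class `selection_result`): `selected` data.frame
#'   (cell_type, lasso_coefficient), `lambda_chosen`, `seed`, `fit`.
#' @export
lasso_select <- function(scores, study, group_a = "active",
                         group_b = "inactive", n_folds = 10, seed = 1,
                         lambda = NULL) {
  ph <- if (inherits(study, "expression_study")) study$phenotype else study
  ph <- ph[colnames(scores)]
  sel <- ph %in% c(group_a, group_b)
  x <- t(unclass(scores)[, sel, drop = FALSE])
  y <- as.integer(ph[sel] == group_a)
  if (nrow(scores) < 2) stop("lasso_select needs >= 2 cell types")
  if (length(y) < 10) stop("lasso_select needs >= 10 samples")
  set.seed(seed)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda)
    co <- as.matrix(stats::coef(fit))[-1, 1]
    lam <- lambda
  } else {
    if (length(y) < n_folds) {
      warning("fewer samples than folds; reducing folds to ", length(y))
      n_folds <- length(y)
    }
    foldid <- sample(rep(seq_len(n_folds), length.out = length(y)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            type.measure = "deviance")
    co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
    lam <- cv$lambda.1se
    fit <- cv
  }
  nz <- co[co != 0]
  structure(list(selected = data.frame(cell_type = names(nz),
                                       lasso_coefficient = unname(nz),
                                       stringsAsFactors = FALSE),
                 lambda_chosen = lam, seed = seed, fit = fit),
            class = "selection_result")
}

#' Screen-then-select convenience wrapper
#'
#' Runs [univariate_screen()] and then [lasso_select()] on the flagged
#' cell types; the selection-within-screen invariant (`selected` is a
#' subset of the screened list at p < 0.05) holds by construction.
#'
#' @inheritParams lasso_select
#' @param sig univariate flag threshold.
#' @return `selection_result` with an extra `screened` data.frame.
#' @export
select_cell_types <- function(scores, study, group_a = "active",
                              group_b = "inactive", sig = 0.05,
                              n_folds = 10, seed = 1) {
  screened <- univariate_screen(scores, study, group_a, group_b, sig)
  flagged <- screened$cell_type[screened$flagged]
  if (length(flagged) < 2) {
    # the L1 path needs >= 2 predictors; a lone screened type passes through
    if (length(flagged) == 1)
      message("select_cell_types: single screened type '", flagged,
              "' passed through without LASSO")
    res <- structure(list(selected = data.frame(cell_type = flagged,
                                                lasso_coefficient =
                                                  rep(NA_real_, length(flagged)),
                                                stringsAsFactors = FALSE),
                          lambda_chosen = NA_real_, seed = seed, fit = NULL),
                     class = "selection_result")
    res$screened <- screened
    return(res)
  }
  res <- lasso_select(scores[flagged, , drop = FALSE], study, group_a,
                      group_b, n_folds, seed)
  res$screened <- screened
  res
}

#' Correlate risk-gene expression with cell-type scores
#'
#' Pearson (or Spearman) correlation and two-sided p for every
#' (gene, cell type) pair, plus the per-gene count of cell types with
#' p < 0.05. Zero-variance genes or scores give missing correlations with
#' a warning.
#'
#' @param study an [expression_study()].
#' @param genes gene ids to correlate (e.g. the risk genes).
#' @param scores a `cell_score_matrix`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` and `p` matrices (gene x cell type) and
#'   `n_significant` per gene.
#' @export
correlate_genes_cells <- function(study, genes, scores,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  samples <- intersect(colnames(study$values), colnames(scores))
  if (length(samples) < 3) stop("need >= 3 shared samples")
  genes <- intersect(genes, rownames(study$values))
  if (length(genes) == 0L) stop("none of the requested genes are in the study")
  r <- p <- matrix(NA_real_, length(genes), nrow(scores),
                   dimnames = list(genes, rownames(scores)))
  warned <- FALSE
  for (g in genes) {
    xg <- study$values[g, samples]
    for (ct in rownames(scores)) {
      sc <- scores[ct, samples]
      if (stats::sd(xg) == 0 || stats::sd(sc) == 0) {
        warned <- TRUE
        next
      }
      ct_test <- suppressWarnings(stats::cor.test(xg, sc, method = method))
      r[g, ct] <- unname(ct_test$estimate)
      p[g, ct] <- ct_test$p.value
    }
  }
  if (warned)
    warning("zero-variance gene(s) or score(s): correlations reported as missing")
  list(r = r, p = p,
       n_significant = apply(p, 1, function(v) sum(!is.na(v) & v < 0.05)))
}
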