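# Gene-level pipeline: moderated differential expression, per-gene QTL MR
# against the outcome, odds-ratio-based risk/protective classification, and
# protein-level verification.

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated two-group differential expression
#'
#' Per-gene linear model contrasting two phenotype groups, with
#' empirical-Bayes variance moderation: the posterior variance is the
#' convex combination `s2_post = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`,
#' where the prior df `d0` and prior variance `s0^2` are fitted by moment
#' matching on the distribution of log residual variances, and the
#' moderated t has `d0 + dg` degrees of freedom. P-values are adjusted by
#' Benjamini-Hochberg across all genes.
#'
#' @param study an [expression_study()].
#' @param contrast character pair of phenotype labels, effect =
#'   `contrast[1] - contrast[2]`. A label may also be a `+`-joined union of
#'   labels (e.g. `"active+inactive"` for all patients).
#' @return data.frame (gene_id, log_fc, moderated_t, pval, adj_pval) in
#'   study gene order.
#' @export
moderated_de <- function(study, contrast = c("active", "inactive")) {
  stopifnot(inherits(study, "expression_study"), length(contrast) == 2)
  groups <- lapply(contrast, function(lbl) {
    labs <- strsplit(lbl, "+", fixed = TRUE)[[1]]
    unknown <- setdiff(labs, unique(study$phenotype))
    if (length(unknown))
      stop("contrast level(s) absent from study: ",
           paste(unknown, collapse = ", "))
    which(study$phenotype %in% labs)
  })
  n1 <- length(groups[[1]]); n2 <- length(groups[[2]])
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per contrast level")
  x1 <- study$values[, groups[[1]], drop = FALSE]
  x2 <- study$values[, groups[[2]], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log_fc <- m1 - m2
  dg <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  s2 <- pmax(s2, 1e-12)

  # moment matching on z = log(s2): E[z] = log(s0^2) + digamma(dg/2) -
  # log(dg/2), Var[z] = trigamma(dg/2) + trigamma(d0/2)
  z <- log(s2)
  excess <- stats::var(z) - trigamma(dg / 2)
  if (is.finite(excess) && excess > 1e-8) {
    d0 <- 2 * .trigamma_inverse(excess)
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  } else {
    # no excess dispersion: variances fully shrunk to the common value
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
    d0 <- Inf
  }
  tstat <- log_fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene_id = rownames(study$values), log_fc = log_fc,
                    moderated_t = tstat, pval = pval,
                    adj_pval = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "eb") <- list(d0 = d0, s0_2 = s02, dg = dg, s2 = unname(s2),
                          s2_post = unname(s2_post))
  rownames(out) <- NULL
  out
}

.classify_gene <- function(or_, pval, sig = 0.05) {
  if (is.na(pval) || pval >= sig || or_ == 1) "excluded"
  else if (or_ > 1) "risk" else "protective"
}

.gene_mr_row <- function(gene_id, n_snps, method, beta, se, pval, label,
                         reason = NA_character_) {
  data.frame(gene_id = gene_id, n_snps = as.integer(n_snps), method = method,
             beta = beta, se = se, or_ = exp(beta), pval = pval,
             label = label, reason = reason, stringsAsFactors = FALSE)
}

#' Per-gene QTL Mendelian randomization screen
#'
#' Each gene's QTL table is treated as an exposure against the shared
#' outcome: harmonization, instrument selection at the strict tier only
#' (no fallback; `p < 5e-8`, clumping `r^2 = 0.001`, outcome-association
#' removal, F >= 10), then Wald ratio (one instrument) or IVW (several).
#' Significant genes (raw `p < 0.05`) are labeled `risk` when OR > 1 and
#' `protective` when OR < 1; everything else (including genes with no
#' surviving instruments) is `excluded` with a reason.
#'
#' @param catalog named list gene -> [summary_stats()].
#' @param outcome [summary_stats()] for the outcome trait.
#' @param ld optional [ld_matrix()] over the instrument universe.
#' @param p_primary,r2_primary,p_outcome_max,f_min selection thresholds.
#' @param sig significance level on the raw p-value.
#' @return data.frame with one row per gene (gene_id, n_snps, method, beta,
#'   se, or_, pval, label, reason), class `gene_mr_table`.
#' @export
qtl_mr_screen <- function(catalog, outcome, ld = NULL, p_primary = 5e-8,
                          r2_primary = 0.001, p_outcome_max = 5e-6,
                          f_min = 10, sig = 0.05) {
  if (length(catalog) == 0L) {
    empty <- data.frame(gene_id = character(0), n_snps = integer(0),
                        method = character(0), beta = numeric(0),
                        se = numeric(0), or_ = numeric(0),
                        pval = numeric(0), label = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
    return(structure(empty, class = c("gene_mr_table", "data.frame")))
  }
  if (!inherits(outcome, "summary_stats") || nrow(outcome$records) == 0L)
    stop("outcome table is empty")
  rows <- lapply(names(catalog), function(g) {
    h <- tryCatch(harmonize(catalog[[g]], outcome), error = function(e) NULL)
    if (is.null(h))
      return(.gene_mr_row(g, 0L, "none", NA_real_, NA_real_, NA_real_,
                          "excluded", "no_shared_variants"))
    sel <- tryCatch(
      select_instruments(h, ld, p_primary = p_primary,
                         r2_primary = r2_primary,
                         p_outcome_max = p_outcome_max, f_min = f_min,
                         fallback = FALSE),
      error = function(e) NULL)
    if (is.null(sel)) {
      reason <- if (any(h$records$f_stat < f_min)) "weak_instrument"
                else "no_surviving_instruments"
      return(.gene_mr_row(g, 0L, "none", NA_real_, NA_real_, NA_real_,
                          "excluded", reason))
    }
    fit <- ivw(sel)
    .gene_mr_row(g, fit$n_snps, fit$method, fit$beta, fit$se, fit$pval,
                 .classify_gene(fit$or_, fit$pval, sig))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_mr_table", "data.frame")
  out
}

#' Annotate a gene MR table with differential-expression direction
#'
#' Adds `log_fc` and `direction` (up/down/na) per gene and reports the
#' cross-tabulation of MR label by expression direction.
#'
#' @param mr a `gene_mr_table`.
#' @param de output of [moderated_de()] (may be empty).
#' @return the annotated table; attribute `"crosstab"` holds the counts of
#'   (risk, protective) x (up, down).
#' @export
intersect_with_de <- function(mr, de) {
  idx <- if (!is.null(de) && nrow(de)) match(mr$gene_id, de$gene_id)
         else rep(NA_integer_, nrow(mr))
  mr$log_fc <- ifelse(is.na(idx), NA_real_, de$log_fc[idx])
  mr$direction <- ifelse(is.na(mr$log_fc), "na",
                         ifelse(mr$log_fc > 0, "up", "down"))
  ct <- sapply(c(up = "up", down = "down"), function(d)
    sapply(c(risk = "risk", protective = "protective"), function(l)
      sum(mr$label == l & mr$direction == d)))
  attr(mr, "crosstab") <- ct
  mr
}

#' Protein-level verification screen
#'
#' Identical machinery to [qtl_mr_screen()] run on a pQTL catalog; genes
#' significant with the same effect direction in both tables are flagged
#' concordant.
#'
#' @param protein_catalog named list gene -> [summary_stats()] of pQTLs
#'   (may be empty; returns an empty table).
#' @param outcome outcome [summary_stats()].
#' @param eqtl_table optional `gene_mr_table` from the eQTL screen used for
#'   the concordance flag.
#' @param ... thresholds forwarded to [qtl_mr_screen()].
#' @return `gene_mr_table` with an extra logical `concordant` column.
#' @export
pqtl_verify <- function(protein_catalog, outcome, eqtl_table = NULL, ...) {
  if (length(protein_catalog) == 0L) {
    out <- qtl_mr_screen(list(), outcome)
    out$concordant <- logical(0)
    return(out)
  }
  out <- qtl_mr_screen(protein_catalog, outcome, ...)
  out$concordant <- FALSE
  if (!is.null(eqtl_table) && nrow(eqtl_table)) {
    idx <- match(out$gene_id, eqtl_table$gene_id)
    both_sig <- out$label %in% c("risk", "protective") &
      !is.na(idx) & eqtl_table$label[idx] %in% c("risk", "protective")
    same_dir <- !is.na(idx) & out$label == eqtl_table$label[idx]
    out$concordant <- both_sig & same_dir
  }
  out
}
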