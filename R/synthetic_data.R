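# Generators for every input the pipeline consumes. All are pure functions
# of their config (seed included); truth objects accompany the data so
# recovery tests never re-derive ground truth.

.nonpalindromic_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Configuration for a simulated exposure/outcome GWAS pair
#'
#' Instrument strength is parameterized by a target first-stage F statistic
#' (`f_target`): exposure effects are drawn as
#' `|gamma| = se_x * sqrt(f_target) * U(0.9, 1.1)` with random sign, so that
#' observed F values concentrate near `f_target` and tests can straddle the
#' F = 10 weak-instrument filter deliberately.
#'
#' @param n_variants number of variants (>= 1).
#' @param beta_causal true causal effect (log-odds per exposure unit).
#' @param pleiotropy_frac proportion of variants with direct outcome effects.
#' @param pleiotropy_sd SD of those direct effects.
#' @param balanced if `TRUE` direct effects have mean zero; if `FALSE` they
#'   are directional with mean `pleiotropy_sd`.
#' @param het_sd extra heterogeneity SD added to outcome effects (not
#'   reflected in the reported SEs).
#' @param exposure_se_scale,outcome_se_scale SE magnitudes.
#' @param f_target target first-stage F.
#' @param ld_block_size,ld_block_r2 LD is identity unless `ld_block_size > 1`,
#'   in which case consecutive blocks share off-diagonal r^2 `ld_block_r2`.
#' @param seed integer seed.
#' @export
gwas_sim_config <- function(n_variants = 50, beta_causal = 0,
                            pleiotropy_frac = 0, pleiotropy_sd = 0.1,
                            balanced = TRUE, het_sd = 0,
                            exposure_se_scale = 0.02, outcome_se_scale = 0.02,
                            f_target = 100, ld_block_size = 1,
                            ld_block_r2 = 0, seed = 1) {
  stopifnot(n_variants >= 1, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            pleiotropy_sd >= 0, het_sd >= 0, exposure_se_scale > 0,
            outcome_se_scale > 0, f_target > 0, ld_block_size >= 1,
            ld_block_r2 >= 0, ld_block_r2 <= 1)
  structure(as.list(environment()), class = "gwas_sim_config")
}

.sim_alleles <- function(k) {
  idx <- sample.int(nrow(.nonpalindromic_pairs), k, replace = TRUE)
  list(effect = .nonpalindromic_pairs[idx, 1],
       other = .nonpalindromic_pairs[idx, 2])
}

#' Simulate a two-sample GWAS exposure/outcome pair
#'
#' Per variant k the exposure effect is observed as
#' `gamma_hat_k = gamma_k + N(0, se_x_k^2)` and the outcome effect as
#' `Gamma_hat_k = beta_causal * gamma_k + alpha_k * [k pleiotropic] +
#' N(0, se_y_k^2 + het_sd^2)`. Allele pairs are non-palindromic and shared
#' between the two tables so harmonization retains every variant.
#'
#' @param cfg a [gwas_sim_config()].
#' @return list with elements `exposure`, `outcome` (both [summary_stats()]),
#'   `ld` ([ld_matrix()]), and `truth` (gamma, alpha, pleiotropic index).
#' @export
simulate_gwas_pair <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  set.seed(cfg$seed)
  k <- cfg$n_variants
  ids <- sprintf("rs%d", seq_len(k))
  al <- .sim_alleles(k)
  eaf <- stats::runif(k, 0.1, 0.9)
  se_x <- cfg$exposure_se_scale * stats::runif(k, 0.8, 1.2)
  se_y <- cfg$outcome_se_scale * stats::runif(k, 0.8, 1.2)
  gamma <- sample(c(-1, 1), k, replace = TRUE) *
    se_x * sqrt(cfg$f_target) * stats::runif(k, 0.9, 1.1)
  n_pleio <- round(cfg$pleiotropy_frac * k)
  pleio_idx <- if (n_pleio > 0) sort(sample.int(k, n_pleio)) else integer(0)
  alpha <- numeric(k)
  if (n_pleio > 0) {
    mu <- if (cfg$balanced) 0 else cfg$pleiotropy_sd
    alpha[pleio_idx] <- stats::rnorm(n_pleio, mu, cfg$pleiotropy_sd)
  }
  gamma_hat <- gamma + stats::rnorm(k, 0, se_x)
  big_gamma_hat <- cfg$beta_causal * gamma + alpha +
    stats::rnorm(k, 0, sqrt(se_y^2 + cfg$het_sd^2))
  exposure <- summary_stats(data.frame(
    variant_id = ids, effect_allele = al$effect, other_allele = al$other,
    eaf = eaf, beta = gamma_hat, se = se_x,
    pval = 2 * stats::pnorm(-abs(gamma_hat) / se_x),
    n = 50000, stringsAsFactors = FALSE), "sim_exposure")
  outcome <- summary_stats(data.frame(
    variant_id = ids, effect_allele = al$effect, other_allele = al$other,
    eaf = eaf, beta = big_gamma_hat, se = se_y,
    pval = 2 * stats::pnorm(-abs(big_gamma_hat) / se_y),
    n = 50000, stringsAsFactors = FALSE), "sim_outcome")
  vals <- diag(k)
  if (cfg$ld_block_size > 1) {
    block <- (seq_len(k) - 1) %/% cfg$ld_block_size
    vals <- outer(block, block, "==") * cfg$ld_block_r2
    diag(vals) <- 1
  }
  list(exposure = exposure, outcome = outcome,
       ld = ld_matrix(vals, ids),
       truth = list(gamma = stats::setNames(gamma, ids),
                    alpha = stats::setNames(alpha, ids),
                    pleiotropic = ids[pleio_idx],
                    beta_causal = cfg$beta_causal))
}

#' Simulate a per-gene cis-QTL catalog plus a shared outcome table
#'
#' A known subset of genes carries a non-null causal effect on the outcome;
#' effect signs are randomized so both risk (OR > 1) and protective (OR < 1)
#' genes exist. Instruments are strong (tiny SEs, genome-wide significant)
#' so the per-gene screen exercises its estimators rather than its filters.
#'
#' @param n_genes number of genes.
#' @param snps_per_gene cis instruments per gene (>= 1).
#' @param frac_causal fraction of genes with a true effect.
#' @param or_range range of true odds ratios (per expression unit) for causal
#'   genes; sign of log-OR randomized. The default keeps single-variant
#'   mediated outcome associations below the outcome-association removal
#'   threshold (as in real data, where a QTL's effect on disease is far
#'   weaker than its effect on expression) while leaving the combined
#'   instrument well powered.
#' @param seed integer seed.
#' @param f_target target instrument F.
#' @return list with `catalog` (named list gene -> [summary_stats()]),
#'   `outcome` ([summary_stats()] over all instruments), `ld` (identity
#'   [ld_matrix()]), and `truth` data.frame (gene, theta = true log-OR,
#'   causal flag).
#' @export
simulate_eqtl_catalog <- function(n_genes = 100, snps_per_gene = 3,
                                  frac_causal = 0.2, or_range = c(1.1, 1.25),
                                  seed = 1, f_target = 400) {
  stopifnot(n_genes >= 1, snps_per_gene >= 1, frac_causal >= 0,
            frac_causal <= 1, length(or_range) == 2, all(or_range > 1))
  set.seed(seed)
  genes <- sprintf("G%d", seq_len(n_genes))
  n_causal <- round(frac_causal * n_genes)
  causal <- genes %in% sample(genes, n_causal)
  theta <- numeric(n_genes)
  theta[causal] <- sample(c(-1, 1), n_causal, replace = TRUE) *
    log(stats::runif(n_causal, or_range[1], or_range[2]))
  catalog <- vector("list", n_genes)
  names(catalog) <- genes
  out_rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    m <- snps_per_gene
    ids <- sprintf("%s_rs%d", genes[g], seq_len(m))
    al <- .sim_alleles(m)
    eaf <- stats::runif(m, 0.1, 0.9)
    se_x <- 0.02 * stats::runif(m, 0.8, 1.2)
    se_y <- 0.02 * stats::runif(m, 0.8, 1.2)
    gamma <- sample(c(-1, 1), m, replace = TRUE) *
      se_x * sqrt(f_target) * stats::runif(m, 0.9, 1.1)
    gamma_hat <- gamma + stats::rnorm(m, 0, se_x)
    big <- theta[g] * gamma + stats::rnorm(m, 0, se_y)
    catalog[[g]] <- summary_stats(data.frame(
      variant_id = ids, effect_allele = al$effect, other_allele = al$other,
      eaf = eaf, beta = gamma_hat, se = se_x,
      pval = 2 * stats::pnorm(-abs(gamma_hat) / se_x),
      n = 30000, stringsAsFactors = FALSE), genes[g])
    out_rows[[g]] <- data.frame(
      variant_id = ids, effect_allele = al$effect, other_allele = al$other,
      eaf = eaf, beta = big, se = se_y,
      pval = 2 * stats::pnorm(-abs(big) / se_y),
      n = 50000, stringsAsFactors = FALSE)
  }
  out_tab <- do.call(rbind, out_rows)
  outcome <- summary_stats(out_tab, "sim_outcome")
  list(catalog = catalog, outcome = outcome,
       ld = ld_matrix(diag(nrow(out_tab)), out_tab$variant_id),
       truth = data.frame(gene = genes, theta = theta, causal = causal,
                          stringsAsFactors = FALSE))
}

#' Configuration for a simulated whole-blood-like expression study
#'
#' Baseline values are i.i.d. normal (array-style continuous data after
#' normalization). Risk genes are shifted up by `activity_effect` (in
#' `noise_sd` units) in active samples and protective genes down by the same
#' amount; TF targets are generated as
#' `effect_strength * tf_value + N(0, noise_sd)` so mutual-information
#' detectable dependence exists; cell-signature genes are shifted per group
#' by the configured abundance.
#'
#' @param n_genes total genes (ids `G1..Gn`).
#' @param n_active,n_inactive,n_control samples per phenotype group.
#' @param risk_gene_ids,protective_gene_ids planted (disjoint) memberships.
#' @param activity_effect mean shift of risk genes in active vs inactive
#'   samples, in expression-SD units.
#' @param tf_specs list of specs `list(tf_id=, target_ids=, effect_strength=,
#'   signs= (optional, +-1 per target), group_effect= (optional shift of the
#'   TF itself in active samples))`.
#' @param cell_specs list of specs `list(cell_type=, genes=, abundance=
#'   c(active=, inactive=, control=))` (shifts in SD units).
#' @param noise_sd residual SD.
#' @param seed integer seed.
#' @export
expr_sim_config <- function(n_genes = 500, n_active = 12, n_inactive = 12,
                            n_control = 12,
                            risk_gene_ids = sprintf("G%d", 1:20),
                            protective_gene_ids = sprintf("G%d", 21:40),
                            activity_effect = 1, tf_specs = list(),
                            cell_specs = list(), noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 1, n_active >= 0, n_inactive >= 0, n_control >= 0,
            noise_sd > 0)
  if (length(intersect(risk_gene_ids, protective_gene_ids)))
    stop("risk and protective gene sets must be disjoint")
  tf_ids <- vapply(tf_specs, `[[`, character(1), "tf_id")
  if (length(intersect(tf_ids, c(risk_gene_ids, protective_gene_ids))))
    stop("TF ids must be disjoint from planted risk/protective sets")
  structure(as.list(environment())[names(formals(expr_sim_config))],
            class = "expr_sim_config")
}

#' Simulate an expression study with planted structure
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `study` ([expression_study()]) and `truth` (planted
#'   memberships and parameters).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%d", seq_len(cfg$n_genes))
  groups <- c(rep("active", cfg$n_active), rep("inactive", cfg$n_inactive),
              rep("control", cfg$n_control))
  n <- length(groups)
  samples <- sprintf("S%d", seq_len(n))
  for (ids in list(cfg$risk_gene_ids, cfg$protective_gene_ids)) {
    miss <- setdiff(ids, genes)
    if (length(miss)) stop("planted gene(s) outside gene universe: ",
                           paste(miss, collapse = ", "))
  }
  x <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n,
              dimnames = list(genes, samples))
  active <- groups == "active"
  shift <- cfg$activity_effect * cfg$noise_sd
  x[cfg$risk_gene_ids, active] <- x[cfg$risk_gene_ids, active] + shift
  x[cfg$protective_gene_ids, active] <- x[cfg$protective_gene_ids, active] - shift
  tf_truth <- list()
  for (spec in cfg$tf_specs) {
    tf <- spec$tf_id
    if (!tf %in% genes) stop("tf_id not in gene universe: ", tf)
    targets <- spec$target_ids
    if (tf %in% targets) stop("TF cannot be its own target: ", tf)
    signs <- spec$signs %||% rep(1, length(targets))
    stopifnot(length(signs) == length(targets), all(signs %in% c(-1, 1)))
    ge <- spec$group_effect %||% 0
    tf_val <- stats::rnorm(n, 0, cfg$noise_sd) + ge * cfg$noise_sd * active
    x[tf, ] <- tf_val
    for (j in seq_along(targets)) {
      x[targets[[j]], ] <- signs[[j]] * spec$effect_strength * tf_val +
        stats::rnorm(n, 0, cfg$noise_sd)
    }
    tf_truth[[tf]] <- list(targets = targets, signs = signs,
                           effect_strength = spec$effect_strength,
                           group_effect = ge)
  }
  for (spec in cfg$cell_specs) {
    ab <- spec$abundance
    for (grp in names(ab)) {
      sel <- groups == grp
      x[spec$genes, sel] <- x[spec$genes, sel] + ab[[grp]] * cfg$noise_sd
    }
  }
  study <- expression_study(x, stats::setNames(groups, samples))
  list(study = study,
       truth = list(risk_genes = cfg$risk_gene_ids,
                    protective_genes = cfg$protective_gene_ids,
                    activity_effect = cfg$activity_effect,
                    tfs = tf_truth,
                    cells = cfg$cell_specs))
}
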