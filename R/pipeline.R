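# Config-driven orchestration of the three analysis arcs (trait-level MR;
# gene screen + risk scores; activity deep-dive), with seeded stages and a
# JSON/TSV report tree.

#' Derive a per-stage seed from the global seed
#'
#' Stage names are hashed (sum of UTF-8 code points with a rolling
#' multiplier) and mixed with the global seed modulo 2^31 - 1, so reruns
#' of one stage are isolated from the others.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a JSON file holding one) with
#' elements `seed` (mandatory), `out_dir`, file paths (`exposures`,
#' `outcomes`, `ld`, `exclusion_list`, `expression`, `phenotype`,
#' `catalog_dir`, `pqtl_dir`, `pathway_gmt`, `signature_gmt`, `cellmap`,
#' `spillover`, `tfs`) and optional threshold overrides (all of §2.1-§2.6's
#' defaults apply otherwise).
#'
#' @param config named list or path to a JSON file.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  path_fields <- c("ld", "exclusion_list", "expression", "phenotype",
                   "pathway_gmt", "signature_gmt", "cellmap", "spillover",
                   "tfs", "qtl_outcome")
  for (f in path_fields) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config$", f, ": no such file: ", config[[f]])
  }
  for (f in c("exposures", "outcomes")) {
    for (p in config[[f]]) if (!file.exists(p))
      stop("config$", f, ": no such file: ", p)
  }
  for (f in c("catalog_dir", "pqtl_dir")) {
    if (!is.null(config[[f]]) && !dir.exists(config[[f]]))
      stop("config$", f, ": no such directory: ", config[[f]])
  }
  defaults <- list(p_primary = 5e-8, p_fallback = 5e-6, r2_primary = 0.001,
                   r2_fallback = 0.01, min_iv = 20, p_outcome_max = 5e-6,
                   f_min = 10, n_sim_presso = 1000, n_perm = 1000,
                   ssgsea_alpha = 0.25, sig = 0.05,
                   de_contrast = c("active+inactive", "control"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  structure(config, class = c("pipeline_config", "list"))
}

.read_catalog_dir <- function(dir, dialect = "plain") {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  cat <- lapply(files, read_summary_stats, dialect = dialect)
  names(cat) <- vapply(cat, `[[`, character(1), "trait_id")
  cat
}

#' Trait-level MR across all exposure x outcome pairs
#'
#' Runs harmonization, instrument selection and the full MR report for the
#' Cartesian product of the configured exposures and outcomes. Per-pair
#' failures are recorded and the run continues. Writes
#' `trait_mr_summary.tsv` (Table-1-shaped: exposure, outcome, method, p,
#' OR, CI) and `trait_mr_report.json` under `out_dir` when set.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @return list with `summary` data.frame and per-pair `reports`.
#' @export
run_trait_mr <- function(config) {
  config <- pipeline_config(config)
  exclusion <- if (!is.null(config$exclusion_list))
    readLines(config$exclusion_list, warn = FALSE) else character()
  ld <- if (!is.null(config$ld)) read_ld_matrix(config$ld) else NULL
  exposures <- lapply(config$exposures, read_summary_stats,
                      dialect = config$dialect %||% "plain")
  outcomes <- lapply(config$outcomes, read_summary_stats,
                     dialect = config$dialect %||% "plain")
  rows <- list(); reports <- list()
  for (ex in exposures) {
    for (out in outcomes) {
      pair <- paste(ex$trait_id, out$trait_id, sep = "->")
      res <- tryCatch({
        h <- harmonize(ex, out)
        sel <- select_instruments(
          h, ld, p_primary = config$p_primary, p_fallback = config$p_fallback,
          r2_primary = config$r2_primary, r2_fallback = config$r2_fallback,
          min_iv = config$min_iv, p_outcome_max = config$p_outcome_max,
          f_min = config$f_min, exclusion_list = exclusion)
        rep <- full_mr_report(sel, seed = derive_seed(config$seed, pair),
                              n_sim = config$n_sim_presso)
        pr <- rep$primary
        list(report = rep,
             row = data.frame(exposure = ex$trait_id,
                              outcome = out$trait_id,
                              method = pr$method, n_snps = pr$n_snps,
                              pval = pr$pval, or_ = pr$or_,
                              ci_low = pr$ci_low, ci_high = pr$ci_high,
                              status = "ok", stringsAsFactors = FALSE))
      }, error = function(e) {
        list(report = NULL,
             row = data.frame(exposure = ex$trait_id, outcome = out$trait_id,
                              method = NA_character_, n_snps = NA_integer_,
                              pval = NA_real_, or_ = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              status = paste0("failed: ",
                                              conditionMessage(e)),
                              stringsAsFactors = FALSE))
      })
      if (!is.null(res$report)) reports[[pair]] <- res$report
      rows[[pair]] <- res$row
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary,
                       file.path(config$out_dir, "trait_mr_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) {
        r$primary <- as.data.frame(r$primary); r
      }),
      file.path(config$out_dir, "trait_mr_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  list(summary = summary, reports = reports)
}

#' Gene arc: differential expression, per-gene MR, risk scores
#'
#' Chains [moderated_de()], [qtl_mr_screen()] (plus optional
#' [pqtl_verify()]), [intersect_with_de()], [risk_protective_scores()] and
#' [compare_groups()]; intermediates are persisted under `out_dir`.
#'
#' @param config a [pipeline_config()] with `expression`, `phenotype` and
#'   `catalog_dir` plus one outcome.
#' @return list with `de`, `gene_table`, `pqtl_table` (or NULL), `scores`,
#'   `comparison`.
#' @export
run_gene_arc <- function(config) {
  config <- pipeline_config(config)
  study <- read_expression(config$expression, config$phenotype)
  outcome_path <- config$qtl_outcome %||% config$outcomes[[1]]
  outcome <- read_summary_stats(outcome_path,
                                dialect = config$dialect %||% "plain")
  ld <- if (!is.null(config$ld)) read_ld_matrix(config$ld) else NULL
  de <- moderated_de(study, config$de_contrast)
  catalog <- .read_catalog_dir(config$catalog_dir)
  gene_table <- qtl_mr_screen(catalog, outcome, ld,
                              p_primary = config$p_primary,
                              r2_primary = config$r2_primary,
                              p_outcome_max = config$p_outcome_max,
                              f_min = config$f_min, sig = config$sig)
  gene_table <- intersect_with_de(gene_table, de)
  pqtl_table <- NULL
  if (!is.null(config$pqtl_dir)) {
    pqtl_table <- pqtl_verify(.read_catalog_dir(config$pqtl_dir), outcome,
                              eqtl_table = gene_table)
  }
  scores <- risk_protective_scores(study, gene_table,
                                   alpha = config$ssgsea_alpha)
  comparison <- compare_groups(scores$scores, study)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(de, file.path(config$out_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_table,
                       file.path(config$out_dir, "gene_mr_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comparison,
                       file.path(config$out_dir, "risk_score_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(de = de, gene_table = gene_table, pqtl_table = pqtl_table,
       scores = scores, comparison = comparison)
}

#' Activity arc: regulons, pathways, immune cells
#'
#' Chains [infer_regulons()], [regulon_activity()],
#' [regulon_phenotype_test()], [gsea_two_group()], [score_cell_types()],
#' [spillover_correct()], [select_cell_types()] and
#' [correlate_genes_cells()]; all stages are seeded from the global seed.
#'
#' @param config a [pipeline_config()] with `expression`, `phenotype`,
#'   `tfs`, `pathway_gmt`, `signature_gmt`, `cellmap`, `spillover`; and
#'   optionally `risk_genes` (character vector, else the LASSO correlation
#'   step is skipped).
#' @return list with `regulons`, `activity`, `regulon_tests`, `gsea`,
#'   `cell_scores`, `selection`, `correlations`.
#' @export
run_activity_arc <- function(config) {
  config <- pipeline_config(config)
  study <- read_expression(config$expression, config$phenotype)
  tfs <- readLines(config$tfs, warn = FALSE)
  tfs <- tfs[nzchar(tfs)]
  regulons <- infer_regulons(study, tfs, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "regulon"))
  nonempty <- vapply(regulons, function(r) nrow(r$targets) > 0, logical(1))
  activity <- if (any(nonempty))
    regulon_activity(study, regulons[nonempty]) else NULL
  regulon_tests <- if (any(nonempty))
    regulon_phenotype_test(study, regulons[nonempty], tails = "two",
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "regulon_test"))
    else NULL
  gsea <- NULL
  if (!is.null(config$pathway_gmt)) {
    gsea <- gsea_two_group(study, read_gmt(config$pathway_gmt),
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "gsea"))
  }
  cells <- NULL; selection <- NULL; correlations <- NULL
  if (!is.null(config$signature_gmt)) {
    sigs <- read_signatures(config$signature_gmt, config$cellmap)
    raw <- score_cell_types(study, sigs, alpha = config$ssgsea_alpha)
    cells <- if (!is.null(config$spillover))
      spillover_correct(raw, read_spillover(config$spillover)) else raw
    selection <- select_cell_types(cells, study,
                                   seed = derive_seed(config$seed, "lasso"))
    if (!is.null(config$risk_genes))
      correlations <- correlate_genes_cells(study, config$risk_genes, cells)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(activity)) {
      tab <- data.frame(tf_id = rownames(activity), unclass(activity),
                        check.names = FALSE)
      utils::write.table(tab, file.path(config$out_dir, "regulon_activity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report <- list(
      regulons = lapply(regulons, function(r)
        list(tf_id = r$tf_id, targets = r$targets)),
      regulon_tests = regulon_tests, gsea = gsea,
      selection = if (!is.null(selection))
        list(screened = selection$screened, selected = selection$selected,
             lambda_chosen = selection$lambda_chosen) else NULL)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "activity_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(regulons = regulons, activity = activity,
       regulon_tests = regulon_tests, gsea = gsea, cell_scores = cells,
       selection = selection, correlations = correlations)
}

#' Generate a full synthetic input bundle shaped like the study
#'
#' Writes, under `out_dir`: three exposure and two outcome GWAS tables
#' over shared variant panels (one per exposure) with a true causal effect
#' on both outcomes, an identity LD matrix, a per-gene eQTL catalog plus
#' its outcome table, an expression matrix with active/inactive/control
#' groups, planted TF regulons and cell-type signatures, the pathway and
#' signature GMT files, the TF list, a spillover matrix, and `truth.json`.
#'
#' @param out_dir output directory (created).
#' @param seed integer seed.
#' @param n_variants variants per exposure panel.
#' @param n_genes eQTL-catalog size.
#' @return invisibly, a ready-to-run config list pointing at the files.
#' @export
simulate_bundle <- function(out_dir, seed = 1, n_variants = 60,
                            n_genes = 60) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exposure_paths <- character(3); outcome_rows <- list()
  ld_ids <- character(0); truth <- list()
  outcome_tabs <- list(out1 = list(), out2 = list())
  for (i in 1:3) {
    for (j in 1:2) {
      cfg <- gwas_sim_config(n_variants = n_variants, beta_causal = 0.3,
                             seed = derive_seed(seed, sprintf("gwas%d_%d", i, j)))
      sim <- simulate_gwas_pair(cfg)
      # one exposure panel per exposure index; outcome j gets its variants
      if (j == 1) {
        sim$exposure$trait_id <- sprintf("exposure%d", i)
        rec <- sim$exposure$records
        rec$variant_id <- sprintf("e%d_%s", i, rec$variant_id)
        sim$exposure$records <- rec
        exposure_paths[i] <- file.path(out_dir, sprintf("exposure%d.tsv", i))
        write_summary_stats(sim$exposure, exposure_paths[i])
        ld_ids <- c(ld_ids, rec$variant_id)
        exposure_panel <- sim # reused for both outcomes below
      }
      out_rec <- exposure_panel$outcome$records
      out_rec$variant_id <- sprintf("e%d_%s", i,
                                    exposure_panel$outcome$records$variant_id)
      if (j == 2) {
        # independent outcome noise for the second outcome dataset
        set.seed(derive_seed(seed, sprintf("out2_%d", i)))
        tr <- exposure_panel$truth
        out_rec$beta <- 0.3 * unname(tr$gamma) +
          stats::rnorm(nrow(out_rec), 0, out_rec$se)
        out_rec$pval <- 2 * stats::pnorm(-abs(out_rec$beta) / out_rec$se)
      }
      outcome_tabs[[j]][[i]] <- out_rec
    }
  }
  outcome_paths <- character(2)
  for (j in 1:2) {
    tab <- do.call(rbind, outcome_tabs[[j]])
    ss <- summary_stats(tab, sprintf("outcome%d", j))
    outcome_paths[j] <- file.path(out_dir, sprintf("outcome%d.tsv", j))
    write_summary_stats(ss, outcome_paths[j])
  }
  write_ld_matrix(ld_matrix(diag(length(ld_ids)), ld_ids),
                  file.path(out_dir, "ld.tsv"))

  eq <- simulate_eqtl_catalog(n_genes = n_genes, seed = derive_seed(seed, "eqtl"))
  cat_dir <- file.path(out_dir, "eqtl")
  dir.create(cat_dir, showWarnings = FALSE)
  for (g in names(eq$catalog))
    write_summary_stats(eq$catalog[[g]], file.path(cat_dir, paste0(g, ".tsv")))
  write_summary_stats(eq$outcome, file.path(out_dir, "eqtl_outcome.tsv"))

  tf_specs <- list(
    list(tf_id = "G491", target_ids = sprintf("G%d", 101:115),
         effect_strength = 1, group_effect = 1),
    list(tf_id = "G492", target_ids = sprintf("G%d", 121:135),
         effect_strength = 1))
  cell_specs <- list(
    list(cell_type = "T_cell", genes = sprintf("G%d", 141:155),
         abundance = c(active = 1, inactive = 0, control = 0)),
    list(cell_type = "B_cell", genes = sprintf("G%d", 161:175),
         abundance = c(active = 0, inactive = 0, control = 0)))
  ecfg <- expr_sim_config(n_genes = 500, tf_specs = tf_specs,
                          cell_specs = cell_specs,
                          seed = derive_seed(seed, "expr"))
  esim <- simulate_expression(ecfg)
  write_expression(esim$study, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "phenotype.tsv"))
  writeLines(vapply(tf_specs, `[[`, character(1), "tf_id"),
             file.path(out_dir, "tfs.txt"))
  write_gmt(gene_set_collection(list(
    planted_pathway = sprintf("G%d", 1:20),
    null_pathway = sprintf("G%d", 301:320))),
    file.path(out_dir, "pathways.gmt"))
  sig_sets <- list(T_cell_sig1 = sprintf("G%d", 141:148),
                   T_cell_sig2 = sprintf("G%d", 148:155),
                   B_cell_sig1 = sprintf("G%d", 161:168),
                   B_cell_sig2 = sprintf("G%d", 168:175))
  write_gmt(gene_set_collection(sig_sets), file.path(out_dir, "signatures.gmt"))
  cellmap <- data.frame(signature = names(sig_sets),
                        cell_type = c("T_cell", "T_cell", "B_cell", "B_cell"))
  utils::write.table(cellmap, file.path(out_dir, "cellmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- matrix(c(1, 0.1, 0.1, 1), 2, 2,
               dimnames = list(c("B_cell", "T_cell"), c("B_cell", "T_cell")))
  write_spillover(sp, file.path(out_dir, "spillover.tsv"))
  jsonlite::write_json(list(eqtl_truth = eq$truth, expr_truth = esim$truth),
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  config <- list(seed = seed,
                 exposures = exposure_paths, outcomes = outcome_paths,
                 ld = file.path(out_dir, "ld.tsv"),
                 expression = file.path(out_dir, "expression.tsv"),
                 phenotype = file.path(out_dir, "phenotype.tsv"),
                 catalog_dir = cat_dir,
                 qtl_outcome = file.path(out_dir, "eqtl_outcome.tsv"),
                 pathway_gmt = file.path(out_dir, "pathways.gmt"),
                 signature_gmt = file.path(out_dir, "signatures.gmt"),
                 cellmap = file.path(out_dir, "cellmap.tsv"),
                 spillover = file.path(out_dir, "spillover.tsv"),
                 tfs = file.path(out_dir, "tfs.txt"),
                 out_dir = file.path(out_dir, "results"))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config)
}
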