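`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column dialects for summary-statistics tables
#'
#' A dialect maps the internal field names (`variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the column headers
#' found on disk. Two named dialects ship with the package: `"plain"`
#' (internal names used verbatim) and `"ieu"` (IEU OpenGWAS-style exports:
#' `SNP`, `samplesize`, ...). Unknown columns in a file are ignored.
#'
#' @param name dialect name, or a named character vector giving a custom map.
#' @return named character vector mapping internal field -> file column.
#' @export
sumstats_dialect <- function(name = "plain") {
  dialects <- list(
    plain = c(variant_id = "variant_id", effect_allele = "effect_allele",
              other_allele = "other_allele", eaf = "eaf", beta = "beta",
              se = "se", pval = "pval", n = "n"),
    ieu = c(variant_id = "SNP", effect_allele = "effect_allele",
            other_allele = "other_allele", eaf = "eaf", beta = "beta",
            se = "se", pval = "pval", n = "samplesize")
  )
  if (is.character(name) && length(name) == 1L && name %in% names(dialects))
    return(dialects[[name]])
  if (is.character(name) && !is.null(names(name))) return(name)
  stop("unknown dialect: ", paste(name, collapse = ", "))
}

.sumstats_fields <- c("variant_id", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n")

#' Construct a validated summary-statistics object
#'
#' Rows violating the record invariants (se > 0, p in (0,1], eaf in (0,1) or
#' missing, distinct A/C/G/T alleles, finite beta, unique variant id) are
#' dropped with a warning that reports the count; alleles are upper-cased.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `eaf`, `n`.
#' @param trait_id identifier of the trait the table describes.
#' @return object of class `summary_stats` with elements `trait_id` and
#'   `records`.
#' @export
summary_stats <- function(records, trait_id) {
  stopifnot(is.data.frame(records), is.character(trait_id), length(trait_id) == 1L)
  req <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[.sumstats_fields]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])

  ok <- !is.na(records$variant_id) & nzchar(records$variant_id) &
    records$effect_allele %in% c("A", "C", "G", "T") &
    records$other_allele %in% c("A", "C", "G", "T") &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1))
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(records$variant_id) & ok
  n_drop <- sum(!ok) + sum(dup)
  if (n_drop > 0)
    warning(sprintf("summary_stats('%s'): dropped %d invalid row(s) (%d failed validation, %d duplicate ids)",
                    trait_id, n_drop, sum(!ok), sum(dup)))
  records <- records[ok & !dup, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("summary_stats('", trait_id, "'): zero valid rows")
  rownames(records) <- NULL
  structure(list(trait_id = trait_id, records = records),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s': %d variants\n",
              x$trait_id, nrow(x$records)))
  print(utils::head(x$records, 4))
  invisible(x)
}

#' Read a summary-statistics table
#'
#' @param path TSV file with a header row.
#' @param dialect dialect name or named map, see [sumstats_dialect()].
#' @param trait_id trait identifier; default is the file name sans extension.
#' @param or_scale if `TRUE` the beta column holds odds ratios and is stored
#'   as `log(value)` (binary-trait effects are kept as log-odds internally).
#' @return a [summary_stats()] object.
#' @export
read_summary_stats <- function(path, dialect = "plain", trait_id = NULL,
                               or_scale = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- sumstats_dialect(dialect)
  # colClasses: an all-"T" allele column would otherwise parse as logical
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (f in c("eaf", "beta", "se", "pval", "n")) {
    col <- map[[f]]
    if (col %in% names(tab))
      tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  req <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (f in req) {
    if (!map[[f]] %in% names(tab))
      stop("required column '", map[[f]], "' (field ", f, ") not found in ", path)
  }
  out <- data.frame(variant_id = tab[[map[["variant_id"]]]],
                    effect_allele = tab[[map[["effect_allele"]]]],
                    other_allele = tab[[map[["other_allele"]]]],
                    beta = tab[[map[["beta"]]]],
                    se = tab[[map[["se"]]]],
                    pval = tab[[map[["pval"]]]],
                    stringsAsFactors = FALSE)
  out$eaf <- if (map[["eaf"]] %in% names(tab)) tab[[map[["eaf"]]]] else NA_real_
  out$n <- if (map[["n"]] %in% names(tab)) tab[[map[["n"]]]] else NA_real_
  if (or_scale) out$beta <- log(as.numeric(out$beta))
  summary_stats(out, trait_id %||% sub("\\.[^.]*$", "", basename(path)))
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a summary-statistics table (plain dialect, full precision)
#'
#' `read_summary_stats(write_summary_stats(x))` reproduces `x` exactly;
#' missing `eaf`/`n` are serialized as `NA`.
#'
#' @param stats a [summary_stats()] object.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats$records) == 0L) stop("refusing to write empty summary_stats")
  rec <- stats$records
  for (col in c("eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- .fmt_num(rec[[col]])
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are de-duplicated with a warning; lines with fewer than three fields
#' are an error naming the line number.
#'
#' @param path GMT file.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " ('", parts[[1]], "'): duplicated genes de-duplicated")
      genes <- unique(genes)
    }
    sets[[parts[[1]]]] <- genes
    desc[[parts[[1]]]] <- parts[[2]]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors (each non-empty, unique).
#' @param descriptions optional named character vector of descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    for (nm in names(sets)) {
      if (length(sets[[nm]]) == 0L) stop("gene set '", nm, "' is empty")
      if (anyDuplicated(sets[[nm]])) stop("gene set '", nm, "' has duplicate genes")
    }
  }
  structure(list(sets = sets,
                 descriptions = descriptions %||%
                   stats::setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read an expression study (matrix + phenotype labels)
#'
#' @param path TSV, genes in rows (first column gene id), samples in columns.
#' @param phenotype_path two-column TSV `sample_id<TAB>phenotype` with header;
#'   phenotypes are `active`, `inactive` or `control`. Sample sets of the two
#'   files must match exactly.
#' @return object of class `expression_study`: list with `values` (numeric
#'   matrix, genes x samples) and `phenotype` (named character).
#' @export
read_expression <- function(path, phenotype_path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(phenotype_path)) stop("no such file: ", phenotype_path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at gene '", gene_ids[bad[[1]]],
         "', sample '", colnames(vals)[bad[[2]]], "'")
  }
  rownames(vals) <- gene_ids
  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  phenotype <- stats::setNames(as.character(ph[[2]]), as.character(ph[[1]]))
  expression_study(vals, phenotype)
}

#' Construct an expression study
#' @param values numeric matrix genes x samples with dimnames.
#' @param phenotype named character vector sample -> label.
#' @export
expression_study <- function(values, phenotype) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(values))) stop("gene ids are not unique")
  extra_ph <- setdiff(names(phenotype), colnames(values))
  extra_sm <- setdiff(colnames(values), names(phenotype))
  if (length(extra_ph))
    stop("phenotype file has sample(s) absent from matrix: ",
         paste(extra_ph, collapse = ", "))
  if (length(extra_sm))
    stop("matrix sample(s) without phenotype: ", paste(extra_sm, collapse = ", "))
  structure(list(values = values,
                 phenotype = phenotype[colnames(values)]),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$phenotype)),
                            table(x$phenotype)), collapse = ", ")))
  invisible(x)
}

#' Write an expression study to a matrix TSV + phenotype TSV
#' @param study an [expression_study()].
#' @param path matrix output path.
#' @param phenotype_path phenotype output path.
#' @export
write_expression <- function(study, path, phenotype_path) {
  stopifnot(inherits(study, "expression_study"))
  tab <- data.frame(gene_id = rownames(study$values),
                    study$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample_id = names(study$phenotype),
                   phenotype = unname(study$phenotype))
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Construct an LD matrix (pairwise squared correlations)
#'
#' @param values square symmetric numeric matrix, unit diagonal, entries in
#'   \[0, 1\].
#' @param variant_ids ids for rows/columns; defaults to existing dimnames.
#' @return classed matrix `ld_matrix`.
#' @export
ld_matrix <- function(values, variant_ids = rownames(values)) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(variant_ids)) stop("variant ids required")
  dimnames(values) <- list(variant_ids, variant_ids)
  if (any(values < 0 | values > 1)) stop("LD r^2 values must lie in [0, 1]")
  if (max(abs(values - t(values))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  structure(values, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from TSV (header row and first column hold variant ids)
#' @param path input path.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(tab))
}

#' Write an LD matrix as TSV
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  tab <- data.frame(variant_id = rownames(ld), unclass(ld),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a signature collection (signatures tied to cell types)
#' @param signatures named list of gene vectors.
#' @param cell_of named character vector signature -> cell type; every
#'   signature must map to exactly one cell type.
#' @export
signature_collection <- function(signatures, cell_of) {
  gsc <- gene_set_collection(signatures)
  miss <- setdiff(names(gsc$sets), names(cell_of))
  if (length(miss))
    stop("signature(s) without a cell type: ", paste(miss, collapse = ", "))
  structure(list(signatures = gsc$sets,
                 cell_of = cell_of[names(gsc$sets)]),
            class = "signature_collection")
}

#' Read a signature collection: GMT of signatures plus a cell-type map
#' @param gmt_path GMT file of signatures.
#' @param cellmap_path two-column TSV `signature<TAB>cell_type` with header.
#' @export
read_signatures <- function(gmt_path, cellmap_path) {
  gsc <- read_gmt(gmt_path)
  map <- utils::read.delim(cellmap_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  signature_collection(gsc$sets,
                       stats::setNames(as.character(map[[2]]),
                                       as.character(map[[1]])))
}

#' Read a spillover matrix (square, cell types on both axes)
#' @param path TSV with header row and first column of cell types.
#' @export
read_spillover <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("spillover matrix must be square")
  m
}

#' Write a spillover matrix
#' @param m square matrix with cell-type dimnames.
#' @param path output path.
#' @export
write_spillover <- function(m, path) {
  tab <- data.frame(cell_type = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
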