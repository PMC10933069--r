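# Instrument selection and harmonization for two-sample MR: merge exposure
# and outcome tables onto a common effect allele, then apply the selection
# pipeline (outcome-association removal first, p-value threshold with
# fallback tier, LD clumping, F filter, confounder exclusion list).

.PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")
.PALINDROME_EAF_WINDOW <- c(0.42, 0.58)

#' First-stage F statistic of an instrument
#'
#' Instrument strength is measured as `F = (beta / se)^2`; variants with
#' F < 10 are conventionally considered weak.
#'
#' @param beta exposure effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return numeric F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

.new_harmonized_set <- function(exposure_id, outcome_id, records, audit) {
  rownames(records) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 records = records, audit = audit),
            class = "harmonized_set")
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor used by simulations and tests when both tables
#' are already expressed on the same effect allele.
#'
#' @param variant_id,beta_exposure,se_exposure,beta_outcome,se_outcome
#'   aligned vectors.
#' @param pval_exposure,pval_outcome optional; derived from normal theory
#'   when omitted.
#' @param exposure_id,outcome_id trait labels.
#' @export
harmonized_set <- function(variant_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome,
                           pval_exposure = NULL, pval_outcome = NULL,
                           exposure_id = "exposure", outcome_id = "outcome") {
  n <- length(variant_id)
  beta_exposure <- rep_len(beta_exposure, n)
  se_exposure <- rep_len(se_exposure, n)
  beta_outcome <- rep_len(beta_outcome, n)
  se_outcome <- rep_len(se_outcome, n)
  if (!is.null(pval_exposure)) pval_exposure <- rep_len(pval_exposure, n)
  if (!is.null(pval_outcome)) pval_outcome <- rep_len(pval_outcome, n)
  stopifnot(all(se_exposure > 0), all(se_outcome > 0))
  records <- data.frame(
    variant_id = as.character(variant_id),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    pval_exposure = pval_exposure %||%
      (2 * stats::pnorm(-abs(beta_exposure) / se_exposure)),
    pval_outcome = pval_outcome %||%
      (2 * stats::pnorm(-abs(beta_outcome) / se_outcome)),
    stringsAsFactors = FALSE)
  records$f_stat <- f_statistic(records$beta_exposure, records$se_exposure)
  audit <- data.frame(stage = character(), dropped = integer(),
                      reason = character(), stringsAsFactors = FALSE)
  .new_harmonized_set(exposure_id, outcome_id, records, audit)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variants\n",
              x$exposure_id, x$outcome_id, nrow(x$records)))
  if (nrow(x$audit)) {
    cat("audit:\n")
    print(x$audit)
  }
  invisible(x)
}

.audit_row <- function(stage, dropped, reason) {
  data.frame(stage = stage, dropped = as.integer(dropped), reason = reason,
             stringsAsFactors = FALSE)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Variants are merged on `variant_id`. When the outcome's effect allele
#' equals the exposure's other allele (and vice versa) the outcome beta is
#' negated and its allele frequency complemented. Palindromic variants (A/T
#' or C/G) are dropped when either table's effect-allele frequency is
#' missing or falls in the ambiguity window \[0.42, 0.58\]; variants whose
#' alleles cannot be reconciled are dropped. Every drop is audited.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @return a `harmonized_set` (pre-filter; run [select_instruments()] next).
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- exposure$records
  out <- outcome$records
  shared <- intersect(ex$variant_id, out$variant_id)
  if (length(shared) == 0L)
    stop("no shared variants between '", exposure$trait_id, "' and '",
         outcome$trait_id, "'")
  audit <- .audit_row("merge", nrow(ex) - length(shared),
                      "absent_from_outcome")
  ex <- ex[match(shared, ex$variant_id), ]
  out <- out[match(shared, out$variant_id), ]

  same <- out$effect_allele == ex$effect_allele &
    out$other_allele == ex$other_allele
  flipped <- out$effect_allele == ex$other_allele &
    out$other_allele == ex$effect_allele
  mismatched <- !(same | flipped)

  beta_out <- ifelse(flipped, -out$beta, out$beta)
  eaf_out <- ifelse(flipped, 1 - out$eaf, out$eaf)

  pal <- paste(ex$effect_allele, ex$other_allele, sep = "/") %in% .PALINDROMIC
  eaf_ambiguous <- function(eaf) {
    is.na(eaf) | (eaf >= .PALINDROME_EAF_WINDOW[1] &
                    eaf <= .PALINDROME_EAF_WINDOW[2])
  }
  pal_drop <- pal & (eaf_ambiguous(ex$eaf) | eaf_ambiguous(eaf_out))

  keep <- !mismatched & !pal_drop
  audit <- rbind(audit,
                 .audit_row("allele_mismatch", sum(mismatched),
                            "irreconcilable_alleles"),
                 .audit_row("palindromic", sum(pal_drop & !mismatched),
                            "ambiguous_palindromic"))
  records <- data.frame(
    variant_id = ex$variant_id[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    beta_outcome = beta_out[keep], se_outcome = out$se[keep],
    pval_exposure = ex$pval[keep], pval_outcome = out$pval[keep],
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    stop("no usable variants remain after harmonization of '",
         exposure$trait_id, "' and '", outcome$trait_id, "'")
  records$f_stat <- f_statistic(records$beta_exposure, records$se_exposure)
  .new_harmonized_set(exposure$trait_id, outcome$trait_id, records, audit)
}

.ld_r2 <- function(ld, id_a, id_b) {
  if (is.null(ld)) return(0)
  if (!(id_a %in% rownames(ld)) || !(id_b %in% rownames(ld))) return(0)
  ld[id_a, id_b]
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the lowest exposure p-value
#' and discards all remaining variants with r^2 above `r2_max` to it. Ties
#' in p-value are broken by lexicographic variant id, so the result is
#' independent of input row order.
#'
#' @param h a `harmonized_set`.
#' @param ld an [ld_matrix()] (pairs absent from it are treated as unlinked,
#'   logged once).
#' @param r2_max clumping threshold on squared correlation.
#' @return clumped `harmonized_set` with an audit entry.
#' @export
clump <- function(h, ld, r2_max) {
  stopifnot(inherits(h, "harmonized_set"))
  rec <- h$records
  if (nrow(rec) <= 1L) return(h)
  if (!is.null(ld)) {
    absent <- setdiff(rec$variant_id, rownames(ld))
    if (length(absent))
      message("clump: ", length(absent),
              " variant(s) absent from LD matrix treated as unlinked")
  }
  ord <- order(rec$pval_exposure, rec$variant_id)
  rec <- rec[ord, ]
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(rec)) {
      for (j in seq(i + 1L, nrow(rec))) {
        if (alive[j] &&
            .ld_r2(ld, rec$variant_id[i], rec$variant_id[j]) > r2_max)
          alive[j] <- FALSE
      }
    }
  }
  dropped <- nrow(rec) - sum(keep)
  out <- rec[keep, ]
  out <- out[order(match(out$variant_id, h$records$variant_id)), ]
  .new_harmonized_set(h$exposure_id, h$outcome_id, out,
                      rbind(h$audit, .audit_row("clump", dropped,
                                                sprintf("r2>%g", r2_max))))
}

#' Select instruments per the trait-level criteria
#'
#' Pipeline order: (1) remove variants directly associated with the outcome
#' (`pval_outcome < p_outcome_max`); (2) keep variants passing the primary
#' exposure threshold and clump; (3) if fewer than `min_iv` survive, restart
#' step 2 from the post-step-1 candidates with the fallback
#' threshold/clumping pair; (4) drop weak instruments (F < `f_min`);
#' (5) drop ids on the confounder exclusion list (local stand-in for a
#' Phenoscanner screen). Each stage is audited; input count equals output
#' count plus the stage drops.
#'
#' @param h pre-filter `harmonized_set` from [harmonize()].
#' @param ld [ld_matrix()] covering the candidates (absent pairs unlinked).
#' @param p_primary,r2_primary primary exposure threshold and clumping r^2.
#' @param p_fallback,r2_fallback fallback tier engaged below `min_iv`.
#' @param min_iv minimum instrument count before the fallback engages.
#' @param p_outcome_max outcome-association removal threshold.
#' @param f_min minimum F statistic.
#' @param exclusion_list variant ids excluded as potential confounder proxies.
#' @param fallback if `FALSE` the fallback tier is disabled (per-gene screen).
#' @return filtered `harmonized_set`; error if nothing survives.
#' @export
select_instruments <- function(h, ld = NULL, p_primary = 5e-8,
                               p_fallback = 5e-6, r2_primary = 0.001,
                               r2_fallback = 0.01, min_iv = 20,
                               p_outcome_max = 5e-6, f_min = 10,
                               exclusion_list = character(),
                               fallback = TRUE) {
  stopifnot(inherits(h, "harmonized_set"))
  audit <- h$audit
  rec <- h$records

  out_assoc <- rec$pval_outcome < p_outcome_max
  audit <- rbind(audit, .audit_row("outcome_associated", sum(out_assoc),
                                   sprintf("p_outcome<%g", p_outcome_max)))
  rec <- rec[!out_assoc, ]
  candidates <- .new_harmonized_set(h$exposure_id, h$outcome_id, rec,
                                    audit[0, ])

  tier <- function(cand, p_thr, r2_thr) {
    pass <- cand$records$pval_exposure < p_thr
    a <- .audit_row("exposure_threshold", sum(!pass),
                    sprintf("p_exposure>=%g", p_thr))
    sel <- .new_harmonized_set(cand$exposure_id, cand$outcome_id,
                               cand$records[pass, ], a)
    clump(sel, ld, r2_thr)
  }

  sel <- tier(candidates, p_primary, r2_primary)
  used_fallback <- FALSE
  if (fallback && nrow(sel$records) < min_iv) {
    used_fallback <- TRUE
    sel <- tier(candidates, p_fallback, r2_fallback)
  }
  audit <- rbind(audit, sel$audit)
  if (used_fallback)
    audit <- rbind(audit, .audit_row("fallback", 0L,
                                     sprintf("fallback engaged (<%d IVs at primary tier)",
                                             min_iv)))
  rec <- sel$records

  weak <- rec$f_stat < f_min
  audit <- rbind(audit, .audit_row("weak_instrument", sum(weak),
                                   sprintf("F<%g", f_min)))
  rec <- rec[!weak, ]

  excl <- rec$variant_id %in% exclusion_list
  audit <- rbind(audit, .audit_row("exclusion_list", sum(excl),
                                   "confounder_exclusion"))
  rec <- rec[!excl, ]

  if (nrow(rec) == 0L)
    stop("no instruments survive selection for '", h$exposure_id,
         "' -> '", h$outcome_id,
         "'; consider relaxing thresholds (p_fallback/r2_fallback)")
  .new_harmonized_set(h$exposure_id, h$outcome_id, rec, audit)
}
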