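# Causal estimators and pleiotropy diagnostics: Wald ratio, fixed-effect
# IVW, MR-Egger, Cochran's Q, MR-PRESSO (global / outlier / distortion),
# and leave-one-out. Effects are log-odds throughout; odds ratios are
# derived at reporting time as exp(beta).

.mr_result <- function(method, beta, se, n_snps) {
  z <- beta / se
  structure(list(method = method, beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(z)),
                 or_ = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n_snps = as.integer(n_snps)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s (%d SNPs): beta=%.4g se=%.4g p=%.3g OR=%.4g [%.4g, %.4g]\n",
              x$method, x$n_snps, x$beta, x$se, x$pval, x$or_,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             pval = x$pval, or_ = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

.records_of <- function(h) {
  if (inherits(h, "harmonized_set")) h$records else h
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_outcome / beta_exposure` with first-order delta-method
#' standard error `|se_outcome / beta_exposure|` and a two-sided normal p.
#'
#' @param r one-row harmonized record (or a `harmonized_set` of size 1).
#' @return an `mr_result`.
#' @export
wald_ratio <- function(r) {
  rec <- .records_of(r)
  stopifnot(nrow(rec) == 1L)
  if (rec$beta_exposure == 0) stop("wald_ratio undefined: beta_exposure is 0")
  beta <- rec$beta_outcome / rec$beta_exposure
  se <- abs(rec$se_outcome / rec$beta_exposure)
  .mr_result("wald_ratio", beta, se, 1L)
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' `beta = sum(bx * by * w) / sum(bx^2 * w)` with `w = 1 / se_y^2` and
#' `se = 1 / sqrt(sum(bx^2 * w))` — the zero-intercept weighted least
#' squares of outcome on exposure betas. With a single record this reduces
#' exactly to the Wald ratio. A multiplicative random-effects variant
#' (`overdispersion = TRUE`) scales the SE by `max(1, RSE)`.
#'
#' @param h a `harmonized_set` (or its records data.frame), >= 1 record.
#' @param overdispersion inflate SE under heterogeneity (off by default; the
#'   fixed-effect estimator is the primary).
#' @return an `mr_result` with method `"ivw"` (or `"wald_ratio"` for K = 1).
#' @export
ivw <- function(h, overdispersion = FALSE) {
  rec <- .records_of(h)
  if (nrow(rec) == 0L) stop("ivw requires at least one record")
  if (any(rec$se_outcome <= 0)) stop("all se_outcome must be > 0")
  if (nrow(rec) == 1L) return(wald_ratio(rec))
  w <- 1 / rec$se_outcome^2
  s2 <- sum(rec$beta_exposure^2 * w)
  beta <- sum(rec$beta_exposure * rec$beta_outcome * w) / s2
  se <- 1 / sqrt(s2)
  if (overdispersion) {
    rss <- sum(w * (rec$beta_outcome - beta * rec$beta_exposure)^2)
    se <- se * max(1, sqrt(rss / (nrow(rec) - 1)))
  }
  .mr_result("ivw", beta, se, nrow(rec))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept (weights `1 / se_y^2`). Coefficient variances carry a
#' multiplicative overdispersion factor `max(1, RSE^2)`; the intercept p
#' tests directional pleiotropy. Two-sided normal p-values.
#'
#' @param h a `harmonized_set` with >= 3 records.
#' @return list with `slope` (an `mr_result`, method `"egger_slope"`) and
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
egger <- function(h) {
  rec <- .records_of(h)
  if (nrow(rec) < 3L) stop("egger requires at least 3 records")
  w <- 1 / rec$se_outcome^2
  x <- cbind(1, rec$beta_exposure)
  xtwx <- crossprod(x, w * x)
  coefs <- solve(xtwx, crossprod(x, w * rec$beta_outcome))
  resid <- rec$beta_outcome - x %*% coefs
  sigma2 <- sum(w * resid^2) / (nrow(rec) - 2)
  vc <- solve(xtwx) * max(1, sigma2)
  slope <- .mr_result("egger_slope", coefs[2], sqrt(vc[2, 2]), nrow(rec))
  intercept_se <- sqrt(vc[1, 1])
  list(slope = slope,
       intercept = coefs[1], intercept_se = intercept_se,
       intercept_p = 2 * stats::pnorm(-abs(coefs[1] / intercept_se)))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_k * (ratio_k - beta_ivw)^2)` with `w_k = bx_k^2 / se_y_k^2`
#' and `ratio_k = by_k / bx_k`; chi-square p on K - 1 df.
#'
#' @param h a `harmonized_set` with >= 2 records.
#' @return list `(q, df, pval)`.
#' @export
cochran_q <- function(h) {
  rec <- .records_of(h)
  if (nrow(rec) < 2L) stop("cochran_q requires at least 2 records")
  fit <- ivw(rec)
  wk <- rec$beta_exposure^2 / rec$se_outcome^2
  ratios <- rec$beta_outcome / rec$beta_exposure
  q <- sum(wk * (ratios - fit$beta)^2)
  df <- nrow(rec) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

# Leave-one-out IVW betas for observed or simulated outcome vectors.
# by may be a matrix (n_sim x K); returns a matrix of the same shape whose
# [s, k] entry is the IVW beta computed from row s with variant k removed.
.loo_betas <- function(bx, by, w) {
  if (is.null(dim(by))) by <- matrix(by, nrow = 1)
  s2 <- sum(bx^2 * w)
  s1 <- by %*% (bx * w)
  num <- sweep(sweep(by, 2, bx * w, `*`), 1, as.vector(s1), function(a, b) b - a)
  den <- s2 - bx^2 * w
  sweep(num, 2, den, `/`)
}

#' MR-PRESSO pleiotropy residual sum of squares test
#'
#' Global test: the observed (weighted) residual sum of squares of
#' leave-one-out-predicted outcome betas is ranked within its simulated
#' null distribution, where simulated outcome betas are drawn as
#' `Normal(beta_ivw_minus_k * bx_k, se_y_k)`. Outlier test: per-variant
#' observed squared standardized residual versus its simulated counterpart,
#' Bonferroni-adjusted. Distortion test: relative change of the IVW
#' estimate after outlier removal, referenced to random same-size removals.
#' Deterministic given `seed`.
#'
#' @param h a `harmonized_set` with >= 4 records (>= 5 for distortion).
#' @param n_sim number of simulated null datasets.
#' @param alpha_outlier threshold on the Bonferroni-adjusted outlier p.
#' @param seed integer seed (required for reproducibility).
#' @return list with `presso_global_p`, `presso_outliers` (variant ids),
#'   `presso_distortion_p` (NA when no outliers or K < 5), and the
#'   outlier-corrected `mr_result` (`corrected`, NULL when no outliers).
#' @export
mr_presso <- function(h, n_sim = 1000, alpha_outlier = 0.05, seed = 1) {
  rec <- .records_of(h)
  k <- nrow(rec)
  if (k < 4L) stop("mr_presso requires at least 4 records")
  set.seed(seed)
  bx <- rec$beta_exposure; by <- rec$beta_outcome; sy <- rec$se_outcome
  w <- 1 / sy^2
  loo_obs <- as.vector(.loo_betas(bx, by, w))
  res_obs <- ((by - loo_obs * bx) / sy)^2
  rss_obs <- sum(res_obs)

  by_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(loo_obs * bx, each = n_sim),
                                sd = rep(sy, each = n_sim)), n_sim, k)
  loo_sim <- .loo_betas(bx, by_sim, w)
  res_sim <- sweep(by_sim - loo_sim * sweep(matrix(1, n_sim, k), 2, bx, `*`),
                   2, sy, `/`)^2
  rss_sim <- rowSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)

  p_var <- (1 + colSums(sweep(res_sim, 2, res_obs, `>=`))) / (1 + n_sim)
  p_adj <- pmin(1, p_var * k)
  outliers <- rec$variant_id[p_adj < alpha_outlier]

  distortion_p <- NA_real_
  corrected <- NULL
  if (length(outliers) > 0 && k >= 5L && length(outliers) < k - 1L) {
    beta_all <- ivw(rec)$beta
    keep <- !(rec$variant_id %in% outliers)
    corrected <- ivw(rec[keep, ])
    d_obs <- (beta_all - corrected$beta) / abs(corrected$beta)
    nb <- length(outliers)
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop_idx <- sample.int(k, nb)
      b <- ivw(rec[-drop_idx, ])$beta
      (beta_all - b) / abs(b)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
  }
  list(presso_global_p = global_p, presso_outliers = outliers,
       presso_distortion_p = distortion_p, corrected = corrected)
}

#' Leave-one-out analysis
#'
#' One IVW fit per excluded variant, in input order.
#'
#' @param h a `harmonized_set` with >= 2 records.
#' @return data.frame (excluded, beta, se, pval).
#' @export
leave_one_out <- function(h) {
  rec <- .records_of(h)
  if (nrow(rec) < 2L) stop("leave_one_out requires at least 2 records")
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    fit <- ivw(rec[-i, ])
    data.frame(excluded = rec$variant_id[i], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full MR report: primary estimate plus all diagnostics
#'
#' The primary estimate is the fixed-effect IVW (Wald ratio when only one
#' instrument is available). Diagnostics below their minimum instrument
#' counts are skipped with a note.
#'
#' @param h a `harmonized_set`.
#' @param seed seed forwarded to [mr_presso()].
#' @param n_sim MR-PRESSO simulation count.
#' @return list with `primary` (`mr_result`), `pleiotropy` (Egger intercept,
#'   Cochran's Q, MR-PRESSO fields), `egger_slope`, `loo`, `notes`.
#' @export
full_mr_report <- function(h, seed = 1, n_sim = 1000) {
  rec <- .records_of(h)
  k <- nrow(rec)
  notes <- character()
  primary <- ivw(rec)
  pleio <- list(egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                egger_intercept_p = NA_real_, cochran_q = NA_real_,
                q_df = NA_integer_, q_pval = NA_real_,
                presso_global_p = NA_real_, presso_outliers = character(),
                presso_distortion_p = NA_real_)
  egger_slope <- NULL
  if (k >= 3L) {
    e <- egger(rec)
    egger_slope <- e$slope
    pleio$egger_intercept <- e$intercept
    pleio$egger_intercept_se <- e$intercept_se
    pleio$egger_intercept_p <- e$intercept_p
  } else notes <- c(notes, "egger skipped: fewer than 3 instruments")
  if (k >= 2L) {
    q <- cochran_q(rec)
    pleio$cochran_q <- q$q; pleio$q_df <- q$df; pleio$q_pval <- q$pval
  } else notes <- c(notes, "cochran_q skipped: fewer than 2 instruments")
  if (k >= 4L) {
    p <- mr_presso(rec, n_sim = n_sim, seed = seed)
    pleio$presso_global_p <- p$presso_global_p
    pleio$presso_outliers <- p$presso_outliers
    pleio$presso_distortion_p <- p$presso_distortion_p
  } else notes <- c(notes, "mr_presso skipped: fewer than 4 instruments")
  loo <- NULL
  if (k >= 2L) loo <- leave_one_out(rec)
  else notes <- c(notes, "leave_one_out skipped: fewer than 2 instruments")
  list(primary = primary, pleiotropy = pleio, egger_slope = egger_slope,
       loo = loo, notes = notes)
}
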