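make_ss <- function(ids, ea, oa, beta, se, pval, eaf = NA, trait = "t") {
  summary_stats(data.frame(variant_id = ids, effect_allele = ea,
                           other_allele = oa, beta = beta, se = se,
                           pval = pval, eaf = eaf,
                           stringsAsFactors = FALSE), trait)
}

test_that("f_statistic follows the (beta/se)^2 formula", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.05), 0)
  expect_equal(f_statistic(-0.05, 0.01), 25)  # sign-invariant
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("harmonize flips swapped alleles and drops ambiguous palindromes", {
  ex <- make_ss(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "T"),
                c(0.1, 0.1, 0.1), 0.02, 1e-10, eaf = c(0.3, 0.3, 0.50))
  out <- make_ss(c("rs1", "rs2", "rs3"), c("A", "G", "A"), c("G", "A", "T"),
                 c(0.2, 0.2, 0.2), 0.02, 0.5, eaf = c(0.3, 0.7, 0.50))
  h <- harmonize(ex, out)
  expect_equal(h$records$variant_id, c("rs1", "rs2"))
  expect_equal(h$records$beta_outcome, c(0.2, -0.2))  # rs2 sign-flipped
  expect_equal(sum(h$audit$dropped), 1)  # rs3 palindromic, eaf 0.5
  # palindrome with clear eaf is kept
  ex2 <- make_ss("rs9", "A", "T", 0.1, 0.02, 1e-10, eaf = 0.1)
  out2 <- make_ss("rs9", "A", "T", 0.05, 0.02, 0.5, eaf = 0.1)
  expect_equal(nrow(harmonize(ex2, out2)$records), 1)
  # palindrome with missing eaf is dropped -> empty intersection errors
  ex3 <- make_ss("rs9", "A", "T", 0.1, 0.02, 1e-10)
  expect_error(suppressWarnings(harmonize(ex3, out2)), "")
  expect_error(harmonize(ex, make_ss("zz1", "A", "G", 1, 1, 0.5)),
               "no shared variants")
})

test_that("clump keeps the most significant representative per LD cluster", {
  h <- harmonized_set(c("A", "B", "C"), c(0.2, 0.2, 0.2), 0.02,
                      c(0.1, 0.1, 0.1), 0.02,
                      pval_exposure = c(1e-12, 1e-10, 1e-8))
  ld_vals <- matrix(c(1, 0.5, 0, 0.5, 1, 0.5, 0, 0.5, 1), 3)
  ld <- ld_matrix(ld_vals, c("A", "B", "C"))
  # chain A-B r2=0.5, B-C r2=0.5, A-C r2=0: keep {A, C} at threshold 0.3
  res <- clump(h, ld, 0.3)
  expect_equal(sort(res$records$variant_id), c("A", "C"))
  # identity LD keeps everything
  expect_equal(nrow(clump(h, ld_matrix(diag(3), c("A", "B", "C")),
                          0.001)$records), 3)
  # pairwise r2=0.9: keep only the smaller p
  h2 <- harmonized_set(c("X", "Y"), c(0.2, 0.2), 0.02, c(0.1, 0.1), 0.02,
                       pval_exposure = c(1e-10, 1e-9))
  ld2 <- ld_matrix(matrix(c(1, .9, .9, 1), 2), c("X", "Y"))
  expect_equal(clump(h2, ld2, 0.3)$records$variant_id, "X")
})

test_that("clumping is independent of input row order (ties by id)", {
  set.seed(8)
  ids <- sprintf("rs%02d", 1:12)
  vals <- matrix(runif(144, 0, 0.4), 12); vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  ld <- ld_matrix(vals, ids)
  pv <- rep(c(1e-10, 1e-9, 1e-8), each = 4)  # deliberate ties
  h1 <- harmonized_set(ids, 0.2, 0.02, 0.1, 0.02, pval_exposure = pv)
  perm <- sample(12)
  h2 <- harmonized_set(ids[perm], 0.2, 0.02, 0.1, 0.02,
                       pval_exposure = pv[perm])
  expect_setequal(clump(h1, ld, 0.1)$records$variant_id,
                  clump(h2, ld, 0.1)$records$variant_id)
})

test_that("select_instruments applies the documented stage order", {
  k <- 30
  h <- harmonized_set(sprintf("rs%d", 1:k), rep(0.2, k), 0.02,
                      rep(0.05, k), 0.02,
                      pval_exposure = rep(1e-9, k),
                      pval_outcome = rep(0.5, k))
  ld <- ld_matrix(diag(k), sprintf("rs%d", 1:k))
  sel <- select_instruments(h, ld)
  expect_equal(nrow(sel$records), 30)  # all strong, unlinked, significant
  # outcome-associated variants are removed first
  h2 <- h; h2$records$pval_outcome[1:3] <- 1e-8
  sel2 <- select_instruments(h2, ld)
  expect_equal(nrow(sel2$records), 27)
  expect_equal(sel2$audit$dropped[sel2$audit$stage == "outcome_associated"], 3L)
  # F = 9 dropped (beta/se = 3)
  h3 <- h; h3$records$beta_exposure[5] <- 0.06; h3$records$f_stat[5] <- 9
  sel3 <- select_instruments(h3, ld)
  expect_false("rs5" %in% sel3$records$variant_id)
  # exclusion list applied last
  sel4 <- select_instruments(h, ld, exclusion_list = c("rs7", "rs8"))
  expect_equal(nrow(sel4$records), 28)
  expect_error(select_instruments(h, ld, exclusion_list = sprintf("rs%d", 1:k)),
               "relaxing")
})

test_that("fallback tier engages below min_iv and is audited", {
  k <- 30
  pv <- c(rep(1e-9, 5), rep(1e-7, 25))  # 5 pass 5e-8, 30 pass 5e-6
  h <- harmonized_set(sprintf("rs%d", 1:k), 0.2, 0.02, 0.05, 0.02,
                      pval_exposure = pv, pval_outcome = rep(0.5, k))
  ld <- ld_matrix(diag(k), sprintf("rs%d", 1:k))
  sel <- select_instruments(h, ld)
  expect_equal(nrow(sel$records), 30)
  expect_true("fallback" %in% sel$audit$stage)
  # with min_iv = 3 the primary tier suffices
  sel2 <- select_instruments(h, ld, min_iv = 3)
  expect_equal(nrow(sel2$records), 5)
  expect_false("fallback" %in% sel2$audit$stage)
  # fallback disabled (per-gene mode)
  sel3 <- select_instruments(h, ld, fallback = FALSE)
  expect_equal(nrow(sel3$records), 5)
})

test_that("select_instruments is idempotent and audit-conserving", {
  set.seed(5)
  k <- 40
  h <- harmonized_set(sprintf("rs%d", 1:k), rnorm(k, 0.2, 0.1),
                      runif(k, 0.015, 0.05), rnorm(k, 0.05, 0.05),
                      runif(k, 0.015, 0.05),
                      pval_exposure = 10^runif(k, -12, -5),
                      pval_outcome = 10^runif(k, -7, 0))
  ld <- ld_matrix(diag(k), sprintf("rs%d", 1:k))
  sel <- select_instruments(h, ld)
  again <- select_instruments(sel, ld)
  expect_equal(again$records, sel$records)
  # conservation: input = output + stage drops recorded during selection
  new_stages <- setdiff(seq_len(nrow(sel$audit)), seq_len(nrow(h$audit)))
  expect_equal(nrow(h$records),
               nrow(sel$records) + sum(sel$audit$dropped[new_stages]))
})
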