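test_that("BH adjustment matches the brute-force oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(50)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
  st <- tiny_study(30, 12, seed = 2,
                   labels = rep(c("active", "inactive"), each = 6))
  de <- moderated_de(st)
  expect_equal(de$adj_pval, bh_oracle(de$pval))
  expect_true(all(de$adj_pval >= de$pval))
})

test_that("moderated variances are convex combinations (shrinkage)", {
  st <- tiny_study(80, 16, seed = 3,
                   labels = rep(c("active", "inactive"), each = 8))
  de <- moderated_de(st)
  eb <- attr(de, "eb")
  lo <- pmin(eb$s2, eb$s0_2); hi <- pmax(eb$s2, eb$s0_2)
  expect_true(all(eb$s2_post >= lo - 1e-12 & eb$s2_post <= hi + 1e-12))
})

test_that("flat genes give zero log-fc and t; bad contrasts error", {
  vals <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("G%d", 1:10), sprintf("S%d", 1:4)))
  vals[1, ] <- 5  # identical in both groups
  st <- expression_study(vals, setNames(rep(c("active", "inactive"), 2),
                                        colnames(vals)))
  de <- moderated_de(st)
  expect_equal(de$log_fc[de$gene_id == "G1"], 0)
  expect_equal(de$moderated_t[de$gene_id == "G1"], 0)
  expect_error(moderated_de(st, c("active", "nosuch")), "nosuch")
  # union contrast pools labels
  st2 <- tiny_study(10, 9, seed = 4,
                    labels = rep(c("active", "inactive", "control"), 3))
  expect_silent(moderated_de(st2, c("active+inactive", "control")))
})

test_that("moderated_de agrees with the limma oracle on ranks and effects", {
  st <- tiny_study(120, 12, seed = 9,
                   labels = rep(c("active", "inactive"), 6))
  de <- moderated_de(st)
  design <- model.matrix(~ 0 + factor(st$phenotype,
                                      c("active", "inactive")))
  colnames(design) <- c("active", "inactive")
  fit <- limma::lmFit(st$values, design)
  fit <- limma::contrasts.fit(fit,
                              limma::makeContrasts(active - inactive,
                                                   levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(de$log_fc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  # hyperparameter fitting differs; ranks and magnitudes must agree closely
  expect_gt(cor(de$moderated_t, fit$t[, 1]), 0.999)
  expect_gt(cor(rank(de$pval), rank(fit$p.value[, 1])), 0.99)
})

test_that("classification is a pure function of (or_, pval)", {
  set.seed(10)
  cat_ <- simulate_eqtl_catalog(n_genes = 25, frac_causal = 0.4, seed = 10)
  tab <- qtl_mr_screen(cat_$catalog, cat_$outcome)
  sig <- !is.na(tab$pval) & tab$pval < 0.05
  expect_true(all(tab$label[sig & tab$or_ > 1] == "risk"))
  expect_true(all(tab$label[sig & tab$or_ < 1] == "protective"))
  expect_true(all(tab$label[!sig] == "excluded"))
})

test_that("qtl screen recovers planted signs and handles edge genes", {
  cat_ <- simulate_eqtl_catalog(n_genes = 60, frac_causal = 0.5, seed = 2)
  tab <- qtl_mr_screen(cat_$catalog, cat_$outcome)
  truth <- cat_$truth
  causal <- truth$gene[truth$causal]
  called <- tab[match(causal, tab$gene_id), ]
  expected <- ifelse(truth$theta[truth$causal] > 0, "risk", "protective")
  agree <- mean(called$label == expected)
  expect_gte(agree, 0.9)
  expect_true(all(tab$method[tab$n_snps > 1] == "ivw"))
  # single-instrument gene uses the Wald ratio
  cat1 <- simulate_eqtl_catalog(n_genes = 5, snps_per_gene = 1, seed = 3)
  tab1 <- qtl_mr_screen(cat1$catalog, cat1$outcome)
  expect_true(all(tab1$method[tab1$label != "excluded"] == "wald_ratio"))
  # weak instrument -> excluded with reason
  weak <- cat1$catalog[1]
  weak[[1]]$records$beta <- weak[[1]]$records$se * 2  # F = 4
  weak[[1]]$records$pval <- 1e-9  # still "significant" but weak
  tabw <- qtl_mr_screen(weak, cat1$outcome)
  expect_equal(tabw$label, "excluded")
  expect_equal(tabw$reason, "weak_instrument")
})

test_that("null catalog yields ~5% raw-significant genes", {
  hits <- unlist(lapply(1:4, function(i) {
    cat_ <- simulate_eqtl_catalog(n_genes = 100, frac_causal = 0,
                                  seed = 400 + i)
    tab <- qtl_mr_screen(cat_$catalog, cat_$outcome)
    tab$label != "excluded"
  }))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("intersect_with_de annotates directions and cross-tabulates", {
  mr <- structure(data.frame(gene_id = c("G1", "G2", "G3"),
                             n_snps = 1L, method = "wald_ratio",
                             beta = c(0.5, -0.5, 0.2), se = 0.1,
                             or_ = exp(c(0.5, -0.5, 0.2)),
                             pval = c(0.01, 0.01, 0.5),
                             label = c("risk", "protective", "excluded"),
                             reason = NA_character_,
                             stringsAsFactors = FALSE),
                  class = c("gene_mr_table", "data.frame"))
  de <- data.frame(gene_id = c("G1", "G2"), log_fc = c(1.2, -0.4),
                   moderated_t = 0, pval = 0.01, adj_pval = 0.02)
  ann <- intersect_with_de(mr, de)
  expect_equal(ann$direction, c("up", "down", "na"))
  ct <- attr(ann, "crosstab")
  expect_equal(ct["risk", "up"], 1)
  expect_equal(ct["protective", "down"], 1)
  ann0 <- intersect_with_de(mr, de[0, ])
  expect_true(all(ann0$direction == "na"))
})

test_that("pqtl_verify flags concordance correctly", {
  cat_ <- simulate_eqtl_catalog(n_genes = 30, frac_causal = 0.5, seed = 6)
  etab <- qtl_mr_screen(cat_$catalog, cat_$outcome)
  # same catalog as proteins: fully self-concordant
  ptab <- pqtl_verify(cat_$catalog, cat_$outcome, eqtl_table = etab)
  sig <- ptab$label %in% c("risk", "protective")
  expect_true(all(ptab$concordant[sig]))
  expect_false(any(ptab$concordant[!sig]))
  # sign-flipped protein effects: discordant
  flipped <- lapply(cat_$catalog, function(ss) {
    ss$records$beta <- -ss$records$beta
    ss
  })
  outf <- cat_$outcome
  ftab <- pqtl_verify(flipped, outf, eqtl_table = etab)
  sigf <- ftab$label %in% c("risk", "protective") &
    etab$label[match(ftab$gene_id, etab$gene_id)] %in%
      c("risk", "protective")
  expect_false(any(ftab$concordant[sigf]))
  # empty catalog: empty table, no error
  empty <- pqtl_verify(list(), cat_$outcome)
  expect_equal(nrow(empty), 0)
})
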