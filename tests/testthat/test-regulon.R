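test_that("mutual information: identity, symmetry, oracle, errors", {
  set.seed(1)
  x <- rnorm(39)  # 39 divisible by 3: exact equal-frequency bins
  expect_equal(mutual_information(x, x), log(3), tolerance = 1e-12)
  y <- rnorm(39)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, y), 0)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(40); b <- 0.5 * a + rnorm(40)
    expect_equal(mutual_information(a, b, bins = 4), mi_oracle(a, b, 4),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(rnorm(10), rnorm(9)), "length mismatch")
  expect_error(mutual_information(rnorm(5), rnorm(5)), ">= 8")
})

test_that("MI approaches the bivariate-normal closed form", {
  set.seed(4)
  n <- 2000; rho <- 0.8
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  closed <- -0.5 * log(1 - rho^2)
  expect_lt(abs(mutual_information(x, y) - closed) / closed, 0.25)
})

test_that("independent vectors rarely beat their permutation null", {
  set.seed(6)
  hits <- replicate(40, {
    x <- rnorm(60); y <- rnorm(60)
    obs <- mutual_information(x, y)
    null <- replicate(200, mutual_information(sample(x), y))
    (1 + sum(null >= obs)) / 201 <= 0.05
  })
  expect_lte(mean(hits), 0.15)
})

planted_tf_study <- function(seed, n = 40, effect = 2, n_genes = 40) {
  cfg <- expr_sim_config(n_genes = n_genes, n_active = n / 2,
                         n_inactive = n / 2, n_control = 0,
                         risk_gene_ids = character(0),
                         protective_gene_ids = character(0),
                         tf_specs = list(list(
                           tf_id = sprintf("G%d", n_genes),
                           target_ids = sprintf("G%d", 1:8),
                           effect_strength = effect,
                           signs = c(1, 1, 1, 1, 1, 1, -1, -1))),
                         seed = seed)
  simulate_expression(cfg)$study
}

test_that("infer_regulons recovers a strongly planted regulon with signs", {
  st <- planted_tf_study(3)
  tf <- "G40"
  regs <- infer_regulons(st, tf, n_perm = 500, n_boot = 50, seed = 3)
  tg <- regs[[tf]]$targets
  expect_gte(length(intersect(tg$gene_id, sprintf("G%d", 1:8))), 6)
  expect_lte(length(setdiff(tg$gene_id, sprintf("G%d", 1:8))), 2)
  found_neg <- intersect(tg$gene_id, c("G7", "G8"))
  expect_true(all(tg$sign[tg$gene_id %in% found_neg] == -1))
  found_pos <- intersect(tg$gene_id, sprintf("G%d", 1:6))
  expect_true(all(tg$sign[tg$gene_id %in% found_pos] == 1))
})

test_that("inference is seed-deterministic and gene-order independent", {
  st <- planted_tf_study(5)
  r1 <- infer_regulons(st, "G40", n_perm = 300, n_boot = 30, seed = 9)
  r2 <- infer_regulons(st, "G40", n_perm = 300, n_boot = 30, seed = 9)
  expect_identical(r1, r2)
  perm <- sample(nrow(st$values))
  st_perm <- expression_study(st$values[perm, ], st$phenotype)
  r3 <- infer_regulons(st_perm, "G40", n_perm = 300, n_boot = 30, seed = 9)
  expect_identical(r1, r3)
})

test_that("dpi_tol = Inf disables pruning; pruning never adds edges", {
  set.seed(2)
  n <- 60
  tfv <- rnorm(n); y <- tfv + 0.5 * rnorm(n); z <- y + 0.5 * rnorm(n)
  x <- rbind(TF = tfv, YY = y, ZZ = z,
             matrix(rnorm(10 * n), 10, n,
                    dimnames = list(sprintf("N%d", 1:10), NULL)))
  colnames(x) <- sprintf("S%d", 1:n)
  st <- expression_study(x, setNames(rep(c("active", "inactive"), n / 2),
                                     colnames(x)))
  pruned <- infer_regulons(st, c("TF", "YY"), n_perm = 300, n_boot = 30,
                           seed = 4)
  unpruned <- infer_regulons(st, c("TF", "YY"), n_perm = 300, n_boot = 30,
                             seed = 4, dpi_tol = Inf)
  for (tf in c("TF", "YY")) {
    expect_true(all(pruned[[tf]]$targets$gene_id %in%
                      unpruned[[tf]]$targets$gene_id))
  }
  expect_error(infer_regulons(st, "NOPE", seed = 1), "NOPE")
  small <- expression_study(x[, 1:6], st$phenotype[1:6])
  expect_error(infer_regulons(small, "TF", seed = 1), ">= 8 samples")
})

test_that("regulon activity is extremal at the top and antisymmetric", {
  st <- tiny_study(20, 5, seed = 11)
  # sample 1: targets placed exactly at the top of the ranking
  top <- rownames(st$values)[order(-st$values[, 1])][1:4]
  reg <- list(structure(list(tf_id = "TFX",
                             targets = data.frame(gene_id = top, mi = 1,
                                                  sign = 1)),
                        class = "regulon"))
  act <- regulon_activity(st, reg)
  expect_equal(unname(which.max(act["TFX", ])), 1L)
  reg_neg <- reg
  reg_neg[[1]]$targets$sign <- -1
  act_neg <- regulon_activity(st, reg_neg)
  expect_equal(unclass(act_neg), -unclass(act), ignore_attr = TRUE)
  # regulon with no targets in study is skipped with warning
  reg2 <- c(reg, list(structure(list(tf_id = "TFY",
                                     targets = data.frame(gene_id = "ZZZ",
                                                          mi = 1, sign = 1)),
                                class = "regulon")))
  expect_warning(act2 <- regulon_activity(st, reg2), "TFY")
  expect_equal(rownames(act2), "TFX")
})

test_that("planted group-dependent TF separates groups in activity space", {
  hits <- vapply(1:10, function(i) {
    cfg <- expr_sim_config(n_genes = 60, n_active = 12, n_inactive = 12,
                           n_control = 0, risk_gene_ids = character(0),
                           protective_gene_ids = character(0),
                           tf_specs = list(list(tf_id = "G60",
                                                target_ids = sprintf("G%d", 1:10),
                                                effect_strength = 2,
                                                group_effect = 2)),
                           seed = 100 + i)
    sim <- simulate_expression(cfg)
    regs <- infer_regulons(sim$study, "G60", n_perm = 300, n_boot = 30,
                           seed = i)
    if (nrow(regs[["G60"]]$targets) == 0) return(FALSE)
    act <- regulon_activity(sim$study, regs)
    cmp <- compare_groups(act["G60", ], sim$study)
    cmp$pval < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("regulon-phenotype tests detect planted dependence, validate input", {
  cfg <- expr_sim_config(n_genes = 60, n_active = 12, n_inactive = 12,
                         n_control = 0, risk_gene_ids = character(0),
                         protective_gene_ids = character(0),
                         tf_specs = list(list(tf_id = "G60",
                                              target_ids = sprintf("G%d", 1:10),
                                              effect_strength = 2,
                                              group_effect = 2)),
                         seed = 21)
  sim <- simulate_expression(cfg)
  regs <- infer_regulons(sim$study, "G60", n_perm = 300, n_boot = 30, seed = 2)
  for (mode in c("one", "two")) {
    res <- regulon_phenotype_test(sim$study, regs, tails = mode,
                                  n_perm = 300, seed = 5)
    expect_lt(res$pval, 0.05)
  }
  r1 <- regulon_phenotype_test(sim$study, regs, n_perm = 200, seed = 5)
  r2 <- regulon_phenotype_test(sim$study, regs, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  bad <- list(structure(list(tf_id = "TFZ",
                             targets = data.frame(gene_id = "NOPE", mi = 1,
                                                  sign = 1)),
                        class = "regulon"))
  expect_error(regulon_phenotype_test(sim$study, bad), "TFZ")
  expect_error(regulon_phenotype_test(sim$study, regs, tails = "three"))
})
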