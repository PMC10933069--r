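test_that("wald_ratio follows the ratio formula and delta-method SE", {
  h <- harmonized_set("rs1", 0.2, 0.02, 0.1, 0.03)
  w <- wald_ratio(h)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.03 / 0.2)
  h0 <- harmonized_set("rs1", 0.2, 0.02, 0, 0.03)
  expect_equal(wald_ratio(h0)$beta, 0)
  expect_equal(wald_ratio(h0)$or_, 1)
  hz <- harmonized_set("rs1", 0, 0.02, 0.1, 0.03)
  hz$records$beta_exposure <- 0
  expect_error(wald_ratio(hz), "beta_exposure")
})

test_that("delta-method SE agrees with a parametric bootstrap at high F", {
  set.seed(21)
  bx <- 0.2; sx <- 0.02; by <- 0.06; sy <- 0.02  # F = 100
  boot <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  h <- harmonized_set("rs1", bx, sx, by, sy)
  expect_lt(abs(wald_ratio(h)$se - sd(boot)) / sd(boot), 0.10)
})

test_that("ivw reduces to wald_ratio and to the K-identical closed form", {
  h1 <- harmonized_set("rs1", 0.2, 0.02, 0.1, 0.03)
  expect_equal(ivw(h1)[c("beta", "se", "pval")],
               wald_ratio(h1)[c("beta", "se", "pval")])
  k <- 7
  hk <- harmonized_set(sprintf("rs%d", 1:k), rep(0.2, k), 0.02,
                       rep(0.1, k), rep(0.03, k))
  fit <- ivw(hk)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, (0.03 / 0.2) / sqrt(k))
  expect_error(ivw(hk$records[0, ]), "at least one")
})

test_that("ivw equals the WLS-through-origin oracle on random sets", {
  for (seed in 1:25) {
    h <- random_harmonized(20, seed)
    fit <- ivw(h)
    o <- wls_origin_oracle(h$records$beta_exposure, h$records$beta_outcome,
                           h$records$se_outcome)
    expect_equal(fit$beta, o$beta, tolerance = 1e-10)
    expect_equal(fit$se, o$se, tolerance = 1e-10)
  }
})

test_that("OR and CI are exp-consistent with beta and se", {
  for (seed in 1:10) {
    h <- random_harmonized(12, seed + 100)
    fit <- ivw(h)
    expect_identical(fit$or_, exp(fit$beta))
    expect_identical(fit$ci_low, exp(fit$beta - 1.96 * fit$se))
    expect_identical(fit$ci_high, exp(fit$beta + 1.96 * fit$se))
    expect_true(fit$ci_low < fit$or_ && fit$or_ < fit$ci_high)
  }
})

test_that("egger recovers an exact line and rejects K < 3", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  by <- 0.05 + 0.3 * bx
  h <- harmonized_set(sprintf("rs%d", 1:5), bx, 0.02, by, 0.02)
  e <- egger(h)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  h2 <- harmonized_set(c("a", "b"), c(0.1, 0.2), 0.02, c(0.1, 0.2), 0.02)
  expect_error(egger(h2), "at least 3")
})

test_that("egger intercept is calibrated under no pleiotropy", {
  hits <- vapply(1:120, function(i) {
    sim <- simulate_gwas_pair(gwas_sim_config(n_variants = 30,
                                              beta_causal = 0.2, seed = i))
    e <- egger(harmonize(sim$exposure, sim$outcome))
    abs(e$intercept) <= 2 * e$intercept_se
  }, logical(1))
  expect_gte(mean(hits), 0.90)  # nominal ~95% coverage
})

test_that("cochran_q matches a hand-computed 3-record instance", {
  bx <- c(0.2, 0.25, 0.3); by <- c(0.10, 0.11, 0.18); sy <- c(0.02, 0.03, 0.025)
  h <- harmonized_set(c("a", "b", "c"), bx, 0.02, by, sy)
  # hand computation of the formula
  w <- bx^2 / sy^2
  ratios <- by / bx
  b_ivw <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  q_hand <- sum(w * (ratios - b_ivw)^2)
  res <- cochran_q(h)
  expect_equal(res$q, q_hand, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$pval, pchisq(q_hand, 2, lower.tail = FALSE))
  # all ratios equal -> Q = 0, p = 1
  h0 <- harmonized_set(c("a", "b"), c(0.1, 0.2), 0.02, c(0.05, 0.10), 0.02)
  expect_equal(cochran_q(h0)$q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(h0)$pval, 1)
  expect_error(cochran_q(h0$records[1, ]), "at least 2")
})

test_that("mr_presso is seeded-reproducible and enforces minima", {
  h <- random_harmonized(10, 31)
  a <- mr_presso(h, n_sim = 200, seed = 7)
  b <- mr_presso(h, n_sim = 200, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, mr_presso(h, n_sim = 200, seed = 8)))
  expect_error(mr_presso(random_harmonized(3, 1)), "at least 4")
})

test_that("mr_presso flags an injected outlier and distortion responds", {
  sim <- simulate_gwas_pair(gwas_sim_config(n_variants = 30,
                                            beta_causal = 0.3, seed = 3))
  h <- harmonize(sim$exposure, sim$outcome)
  fit <- ivw(h)
  h$records$beta_outcome[5] <- 10 * fit$beta * h$records$beta_exposure[5]
  # n_sim = 1000: the per-variant permutation p has floor 1/(n_sim+1), so
  # Bonferroni-adjusted detection at K = 30 needs n_sim > K/alpha - 1
  res <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_true("rs5" %in% res$presso_outliers)
  expect_lt(res$presso_global_p, 0.05)
  expect_false(is.na(res$presso_distortion_p))
  expect_s3_class(res$corrected, "mr_result")
  # removing the outlier moves the estimate toward truth more than any
  # other single removal
  loo <- leave_one_out(h)
  gain <- abs(loo$beta - 0.3)
  expect_equal(loo$excluded[which.min(gain)], "rs5")
})

test_that("leave_one_out reduces correctly at K = 2 and for identical rows", {
  h2 <- harmonized_set(c("a", "b"), c(0.2, 0.4), 0.02, c(0.1, 0.3), 0.03)
  loo <- leave_one_out(h2)
  expect_equal(loo$beta[loo$excluded == "a"],
               wald_ratio(h2$records[2, ])$beta)
  expect_equal(loo$beta[loo$excluded == "b"],
               wald_ratio(h2$records[1, ])$beta)
  k <- 5
  hk <- harmonized_set(sprintf("rs%d", 1:k), 0.2, 0.02, 0.1, 0.03)
  lk <- leave_one_out(hk)
  expect_true(all(abs(lk$beta - ivw(hk)$beta) < 1e-12))
  expect_error(leave_one_out(hk$records[1, ]), "at least 2")
})

test_that("full_mr_report composes and serializes losslessly", {
  h1 <- harmonized_set("rs1", 0.2, 0.02, 0.1, 0.03)
  rep1 <- full_mr_report(h1)
  expect_equal(rep1$primary$method, "wald_ratio")
  expect_true(any(grepl("skipped", rep1$notes)))

  sim <- simulate_gwas_pair(gwas_sim_config(beta_causal = 0.3, seed = 5))
  h <- harmonize(sim$exposure, sim$outcome)
  rep <- full_mr_report(h, seed = 2, n_sim = 200)
  expect_equal(rep$primary$method, "ivw")
  expect_lt(abs(rep$primary$beta - 0.3), 3 * rep$primary$se)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(primary = as.data.frame(rep$primary),
                            pleiotropy = rep$pleiotropy, loo = rep$loo),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$primary$beta, rep$primary$beta)
  expect_equal(back$pleiotropy$cochran_q, rep$pleiotropy$cochran_q)
  expect_equal(back$loo$beta, rep$loo$beta)
})
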