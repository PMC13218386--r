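test_that("Wald test reproduces published effect/SE pairs", {
  # rice KGW peak: effect -1.0259, SE 0.1955 -> Wald 27.52
  expect_equal(wald_test(-1.0259, 0.1955)$wald, 27.52, tolerance = 2e-3)
  # binary trait peak: effect 1.1287, SE 0.2010 -> Wald 31.53
  expect_equal(wald_test(1.1287, 0.2010)$wald, 31.53, tolerance = 2e-3)
  z <- wald_test(0, 1)
  expect_equal(z$wald, 0)
  expect_equal(z$pvalue, 1)
  expect_error(wald_test(1, 0), "> 0")
  # internal identity wald = (effect/se)^2 and pvalue consistency
  wt <- wald_test(c(-0.3, 1.7), c(0.1, 0.4))
  expect_equal(wt$wald, (c(-0.3, 1.7) / c(0.1, 0.4))^2)
  expect_equal(wt$pvalue, pchisq(wt$wald, 1, lower.tail = FALSE))
})

test_that("Bonferroni thresholds match the published critical values", {
  thr <- bonferroni_threshold(1619, 0.05)
  expect_equal(thr$wald_crit, 17.36, tolerance = 3e-4)
  expect_equal(thr$neglog10p_crit, 4.51, tolerance = 2e-3)
  expect_equal(bonferroni_threshold(1, 0.05)$wald_crit, qchisq(0.95, 1))
  expect_equal(bonferroni_threshold(10, 0.05)$neglog10p_crit, -log10(0.005))
  # monotone in m
  ms <- c(1, 10, 100, 1619)
  wc <- vapply(ms, function(m) bonferroni_threshold(m)$wald_crit, 0)
  expect_true(all(diff(wc) > 0))
})

test_that("QTL heritability arithmetic validates against the published row and an ANOVA oracle", {
  row <- qtl_summary_from_ms(15.3035, 0.5560, 278)
  expect_equal(row$sigma_qtl2, 0.0532, tolerance = 1e-3)
  expect_equal(row$h_qtl2, 0.0874, tolerance = 1e-3)
  # data route against R's own ANOVA
  set.seed(101)
  n <- 60
  x <- sample(c(-1, 1), n, replace = TRUE)
  p_til <- 0.4 * x + rnorm(n)
  ours <- qtl_summary(p_til, x, list(sigma_g2 = 0.5, sigma_e2 = 1))
  an <- anova(lm(p_til ~ x))
  expect_equal(ours$ms_qtl, an$`Mean Sq`[1], tolerance = 1e-10)
  expect_equal(ours$ms_e, an$`Mean Sq`[2], tolerance = 1e-10)
  expect_equal(ours$sigma_qtl2, max(0, (an$`Mean Sq`[1] - an$`Mean Sq`[2]) / (n - 1)))
  # orthogonal marker truncates at zero
  y2 <- rnorm(200)
  x2 <- rep(c(-1, 1), 100)
  s2 <- qtl_summary(y2 - mean(y2) + 0 * x2, x2)
  expect_gte(s2$sigma_qtl2, 0)
  # perfect fit reports the h2 -> 1 limit via the MS_E floor
  s3 <- qtl_summary(x2, x2)
  expect_gt(s3$h_qtl2, 0.999)
  expect_error(qtl_summary(y2, rep(1, 200)), "constant")
})

test_that("gaussian scans collapse onto their least-squares / EMMAX oracles", {
  sim <- simulate_trait(
    n = 80, m = 30, beta_q = 0.8, sigma_g2 = 1, sigma_e2 = 1,
    family = "gaussian", seed = 201
  )
  glm_scan <- psr_scan(sim$pheno, sim$geno, NULL, method = "glm")
  # per-marker OLS oracle: t^2 on the marker coefficient
  for (k in c(3, 15, 28)) {
    fit <- summary(lm(sim$pheno$y ~ sim$geno$codes[, k]))
    expect_equal(glm_scan$wald[k], fit$coefficients[2, "t value"]^2, tolerance = 1e-8)
    expect_equal(glm_scan$effect[k], fit$coefficients[2, "Estimate"], tolerance = 1e-10)
  }
  p3d <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "p3d")
  psr <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
  glmm <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "glmm")
  # identity link: the frozen pseudo response IS the trait, so P3D and PSR
  # give identical records
  expect_equal(psr$effect, p3d$effect, tolerance = 1e-8)
  expect_equal(psr$se, p3d$se, tolerance = 1e-8)
  # exact scan equals a per-marker REML oracle
  for (k in c(5, 22)) {
    o <- fit_lmm_reml(sim$pheno$y, cbind(1, sim$geno$codes[, k]), sim$kinship)
    expect_equal(glmm$effect[k], unname(o$beta[2]), tolerance = 1e-6)
    expect_equal(glmm$se[k], unname(o$se_beta[2]), tolerance = 1e-6)
  }
})

test_that("binary GLM scan matches an independent IRLS oracle and flags separation", {
  set.seed(205)
  n <- 120
  g <- simulate_genotypes(n, 12, seed = 205)
  x <- g$codes[, 6]
  y <- rbinom(n, 1, 1 / (1 + exp(-0.6 * x)))
  pheno <- tibble::tibble(id = g$sample_ids, y = y)
  attr(pheno, "family") <- psr_family("binary")
  scan <- psr_scan(pheno, g, NULL, method = "glm")
  o <- irls_logit(cbind(1, x), y)
  expect_equal(scan$effect[6], unname(o$beta[2]), tolerance = 1e-6)
  expect_equal(scan$se[6], unname(o$se[2]), tolerance = 1e-6)
  expect_equal(scan$wald[6], unname((o$beta[2] / o$se[2])^2), tolerance = 1e-5)
  # perfect co-segregation: flagged, Wald collapses
  y_sep <- as.numeric(x > 0)
  pheno2 <- tibble::tibble(id = g$sample_ids, y = y_sep)
  attr(pheno2, "family") <- psr_family("binary")
  scan2 <- psr_scan(pheno2, g, NULL, method = "glm")
  expect_equal(scan2$note[6], "separation")
  expect_lt(scan2$wald[6], 1)
})

test_that("scan records satisfy their identities and flag monomorphic markers", {
  sim <- simulate_trait(n = 60, m = 20, beta_q = 1, sigma_g2 = 1, family = "binary", seed = 210)
  sim$geno$codes[, 4] <- 1 # force monomorphic
  sim$geno$monomorphic[4] <- TRUE
  scan <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
  expect_equal(scan$note[4], "monomorphic")
  expect_equal(scan$pvalue[4], 1)
  ok <- scan$note == ""
  expect_equal(scan$wald[ok], (scan$effect[ok] / scan$se[ok])^2, tolerance = 1e-8)
  expect_equal(scan$neglog10p[ok], -log10(scan$pvalue[ok]), tolerance = 1e-8)
  thr <- attr(scan, "threshold")
  expect_equal(thr$m, 19) # monomorphic marker excluded from the correction
})

test_that("approximate scans track the exact scan on binary data", {
  sim <- simulate_trait(n = 150, m = 40, beta_q = 1, sigma_g2 = 1, family = "binary", seed = 215)
  glmm <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "glmm")
  p3d <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "p3d")
  psr <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
  expect_gt(cor(p3d$wald, glmm$wald, method = "spearman"), 0.95)
  expect_gt(cor(psr$effect, glmm$effect), 0.95)
  slope <- coef(lm(psr$effect ~ glmm$effect))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  # all three share the same null model, hence identical variance components
  expect_equal(attr(p3d, "null_fit")$vc$sigma_g2, attr(glmm, "null_fit")$vc$sigma_g2)
  expect_equal(attr(psr, "null_fit")$vc$sigma_g2, attr(glmm, "null_fit")$vc$sigma_g2)
})

test_that("ordinal scan localizes a planted QTL and keeps the sign convention", {
  sim <- simulate_trait(
    n = 120, m = 25, beta_q = 1.2, sigma_g2 = 0.5, sigma_e2 = 1,
    family = "ordinal", seed = 220
  )
  scan <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
  peak <- which.max(scan$wald)
  expect_lte(abs(peak - sim$scenario$qtl_index), 3)
  # positive liability effect shifts mass to higher categories -> positive
  # estimated marker effect under the alpha - (x beta + gamma) convention
  expect_gt(scan$effect[sim$scenario$qtl_index], 0)
})

test_that("per-peak QTL summaries use the reporting method's pseudo response", {
  sim <- simulate_trait(n = 100, m = 30, beta_q = 1, sigma_g2 = 1, family = "binary", seed = 230)
  scan <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
  qs <- scan_qtl_summary(scan, sim$geno)
  expect_equal(nrow(qs), 1)
  expect_true(qs$h_qtl2 >= 0 && qs$h_qtl2 < 1)
  nf <- attr(scan, "null_fit")
  expect_equal(qs$sigma_xi2, nf$vc$sigma_g2)
  # matches a direct call on the frozen pseudo response
  direct <- qtl_summary(nf$p_tilde, sim$geno$codes[, qs$marker], nf$vc)
  expect_equal(qs$ms_qtl, direct$ms_qtl)
  expect_equal(qs$h_qtl2, direct$h_qtl2)
})

test_that("polygenic control keeps a null scan calibrated while plain GLM inflates", {
  sim <- simulate_trait(n = 200, m = 100, beta_q = 0, sigma_g2 = 1, family = "binary", seed = 11)
  half <- 1.96 * sqrt(0.05 * 0.95 / 100)
  for (meth in c("glmm", "p3d", "psr")) {
    sc <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = meth)
    expect_lte(abs(mean(sc$pvalue < 0.05) - 0.05), half, label = meth)
  }
  glm_scan <- psr_scan(sim$pheno, sim$geno, NULL, method = "glm")
  expect_gt(mean(glm_scan$pvalue < 0.05), 0.05 + half)
})

test_that("binomial and poisson scans localize a planted QTL", {
  for (fam in c("binomial", "poisson")) {
    sim <- simulate_trait(
      n = 120, m = 25, beta_q = 1, sigma_g2 = 0.5, family = fam,
      seed = 240 + nchar(fam), a = if (fam == "poisson") log(4) else 0
    )
    scan <- psr_scan(sim$pheno, sim$geno, sim$kinship, method = "psr")
    expect_lte(abs(which.max(scan$wald) - sim$scenario$qtl_index), 3, label = fam)
    ok <- scan$note == ""
    expect_equal(scan$wald[ok], (scan$effect[ok] / scan$se[ok])^2,
      tolerance = 1e-8, label = fam
    )
  }
})
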