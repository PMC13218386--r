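test_that("kinship equals the hand-computed centered cross-product", {
  codes <- matrix(
    c(
      -1, 1, 1, -1, 1, -1,
      1, 1, -1, -1, 1, 1,
      -1, -1, 1, 1, -1, 1,
      1, -1, -1, 1, 1, -1
    ),
    nrow = 4, byrow = TRUE
  )
  rownames(codes) <- paste0("i", 1:4)
  colnames(codes) <- paste0("m", 1:6)
  Cc <- sweep(codes, 2, colMeans(codes))
  K_hand <- tcrossprod(Cc) / mean(diag(tcrossprod(Cc)))
  K <- kinship_from_markers(codes)
  expect_equal(unname(K), unname(K_hand), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mean(diag(K)), 1, tolerance = 1e-12)
  # the attached factor reproduces K exactly
  P <- attr(K, "factor")
  expect_equal(unname(tcrossprod(P)), unname(K_hand), tolerance = 1e-12)
})

test_that("kinship of identical individuals and degenerate input", {
  codes <- rbind(a = c(1, -1, 1, -1), b = c(1, -1, 1, -1), c = c(-1, 1, -1, 1))
  colnames(codes) <- paste0("m", 1:4)
  K <- kinship_from_markers(codes)
  expect_equal(K["a", "b"], K["a", "a"], tolerance = 1e-12)
  mono <- matrix(1, 3, 4, dimnames = list(letters[1:3], paste0("m", 1:4)))
  expect_error(kinship_from_markers(mono), "monomorphic")
})

test_that("simulated genotypes respect the Markov switch model and determinism", {
  g0 <- simulate_genotypes(30, 20, n_chrom = 2, switch_prob = 0, seed = 301)
  # no switches: within a chromosome every marker is identical per individual
  expect_true(all(g0$codes[, 1] == g0$codes[, 10]))
  expect_true(all(g0$codes[, 11] == g0$codes[, 20]))
  g_half <- simulate_genotypes(500, 10, n_chrom = 1, switch_prob = 0.5, seed = 302)
  r_adj <- cor(g_half$codes[, 5], g_half$codes[, 6])
  expect_lt(abs(r_adj), 0.1)
  # determinism under the seed
  g1 <- simulate_genotypes(25, 15, seed = 303)
  g2 <- simulate_genotypes(25, 15, seed = 303)
  expect_identical(g1$codes, g2$codes)
  # f2 coding
  gf <- simulate_genotypes(40, 10, type = "f2", seed = 304)
  expect_true(all(gf$codes %in% c(-1, 0, 1)))
})

test_that("liability composition behaves at its degenerate corners", {
  g <- simulate_genotypes(300, 20, seed = 310)
  l0 <- simulate_liability(g, qtl_index = 10, beta_q = 0, sigma_g2 = 0, sigma_e2 = 1.5, seed = 311)
  expect_lt(abs(var(l0) - 1.5), 0.3)
  l1 <- simulate_liability(g, qtl_index = 10, beta_q = 0.7, sigma_g2 = 0, sigma_e2 = 0, seed = 312)
  expect_equal(cor(l1, g$codes[, 10]), 1, tolerance = 1e-12)
})

test_that("the bias-study effect sizes imply the published QTL heritabilities", {
  # x in {-1, +1} equifrequent has unit variance; with unit polygenic variance
  # and the logistic observation variance pi^2/3 the implied QTL heritability
  # is 0.10 at effect 0.7 and 0.18 at effect 1.0
  h2 <- function(b) b^2 / (b^2 + 1 + pi^2 / 3)
  expect_equal(h2(0.7), 0.10, tolerance = 0.03)
  expect_equal(h2(1.0), 0.18, tolerance = 0.06)
})

test_that("liability transformations produce the requested trait laws", {
  set.seed(320)
  liab <- rnorm(900)
  yb <- liability_to_trait(liab, "binary", mode = "threshold", threshold_q = 0.5, seed = 321)
  expect_equal(mean(yb), sum(liab > quantile(liab, 0.5)) / 900)
  yo <- liability_to_trait(liab, "ordinal", n_categories = 3, seed = 322)
  counts <- table(yo)
  expect_true(all(abs(counts - 300) <= 1))
  yp <- liability_to_trait(liab, "poisson", a = log(5), b = 0, seed = 323)
  expect_lt(abs(mean(yp) - 5), 3 * sqrt(5 / 900))
  ybin <- liability_to_trait(liab, "binomial", trials = 10, seed = 324)
  expect_true(all(attr(ybin, "events") <= attr(ybin, "trials")))
  expect_error(liability_to_trait(liab, "beta"), "unknown family")
})

test_that("simulators are reproducible end to end", {
  s1 <- simulate_trait(n = 40, m = 20, beta_q = 1, family = "binary", seed = 330)
  s2 <- simulate_trait(n = 40, m = 20, beta_q = 1, family = "binary", seed = 330)
  expect_identical(s1$pheno$y, s2$pheno$y)
  expect_identical(s1$geno$codes, s2$geno$codes)
  expect_identical(s1$kinship, s2$kinship)
  expect_equal(s1$scenario$seed, 330)
})

test_that("a null power study gives chance-level AUC", {
  pw <- run_power_study(
    effects = 0, n = 60, m = 12, replicates = 25,
    methods = "psr", seed = 340
  )
  expect_true(abs(pw$auc$auc - 0.5) < 0.15)
  expect_true(all(pw$roc$fpr >= 0 & pw$roc$fpr <= 1))
  expect_true(all(pw$roc$tpr >= 0 & pw$roc$tpr <= 1))
})

test_that("rank AUC equals an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(350)
  pv <- runif(200)
  lab <- rbinom(200, 1, 0.3) == 1
  pv[lab] <- pv[lab]^2 # enrich small p among positives
  ours <- psrglmm:::auc_rank(pv, lab)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lab, -pv, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})
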