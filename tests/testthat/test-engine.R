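test_that("pseudo response reduces to the response for the identity link", {
  y <- c(-1.2, 0.4, 3.3)
  for (eta in list(rep(0, 3), c(5, -2, 0.1))) {
    ps <- pseudo_response(y, eta, psr_family("gaussian"))
    expect_equal(ps$p_tilde, y)
    expect_equal(ps$weights, rep(1, 3))
  }
})

test_that("binary pseudo response at eta = 0 is +/- 2", {
  ps <- pseudo_response(c(1, 0), c(0, 0), psr_family("binary"))
  expect_equal(ps$p_tilde, c(2, -2))
  expect_equal(ps$weights, c(0.25, 0.25))
})

test_that("restricted likelihood matches the naive dense oracle on a toy fixture", {
  set.seed(41)
  n <- 4
  p <- c(0.3, -1.1, 2.2, 0.4)
  X <- cbind(1, c(0, 1, 0, 1))
  A <- matrix(rnorm(n * n), n)
  K <- crossprod(A) / n
  w <- c(0.5, 1.2, 2, 0.8)
  for (lam in c(0.5, 2)) {
    ours <- reml_loglik(lam, p, X, K, w)
    oracle <- dense_reml_oracle(lam, p, X, K, w)
    expect_equal(ours$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(ours$sigma_e2, oracle$sigma_e2, tolerance = 1e-10)
    expect_equal(ours$beta, oracle$beta, tolerance = 1e-10)
  }
})

test_that("eigendecomposition path agrees with the dense criterion on random fixtures", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 6
    p_til <- rnorm(n)
    X <- cbind(1, rnorm(n))
    A <- matrix(rnorm(n * n), n)
    K <- crossprod(A) / n
    w <- runif(n, 0.3, 2)
    fit <- fit_lmm_reml(p_til, X, K, w, psr_control(ridge = 0))
    oracle <- dense_reml_oracle(fit$lambda, p_til, X, K, w)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-8)
    # the fitted lambda maximizes the dense criterion too (probing only
    # inside the search bounds: a boundary estimate is allowed to have the
    # criterion still rising toward the excluded region)
    for (shift in c(0.9, 1.1)) {
      lam_probe <- fit$lambda * shift
      if (lam_probe < 1e-6 || lam_probe > 1e6) next
      expect_lte(
        dense_reml_oracle(lam_probe, p_til, X, K, w)$loglik,
        oracle$loglik + 1e-10
      )
    }
  }
})

test_that("REML is scale-equivariant", {
  set.seed(13)
  sim <- simulate_trait(
    n = 60, m = 40, beta_q = 0.5, sigma_g2 = 1, sigma_e2 = 1,
    family = "gaussian", seed = 13
  )
  X <- cbind(1, sim$geno$codes[, 20])
  f1 <- fit_lmm_reml(sim$pheno$y, X, sim$kinship)
  f2 <- fit_lmm_reml(2 * sim$pheno$y, X, sim$kinship)
  expect_equal(f2$sigma_e2, 4 * f1$sigma_e2, tolerance = 1e-6)
  expect_equal(f2$sigma_g2, 4 * f1$sigma_g2, tolerance = 1e-6)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)
  expect_equal(unname(f2$beta), 2 * unname(f1$beta), tolerance = 1e-8)
})

test_that("REML recovers known variance components in gaussian simulations", {
  set.seed(99)
  n_rep <- 120
  est <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    sim <- simulate_trait(
      n = 50, m = 40, beta_q = 0, sigma_g2 = 1, sigma_e2 = 1,
      family = "gaussian", seed = 1000 + r
    )
    f <- fit_lmm_reml(sim$pheno$y, matrix(1, 50, 1), sim$kinship)
    est[r, ] <- c(f$sigma_g2, f$sigma_e2)
  }
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_rep)
  expect_lt(abs(mean(est[, 1]) - 1), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - 1), 3 * mc_se[2])
})

test_that("pure-noise data drives the variance ratio to its lower bound", {
  set.seed(5)
  n_rep <- 60
  sg <- se <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    g <- simulate_genotypes(40, 30, seed = 2000 + r)
    K <- kinship_from_markers(g)
    y <- rnorm(40, sd = sqrt(2))
    f <- fit_lmm_reml(y, matrix(1, 40, 1), K)
    sg[r] <- f$sigma_g2
    se[r] <- f$sigma_e2
  }
  expect_lt(mean(sg), 0.2) # polygenic variance collapses toward zero
  expect_lt(abs(mean(se) - 2), 3 * stats::sd(se) / sqrt(n_rep))
})

test_that("BLUP solve matches the dense Henderson equations", {
  set.seed(21)
  n <- 5
  p_til <- rnorm(n)
  X <- cbind(1, rnorm(n))
  A <- matrix(rnorm(n * n), n)
  K <- crossprod(A) / n + diag(0.1, n)
  w <- runif(n, 0.5, 1.5)
  vc <- list(sigma_g2 = 0.7, sigma_e2 = 1.3)
  ours <- blup_solve(p_til, X, K, w, vc, psr_control(ridge = 0))
  oracle <- henderson_oracle(p_til, X, K, w, vc$sigma_g2, vc$sigma_e2)
  expect_equal(unname(ours$beta), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(ours$gamma, unname(oracle$gamma), tolerance = 1e-10)
})

test_that("BLUP vanishes without polygenic variance and is permutation-equivariant", {
  set.seed(22)
  n <- 8
  p_til <- rnorm(n)
  X <- cbind(1, rnorm(n))
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  w <- runif(n, 0.5, 2)
  z <- blup_solve(p_til, X, K, w, list(sigma_g2 = 0, sigma_e2 = 1))
  expect_equal(z$gamma, rep(0, n))
  # weighted least squares at sigma_g2 = 0
  wls <- solve(crossprod(X, w * X), crossprod(X, w * p_til))
  expect_equal(unname(z$beta), as.numeric(wls), tolerance = 1e-10)
  # permutation
  perm <- sample(n)
  vc <- list(sigma_g2 = 0.6, sigma_e2 = 0.9)
  a <- blup_solve(p_til, X, K, w, vc, psr_control(ridge = 0))
  b <- blup_solve(p_til[perm], X[perm, ], K[perm, perm], w[perm], vc, psr_control(ridge = 0))
  expect_equal(unname(b$beta), unname(a$beta), tolerance = 1e-9)
  expect_equal(b$gamma, a$gamma[perm], tolerance = 1e-9)
})

test_that("gaussian GLMM fit is exactly the REML LMM fit", {
  sim <- simulate_trait(
    n = 60, m = 40, beta_q = 0.8, sigma_g2 = 1, sigma_e2 = 1,
    family = "gaussian", seed = 31
  )
  X <- cbind(1, sim$geno$codes[, sim$scenario$qtl_index])
  gl <- fit_glmm(sim$pheno$y, X, sim$kinship, psr_family("gaussian"))
  lm_fit <- fit_lmm_reml(sim$pheno$y, X, sim$kinship)
  expect_identical(unname(gl$beta), unname(lm_fit$beta))
  expect_identical(gl$vc$sigma_g2, lm_fit$sigma_g2)
  expect_identical(gl$p_tilde, sim$pheno$y)
  expect_equal(unname(gl$iterations["outer"]), 1)
})

test_that("binary GLMM with a null kinship reduces to IRLS logistic regression", {
  set.seed(44)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 1 / (1 + exp(-(0.3 + 0.8 * x))))
  X <- cbind(1, x)
  K0 <- matrix(0, n, n)
  diag(K0) <- 1e-12 # numerically null polygenic structure
  fit <- fit_glmm(y, X, K0, psr_family("binary"))
  oracle <- irls_logit(X, y)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
  # the free residual scale sits near its theoretical value of 1, so the
  # standard errors agree with the fixed-dispersion IRLS ones only loosely
  expect_equal(unname(fit$se_beta), unname(oracle$se), tolerance = 0.2)
})

test_that("compiled and reference engines produce the same fit", {
  for (fam_name in c("binary", "poisson", "binomial")) {
    sim <- simulate_trait(
      n = 80, m = 40, beta_q = 0.8, sigma_g2 = 0.8,
      family = fam_name, seed = 50 + nchar(fam_name),
      a = if (fam_name == "poisson") log(4) else 0
    )
    trials <- if (fam_name == "binomial") sim$pheno$trials else NULL
    X <- cbind(1, marker = sim$geno$codes[, sim$scenario$qtl_index])
    fam <- attr(sim$pheno, "family")
    fc <- fit_glmm(sim$pheno$y, X, sim$kinship, fam, trials = trials)
    fr <- fit_glmm(sim$pheno$y, X, sim$kinship, fam, trials = trials, engine = "r")
    expect_equal(unname(fc$beta), unname(fr$beta), tolerance = 1e-6, label = fam_name)
    expect_equal(fc$vc$sigma_g2, fr$vc$sigma_g2, tolerance = 1e-6)
    expect_equal(fc$vc$sigma_e2, fr$vc$sigma_e2, tolerance = 1e-6)
    expect_equal(unname(fc$se_beta), unname(fr$se_beta), tolerance = 1e-6)
    expect_equal(fc$gamma, fr$gamma, tolerance = 1e-5)
  }
})

test_that("degenerate two-category ordinal fit reproduces the binary fit", {
  sim <- simulate_trait(
    n = 70, m = 30, beta_q = 1, sigma_g2 = 0.5, family = "binary", seed = 61
  )
  X <- cbind(1, marker = sim$geno$codes[, sim$scenario$qtl_index])
  fb <- fit_glmm(sim$pheno$y, X, sim$kinship, psr_family("binary"), engine = "r")
  y_ord <- sim$pheno$y + 1
  fo <- fit_glmm(y_ord, X, sim$kinship, psr_family("ordinal", n_categories = 2))
  # eta_ord = alpha - (x beta + gamma): the marker effect matches directly,
  # the single threshold matches the negated intercept
  expect_equal(unname(fo$beta["marker"]), unname(fb$beta[2]), tolerance = 1e-4)
  expect_equal(unname(fo$beta["alpha1"]), -unname(fb$beta[1]), tolerance = 1e-4)
  expect_equal(fo$vc$sigma_g2, fb$vc$sigma_g2, tolerance = 1e-4)
})

test_that("binary fits flag separation-like divergence instead of failing", {
  set.seed(71)
  n <- 40
  g <- simulate_genotypes(n, 20, seed = 71)
  K <- kinship_from_markers(g)
  x <- g$codes[, 10]
  y <- as.numeric(x > 0) # perfect co-segregation
  X <- cbind(1, marker = x)
  fit <- fit_glmm(y, X, K, psr_family("binary"))
  expect_true(fit$clamped)
})

test_that("restricted likelihood is non-decreasing across REML updates at fixed pseudo data", {
  sim <- simulate_trait(n = 60, m = 30, beta_q = 1, sigma_g2 = 1, family = "binary", seed = 81)
  X <- cbind(1, sim$geno$codes[, sim$scenario$qtl_index])
  fit <- fit_glmm(sim$pheno$y, X, sim$kinship, psr_family("binary"), engine = "r")
  # at the converged pseudo data, the fitted lambda attains the maximum of the
  # profiled criterion among a grid of alternatives
  su_ll <- function(lam) {
    reml_loglik(lam, fit$p_tilde, X, sim$kinship, fit$W$w)$loglik
  }
  ll_hat <- su_ll(fit$vc$lambda)
  for (lam in c(0.1, 0.5, 2, 5) * fit$vc$lambda) {
    expect_lte(su_ll(lam), ll_hat + 1e-6)
  }
})
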