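# Shared fixtures and independent oracles used across the test files.

# tiny genotype object built directly (bypasses file I/O)
make_geno <- function(codes, chrom = NULL, pos = NULL) {
  n <- nrow(codes)
  m <- ncol(codes)
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("mk%03d", seq_len(m))
  map <- tibble::tibble(
    marker = colnames(codes),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq_len(m)
  )
  psrglmm:::new_psr_geno(codes, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent IRLS for logistic regression (the GLM oracle)
irls_logit <- function(X, y, wts = NULL, maxit = 60, tol = 1e-12) {
  wts <- wts %||% rep(1, length(y))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- wts * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- wts * mu * (1 - mu)
  covb <- solve(crossprod(X, w * X))
  list(beta = as.numeric(beta), se = sqrt(diag(covb)))
}

# dense restricted log-likelihood of the linearized model, written straight
# from the variance expression V = sigma_g2 K + sigma_e2 W^{-1}: explicit
# inverse and determinants, residual scale profiled out. Kept deliberately
# naive -- it is the oracle for the package's eigendecomposition route.
dense_reml_oracle <- function(lambda, p, X, K, w) {
  N <- length(p)
  q <- ncol(X)
  V0 <- lambda * K + diag(1 / w, N)
  V0i <- solve(V0)
  XtViX <- t(X) %*% V0i %*% X
  beta <- solve(XtViX) %*% t(X) %*% V0i %*% p
  r <- p - X %*% beta
  quad <- as.numeric(t(r) %*% V0i %*% r)
  s2 <- quad / (N - q)
  V <- s2 * V0
  Vi <- V0i / s2
  ll <- -0.5 * (log(det(V)) + log(det(t(X) %*% Vi %*% X)) + quad / s2)
  list(loglik = ll, sigma_e2 = s2, beta = as.numeric(beta))
}

# Henderson mixed-model equations solved densely (BLUP oracle)
henderson_oracle <- function(p, X, K, w, sigma_g2, sigma_e2) {
  n <- length(p)
  Rinv <- diag(w / sigma_e2, n)
  Ginv <- solve(K) / sigma_g2
  lhs <- rbind(
    cbind(t(X) %*% Rinv %*% X, t(X) %*% Rinv),
    cbind(Rinv %*% X, Rinv + Ginv)
  )
  rhs <- c(t(X) %*% Rinv %*% p, Rinv %*% p)
  sol <- solve(lhs, rhs)
  list(beta = sol[seq_len(ncol(X))], gamma = sol[-seq_len(ncol(X))])
}
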