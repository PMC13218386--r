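#' Wald test of a marker effect
#'
#' \eqn{W = (\hat\beta/\mathrm{se})^2}, compared to the 1-df chi-square.
#'
#' @param effect estimated effect(s), link scale.
#' @param se standard error(s), strictly positive.
#' @return tibble with `wald`, `pvalue`, `neglog10p`.
#' @examples
#' wald_test(-1.0259, 0.1955) # Wald about 27.5
#' @export
wald_test <- function(effect, se) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be > 0", call. = FALSE)
  wald <- (effect / se)^2
  pvalue <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  tibble::tibble(wald = wald, pvalue = pvalue, neglog10p = -log10(pvalue))
}

#' Bonferroni genome-scan thresholds
#'
#' Family-wise critical values for `m` tests at level `alpha`: the 1-df
#' chi-square quantile at `1 - alpha/m` for the Wald statistic and
#' `-log10(alpha/m)` on the p-value scale.
#'
#' @param m number of markers tested (>= 1).
#' @param alpha family-wise error rate.
#' @return tibble with `m`, `alpha`, `wald_crit`, `neglog10p_crit`.
#' @examples
#' bonferroni_threshold(1619) # wald_crit about 17.36, -log10 p about 4.51
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  tibble::tibble(
    m = m, alpha = alpha,
    wald_crit = stats::qchisq(1 - alpha / m, df = 1),
    neglog10p_crit = -log10(alpha / m)
  )
}

#' QTL variance and heritability from a one-way ANOVA of the pseudo response
#'
#' Regresses the converged pseudo response on the marker: `MS_QTL` is the
#' 1-df model mean square, `MS_E` the residual mean square on `N - 2` df,
#' \eqn{\hat\sigma^2_{QTL} = \max\{0, (MS_{QTL} - MS_E)/(N-1)\}} and
#' \eqn{\hat h^2_{QTL} = \hat\sigma^2_{QTL} / (\hat\sigma^2_{QTL} + MS_E)}.
#' Because each scan method converges to its own pseudo response, the mean
#' squares (and hence the heritability) are method-specific.
#'
#' @param p_tilde converged pseudo response of the reporting method (the trait
#'   itself for gaussian).
#' @param x_marker marker codes (expanded to match `p_tilde` for ordinal).
#' @param vc optional variance components of the fit; copied into the output.
#' @return one-row tibble: `sigma_xi2`, `sigma_e2`, `ms_qtl`, `ms_e`,
#'   `sigma_qtl2`, `h_qtl2`.
#' @export
qtl_summary <- function(p_tilde, x_marker, vc = NULL) {
  N <- length(p_tilde)
  if (length(x_marker) != N) stop("p_tilde and x_marker lengths differ", call. = FALSE)
  if (diff(range(x_marker)) == 0) stop("marker is constant", call. = FALSE)
  xc <- x_marker - mean(x_marker)
  yc <- p_tilde - mean(p_tilde)
  bhat <- sum(xc * yc) / sum(xc^2)
  ssr <- bhat^2 * sum(xc^2)
  rss <- sum(yc^2) - ssr
  ms_qtl <- ssr # 1 df
  ms_e <- max(rss / (N - 2), 1e-12)
  out <- qtl_summary_from_ms(ms_qtl, ms_e, N)
  out$sigma_xi2 <- vc$sigma_g2 %||% NA_real_
  out$sigma_e2 <- vc$sigma_e2 %||% NA_real_
  out[c("sigma_xi2", "sigma_e2", "ms_qtl", "ms_e", "sigma_qtl2", "h_qtl2")]
}

#' QTL variance and heritability from given mean squares
#'
#' The arithmetic behind [qtl_summary()]:
#' \eqn{\hat\sigma^2_{QTL} = \max\{0, (MS_{QTL} - MS_E)/(n-1)\}} and
#' \eqn{\hat h^2_{QTL} = \hat\sigma^2_{QTL}/(\hat\sigma^2_{QTL} + MS_E)}.
#'
#' @param ms_qtl model mean square on 1 df.
#' @param ms_e residual mean square.
#' @param n number of observations in the ANOVA.
#' @return one-row tibble: `ms_qtl`, `ms_e`, `sigma_qtl2`, `h_qtl2`.
#' @export
qtl_summary_from_ms <- function(ms_qtl, ms_e, n) {
  sigma_qtl2 <- max(0, (ms_qtl - ms_e) / (n - 1))
  tibble::tibble(
    ms_qtl = ms_qtl, ms_e = ms_e,
    sigma_qtl2 = sigma_qtl2,
    h_qtl2 = sigma_qtl2 / (sigma_qtl2 + ms_e)
  )
}

#' Genome scan under the pseudo-response GLMM framework
#'
#' Tests every marker for association with the trait, by one of four
#' strategies:
#'
#' * `"glm"` — per-marker generalized linear model with no polygenic control
#'   (the naive baseline; inflated under population structure);
#' * `"glmm"` — the exact mixed-model route: the full doubly iterative fit per
#'   marker, variance components re-estimated each time;
#' * `"p3d"` — variance components estimated once under the null model and held
#'   fixed; each marker re-runs only the linearization loop;
#' * `"psr"` — the fast route: the null fit's pseudo response, working weights
#'   and variance components are frozen, the whitened kinship is eigendecomposed
#'   once, and each marker costs a single generalized least-squares solve.
#'
#' For gaussian traits the pseudo response equals the trait, so `"p3d"` and
#' `"psr"` coincide (an EMMAX-style scan) and `"glmm"` is an exact REML scan.
#'
#' Monomorphic markers are skipped with a sentinel record (effect 0, p 1, note
#' `"monomorphic"`); separation in the GLM route and non-convergence in the
#' mixed-model routes are flagged in the `note` column.
#'
#' @param pheno phenotype tibble from [read_phenotypes()], or any data frame
#'   with columns `id` and `y` (plus `trials` for binomial) and a family given
#'   via `family`.
#' @param geno a [read_genotypes()] / [simulate_genotypes()] object.
#' @param kinship kinship matrix, or `NULL` to compute it from all markers via
#'   [kinship_from_markers()] (the GLM method needs none).
#' @param method one of `"psr"`, `"p3d"`, `"glmm"`, `"glm"`.
#' @param family a [psr_family()]; defaults to the phenotype attribute.
#' @param covariates character vector of extra fixed-effect columns in `pheno`.
#' @param alpha family-wise error rate for the Bonferroni threshold attached to
#'   the result.
#' @param control a [psr_control()].
#' @return a tibble of class `psr_scan` with one row per marker: `marker`,
#'   `chrom`, `pos`, `effect`, `se`, `wald`, `pvalue`, `neglog10p`, `note`.
#'   Attributes: `method`, `family`, `null_fit` (mixed methods), `threshold`,
#'   `timing` (seconds).
#' @export
psr_scan <- function(pheno, geno, kinship = NULL,
                     method = c("psr", "p3d", "glmm", "glm"),
                     family = NULL, covariates = NULL, alpha = 0.05,
                     control = psr_control()) {
  method <- match.arg(method)
  family <- family %||% attr(pheno, "family")
  if (is.null(family)) stop("no trait family: pass `family` or a read_phenotypes() table", call. = FALSE)
  if (method != "glm" && is.null(kinship)) kinship <- kinship_from_markers(geno)
  al <- align_samples(geno, pheno, kinship)
  geno <- al$geno
  pheno <- al$pheno
  kinship <- al$kinship
  y <- pheno$y
  trials <- if (family$name == "binomial") pheno$trials else NULL
  X0 <- cbind("(Intercept)" = rep(1, length(y)))
  if (!is.null(covariates)) {
    X0 <- cbind(X0, as.matrix(pheno[covariates]))
  }
  t0 <- proc.time()[3]
  rec <- switch(method,
    glm = scan_glm_impl(y, X0, geno, family, trials, control),
    glmm = scan_glmm_impl(y, X0, geno, kinship, family, trials, control, exact = TRUE),
    p3d = scan_glmm_impl(y, X0, geno, kinship, family, trials, control, exact = FALSE),
    psr = scan_psr_impl(y, X0, geno, kinship, family, trials, control)
  )
  out <- dplyr::bind_cols(geno$map, rec$records)
  out <- tibble::new_tibble(out, class = "psr_scan")
  attr(out, "method") <- method
  attr(out, "family") <- family
  attr(out, "null_fit") <- rec$null_fit
  attr(out, "threshold") <- bonferroni_threshold(sum(!geno$monomorphic), alpha)
  attr(out, "timing") <- unname(proc.time()[3] - t0)
  out
}

sentinel_record <- function(note) {
  tibble::tibble(
    effect = 0, se = NA_real_, wald = 0, pvalue = 1, neglog10p = 0, note = note
  )
}

record_from <- function(effect, se, note = "") {
  effect <- unname(effect)
  se <- unname(se)
  wt <- wald_test(effect, se)
  tibble::tibble(
    effect = effect, se = se, wald = wt$wald,
    pvalue = wt$pvalue, neglog10p = wt$neglog10p, note = note
  )
}

scan_glm_impl <- function(y, X0, geno, family, trials, control) {
  m <- ncol(geno$codes)
  recs <- vector("list", m)
  for (k in seq_len(m)) {
    if (geno$monomorphic[k]) {
      recs[[k]] <- sentinel_record("monomorphic")
      next
    }
    x <- geno$codes[, k]
    recs[[k]] <- glm_marker_fit(y, cbind(X0, marker = x), family, trials, control)
  }
  list(records = dplyr::bind_rows(recs), null_fit = NULL)
}

glm_marker_fit <- function(y, X, family, trials, control) {
  j <- ncol(X)
  if (family$name == "ordinal") {
    df <- as.data.frame(X[, -1, drop = FALSE])
    df$.y <- factor(y, ordered = TRUE)
    fit <- try(
      suppressWarnings(MASS::polr(.y ~ ., data = df, Hess = TRUE, method = "logistic")),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      return(sentinel_record("nonconverged"))
    }
    sm <- summary(fit)$coefficients
    eff <- sm["marker", "Value"]
    se <- sm["marker", "Std. Error"]
    note <- if (abs(eff / se) > 1e3) "separation" else ""
    return(record_from(eff, se, note))
  }
  glm_fam <- switch(family$name,
    gaussian = stats::gaussian(),
    binary = stats::binomial(),
    binomial = stats::binomial(),
    poisson = stats::poisson()
  )
  wts <- if (family$name == "binomial") trials else rep(1, length(y))
  fit <- suppressWarnings(stats::glm.fit(X, y, weights = wts, family = glm_fam))
  cf <- fit$coefficients
  if (anyNA(cf)) {
    return(sentinel_record("collinear"))
  }
  eta <- as.numeric(X %*% cf)
  separated <- family$name != "gaussian" &&
    (!fit$converged || max(abs(eta)) > control$eta_clamp)
  # dispersion: fixed at 1 for the discrete families, estimated for gaussian
  XtWX <- crossprod(X * sqrt(fit$weights), X * sqrt(fit$weights))
  covb <- solve(XtWX)
  if (family$name == "gaussian") {
    covb <- covb * sum(fit$weights * fit$residuals^2) / fit$df.residual
  }
  record_from(cf[j], sqrt(covb[j, j]), if (separated) "separation" else "")
}

scan_glmm_impl <- function(y, X0, geno, K, family, trials, control, exact) {
  null_fit <- fit_glmm(y, X0, K, family, trials, control)
  vc0 <- null_fit$vc
  m <- ncol(geno$codes)
  recs <- vector("list", m)
  # warm-start chain: adjacent bins are in LD, so the previous marker's
  # solution is usually an excellent starting point; reset to the null fit
  # whenever a fit fails or does not converge
  start0 <- list(beta = c(null_fit$beta, 0), gamma = null_fit$gamma, vc = vc0)
  chain <- start0
  for (k in seq_len(m)) {
    if (geno$monomorphic[k]) {
      recs[[k]] <- sentinel_record("monomorphic")
      next
    }
    X <- cbind(X0, marker = geno$codes[, k])
    fit <- try(
      fit_glmm(y, X, K, family, trials, control,
        start = chain,
        fix_vc = if (exact) NULL else vc0
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      recs[[k]] <- sentinel_record("nonconverged")
      chain <- start0
      next
    }
    j <- length(fit$beta)
    note <- if (!fit$converged) "nonconverged" else if (fit$clamped) "clamped" else ""
    recs[[k]] <- record_from(unname(fit$beta[j]), fit$se_beta[j], note)
    chain <- if (fit$converged) {
      list(beta = fit$beta, gamma = fit$gamma, vc = fit$vc)
    } else {
      start0
    }
  }
  list(records = dplyr::bind_rows(recs), null_fit = null_fit)
}

scan_psr_impl <- function(y, X0, geno, K, family, trials, control) {
  null_fit <- fit_glmm(y, X0, K, family, trials, control)
  su <- null_fit$setup
  lambda <- null_fit$vc$lambda
  s2 <- null_fit$vc$sigma_e2
  dv <- lambda * su$d + 1
  a <- 1 / dv - 1
  n <- null_fit$n
  k_exp <- if (family$name == "ordinal") family$n_categories - 1L else 1L
  # whiten all marker columns at once: x* = W^{1/2} x (ordinal: -x expanded),
  # then project on the rotated basis; the frozen GLS for marker k only needs
  # small cross-products with the null design and pseudo response
  codes <- geno$codes
  Xmark <- if (k_exp > 1L) {
    -codes[rep(seq_len(n), each = k_exp), , drop = FALSE]
  } else {
    codes
  }
  Xm_star <- w_half_mult(su$Wh, Xmark)
  Xmr <- crossprod(su$U, Xm_star)
  A00 <- su$XtX + crossprod(su$Xr, a * su$Xr)
  b0 <- su$Xty + as.numeric(crossprod(su$Xr, a * su$yr))
  cross0 <- crossprod(su$Xstar, Xm_star) + crossprod(su$Xr, a * Xmr)
  xx <- colSums(Xm_star^2) + colSums(Xmr^2 * a)
  xy <- as.numeric(crossprod(Xm_star, su$ystar)) + as.numeric(crossprod(Xmr, a * su$yr))
  p0 <- ncol(A00)
  j <- p0 + 1L
  m <- ncol(codes)
  recs <- vector("list", m)
  for (k in seq_len(m)) {
    if (geno$monomorphic[k]) {
      recs[[k]] <- sentinel_record("monomorphic")
      next
    }
    A <- rbind(cbind(A00, cross0[, k]), c(cross0[, k], xx[k]))
    b <- c(b0, xy[k])
    covb <- s2 * solve(A)
    beta <- solve(A, b)
    recs[[k]] <- record_from(beta[j], sqrt(covb[j, j]))
  }
  list(records = dplyr::bind_rows(recs), null_fit = null_fit)
}

#' Per-peak QTL summaries for a scan
#'
#' Applies [qtl_summary()] to selected markers using the reporting method's
#' converged null pseudo response.
#'
#' @param scan a [psr_scan()] result from one of the mixed-model methods.
#' @param geno the genotype object used for the scan.
#' @param markers marker IDs to summarize; default the scan's top marker.
#' @return tibble with one row per marker: marker id, scan record fields and
#'   the [qtl_summary()] columns.
#' @export
scan_qtl_summary <- function(scan, geno, markers = NULL) {
  nf <- attr(scan, "null_fit")
  if (is.null(nf)) stop("scan has no null fit (GLM method); QTL summaries need a mixed fit", call. = FALSE)
  if (is.null(markers)) markers <- scan$marker[which.max(scan$wald)]
  fam <- attr(scan, "family")
  k_exp <- if (fam$name == "ordinal") fam$n_categories - 1L else 1L
  purrr::map_dfr(markers, function(mk) {
    x <- geno$codes[, mk]
    if (k_exp > 1L) x <- -rep(x, each = k_exp)
    dplyr::bind_cols(
      scan[scan$marker == mk, c("marker", "effect", "se", "wald", "pvalue")],
      qtl_summary(nf$p_tilde, x, nf$vc)
    )
  })
}
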