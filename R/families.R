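#' Trait families for pseudo-response mixed models
#'
#' A `psr_family` bundles the mean function \eqn{\mu = \zeta(\eta)}, its
#' derivative \eqn{\Delta = \partial\mu/\partial\eta}, the response variance
#' function \eqn{\Sigma(\mu)} and the implied working weights used by the
#' pseudo-response linearization. Five families are supported:
#'
#' * `gaussian` — identity link, constant variance (the scale is carried by the
#'   residual variance component, so `variance_function()` returns 1);
#' * `binary` — logit link, \eqn{\Sigma = \mu(1-\mu)};
#' * `binomial` — logit link on the *proportion* scale: the observation is
#'   `events/trials` and \eqn{\Sigma = \mu(1-\mu)/n_i}. Parameterizing on the
#'   proportion keeps the pseudo-response formulas identical to the binary case;
#' * `poisson` — log link, \eqn{\Sigma = \mu};
#' * `ordinal` — cumulative-logit (proportional odds) with `C >= 3` categories.
#'   Each individual carries `C - 1` cumulative linear predictors
#'   \eqn{\eta_{ic} = \alpha_c - (x_i'\beta + \gamma_i)}, so a positive
#'   coefficient shifts probability mass toward *higher* categories.
#'
#' Means are clamped away from the domain boundary (`mu_eps`, default `1e-8`)
#' because the linearization divides by \eqn{\Delta}; under perfect
#' co-segregation the unclamped weights collapse to zero.
#'
#' @param name one of `"gaussian"`, `"binary"`, `"binomial"`, `"poisson"`,
#'   `"ordinal"`.
#' @param n_categories number of ordinal categories `C` (ordinal only, >= 3).
#' @param mu_eps boundary clamp for means/probabilities.
#' @return an object of class `psr_family`: a list with fields `name`, `link`,
#'   `n_categories`, `mu_eps`.
#' @examples
#' fam <- psr_family("binary")
#' fam_mean(fam, 0)       # 0.5
#' fam_dmu_deta(fam, 0)   # 0.25
#' @export
psr_family <- function(name = c("gaussian", "binary", "binomial", "poisson", "ordinal"),
                       n_categories = NULL, mu_eps = 1e-8) {
  name <- match.arg(name)
  link <- switch(name,
    gaussian = "identity",
    binary = "logit",
    binomial = "logit",
    poisson = "log",
    ordinal = "cumulative-logit"
  )
  if (name == "ordinal") {
    # C = 2 is allowed as the degenerate case (it reproduces the binary fit);
    # phenotype validation requires at least 3 observed categories
    if (is.null(n_categories) || n_categories < 2) {
      stop("ordinal family requires `n_categories` >= 2", call. = FALSE)
    }
  } else {
    n_categories <- NULL
  }
  structure(
    list(name = name, link = link, n_categories = n_categories, mu_eps = mu_eps),
    class = "psr_family"
  )
}

#' @export
print.psr_family <- function(x, ...) {
  cat("<psr_family> ", x$name, " (", x$link, " link",
    if (!is.null(x$n_categories)) paste0(", C = ", x$n_categories), ")\n",
    sep = ""
  )
  invisible(x)
}

clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

expit <- function(x) 1 / (1 + exp(-x))

#' Mean function \eqn{\mu = \zeta(\eta)}
#'
#' Maps the linear predictor to the mean. For the ordinal family `eta` holds
#' cumulative-logit predictors and the result is the vector of cumulative
#' probabilities (clamped into the open unit interval).
#'
#' @param family a [psr_family()].
#' @param eta numeric vector of linear predictors.
#' @return numeric vector of means (cumulative probabilities for ordinal).
#' @export
fam_mean <- function(family, eta) {
  eps <- family$mu_eps
  switch(family$name,
    gaussian = eta,
    binary = ,
    binomial = ,
    ordinal = clamp01(expit(eta), eps),
    poisson = pmax(exp(eta), eps)
  )
}

#' Mean derivative \eqn{\Delta = \partial\mu/\partial\eta}
#'
#' @inheritParams fam_mean
#' @return numeric vector, elementwise derivative at `eta`.
#' @export
fam_dmu_deta <- function(family, eta) {
  mu <- fam_mean(family, eta)
  switch(family$name,
    gaussian = rep(1, length(eta)),
    binary = ,
    binomial = ,
    ordinal = mu * (1 - mu),
    poisson = mu
  )
}

#' Response variance function \eqn{\Sigma(\mu)}
#'
#' Per-observation response variance. `gaussian` returns 1 (scale lives in the
#' residual variance component); `binomial` is on the proportion scale so the
#' variance is divided by the trial count. For `ordinal` use
#' [ordinal_sigma_block()], which returns the full (C-1) x (C-1) covariance of
#' the cumulative indicators.
#'
#' @inheritParams fam_mean
#' @param mu numeric vector of means (proportion scale for binomial).
#' @param trials binomial trial counts, recycled to `length(mu)`.
#' @return numeric vector of variances.
#' @export
fam_variance <- function(family, mu, trials = NULL) {
  switch(family$name,
    gaussian = rep(1, length(mu)),
    binary = mu * (1 - mu),
    binomial = {
      if (is.null(trials)) stop("binomial family requires `trials`", call. = FALSE)
      mu * (1 - mu) / trials
    },
    poisson = mu,
    ordinal = stop("use ordinal_sigma_block() for the ordinal family", call. = FALSE)
  )
}

#' Working weight \eqn{w = \Delta \Sigma^{-1} \Delta}
#'
#' The univariate working weight of the linearized model, so that the working
#' residual covariance is \eqn{R = \sigma_\varepsilon^2\,\mathrm{diag}(1/w)}.
#' For ordinal traits use [ordinal_weight_block()].
#'
#' @inheritParams fam_variance
#' @param eta numeric linear predictors.
#' @return numeric vector of strictly positive weights.
#' @export
fam_weight <- function(family, eta, trials = NULL) {
  mu <- fam_mean(family, eta)
  switch(family$name,
    gaussian = rep(1, length(eta)),
    binary = mu * (1 - mu),
    binomial = {
      if (is.null(trials)) stop("binomial family requires `trials`", call. = FALSE)
      trials * mu * (1 - mu)
    },
    poisson = mu,
    ordinal = stop("use ordinal_weight_block() for the ordinal family", call. = FALSE)
  )
}

#' Covariance block of cumulative indicators for one ordinal individual
#'
#' With cumulative probabilities \eqn{\pi_1 \le \dots \le \pi_{C-1}} the
#' indicators \eqn{u_c = I(y \le c)} have
#' \eqn{\mathrm{cov}(u_c, u_{c'}) = \pi_{\min(c,c')}(1 - \pi_{\max(c,c')})}.
#'
#' @param pi numeric vector of cumulative probabilities (length C-1), strictly
#'   increasing within (0, 1).
#' @return (C-1) x (C-1) covariance matrix.
#' @export
ordinal_sigma_block <- function(pi) {
  cmin <- outer(pi, pi, pmin)
  cmax <- outer(pi, pi, pmax)
  cmin * (1 - cmax)
}

#' Working-weight block for one ordinal individual
#'
#' \eqn{W_i = \Delta_i \Sigma_i^{-1} \Delta_i} with diagonal
#' \eqn{\Delta_i = \mathrm{diag}\{\pi_c(1-\pi_c)\}} and \eqn{\Sigma_i} from
#' [ordinal_sigma_block()].
#'
#' @inheritParams ordinal_sigma_block
#' @return (C-1) x (C-1) positive-definite weight matrix.
#' @export
ordinal_weight_block <- function(pi) {
  delta <- pi * (1 - pi)
  sig <- ordinal_sigma_block(pi)
  d_sig_inv <- solve(sig, diag(delta, nrow = length(pi)))
  diag(delta, nrow = length(pi)) %*% d_sig_inv
}

#' Convert cumulative probabilities to category probabilities
#'
#' @param pi numeric vector of cumulative probabilities \eqn{\pi_1, \dots,
#'   \pi_{C-1}}; must be non-decreasing and inside (0, 1).
#' @return numeric vector of `C` category probabilities summing to 1.
#' @examples
#' cumulative_to_category(c(0.5, 0.75)) # 0.50 0.25 0.25
#' @export
cumulative_to_category <- function(pi) {
  if (any(pi <= 0 | pi >= 1)) {
    stop("cumulative probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(pi, strictly = FALSE)) {
    stop("cumulative probabilities must be non-decreasing", call. = FALSE)
  }
  c(pi[1], diff(pi), 1 - pi[length(pi)])
}
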