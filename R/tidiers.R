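#' Tidy a pseudo-response GLMM fit
#'
#' One row per fixed effect (including ordinal thresholds) with the Wald
#' statistic and p-value per term.
#'
#' @param x a [fit_glmm()] object.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic` (1-df
#'   Wald), `p.value`.
#' @method tidy psr_glmm
#' @export
tidy.psr_glmm <- function(x, ...) {
  wt <- wald_test(unname(x$beta), x$se_beta)
  tibble::tibble(
    term = names(x$beta) %||% paste0("b", seq_along(x$beta)),
    estimate = unname(x$beta),
    std.error = x$se_beta,
    statistic = wt$wald,
    p.value = wt$pvalue
  )
}

#' One-row model summary of a pseudo-response GLMM fit
#'
#' @param x a [fit_glmm()] object.
#' @param ... unused.
#' @return tibble with the variance components, restricted log-likelihood,
#'   iteration counts and convergence flag.
#' @method glance psr_glmm
#' @export
glance.psr_glmm <- function(x, ...) {
  tibble::tibble(
    family = x$family$name,
    nobs = x$n,
    sigma_g2 = x$vc$sigma_g2,
    sigma_e2 = x$vc$sigma_e2,
    lambda = x$vc$lambda,
    logLik = x$loglik,
    inner1 = unname(x$iterations["inner1"]),
    inner2 = unname(x$iterations["inner2"]),
    outer = unname(x$iterations["outer"]),
    converged = x$converged
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
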