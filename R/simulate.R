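#' Marker-based kinship matrix
#'
#' Centered cross-product of the genotype codes, \eqn{K = CC'/s} with C the
#' column-centered code matrix and the scale `s` chosen so that the mean of
#' `diag(K)` is exactly 1. All markers enter, including monomorphic ones
#' (which contribute nothing after centering) and any candidate marker later
#' tested in a scan.
#'
#' @param geno a genotype object, or a plain individuals-by-markers numeric
#'   matrix.
#' @return n x n symmetric kinship matrix with sample IDs as dimnames.
#' @export
kinship_from_markers <- function(geno) {
  codes <- if (inherits(geno, "psr_geno")) geno$codes else as.matrix(geno)
  Cc <- sweep(codes, 2, colMeans(codes))
  if (all(abs(Cc) < 1e-12)) stop("all markers are monomorphic", call. = FALSE)
  K <- tcrossprod(Cc)
  scl <- mean(diag(K))
  K <- K / scl
  dimnames(K) <- list(rownames(codes), rownames(codes))
  # carry the marker factor (K = P P'): the solvers use it to replace the
  # per-iteration eigendecomposition by a thin SVD when m is well below n
  attr(K, "factor") <- Cc / sqrt(scl)
  K
}

#' Simulate bin genotypes with Markov-chain linkage blocks
#'
#' Generates marker codes along each chromosome as a two-state Markov chain:
#' adjacent bins share a genotype unless a recombination "switch" occurs
#' (probability `switch_prob`), which produces realistic LD blocks.
#' `type = "ril"` gives codes −1/+1 (recombinant inbred lines);
#' `type = "f2"` sums two independent gametes to codes −1/0/+1.
#'
#' @param n individuals.
#' @param m markers (split as evenly as possible across chromosomes).
#' @param n_chrom number of chromosomes.
#' @param switch_prob per-interval switch probability.
#' @param type `"ril"` or `"f2"`.
#' @param seed RNG seed; recorded in the output.
#' @return a `psr_geno` object (codes, map, sample IDs).
#' @export
simulate_genotypes <- function(n, m, n_chrom = 5, switch_prob = 0.05,
                               type = c("ril", "f2"), seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  sizes <- diff(round(seq(0, m, length.out = n_chrom + 1)))
  gamete <- function(mc) {
    first <- sample(c(-1, 1), n, replace = TRUE)
    if (mc == 1) {
      return(matrix(first, n, 1))
    }
    cs <- matrix(as.numeric(stats::runif(n * (mc - 1)) < switch_prob), n, mc - 1)
    if (ncol(cs) > 1) {
      for (j in 2:ncol(cs)) cs[, j] <- cs[, j] + cs[, j - 1]
    }
    flips <- cbind(0, cs) %% 2
    first * (1 - 2 * flips)
  }
  blocks <- lapply(sizes, function(mc) {
    if (type == "ril") gamete(mc) else (gamete(mc) + gamete(mc)) / 2
  })
  codes <- do.call(cbind, blocks)
  ids <- sprintf("ind%03d", seq_len(n))
  markers <- sprintf("bin%04d", seq_len(m))
  dimnames(codes) <- list(ids, markers)
  map <- tibble::tibble(
    marker = markers,
    chrom = as.character(rep(seq_len(n_chrom), sizes)),
    pos = as.integer(unlist(lapply(sizes, seq_len)))
  )
  out <- new_psr_geno(codes, map)
  attr(out, "seed") <- seed
  out
}

#' Simulate a polygenic liability with planted QTLs
#'
#' \eqn{\ell = \sum_q \beta_q x_q + \gamma + e}, with polygenic effects
#' \eqn{\gamma \sim N(0, \sigma_\gamma^2 K)} and independent residual
#' \eqn{e \sim N(0, \sigma_e^2 I)}. With `sigma_e2 = 0` the only residual
#' variation enters later at the observation step (e.g. the logistic variance
#' \eqn{\pi^2/3} for a Bernoulli trait), which is the configuration used by
#' the bias study.
#'
#' @param geno genotype object.
#' @param qtl_index marker indices of the planted QTLs.
#' @param beta_q effects on the liability scale, recycled to `qtl_index`.
#' @param sigma_g2 polygenic variance.
#' @param sigma_e2 residual liability variance.
#' @param K kinship; computed from `geno` when `NULL`.
#' @param seed RNG seed.
#' @return numeric liability vector with attribute `seed`.
#' @export
simulate_liability <- function(geno, qtl_index, beta_q, sigma_g2 = 1,
                               sigma_e2 = 0, K = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno$codes)
  beta_q <- rep_len(beta_q, length(qtl_index))
  fixed <- as.numeric(geno$codes[, qtl_index, drop = FALSE] %*% beta_q)
  gamma <- rep(0, n)
  if (sigma_g2 > 0) {
    if (is.null(K)) K <- kinship_from_markers(geno)
    L <- chol(ridge_kinship(K, 1e-6))
    gamma <- sqrt(sigma_g2) * as.numeric(crossprod(L, stats::rnorm(n)))
  }
  e <- if (sigma_e2 > 0) stats::rnorm(n, 0, sqrt(sigma_e2)) else 0
  out <- fixed + gamma + e
  attr(out, "seed") <- seed
  out
}

#' Transform a liability into an observed non-normal trait
#'
#' * `binary`: `mode = "logistic"` draws `Bernoulli(expit(a + b * l))`;
#'   `mode = "threshold"` cuts deterministically at the `threshold_q` quantile.
#' * `binomial`: `Binomial(trials, expit(a + b * l))`, returned as a tibble-ready
#'   list of events/trials in the `events`/`trials` attributes.
#' * `poisson`: `Poisson(exp(a + b * scale(l)))` (the liability is standardized
#'   so `a` is the baseline log mean).
#' * `ordinal`: deterministic cut at `C - 1` quantile thresholds, categories
#'   `1..C`.
#'
#' @param liability numeric liability vector.
#' @param family family name.
#' @param a,b intercept and slope applied to the liability before the
#'   observation model.
#' @param mode binary mode, `"logistic"` or `"threshold"`.
#' @param threshold_q binary threshold quantile.
#' @param trials binomial trial counts (scalar or vector).
#' @param n_categories ordinal category count C.
#' @param probs ordinal cumulative cut quantiles (length C-1); default equal
#'   thirds for C = 3, equal spacing otherwise.
#' @param seed RNG seed.
#' @return numeric trait vector (proportion-ready events for binomial carry
#'   `events`/`trials` attributes), with attribute `seed`.
#' @export
liability_to_trait <- function(liability, family, a = 0, b = 1,
                               mode = c("logistic", "threshold"), threshold_q = 0.5,
                               trials = 10, n_categories = 3, probs = NULL,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- length(liability)
  out <- switch(family,
    binary = {
      if (mode == "logistic") {
        stats::rbinom(n, 1, expit(a + b * liability))
      } else {
        as.numeric(liability > stats::quantile(liability, threshold_q))
      }
    },
    binomial = {
      trials <- rep_len(trials, n)
      ev <- stats::rbinom(n, trials, expit(a + b * liability))
      y <- ev / trials
      attr(y, "events") <- ev
      attr(y, "trials") <- trials
      y
    },
    poisson = {
      lz <- as.numeric(scale(liability))
      stats::rpois(n, exp(a + b * lz))
    },
    ordinal = {
      probs <- probs %||% seq_len(n_categories - 1) / n_categories
      cuts <- stats::quantile(liability, probs)
      1 + vapply(liability, function(l) sum(l > cuts), 0)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
  attr(out, "seed") <- seed
  out
}

#' One-stop simulation of a study dataset
#'
#' Bundles [simulate_genotypes()], [kinship_from_markers()],
#' [simulate_liability()] and [liability_to_trait()] under a single seed and
#' returns inputs ready for [psr_scan()].
#'
#' @param n,m,n_chrom,switch_prob,type passed to [simulate_genotypes()].
#' @param qtl_index,beta_q,sigma_g2,sigma_e2 passed to [simulate_liability()].
#' @param family trait family ("gaussian" returns the liability itself).
#' @param seed RNG seed (one seed drives the whole dataset).
#' @param ... further arguments to [liability_to_trait()].
#' @return list with `geno`, `pheno` (tibble with family attribute), `kinship`,
#'   `liability` and the scenario parameters.
#' @export
simulate_trait <- function(n, m, qtl_index = NULL, beta_q = 1, sigma_g2 = 1,
                           sigma_e2 = 0, family = "binary", n_chrom = 5,
                           switch_prob = 0.05, type = "ril", seed = 1, ...) {
  set.seed(seed)
  geno <- simulate_genotypes(n, m, n_chrom, switch_prob, type)
  K <- kinship_from_markers(geno)
  qtl_index <- qtl_index %||% ceiling(m / 2)
  liab <- simulate_liability(geno, qtl_index, beta_q, sigma_g2, sigma_e2, K)
  if (family == "gaussian") {
    y <- as.numeric(liab)
    fam <- psr_family("gaussian")
  } else {
    y <- liability_to_trait(liab, family, ...)
    fam <- switch(family,
      binary = psr_family("binary"),
      binomial = psr_family("binomial"),
      poisson = psr_family("poisson"),
      ordinal = psr_family("ordinal",
        n_categories = list(...)$n_categories %||% 3
      )
    )
  }
  pheno <- tibble::tibble(id = geno$sample_ids, y = as.numeric(y))
  if (family == "binomial") {
    pheno$events <- attr(y, "events")
    pheno$trials <- attr(y, "trials")
  }
  attr(pheno, "family") <- fam
  list(
    geno = geno, pheno = pheno, kinship = K, liability = as.numeric(liab),
    scenario = list(
      n = n, m = m, qtl_index = qtl_index, beta_q = beta_q,
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, family = family, seed = seed
    )
  )
}

#' Replicated power study with ROC/AUC summaries
#'
#' For each QTL effect size, simulates `replicates` datasets, scans each with
#' the requested methods, and labels the causal marker and its LD neighbors
#' (same chromosome, within `window` bins) as positives. ROC curves pool the
#' per-marker p-values over replicates; AUC is the trapezoid area (equivalently
#' the rank statistic).
#'
#' @param effects QTL effect grid on the liability scale. The default is six
#'   evenly spaced effects that include 0.7 and 1.0, the sizes whose QTL
#'   heritabilities under a logistic binary trait with unit polygenic variance
#'   are about 0.10 and 0.18.
#' @param n,m individuals and markers per replicate.
#' @param replicates replicates per effect size.
#' @param methods subset of `c("glm", "glmm", "p3d", "psr")`.
#' @param family trait family (binary or ordinal make sense here).
#' @param sigma_g2 polygenic variance of the liability.
#' @param window LD window (bins on the causal chromosome counted as true
#'   positives).
#' @param seed master seed; replicate r of effect level e uses a deterministic
#'   sub-seed.
#' @param alpha level used for the per-replicate detection indicator
#'   (Bonferroni over m).
#' @param control a [psr_control()].
#' @return object of class `psr_power`: list with `auc` (tibble: effect,
#'   method, auc), `roc` (tibble of stepwise FPR/TPR), `detection` (tibble of
#'   per-replicate indicators), and the scenario.
#' @export
run_power_study <- function(effects = seq(0.25, 1, by = 0.15), n = 150, m = 50,
                            replicates = 100, methods = c("glmm", "psr"),
                            family = "binary", sigma_g2 = 1, window = 5,
                            seed = 1, alpha = 0.05, control = psr_control()) {
  stopifnot(replicates >= 1)
  thr <- bonferroni_threshold(m, alpha)
  grid <- tidyr::expand_grid(effect = effects, rep = seq_len(replicates))
  res <- purrr::pmap_dfr(grid, function(effect, rep) {
    sub_seed <- (seed * 10000 + round(effect * 100) * 101 + rep) %% .Machine$integer.max
    sim <- simulate_trait(n, m,
      beta_q = effect, sigma_g2 = sigma_g2, sigma_e2 = 0,
      family = family, seed = sub_seed
    )
    causal <- sim$scenario$qtl_index
    map <- sim$geno$map
    positive <- map$chrom == map$chrom[causal] &
      abs(seq_len(m) - causal) <= window
    purrr::map_dfr(methods, function(meth) {
      sc <- suppressWarnings(psr_scan(sim$pheno, sim$geno, sim$kinship,
        method = meth,
        control = control
      ))
      tibble::tibble(
        effect = effect, rep = rep, method = meth,
        marker = sc$marker, positive = positive, pvalue = sc$pvalue
      )
    })
  })
  auc <- res |>
    dplyr::group_by(.data$effect, .data$method) |>
    dplyr::summarise(auc = auc_rank(.data$pvalue, .data$positive), .groups = "drop")
  roc <- res |>
    dplyr::group_by(.data$effect, .data$method) |>
    dplyr::reframe(roc_points(.data$pvalue, .data$positive))
  detection <- res |>
    dplyr::filter(.data$positive) |>
    dplyr::group_by(.data$effect, .data$method, .data$rep) |>
    dplyr::summarise(
      detected = any(.data$pvalue < alpha / m),
      .groups = "drop"
    )
  structure(
    list(
      auc = auc, roc = roc, detection = detection, records = res,
      scenario = list(
        effects = effects, n = n, m = m, replicates = replicates,
        methods = methods, family = family, sigma_g2 = sigma_g2,
        window = window, seed = seed, alpha = alpha, threshold = thr
      )
    ),
    class = "psr_power"
  )
}

# AUC as the Mann-Whitney rank statistic on -p (ties handled by midranks);
# identical to the trapezoid area under the pooled ROC.
auc_rank <- function(pvalue, positive) {
  score <- -pvalue
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(pvalue, positive) {
  o <- order(pvalue)
  tp <- cumsum(positive[o])
  fp <- cumsum(!positive[o])
  tibble::tibble(
    fpr = c(0, fp / max(fp[length(fp)], 1)),
    tpr = c(0, tp / max(tp[length(tp)], 1))
  )
}

#' @export
print.psr_power <- function(x, ...) {
  cat(
    "<psr_power> ", length(x$scenario$effects), " effect levels x ",
    x$scenario$replicates, " replicates (", x$scenario$family, ")\n",
    sep = ""
  )
  print(tidyr::pivot_wider(x$auc, names_from = "method", values_from = "auc"))
  invisible(x)
}

#' Bias study of the pseudo-response estimator
#'
#' Replicated single-marker binary simulations with unit polygenic variance and
#' QTL effects 0 (null), 0.7 and 1.0 — under a logistic observation model these
#' correspond to QTL heritabilities of about 0.10 and 0.18. Each replicate fits
#' the causal-marker GLMM by the pseudo-response method and records the
#' estimated QTL effect, polygenic variance and marker p-value. The estimator's
#' known downward bias in \eqn{(\hat\beta_q, \hat\sigma_\gamma^2)} grows with
#' the QTL size, while the Wald test stays calibrated under the null.
#'
#' @param replicates replicates per effect level.
#' @param effects QTL effect grid (0 rows feed the type-I-error summary).
#' @param n,m individuals and markers.
#' @param sigma_g2 true polygenic variance.
#' @param seed master seed.
#' @param control a [psr_control()].
#' @return object of class `psr_bias`: `estimates` (per-replicate tibble) and
#'   `summary` (per-effect means, Monte-Carlo SEs, type-I error at 0.05).
#' @export
run_bias_study <- function(replicates = 100, effects = c(0, 0.7, 1.0),
                           n = 200, m = 100, sigma_g2 = 1, seed = 1,
                           control = psr_control()) {
  grid <- tidyr::expand_grid(effect = effects, rep = seq_len(replicates))
  est <- purrr::pmap_dfr(grid, function(effect, rep) {
    sub_seed <- (seed * 20000 + round(effect * 100) * 211 + rep) %% .Machine$integer.max
    sim <- simulate_trait(n, m,
      beta_q = effect, sigma_g2 = sigma_g2, sigma_e2 = 0,
      family = "binary", seed = sub_seed
    )
    x <- sim$geno$codes[, sim$scenario$qtl_index]
    X <- cbind("(Intercept)" = 1, marker = x)
    fit <- suppressWarnings(
      fit_glmm(sim$pheno$y, X, sim$kinship, psr_family("binary"), control = control)
    )
    wt <- wald_test(unname(fit$beta["marker"]), fit$se_beta[2])
    tibble::tibble(
      effect = effect, rep = rep,
      beta_hat = unname(fit$beta["marker"]),
      sigma_g2_hat = fit$vc$sigma_g2,
      sigma_e2_hat = fit$vc$sigma_e2,
      pvalue = wt$pvalue, converged = fit$converged,
      # a fit that runs the variance ratio into its search bound has escaped
      # the pseudo-likelihood's domain of validity (quasi-separation through
      # the polygenic term); such fits are flagged and excluded from the
      # bias summaries, which report how many were kept
      boundary = fit$vc$lambda > 0.1 * psr_control()$lambda_bounds[2]
    )
  })
  summ <- est |>
    dplyr::filter(.data$converged, !.data$boundary) |>
    dplyr::group_by(.data$effect) |>
    dplyr::summarise(
      n_kept = dplyr::n(),
      mean_beta = mean(.data$beta_hat),
      se_beta = stats::sd(.data$beta_hat) / sqrt(dplyr::n()),
      mean_sigma_g2 = mean(.data$sigma_g2_hat),
      se_sigma_g2 = stats::sd(.data$sigma_g2_hat) / sqrt(dplyr::n()),
      type1_error = mean(.data$pvalue < 0.05),
      .groups = "drop"
    )
  structure(
    list(
      estimates = est, summary = summ,
      scenario = list(
        replicates = replicates, effects = effects, n = n, m = m,
        sigma_g2 = sigma_g2, seed = seed
      )
    ),
    class = "psr_bias"
  )
}

#' @export
print.psr_bias <- function(x, ...) {
  cat(
    "<psr_bias> ", x$scenario$replicates, " replicates, true sigma_g2 = ",
    x$scenario$sigma_g2, "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}
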