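#' Read a genotype matrix with its marker map
#'
#' Expects a header row `marker, chrom, pos, <id1>, <id2>, ...` with one row
#' per marker and numeric codes per individual; the delimiter is taken from the
#' file extension (`.csv` comma, `.tsv`/`.txt` tab) unless `delim` is given.
#' Missing cells (`NA`) are imputed with the per-marker mean of the observed
#' codes, which keeps every marker column complete for scanning and kinship
#' work; the number of imputed cells is recorded.
#'
#' @param path path to the genotype file.
#' @param delim optional delimiter override.
#' @return a `psr_geno` object: list with `codes` (n x m numeric matrix,
#'   individuals x markers, dimnames set), `map` (tibble: marker, chrom, pos),
#'   `sample_ids`, `n_imputed`, and `monomorphic` (logical per marker).
#' @export
read_genotypes <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(raw)[1:3])) {
    stop("genotype file must start with columns marker, chrom, pos", call. = FALSE)
  }
  if (anyDuplicated(raw$marker)) {
    dups <- unique(raw$marker[duplicated(raw$marker)])
    stop("duplicate marker ID(s): ", paste(dups, collapse = ", "), call. = FALSE)
  }
  sample_ids <- setdiff(names(raw), need)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in header", call. = FALSE)
  code_cols <- raw[sample_ids]
  for (j in seq_along(code_cols)) {
    cj <- code_cols[[j]]
    if (!is.numeric(cj)) {
      bad <- which(!is.na(cj) & is.na(suppressWarnings(as.numeric(cj))))
      if (length(bad)) {
        stop(
          "non-numeric genotype code in column '", sample_ids[j],
          "', marker '", raw$marker[bad[1]], "'",
          call. = FALSE
        )
      }
      code_cols[[j]] <- suppressWarnings(as.numeric(cj))
    }
  }
  codes <- t(as.matrix(code_cols)) # individuals x markers
  dimnames(codes) <- list(sample_ids, raw$marker)
  new_psr_geno(codes, tibble::tibble(
    marker = as.character(raw$marker),
    chrom = as.character(raw$chrom),
    pos = as.integer(raw$pos)
  ))
}

new_psr_geno <- function(codes, map) {
  n_missing <- sum(is.na(codes))
  if (n_missing > 0) {
    mk_mean <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mk_mean[idx[, 2]]
  }
  mono <- apply(codes, 2, function(x) diff(range(x)) == 0)
  structure(
    list(
      codes = codes, map = map, sample_ids = rownames(codes),
      n_imputed = n_missing, monomorphic = unname(mono)
    ),
    class = "psr_geno"
  )
}

#' @export
print.psr_geno <- function(x, ...) {
  cat(
    "<psr_geno> ", nrow(x$codes), " individuals x ", ncol(x$codes), " markers; ",
    sum(x$monomorphic), " monomorphic; ", x$n_imputed, " imputed cells\n",
    sep = ""
  )
  invisible(x)
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a phenotype table
#'
#' Expects a header `id, <trait1>, ...`. Rows with a missing phenotype (or, for
#' binomial traits, a missing event/trial) are dropped and counted. Family
#' invariants are enforced: binary values in {0, 1}; binomial
#' `0 <= event <= trial`, `trial >= 1`; Poisson non-negative integers; ordinal
#' integer categories `1..C` with at least three observed.
#'
#' @param path phenotype file (`.csv` comma, `.tsv`/`.txt` tab).
#' @param trait trait column name (ignored for binomial when `event_col` and
#'   `trial_col` are given).
#' @param family family tag: gaussian, binary, binomial, poisson or ordinal.
#' @param event_col,trial_col binomial event/trial column names.
#' @param delim optional delimiter override.
#' @return a tibble with columns `id`, `y` (trait value; proportion for
#'   binomial), plus `events` and `trials` for binomial; attributes
#'   `family` ([psr_family()]) and `n_dropped`.
#' @export
read_phenotypes <- function(path, trait = NULL,
                            family = c("gaussian", "binary", "binomial", "poisson", "ordinal"),
                            event_col = NULL, trial_col = NULL, delim = NULL) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
  if (!"id" %in% names(raw)) stop("phenotype file must have an 'id' column", call. = FALSE)
  raw$id <- as.character(raw$id)

  if (family == "binomial") {
    if (is.null(event_col) || is.null(trial_col)) {
      stop("binomial traits need `event_col` and `trial_col`", call. = FALSE)
    }
    for (cc in c(event_col, trial_col)) {
      if (!cc %in% names(raw)) stop("column '", cc, "' not found", call. = FALSE)
    }
    keep <- !is.na(raw[[event_col]]) & !is.na(raw[[trial_col]])
    out <- tibble::tibble(
      id = raw$id[keep],
      events = as.numeric(raw[[event_col]][keep]),
      trials = as.numeric(raw[[trial_col]][keep])
    )
    if (any(out$trials < 1)) stop("binomial trials must be >= 1", call. = FALSE)
    if (any(out$events < 0 | out$events > out$trials)) {
      stop("binomial events must satisfy 0 <= event <= trial", call. = FALSE)
    }
    out$y <- out$events / out$trials
    out <- out[c("id", "y", "events", "trials")]
    fam <- psr_family("binomial")
  } else {
    if (is.null(trait)) stop("`trait` must name a phenotype column", call. = FALSE)
    if (!trait %in% names(raw)) stop("trait column '", trait, "' not found", call. = FALSE)
    keep <- !is.na(raw[[trait]])
    y <- as.numeric(raw[[trait]][keep])
    if (family == "binary" && !all(y %in% c(0, 1))) {
      stop("binary trait must contain only 0/1 values", call. = FALSE)
    }
    if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
      stop("poisson trait must be non-negative integers", call. = FALSE)
    }
    if (family == "ordinal") {
      if (any(y != round(y)) || any(y < 1)) {
        stop("ordinal trait must be integer categories 1..C", call. = FALSE)
      }
      C <- max(y)
      if (length(unique(y)) < 3) {
        stop("ordinal trait must have at least 3 observed categories", call. = FALSE)
      }
      fam <- psr_family("ordinal", n_categories = C)
    } else {
      fam <- psr_family(family)
    }
    out <- tibble::tibble(id = raw$id[keep], y = y)
  }
  attr(out, "family") <- fam
  attr(out, "n_dropped") <- nrow(raw) - nrow(out)
  out
}

#' Read a square kinship matrix
#'
#' First row and first column carry sample IDs. Symmetry is checked to 1e-10.
#'
#' @param path kinship CSV/TSV.
#' @param delim optional delimiter override.
#' @return numeric n x n matrix with dimnames.
#' @export
read_kinship <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("kinship file not found: ", path, call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(raw[[1]])
  K <- as.matrix(raw[, -1])
  storage.mode(K) <- "double"
  dimnames(K) <- list(ids, colnames(raw)[-1])
  if (!identical(rownames(K), colnames(K))) {
    stop("kinship row and column IDs disagree", call. = FALSE)
  }
  if (max(abs(K - t(K))) > 1e-10) stop("kinship matrix is not symmetric", call. = FALSE)
  if (any(diag(K) <= 0)) stop("kinship diagonal must be strictly positive", call. = FALSE)
  K
}

#' Align genotypes, phenotypes and kinship on shared samples
#'
#' Restricts all inputs to the intersection of their sample IDs, in the order
#' the IDs appear in the phenotype table; kinship rows and columns are permuted
#' together. Aligning an already aligned triple is a no-op.
#'
#' @param geno a [read_genotypes()] object.
#' @param pheno a [read_phenotypes()] tibble.
#' @param kinship optional kinship matrix with dimnames.
#' @return list with `geno`, `pheno`, `kinship` and `n_dropped` (samples
#'   discarded from any input).
#' @export
align_samples <- function(geno, pheno, kinship = NULL) {
  ids <- intersect(pheno$id, geno$sample_ids)
  if (!is.null(kinship)) ids <- intersect(ids, rownames(kinship))
  if (length(ids) == 0) stop("no shared sample IDs between inputs", call. = FALSE)
  n_dropped <- (nrow(pheno) - length(ids)) + (length(geno$sample_ids) - length(ids)) +
    if (is.null(kinship)) 0L else nrow(kinship) - length(ids)
  fam <- attr(pheno, "family")
  pheno2 <- pheno[match(ids, pheno$id), , drop = FALSE]
  attr(pheno2, "family") <- fam
  geno2 <- geno
  geno2$codes <- geno$codes[ids, , drop = FALSE]
  geno2$sample_ids <- ids
  geno2$monomorphic <- unname(apply(geno2$codes, 2, function(x) diff(range(x)) == 0))
  kin2 <- NULL
  if (!is.null(kinship)) {
    kin2 <- kinship[ids, ids, drop = FALSE]
    P <- attr(kinship, "factor")
    if (!is.null(P)) {
      attr(kin2, "factor") <- P[match(ids, rownames(kinship)), , drop = FALSE]
    }
  }
  list(geno = geno2, pheno = pheno2, kinship = kin2, n_dropped = n_dropped)
}

#' Write scan records to a TSV file
#'
#' Columns `marker, chrom, pos, effect, se, wald, pvalue, neglog10p` (plus a
#' `note` column when present), written at full double precision so a
#' read-back round-trips every numeric field.
#'
#' @param records a scan result tibble (see [psr_scan()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no scan records to write", call. = FALSE)
  }
  cols <- c("marker", "chrom", "pos", "effect", "se", "wald", "pvalue", "neglog10p")
  cols <- c(cols, intersect("note", names(records)))
  out <- as.data.frame(records[cols])
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read scan records written by [write_scan_results()]
#'
#' @param path scan TSV.
#' @return tibble of scan records.
#' @export
read_scan_results <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  raw$marker <- as.character(raw$marker)
  raw$chrom <- as.character(raw$chrom)
  tibble::as_tibble(raw)
}
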