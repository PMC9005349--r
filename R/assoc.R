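# Per-SNP association testing. Covariates are projected out of the phenotype
# and every coded genotype column once (Frisch-Waugh), then each SNP is a
# one-variable least-squares fit, which gives the same estimates as per-SNP
# multiple regressions in linear time.

GWAS_CODINGS <- c("additive_012", "dominance_dev", "x_male02")

#' Build a GWAS covariate design matrix
#'
#' Standard baseline controls: sex, a full set of birth-year dummies, their
#' interactions, and the top genetic principal components. Collinear columns
#' are dropped (pivoted QR), so the result has full column rank.
#'
#' @param sex factor/character/numeric sex indicator (optional).
#' @param birth_year vector treated as categorical (optional).
#' @param pcs matrix of principal components (optional).
#' @return Numeric matrix without an intercept column (the fitters add one).
#' @export
make_covariates <- function(sex = NULL, birth_year = NULL, pcs = NULL) {
  parts <- list()
  if (!is.null(sex) && !is.null(birth_year)) {
    mm <- stats::model.matrix(~ factor(sex) * factor(birth_year))
    parts$sb <- mm[, -1, drop = FALSE]
  } else if (!is.null(sex)) {
    parts$sex <- stats::model.matrix(~ factor(sex))[, -1, drop = FALSE]
  } else if (!is.null(birth_year)) {
    parts$by <- stats::model.matrix(~ factor(birth_year))[, -1, drop = FALSE]
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- colnames(pcs) %||% paste0("PC", seq_len(ncol(pcs)))
    parts$pcs <- pcs
  }
  if (!length(parts)) return(NULL)
  X <- do.call(cbind, parts)
  qrX <- qr(cbind(1, X))
  keep <- qrX$pivot[seq_len(qrX$rank)]
  keep <- setdiff(keep, 1L) - 1L  # drop the probe intercept
  X[, keep, drop = FALSE]
}

# residualize columns of M on covariates C (with intercept)
residualize <- function(M, C = NULL) {
  M <- as.matrix(M)
  C1 <- if (is.null(C)) matrix(1, nrow(M), 1) else cbind(1, as.matrix(C))
  qrC <- qr(C1)
  if (qrC$rank < ncol(C1)) stop("rank-deficient covariate matrix")
  M - C1 %*% qr.coef(qrC, M)
}

#' Genome-wide association scan
#'
#' Per-SNP least squares of the covariate-residualized phenotype on the coded,
#' covariate-residualized genotype. Codings: `additive_012` uses allele counts
#' as given; `dominance_dev` uses the orthogonal coding `{0, 2p, 4p - 2}` with
#' the in-sample allele frequency `p`; `x_male02` expects male genotypes in
#' `{0, 2}` (X-chromosome convention) and otherwise behaves additively.
#'
#' @param genotypes numeric matrix, individuals by SNPs, allele counts 0/1/2.
#' @param y numeric phenotype, no missing values.
#' @param covariates optional covariate matrix (no intercept column).
#' @param coding one of `"additive_012"`, `"dominance_dev"`, `"x_male02"`.
#' @param sex required for `x_male02`: "M"/"F" vector used to validate the
#'   male 0/2 coding.
#' @param snp_info optional data frame with per-SNP `snp_id`, `chr`, `pos`,
#'   `a1`, `a2` (defaults are generated).
#' @return Data frame of summary statistics, one row per SNP, with columns
#'   `snp_id, chr, pos, a1, a2, freq_a1, n, beta, se, z, p, coding`.
#'   Monomorphic SNPs are flagged (`note = "monomorphic"`) with `NA`
#'   estimates.
#' @export
run_gwas <- function(genotypes, y, covariates = NULL,
                     coding = c("additive_012", "dominance_dev", "x_male02"),
                     sex = NULL, snp_info = NULL) {
  coding <- match.arg(coding)
  G <- as.matrix(genotypes)
  n <- nrow(G)
  stopifnot(length(y) == n)
  if (anyNA(y)) stop("missing phenotype values are not allowed")
  if (anyNA(G)) stop("missing genotypes are not allowed in run_gwas")
  if (!all(G %in% 0:2)) stop("genotypes must be allele counts in {0, 1, 2}")
  if (coding == "x_male02") {
    if (is.null(sex)) stop("x_male02 coding requires a sex vector")
    male <- sex == "M" | sex == 1
    if (any(G[male, ] == 1)) {
      stop("x_male02 coding: male genotypes must lie in {0, 2}")
    }
  }

  freq <- colMeans(G) / 2
  mono <- freq <= 0 | freq >= 1
  X <- switch(coding,
    additive_012 = G,
    x_male02 = G,
    dominance_dev = dominance_coding(G, freq))

  q <- if (is.null(covariates)) 1L else 1L + ncol(as.matrix(covariates))
  yr <- drop(residualize(y, covariates))
  Xr <- residualize(X, covariates)

  sxx <- colSums(Xr^2)
  sxy <- drop(crossprod(Xr, yr))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  df <- n - q - 1L
  if (df <= 0) stop("not enough observations for the covariate set")
  rss <- sum(yr^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  z <- beta / se
  p <- z_to_p(z)

  if (is.null(snp_info)) {
    snp_info <- data.frame(
      snp_id = colnames(G) %||% sprintf("rs%05d", seq_len(ncol(G))),
      chr = 1L, pos = seq_len(ncol(G)), a1 = "A", a2 = "G",
      stringsAsFactors = FALSE)
  }
  out <- data.frame(
    snp_id = snp_info$snp_id, chr = snp_info$chr, pos = snp_info$pos,
    a1 = snp_info$a1, a2 = snp_info$a2, freq_a1 = freq, n = n,
    beta = beta, se = se, z = z, p = p, coding = coding,
    note = ifelse(mono, "monomorphic", ""),
    stringsAsFactors = FALSE)
  out[mono, c("beta", "se", "z", "p")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Top genetic principal components
#'
#' Top-`k` eigenvectors (unit norm) of the individual-by-individual
#' cross-product of column-standardized genotypes -- the usual PCs of the
#' genomic relatedness matrix.
#'
#' @param genotypes allele-count matrix, individuals by SNPs.
#' @param k number of components (`0` returns a zero-column matrix).
#' @return Numeric matrix, individuals by `k`, columns `PC1..PCk`.
#' @export
compute_pcs <- function(genotypes, k = 10L) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (k == 0L) return(matrix(numeric(0), n, 0))
  if (n < k + 1L) stop("need at least k + 1 individuals")
  sds <- apply(G, 2, stats::sd)
  keep <- sds > 0
  Z <- scale(G[, keep, drop = FALSE])
  sv <- svd(Z, nu = k, nv = 0)
  if (k > sum(sv$d > 1e-8)) stop("k exceeds the rank of the genotype matrix")
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Sex-stratified association scans
#'
#' Runs [run_gwas()] independently within each sex, producing per-stratum
#' summary statistics suitable for inverse-variance-weighted combination and
#' cross-stratum genetic-correlation estimation.
#'
#' @inheritParams run_gwas
#' @param sex "M"/"F" vector; both sexes must be present.
#' @param covariates optional covariate matrix (subset per stratum).
#' @return List with elements `male` and `female`, each a summary-statistic
#'   data frame.
#' @export
sex_stratified_gwas <- function(genotypes, y, sex, covariates = NULL,
                                coding = "additive_012", snp_info = NULL) {
  male <- sex == "M" | sex == 1
  if (!any(male) || all(male)) stop("both sexes must be present")
  sub <- function(idx) {
    cv <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[idx, , drop = FALSE]
    run_gwas(genotypes[idx, , drop = FALSE], y[idx], cv, coding = coding,
             sex = sex[idx], snp_info = snp_info)
  }
  list(male = sub(which(male)), female = sub(which(!male)))
}
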