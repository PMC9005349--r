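# LD-score regression for additive and dominance-deviation summary
# statistics. Under Hardy-Weinberg equilibrium the correlation between the
# dominance codings of two SNPs equals the squared allele-count correlation,
# so the dominance LD score is the sum of fourth powers of r where the
# additive score sums squares; dominance information decays faster with LD.

#' Compute additive and dominance LD scores
#'
#' Either empirically from a genotype panel (pairwise correlations within the
#' supplied blocks, optionally bias-adjusted), or analytically from a block
#' specification when the LD structure is exchangeable with known within-block
#' correlation `r`: `l_add = 1 + (m_b - 1) r^2`, `l_dom = 1 + (m_b - 1) r^4`.
#'
#' @param panel optional genotype matrix (individuals by SNPs, >= 50
#'   individuals) used for empirical estimation.
#' @param block_spec optional analytic specification: list with `block_sizes`
#'   (integer vector) and `r` (within-block genotype correlation).
#' @param blocks with `panel`: integer vector assigning SNPs to LD blocks
#'   (cross-block r is taken as 0). Defaults to one common block.
#' @param adjust with `panel`: subtract the small-sample bias
#'   `(1 - r^2) / (n - 2)` from each squared correlation.
#' @return Data frame `snp_id`, `l_add`, `l_dom`, `block` (jackknife block
#'   ids are assigned downstream by [ldsc_fit()]).
#' @export
compute_ld_scores <- function(panel = NULL, block_spec = NULL, blocks = NULL,
                              adjust = TRUE) {
  if (is.null(panel) == is.null(block_spec)) {
    stop("supply exactly one of panel or block_spec")
  }
  if (!is.null(block_spec)) {
    m_b <- block_spec$block_sizes
    r2 <- block_spec$r^2
    l_add <- unlist(lapply(m_b, function(m) rep(1 + (m - 1) * r2, m)))
    l_dom <- unlist(lapply(m_b, function(m) rep(1 + (m - 1) * r2^2, m)))
    block <- rep(seq_along(m_b), m_b)
  } else {
    G <- as.matrix(panel)
    if (nrow(G) < 50) stop("panel must contain at least 50 individuals")
    if (any(apply(G, 2, stats::sd) == 0)) {
      stop("monomorphic SNP in the LD panel")
    }
    m <- ncol(G)
    block <- blocks %||% rep(1L, m)
    stopifnot(length(block) == m)
    n <- nrow(G)
    l_add <- numeric(m); l_dom <- numeric(m)
    for (b in unique(block)) {
      cols <- which(block == b)
      R2 <- stats::cor(G[, cols, drop = FALSE])^2
      if (adjust) R2 <- R2 - (1 - R2) / (n - 2)
      diag(R2) <- 1
      R2 <- pmax(R2, 0)
      l_add[cols] <- rowSums(R2)
      l_dom[cols] <- rowSums(R2^2)
    }
  }
  data.frame(snp_id = sprintf("rs%05d", seq_along(l_add)),
             l_add = l_add, l_dom = pmin(l_dom, l_add), block = block,
             stringsAsFactors = FALSE)
}

# contiguous jackknife block ids for M SNPs; when an LD-block assignment is
# given, jackknife units are unions of whole LD blocks so that correlated
# chi-squared values are never split across units
jackknife_blocks <- function(M, n_blocks = 200L, ld_blocks = NULL) {
  n_blocks <- max(min(n_blocks, M %/% 10L), 2L)
  if (is.null(ld_blocks)) return(sort(rep_len(seq_len(n_blocks), M)))
  stopifnot(length(ld_blocks) == M)
  u <- unique(ld_blocks)
  n_blocks <- min(n_blocks, length(u))
  grp <- stats::setNames(sort(rep_len(seq_len(n_blocks), length(u))), u)
  unname(grp[as.character(ld_blocks)])
}

# weighted least squares of chisq on l; returns c(intercept, slope)
ldsc_wls <- function(chisq, l, w) {
  X <- cbind(1, l)
  fit <- stats::lm.wfit(X, chisq, w)
  fit$coefficients
}

#' LD-score regression fit
#'
#' Weighted regression of the association chi-squared statistics on LD scores
#' with a free intercept. The slope estimates `N h2 / M`, so
#' `h2 = slope * M / N`; the intercept captures confounding-type inflation.
#' Standard errors come from a delete-one block jackknife over contiguous SNP
#' blocks. Weights are `1 / max(l, 1)` in a single pass.
#'
#' @param chisq per-SNP chi-squared statistics (`z^2`).
#' @param ld_scores per-SNP LD scores (`l_add` for additive mode, `l_dom` for
#'   dominance mode).
#' @param N GWAS sample size (scalar or per-SNP; the mean is used).
#' @param M number of SNPs the heritability refers to (defaults to
#'   `length(chisq)`).
#' @param mode `"additive"` or `"dominance"` (label only; pass the matching
#'   scores).
#' @param n_jackknife_blocks number of contiguous jackknife blocks
#'   (default 200, reduced to `M / 10` for small M).
#' @param ld_blocks optional per-SNP LD-block assignment; jackknife units are
#'   then unions of whole LD blocks, which keeps the block jackknife honest
#'   when LD units are wide.
#' @return List of class `ldsc_fit`: `h2`, `intercept`, `se_h2`,
#'   `se_intercept`, `M`, `N`, `mean_chisq`, `confounding_share` (NA when
#'   mean chi-squared <= 1), `mode`.
#' @export
ldsc_fit <- function(chisq, ld_scores, N, M = length(chisq),
                     mode = c("additive", "dominance"),
                     n_jackknife_blocks = 200L, ld_blocks = NULL) {
  mode <- match.arg(mode)
  ok <- is.finite(chisq) & is.finite(ld_scores)
  chisq <- chisq[ok]; l <- ld_scores[ok]
  if (!is.null(ld_blocks)) ld_blocks <- ld_blocks[ok]
  m_used <- length(chisq)
  if (m_used < 200L) stop("need at least 200 SNPs for LD-score regression")
  if (stats::var(l) <= 0) stop("degenerate LD-score variance")
  Nbar <- mean(N)
  w <- 1 / pmax(l, 1)

  co <- ldsc_wls(chisq, l, w)
  blocks <- jackknife_blocks(m_used, n_jackknife_blocks, ld_blocks)
  B <- max(blocks)
  if (B < 2L) stop("need at least 2 jackknife blocks")
  jk <- vapply(seq_len(B), function(b) {
    keep <- blocks != b
    ldsc_wls(chisq[keep], l[keep], w[keep])
  }, numeric(2))
  jk_se <- sqrt((B - 1) / B * rowSums((jk - rowMeans(jk))^2))

  h2 <- co[2] * M / Nbar
  mean_chi <- mean(chisq)
  conf <- if (mean_chi > 1) {
    min(max((co[1] - 1) / (mean_chi - 1), 0), 1)
  } else NA_real_
  structure(list(h2 = unname(h2), intercept = unname(co[1]),
                 se_h2 = unname(jk_se[2] * M / Nbar),
                 se_intercept = unname(jk_se[1]),
                 M = M, N = Nbar, mean_chisq = mean_chi,
                 confounding_share = conf, mode = mode,
                 n_jackknife_blocks = B),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit %s> h2 = %.4g (se %.3g), intercept = %.4g (se %.3g), mean chi2 = %.3f, M = %d\n",
              x$mode, x$h2, x$se_h2, x$intercept, x$se_intercept,
              x$mean_chisq, x$M))
  invisible(x)
}

#' Share of chi-squared inflation attributable to confounding
#'
#' The attenuation-ratio convention: `(intercept - 1) / (mean_chisq - 1)`,
#' clipped to `[0, 1]`.
#'
#' @param intercept LD-score regression intercept.
#' @param mean_chisq mean association chi-squared (> 1 required).
#' @return Proportion in `[0, 1]`.
#' @export
confounding_share <- function(intercept, mean_chisq) {
  if (!is.finite(mean_chisq) || mean_chisq <= 1) {
    stop("confounding share is defined only when mean chi-squared exceeds 1")
  }
  min(max((intercept - 1) / (mean_chisq - 1), 0), 1)
}

#' Cross-trait genetic correlation by LD-score regression
#'
#' Regresses the product `z1 * z2` on LD scores; the slope estimates
#' `sqrt(N1 N2) * gencov / M`, and the genetic correlation is
#' `gencov / sqrt(h2_1 h2_2)` with the per-trait heritabilities estimated by
#' [ldsc_fit()]. Uncertainty is a delete-one block jackknife of the whole
#' pipeline (all three slopes recomputed per block).
#'
#' @param z1,z2 per-SNP z statistics of the two traits on a shared SNP set.
#' @param ld_scores per-SNP LD scores.
#' @param N1,N2 the two sample sizes.
#' @param M SNP count for the heritability scale.
#' @param n_jackknife_blocks jackknife granularity.
#' @return List with `rg`, `se`, `gencov`, `h2_1`, `h2_2`.
#' @export
cross_trait_rg <- function(z1, z2, ld_scores, N1, N2, M = length(z1),
                           n_jackknife_blocks = 200L) {
  stopifnot(length(z1) == length(z2), length(z1) == length(ld_scores))
  l <- ld_scores
  w <- 1 / pmax(l, 1)
  est_all <- function(keep) {
    s1 <- ldsc_wls(z1[keep]^2, l[keep], w[keep])[2]
    s2 <- ldsc_wls(z2[keep]^2, l[keep], w[keep])[2]
    sc <- ldsc_wls((z1 * z2)[keep], l[keep], w[keep])[2]
    h1 <- s1 * M / N1; h2 <- s2 * M / N2
    gc <- sc * M / sqrt(N1 * N2)
    if (h1 <= 0 || h2 <= 0) return(c(NA_real_, gc, h1, h2))
    c(gc / sqrt(h1 * h2), gc, h1, h2)
  }
  full <- est_all(rep(TRUE, length(l)))
  if (is.na(full[1])) {
    stop("nonpositive heritability estimate; genetic correlation undefined")
  }
  blocks <- jackknife_blocks(length(l), n_jackknife_blocks)
  B <- max(blocks)
  jk <- vapply(seq_len(B), function(b) est_all(blocks != b)[1], numeric(1))
  jk <- jk[is.finite(jk)]
  se <- sqrt((length(jk) - 1) / length(jk) * sum((jk - mean(jk))^2))
  list(rg = full[1], se = se, gencov = full[2], h2_1 = full[3], h2_2 = full[4])
}

#' Signal share of the variance of estimated dominance effects
#'
#' Decomposes the variance of estimated (dominance) effect sizes into the
#' share due to true effect-size variance versus sampling noise:
#' `max(0, 1 - mean(se^2) / var(beta_hat))`.
#'
#' @param beta_hats estimated per-SNP effects (>= 100 SNPs).
#' @param ses their standard errors.
#' @return Proportion in `[0, 1]`.
#' @export
dominance_signal_share <- function(beta_hats, ses) {
  ok <- is.finite(beta_hats) & is.finite(ses)
  beta_hats <- beta_hats[ok]; ses <- ses[ok]
  if (length(beta_hats) < 100L) stop("need at least 100 SNPs")
  v <- stats::var(beta_hats)
  if (v <= 0) stop("zero variance of the estimated effects")
  max(0, 1 - mean(ses^2) / v)
}
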