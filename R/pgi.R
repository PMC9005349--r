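# Polygenic-index construction and evaluation: clumping + thresholding
# weights, scoring with allele harmonization, incremental R-squared and
# Nagelkerke R-squared, decile reports, accuracy summaries, the expected-R2
# curve and the chi-squared GWAS power model.

#' Clumping-and-thresholding PGI weights
#'
#' Selects lead SNPs by [clump()] at the given p-value threshold and assigns
#' each lead SNP its meta-analysis effect estimate as weight.
#'
#' @param stats summary-statistic data frame (needs `snp_id`, `p`, `beta`,
#'   `a1`).
#' @param ld_lookup LD lookup as in [clump()].
#' @param p_threshold p-value cutoff (`1` keeps every SNP subject to LD
#'   pruning).
#' @param r2_threshold clumping r-squared cutoff.
#' @return Data frame of class `pgi_weights`: `snp_id`, `a1`, `weight`,
#'   `method` (`"ct_<threshold>"`). Empty (with a warning) when no SNP
#'   survives.
#' @export
build_ct_weights <- function(stats, ld_lookup, p_threshold,
                             r2_threshold = 0.1) {
  leads <- clump(stats, ld_lookup, p_threshold, r2_threshold)
  tag <- paste0("ct_", format(p_threshold, scientific = TRUE, digits = 2))
  if (!length(leads)) {
    warning("no SNP survives the p-value threshold ", p_threshold)
  }
  i <- match(leads, stats$snp_id)
  out <- data.frame(snp_id = leads, a1 = stats$a1[i], weight = stats$beta[i],
                    method = rep(tag, length(leads)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pgi_weights", "data.frame")
  out
}

#' Infinitesimal shrinkage weights over LD blocks
#'
#' Closed-form LD-aware shrinkage under an infinitesimal architecture: within
#' each LD block with genotype correlation matrix `R`, the weights solve
#' `(M/(N h2) I + R) w = beta_hat` for the block's standardized marginal
#' effects. For unlinked SNPs this reduces to
#' `w = beta_hat / (1 + M/(N h2))`. A lightweight alternative to full
#' posterior samplers for LD-aware PGI weighting.
#'
#' @param stats summary statistics on the standardized scale (`snp_id`,
#'   `a1`, `beta`, `n`; see [standardized_effects()]).
#' @param blocks per-SNP LD-block assignment.
#' @param within_block_r pairwise genotype correlation inside blocks
#'   (exchangeable LD, as produced by the simulator).
#' @param h2 assumed SNP heritability of the trait.
#' @param M SNP count the heritability refers to.
#' @return A `pgi_weights` data frame with `method = "inf_shrink"`.
#' @export
build_inf_weights <- function(stats, blocks, within_block_r, h2,
                              M = nrow(stats)) {
  stopifnot(length(blocks) == nrow(stats), h2 > 0)
  lambda <- M / (mean(stats$n) * h2)
  w <- numeric(nrow(stats))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    m_b <- length(idx)
    R <- matrix(within_block_r, m_b, m_b)
    diag(R) <- 1
    w[idx] <- solve(R + diag(lambda, m_b), stats$beta[idx])
  }
  out <- data.frame(snp_id = stats$snp_id, a1 = stats$a1, weight = w,
                    method = rep("inf_shrink", nrow(stats)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pgi_weights", "data.frame")
  out
}

#' Score individuals with PGI weights
#'
#' `PGI_i = sum_j dosage_ij * w_j` over the SNPs shared between the genotype
#' matrix and the weight table. Weights whose effect allele is the genotype
#' matrix's other allele are applied to the complementary dosage
#' (`2 - dosage`); unresolvable SNPs are dropped. Missing dosages are imputed
#' with the SNP mean.
#'
#' @param genotypes dosage matrix, individuals by SNPs, colnames = SNP ids.
#' @param weights a `pgi_weights` data frame (or any frame with `snp_id`,
#'   `a1`, `weight`).
#' @param effect_allele the genotype matrix's counted allele per SNP (scalar
#'   or vector; defaults to the `effect_allele` attribute, else weights are
#'   assumed aligned).
#' @param other_allele optional other-allele vector used to resolve swaps.
#' @return Numeric PGI vector, one entry per individual.
#' @export
score_pgi <- function(genotypes, weights, effect_allele = NULL,
                      other_allele = NULL) {
  G <- as.matrix(genotypes)
  snp <- colnames(G)
  stopifnot(!is.null(snp))
  effect_allele <- effect_allele %||% attr(genotypes, "effect_allele")
  i <- match(weights$snp_id, snp)
  ok <- !is.na(i)
  if (!any(ok)) stop("no overlapping SNPs between genotypes and weights")
  i <- i[ok]
  w <- weights$weight[ok]
  if (!is.null(effect_allele)) {
    ea <- rep_len(effect_allele, ncol(G))[i]
    match_ea <- weights$a1[ok] == ea
    if (!is.null(other_allele)) {
      oa <- rep_len(other_allele, ncol(G))[i]
      swapped <- weights$a1[ok] == oa
      drop <- !(match_ea | swapped)
    } else {
      swapped <- !match_ea
      drop <- rep(FALSE, length(i))
    }
    i <- i[!drop]; w <- w[!drop]
    swapped <- swapped[!drop]
  } else {
    swapped <- rep(FALSE, length(i))
  }
  D <- G[, i, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  if (any(swapped)) D[, swapped] <- 2 - D[, swapped, drop = FALSE]
  drop(D %*% w)
}

r2_of_fit <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Incremental R-squared of a PGI
#'
#' Difference in R-squared between the phenotype regression with and without
#' the PGI, the standard baseline being sex, birth-year dummies, their
#' interactions and top PCs. A percentile bootstrap over individuals gives the
#' CI.
#'
#' @param y quantitative phenotype.
#' @param pgi the polygenic index.
#' @param covariates baseline covariate matrix (may be `NULL`).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed,level bootstrap settings.
#' @return List `(delta_r2, r2_with, r2_without, ci, se, n)`.
#' @export
incremental_r2 <- function(y, pgi, covariates = NULL, n_boot = 1000L,
                           seed = 1L, level = 0.95) {
  n <- length(y)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0) else
    as.matrix(covariates)
  stopifnot(nrow(C) == n, length(pgi) == n)
  if (n <= ncol(C) + 2L) stop("too few observations for the covariate set")
  stat <- function(i) {
    r2_of_fit(y[i], cbind(C[i, , drop = FALSE], pgi[i])) -
      (if (ncol(C)) r2_of_fit(y[i], C[i, , drop = FALSE]) else 0)
  }
  d <- stat(seq_len(n))
  reps <- if (n_boot > 0) {
    boot_pairs(n, n_boot, seed, stat)
  } else numeric(0)
  list(delta_r2 = max(d, 0),
       r2_with = r2_of_fit(y, cbind(C, pgi)),
       r2_without = if (ncol(C)) r2_of_fit(y, C) else 0,
       ci = if (length(reps)) percentile_ci(reps, level) else c(NA, NA),
       se = if (length(reps)) stats::sd(reps) else NA_real_, n = n)
}

#' Incremental Nagelkerke R-squared of a PGI for a binary outcome
#'
#' Fits logistic or probit regressions of the outcome on the covariates with
#' and without the PGI and reports the difference of their Nagelkerke
#' R-squared values (each computed against the intercept-only model).
#'
#' @param y_binary 0/1 outcome with both classes present.
#' @param pgi the polygenic index.
#' @param covariates baseline covariates (may be `NULL`).
#' @param link `"logistic"` or `"probit"`.
#' @return List `(delta_r2, r2_with, r2_without, separation)`; `separation`
#'   flags (quasi-)perfect separation, in which case the estimates are `NA`.
#' @export
nagelkerke_incremental <- function(y_binary, pgi, covariates = NULL,
                                   link = c("logistic", "probit")) {
  link <- match.arg(link)
  fam <- stats::binomial(link = if (link == "logistic") "logit" else "probit")
  y <- as.integer(y_binary)
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  n <- length(y)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xw <- if (is.null(C)) cbind(pgi) else cbind(C, pgi)
  sep <- FALSE
  fit_glm <- function(X) {
    withCallingHandlers(
      stats::glm.fit(cbind(1, X), y, family = fam),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
  }
  glm_loglik <- function(fit) {
    mu <- fit$fitted.values
    sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  }
  f0 <- fit_glm(matrix(numeric(0), n, 0))
  fw <- fit_glm(Xw)
  fo <- if (is.null(C)) f0 else fit_glm(C)
  if (sep) {
    return(list(delta_r2 = NA_real_, r2_with = NA_real_,
                r2_without = NA_real_, separation = TRUE))
  }
  l0 <- glm_loglik(f0)
  nag <- function(l1) (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n))
  r2w <- nag(glm_loglik(fw))
  r2o <- if (is.null(C)) 0 else nag(glm_loglik(fo))
  list(delta_r2 = r2w - r2o, r2_with = r2w, r2_without = r2o,
       separation = FALSE)
}

#' Outcome prevalence and odds ratios by PGI decile
#'
#' Splits the sample into PGI deciles (rank order, stable ties), reports the
#' outcome prevalence per decile with exact binomial CIs, and odds ratios of
#' each decile against a reference decile from a logistic regression with
#' covariates.
#'
#' @param pgi polygenic index (n >= 100).
#' @param outcome 0/1 outcome.
#' @param covariates optional covariates for the odds-ratio model.
#' @param reference_decile decile used as odds-ratio reference (default 1,
#'   the lowest).
#' @param level CI level.
#' @return Data frame with one row per decile: `decile`, `n`, `prevalence`,
#'   `prev_lo`, `prev_hi`, `odds_ratio`, `or_lo`, `or_hi`.
#' @export
decile_report <- function(pgi, outcome, covariates = NULL,
                          reference_decile = 1L, level = 0.95) {
  n <- length(pgi)
  stopifnot(length(outcome) == n)
  if (n < 100L) stop("need at least 100 individuals for a decile report")
  y <- as.integer(outcome)
  rk <- rank(pgi, ties.method = "first")
  dec <- ceiling(rk * 10 / n)
  dec <- pmin(pmax(dec, 1L), 10L)

  prev <- t(vapply(1:10, function(d) {
    k <- sum(y[dec == d]); m <- sum(dec == d)
    ci <- stats::binom.test(k, m, conf.level = level)$conf.int
    c(m, k / m, ci[1], ci[2])
  }, numeric(4)))

  or <- matrix(NA_real_, 10, 3)
  or[reference_decile, ] <- c(1, 1, 1)
  if (length(unique(y)) == 2L) {
    df <- data.frame(y = y, dec = stats::relevel(factor(dec),
                                                 as.character(reference_decile)))
    X <- stats::model.matrix(~ dec, df)[, -1, drop = FALSE]
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
    fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    zq <- stats::qnorm(1 - (1 - level) / 2)
    labs <- paste0("Xdec", setdiff(1:10, reference_decile))
    for (d in setdiff(1:10, reference_decile)) {
      row <- paste0("Xdec", d)
      if (row %in% rownames(cf)) {
        b <- cf[row, 1]; s <- cf[row, 2]
        or[d, ] <- exp(c(b, b - zq * s, b + zq * s))
      }
    }
  }
  data.frame(decile = 1:10, n = prev[, 1], prevalence = prev[, 2],
             prev_lo = prev[, 3], prev_hi = prev[, 4],
             odds_ratio = or[, 1], or_lo = or[, 2], or_hi = or[, 3])
}

#' Sample-size-weighted mean R-squared
#'
#' `sum(n_i * r2_i) / sum(n_i)`, e.g. 15.8 percent at n = 5,653 and 12.0
#' percent at n = 10,843 average to 13.3 percent.
#'
#' @param r2_values R-squared values (any consistent scale, e.g. percent).
#' @param sample_sizes positive weights.
#' @return Weighted mean on the input scale.
#' @export
weighted_mean_r2 <- function(r2_values, sample_sizes) {
  stopifnot(length(r2_values) == length(sample_sizes),
            length(r2_values) > 0, all(sample_sizes > 0))
  sum(r2_values * sample_sizes) / sum(sample_sizes)
}

#' Relative prediction accuracy
#'
#' Ratio of the PGI's R-squared in a target sample to the reference sample,
#' in percent: `100 * r2_target / r2_reference`.
#'
#' @param r2_target,r2_reference R-squared values, reference > 0.
#' @return Percentage.
#' @export
relative_accuracy <- function(r2_target, r2_reference) {
  if (r2_reference <= 0) stop("reference R-squared must be positive")
  100 * r2_target / r2_reference
}

#' Fit the expected-accuracy curve E(R2) = A / (B + 1/N)
#'
#' Nonlinear least squares of observed `(N, R2)` points on the two-parameter
#' accuracy curve. Starting values come from the linearization
#' `1/R2 = B/A + (1/A)(1/N)`; two points are solved exactly.
#'
#' @param points data frame with columns `N` and `R2` (>= 2 distinct `N`).
#' @param max_iter Gauss-Newton iteration cap.
#' @return Object of class `expected_r2_curve`: `A`, `B`, `predict(N)`,
#'   `asymptote` (= A/B), `residuals`.
#' @export
fit_expected_r2 <- function(points, max_iter = 100L) {
  stopifnot(all(c("N", "R2") %in% names(points)))
  pts <- points[order(points$N), ]
  if (length(unique(pts$N)) < 2L) stop("need >= 2 points with distinct N")
  lin <- stats::lm(I(1 / R2) ~ I(1 / N), data = pts)
  A0 <- 1 / stats::coef(lin)[2]
  B0 <- stats::coef(lin)[1] * A0
  if (!is.finite(A0) || A0 <= 0 || !is.finite(B0) || B0 <= 0) {
    A0 <- max(pts$R2) / 2; B0 <- 0.5
  }
  if (nrow(pts) == 2L) {
    A <- unname(A0); B <- unname(B0)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(R2 ~ A / (B + 1 / N), data = pts,
                        start = list(A = unname(A0), B = unname(B0)),
                        control = minpack.lm::nls.lm.control(
                          maxiter = max_iter)),
      error = function(e) stop("expected-R2 curve fit did not converge: ",
                               conditionMessage(e)))
    A <- stats::coef(fit)[["A"]]; B <- stats::coef(fit)[["B"]]
  }
  pred <- function(N) A / (B + 1 / N)
  structure(list(A = A, B = B, predict = pred, asymptote = A / B,
                 residuals = pts$R2 - pred(pts$N)),
            class = "expected_r2_curve")
}

#' @export
print.expected_r2_curve <- function(x, ...) {
  cat(sprintf("<expected_r2_curve> A = %.4g, B = %.4g, asymptote A/B = %.4g\n",
              x$A, x$B, x$asymptote))
  invisible(x)
}

#' GWAS power for a given per-SNP R-squared
#'
#' Power of the 1-df chi-squared association test with noncentrality
#' `N * r2` at significance level `alpha`.
#'
#' @param N GWAS sample size.
#' @param r2 phenotypic variance explained by the SNP, in `[0, 1)`.
#' @param alpha two-sided significance level.
#' @return Power in `[0, 1]`; equals `alpha` at `r2 = 0`.
#' @export
gwas_power <- function(N, r2, alpha = 5e-8) {
  stopifnot(N > 0, r2 >= 0, r2 < 1, alpha > 0, alpha < 1)
  q <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(q, df = 1, ncp = N * r2, lower.tail = FALSE)
}

#' Smallest per-SNP R-squared detectable at a given power
#'
#' Inverts [gwas_power()] in `r2` by root-finding.
#'
#' @param N GWAS sample size.
#' @param power target power, in `(alpha, 1)`.
#' @param alpha significance level.
#' @return The detectable R-squared (proportion of variance, not percent).
#' @examples
#' # dominance scan at N = 2,574,253: 80% power needs R2 of about 0.0015%
#' 100 * detectable_r2(2574253, 0.80, 5e-8)
#' @export
detectable_r2 <- function(N, power, alpha = 5e-8) {
  stopifnot(N > 0, alpha > 0, alpha < 1)
  if (power <= alpha || power >= 1) {
    stop("power target must lie strictly between alpha and 1")
  }
  f <- function(r2) gwas_power(N, r2, alpha) - power
  upper <- 0.5
  while (f(upper) < 0 && upper < 1 - 1e-9) upper <- (upper + 1) / 2
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}
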