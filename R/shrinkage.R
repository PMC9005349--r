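# Empirical-Bayes winner's-curse adjustment, replication-record prediction,
# and inbreeding-depression (directional dominance) estimation.
#
# With a proper normal prior on true effects, the posterior mean
# beta * tau2 / (tau2 + se2) is valid conditional on the observed estimate
# regardless of how the SNP was selected for significance -- selection acts
# on the data, not on the prior -- so no explicit truncation correction is
# needed for lead-SNP adjustment.

#' Fit an empirical-Bayes prior for standardized SNP effects
#'
#' Method-of-moments normal prior: since `E[chi2] = 1 + N tau2` for
#' standardized effects, `tau2 = max(0, mean_chi2_adjusted - 1) / mean(N)`
#' where the intercept-adjusted mean chi-squared subtracts any confounding
#' inflation. Optionally a point-normal (spike-and-slab) prior is fitted by
#' maximum likelihood on the z statistics.
#'
#' @param stats summary-statistic data frame (`z`, `n`; >= 1000 SNPs).
#' @param intercept LD-score intercept used to adjust the mean chi-squared.
#' @param method `"normal"` (method of moments, default) or `"point_normal"`
#'   (two-component maximum likelihood with null mass `pi0`).
#' @param min_snps minimum SNP count demanded for a stable moment fit
#'   (default 1000; lower it only for demonstration-scale runs).
#' @return List of class `eb_prior`: `tau2`, `pi0` (1 component: `NA`),
#'   `method`, `n_snps`, `mean_n`.
#' @export
fit_eb_prior <- function(stats, intercept = 1,
                         method = c("normal", "point_normal"),
                         min_snps = 1000L) {
  method <- match.arg(method)
  ok <- is.finite(stats$z) & is.finite(stats$n)
  z <- stats$z[ok]; N <- stats$n[ok]
  if (length(z) < min_snps) {
    stop("need at least ", min_snps, " SNPs to fit the prior")
  }
  mean_chi <- mean(z^2) - (intercept - 1)
  Nbar <- mean(N)
  if (mean_chi < 1) {
    warning("intercept-adjusted mean chi-squared below 1; tau2 set to 0")
  }
  tau2 <- max(0, mean_chi - 1) / Nbar
  pi0 <- NA_real_
  if (method == "point_normal") {
    nll <- function(par) {
      p0 <- stats::plogis(par[1])
      t2 <- exp(par[2])
      -sum(log(p0 * stats::dnorm(z) +
                 (1 - p0) * stats::dnorm(z, 0, sqrt(1 + N * t2))))
    }
    t2_start <- max(tau2, 1e-3 / Nbar)
    opt <- stats::optim(c(0, log(t2_start)), nll, method = "Nelder-Mead")
    pi0 <- stats::plogis(opt$par[1])
    tau2 <- exp(opt$par[2])
  }
  structure(list(tau2 = tau2, pi0 = pi0, method = method,
                 n_snps = length(z), mean_n = Nbar),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("<eb_prior %s> tau2 = %.3g%s (fit on %d SNPs, mean N = %.0f)\n",
              x$method, x$tau2,
              if (is.na(x$pi0)) "" else sprintf(", pi0 = %.3f", x$pi0),
              x$n_snps, x$mean_n))
  invisible(x)
}

#' Winner's-curse adjustment of effect estimates
#'
#' Posterior-mean shrinkage under the fitted prior:
#' `beta * tau2 / (tau2 + se^2)` for the normal prior; the point-normal prior
#' additionally multiplies by the posterior probability of being non-null.
#'
#' @param beta estimated effects (standardized scale matching the prior fit).
#' @param se their standard errors (> 0).
#' @param prior an [fit_eb_prior()] object.
#' @return Vector of posterior-mean effects.
#' @export
winners_curse_adjust <- function(beta, se, prior) {
  stopifnot(inherits(prior, "eb_prior"), all(se > 0))
  shrink <- prior$tau2 / (prior$tau2 + se^2)
  post <- beta * shrink
  if (!is.na(prior$pi0)) {
    z <- beta / se
    lik1 <- stats::dnorm(z, 0, sqrt(1 + prior$tau2 / se^2))
    lik0 <- stats::dnorm(z)
    w1 <- (1 - prior$pi0) * lik1 /
      ((1 - prior$pi0) * lik1 + prior$pi0 * lik0)
    post <- post * w1
  }
  post
}

#' Expected replication record of lead SNPs
#'
#' Under the posterior of the true effect given the discovery estimate
#' (`mean m = beta * tau2/(tau2+se2)`, `var v = tau2 se2/(tau2+se2)`), the
#' replication z statistic is normal with mean `m / se_rep` and variance
#' `1 + v / se_rep^2`. Reports the per-SNP probability of sign concordance
#' and of one-sided significance in the discovery direction at `alpha_rep`,
#' plus their aggregates.
#'
#' @param discovery_stats data frame with `beta` and `se` of the lead SNPs.
#' @param prior an [fit_eb_prior()] object (normal component used).
#' @param N_rep replication sample size (sets `se_rep = 1/sqrt(N_rep)` on the
#'   standardized scale unless `se_rep` is supplied).
#' @param alpha_rep replication significance level in `(0, 1)`.
#' @param se_rep optional per-SNP replication standard errors.
#' @return List with `per_snp` (data frame `p_sign`, `p_sig`) and aggregates
#'   `expected_sign_concordance`, `expected_significant`.
#' @export
replication_expectations <- function(discovery_stats, prior, N_rep,
                                     alpha_rep = 0.05, se_rep = NULL) {
  stopifnot(inherits(prior, "eb_prior"))
  if (alpha_rep <= 0 || alpha_rep >= 1) stop("alpha_rep must be in (0, 1)")
  beta <- discovery_stats$beta
  se <- discovery_stats$se
  se_rep <- se_rep %||% rep(1 / sqrt(N_rep), length(beta))
  t2 <- prior$tau2
  m <- beta * t2 / (t2 + se^2)
  v <- t2 * se^2 / (t2 + se^2)
  mu <- m / se_rep
  sdv <- sqrt(1 + v / se_rep^2)
  sgn <- sign(beta)
  p_sign <- stats::pnorm(0, mean = sgn * mu, sd = sdv, lower.tail = FALSE)
  zcrit <- stats::qnorm(1 - alpha_rep)
  p_sig <- stats::pnorm(zcrit, mean = sgn * mu, sd = sdv, lower.tail = FALSE)
  list(per_snp = data.frame(p_sign = p_sign, p_sig = p_sig),
       expected_sign_concordance = mean(p_sign),
       expected_significant = mean(p_sig))
}

#' Inbreeding depression from individual-level data
#'
#' OLS regression of the phenotype on the pedigree inbreeding coefficient `F`
#' (plus optional covariates). The conventional summary is the expected
#' phenotype difference for offspring of first cousins (`F = 1/16`) relative
#' to outbred individuals, reported in months when the phenotype is in years.
#'
#' @param y phenotype.
#' @param F inbreeding coefficients (must vary).
#' @param covariates optional covariate matrix.
#' @param y_in_years multiply the first-cousin effect by 12 (months).
#' @return List of class `id_estimate`: `b` (slope), `se`, `p`,
#'   `first_cousin_offspring_effect` (`b / 16`, in months if requested), `n`.
#' @export
estimate_id_individual <- function(y, F, covariates = NULL,
                                   y_in_years = TRUE) {
  if (stats::var(F) == 0) {
    stop("inbreeding coefficient is constant; slope undefined")
  }
  df <- data.frame(.y = y, .f = F)
  fit <- if (is.null(covariates)) {
    stats::lm(.y ~ .f, data = df)
  } else {
    stats::lm(.y ~ .f + X, data = cbind(df, X = as.matrix(covariates)))
  }
  cf <- summary(fit)$coefficients
  b <- cf[".f", 1]; se <- cf[".f", 2]; p <- cf[".f", 4]
  fc <- b / 16 * if (y_in_years) 12 else 1
  structure(list(b = unname(b), se = unname(se), p = unname(p),
                 first_cousin_offspring_effect = unname(fc),
                 units = if (y_in_years) "months" else "phenotype units",
                 n = length(y)),
            class = "id_estimate")
}

#' @export
print.id_estimate <- function(x, ...) {
  cat(sprintf("<id_estimate> slope on F = %.3f (se %.3f, p = %.3g); first-cousin offspring effect = %.2f %s\n",
              x$b, x$se, x$p, x$first_cousin_offspring_effect, x$units))
  invisible(x)
}

#' Inbreeding depression from dominance summary statistics
#'
#' Unlinked-SNP approximation: a unit increase in genome-wide inbreeding
#' shifts the mean of the orthogonal dominance coding `{0, 2p, 4p-2}` by
#' `-2 p (1 - p)` at each SNP, so the implied slope of the phenotype on `F`
#' is `B = -sum_j 2 p_j (1 - p_j) delta_hat_j`, with sampling variance
#' `sum_j (2 p_j (1 - p_j))^2 se_j^2`.
#'
#' @param stats dominance-coded summary statistics (`coding` must be
#'   `"dominance_dev"`): columns `beta`, `se`, `freq_a1`.
#' @param y_in_years report the first-cousin effect in months.
#' @return List of class `id_estimate` as in [estimate_id_individual()].
#' @export
estimate_id_sumstats <- function(stats, y_in_years = TRUE) {
  if (!all(stats$coding == "dominance_dev")) {
    stop("summary statistics must carry the dominance_dev coding tag")
  }
  ok <- is.finite(stats$beta) & is.finite(stats$se)
  p <- stats$freq_a1[ok]
  w <- 2 * p * (1 - p)
  B <- -sum(w * stats$beta[ok])
  se <- sqrt(sum(w^2 * stats$se[ok]^2))
  z <- B / se
  fc <- B / 16 * if (y_in_years) 12 else 1
  structure(list(b = B, se = se, p = z_to_p(z),
                 first_cousin_offspring_effect = fc,
                 units = if (y_in_years) "months" else "phenotype units",
                 n = sum(ok)),
            class = "id_estimate")
}
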