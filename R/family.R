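# Direct versus population effects of a polygenic index from trio and
# sibling designs. Relatedness within families is absorbed by a family
# random intercept (lme4); when the mixed fit is singular the estimates
# coincide with OLS.

new_effect_estimate <- function(delta, alpha_f, alpha_m, vcov, design, n,
                                between = NA_real_) {
  structure(list(delta = unname(delta), alpha_f = unname(alpha_f),
                 alpha_m = unname(alpha_m), vcov = vcov, design = design,
                 n = n, between = unname(between)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate %s> delta = %.4f (se %.4f)", x$design,
              x$delta, sqrt(x$vcov[1, 1])))
  if (!is.na(x$alpha_f)) {
    cat(sprintf(", alpha_f = %.4f, alpha_m = %.4f", x$alpha_f, x$alpha_m))
  }
  cat(", n =", x$n, "\n")
  invisible(x)
}

check_pgi_scale <- function(pgi, label) {
  v <- stats::var(pgi)
  if (v == 0) stop("zero variance in ", label)
  if (abs(v - 1) > 0.2) {
    warning(label, " variance is ", format(v, digits = 3),
            "; PGIs should be standardized to variance 1")
  }
}

fit_family_lmm <- function(df, formula, fid) {
  df$.fid <- fid
  # one observation per family leaves no within/between contrast for a
  # random intercept; the mixed fit then reduces to OLS
  if (length(unique(fid)) == length(fid)) {
    fit <- stats::lm(formula, data = df)
    return(list(coef = stats::coef(fit)[-1],
                vcov = suppressWarnings(
                  stats::vcov(fit)[-1, -1, drop = FALSE])))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(stats::update(formula, . ~ . + (1 | .fid)), data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  list(coef = lme4::fixef(fit)[-1],
       vcov = as.matrix(stats::vcov(fit))[-1, -1, drop = FALSE])
}

#' Direct and parental PGI effects from parent-offspring trios
#'
#' Regresses the phenotype on the child's, father's and mother's PGIs jointly
#' (family random intercept). The child coefficient is the direct effect; the
#' parental coefficients absorb indirect effects and assortment-induced
#' components.
#'
#' @param y phenotype (standardized/residualized beforehand).
#' @param pgi_child,pgi_father,pgi_mother PGIs standardized to variance 1.
#' @param family_id family identifier (clustering unit).
#' @return An `effect_estimate` with `design = "trio"` and a 3x3 `vcov` over
#'   `(delta, alpha_f, alpha_m)`.
#' @export
estimate_trio_effects <- function(y, pgi_child, pgi_father, pgi_mother,
                                  family_id = seq_along(y)) {
  n <- length(y)
  stopifnot(length(pgi_child) == n, length(pgi_father) == n,
            length(pgi_mother) == n, length(family_id) == n)
  if (n < 5L) stop("fewer trios than parameters")
  check_pgi_scale(pgi_child, "child PGI")
  df <- data.frame(y = y, pc = pgi_child, pf = pgi_father, pm = pgi_mother)
  fit <- fit_family_lmm(df, y ~ pc + pf + pm, family_id)
  keep <- c("pc", "pf", "pm")
  new_effect_estimate(fit$coef["pc"], fit$coef["pf"], fit$coef["pm"],
                      fit$vcov[keep, keep], "trio", n)
}

#' Direct effect of a PGI from genotyped siblings
#'
#' Regresses the phenotype on the deviation of the individual's PGI from the
#' sibship mean PGI, and on that mean (family random intercept). The deviation
#' coefficient estimates the direct effect; the between-family coefficient is
#' retained for the assortative-mating transform.
#'
#' @param y phenotype.
#' @param pgi standardized PGI.
#' @param sibship_id family identifier; families contribute only if they have
#'   at least two genotyped siblings.
#' @return An `effect_estimate` with `design = "sib"`; `alpha_f`/`alpha_m`
#'   are `NA`, the between-family coefficient is in `$between`, and `vcov` is
#'   2x2 over `(delta, between)`.
#' @export
estimate_sib_effects <- function(y, pgi, sibship_id) {
  n <- length(y)
  stopifnot(length(pgi) == n, length(sibship_id) == n)
  check_pgi_scale(pgi, "PGI")
  size <- stats::ave(rep(1, n), sibship_id, FUN = sum)
  keep <- size >= 2
  if (!any(keep)) stop("no families with two or more genotyped siblings")
  y <- y[keep]; pgi <- pgi[keep]; fid <- sibship_id[keep]
  fam_mean <- stats::ave(pgi, fid)
  dev <- pgi - fam_mean
  if (stats::var(dev) == 0) {
    stop("zero within-family PGI variance (identical siblings only)")
  }
  df <- data.frame(y = y, dev = dev, btw = fam_mean)
  fit <- fit_family_lmm(df, y ~ dev + btw, fid)
  keep2 <- c("dev", "btw")
  new_effect_estimate(fit$coef["dev"], NA_real_, NA_real_,
                      fit$vcov[keep2, keep2], "sib", length(y),
                      between = fit$coef["btw"])
}

#' Population effect from direct and parental effects under assortment
#'
#' At assortative-mating equilibrium with mate-pair PGI correlation `r`, the
#' covariance between a standardized child PGI and either parent's PGI is
#' `(1 + r) / 2`, so the marginal (population) effect of the PGI is
#' `beta_pop = delta + ((1 + r) / 2) * (alpha_f + alpha_m)`.
#'
#' @param delta direct effect.
#' @param alpha_f,alpha_m parental PGI coefficients.
#' @param r_mate_pgi mate-pair PGI correlation, `|r| < 1`.
#' @param vcov optional 3x3 covariance of `(delta, alpha_f, alpha_m)`; when
#'   supplied the 2x2 covariance of `(delta, beta_pop)` is returned too.
#' @return `beta_pop` (scalar), or a list `(beta_pop, vcov)` when `vcov` is
#'   given.
#' @export
population_transform <- function(delta, alpha_f, alpha_m, r_mate_pgi,
                                 vcov = NULL) {
  stopifnot(abs(r_mate_pgi) < 1)
  k <- (1 + r_mate_pgi) / 2
  beta_pop <- delta + k * (alpha_f + alpha_m)
  if (is.null(vcov)) return(beta_pop)
  stopifnot(all(dim(vcov) == c(3L, 3L)))
  Tm <- rbind(c(1, 0, 0), c(1, k, k))
  list(beta_pop = beta_pop, vcov = Tm %*% vcov %*% t(Tm))
}

#' Combine direct-effect estimates across designs
#'
#' Inverse-variance combination of the direct-effect estimates from sibling
#' and trio designs, optionally accounting for covariance between the two
#' estimates when they share a dataset (see
#' [estimate_design_covariance()]).
#'
#' @param estimates list of `effect_estimate` objects.
#' @param cross_cov covariance between the first two estimates' deltas
#'   (0 for independent samples).
#' @return An `effect_estimate` with `design = "combined"`; parental
#'   coefficients are inverse-variance-combined over the estimates that have
#'   them.
#' @export
combine_designs <- function(estimates, cross_cov = 0) {
  stopifnot(length(estimates) >= 1L)
  if (length(estimates) == 1L) return(estimates[[1]])
  d <- vapply(estimates, `[[`, numeric(1), "delta")
  v <- vapply(estimates, function(e) e$vcov[1, 1], numeric(1))
  k <- length(d)
  V <- diag(v, k)
  if (k == 2L) V[1, 2] <- V[2, 1] <- cross_cov
  ones <- rep(1, k)
  Vi <- solve(V)
  w <- drop(Vi %*% ones) / drop(ones %*% Vi %*% ones)
  delta <- sum(w * d)
  var_delta <- 1 / drop(ones %*% Vi %*% ones)

  # parental coefficients: IVW over the estimates that carry them
  has_a <- !vapply(estimates, function(e) is.na(e$alpha_f), logical(1))
  if (any(has_a)) {
    af <- vapply(estimates[has_a], `[[`, numeric(1), "alpha_f")
    am <- vapply(estimates[has_a], `[[`, numeric(1), "alpha_m")
    vf <- vapply(estimates[has_a], function(e) e$vcov[2, 2], numeric(1))
    vm <- vapply(estimates[has_a], function(e) e$vcov[3, 3], numeric(1))
    alpha_f <- sum(af / vf) / sum(1 / vf)
    alpha_m <- sum(am / vm) / sum(1 / vm)
    vcov3 <- diag(c(var_delta, 1 / sum(1 / vf), 1 / sum(1 / vm)))
    # carry the delta-alpha covariances from the trio fits, IVW-scaled
    tr <- estimates[has_a][[1]]
    if (ncol(tr$vcov) == 3L) {
      scale_f <- (1 / sum(1 / vf)) / tr$vcov[2, 2]
      vcov3[1, 2] <- vcov3[2, 1] <- tr$vcov[1, 2] *
        sqrt(scale_f * var_delta / tr$vcov[1, 1])
      scale_m <- (1 / sum(1 / vm)) / tr$vcov[3, 3]
      vcov3[1, 3] <- vcov3[3, 1] <- tr$vcov[1, 3] *
        sqrt(scale_m * var_delta / tr$vcov[1, 1])
    }
  } else {
    alpha_f <- NA_real_; alpha_m <- NA_real_
    vcov3 <- matrix(var_delta, 1, 1)
  }
  n <- sum(vapply(estimates, `[[`, numeric(1), "n"))
  new_effect_estimate(delta, alpha_f, alpha_m, vcov3, "combined", n)
}

#' Cross-design covariance by clustered bootstrap
#'
#' When sibling and trio estimates are computed on overlapping families, their
#' sampling covariance is estimated by resampling whole families and
#' recomputing both direct-effect estimates per replicate.
#'
#' @param sib_data list `(y, pgi, sibship_id)` for the sibling design.
#' @param trio_data list `(y, pgi_child, pgi_father, pgi_mother, family_id)`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return Covariance (scalar) between the two delta estimates.
#' @export
estimate_design_covariance <- function(sib_data, trio_data, n_boot = 200L,
                                       seed = 1L) {
  fams <- union(unique(sib_data$sibship_id), unique(trio_data$family_id))
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(fams, replace = TRUE)
      sib_rows <- unlist(lapply(seq_along(take), function(i) {
        which(sib_data$sibship_id == take[i])
      }))
      trio_rows <- unlist(lapply(seq_along(take), function(i) {
        which(trio_data$family_id == take[i])
      }))
      sib_fid <- rep(seq_along(take), times = vapply(take, function(f) {
        sum(sib_data$sibship_id == f)
      }, numeric(1)))
      ds <- tryCatch(
        estimate_sib_effects(sib_data$y[sib_rows], sib_data$pgi[sib_rows],
                             sib_fid)$delta,
        error = function(e) NA_real_)
      dt <- tryCatch(
        estimate_trio_effects(trio_data$y[trio_rows],
                              trio_data$pgi_child[trio_rows],
                              trio_data$pgi_father[trio_rows],
                              trio_data$pgi_mother[trio_rows],
                              seq_along(trio_rows))$delta,
        error = function(e) NA_real_)
      c(ds, dt)
    }, numeric(2))
  })
  ok <- stats::complete.cases(t(reps))
  stats::cov(reps[1, ok], reps[2, ok])
}

#' Ratio of direct to population effect and the implied R-squared share
#'
#' `ratio = delta / beta_pop`; the share of the PGI's predictive power
#' attributable to the direct effect is `100 * ratio^2` percent. The standard
#' error of the ratio is by the delta method from the joint covariance of
#' `(delta, beta_pop)`.
#'
#' @param delta direct effect.
#' @param beta_pop population effect (nonzero).
#' @param vcov optional 2x2 covariance of `(delta, beta_pop)`.
#' @return List `(ratio, share_pct, se_ratio)` (`se_ratio = NA` without
#'   `vcov`).
#' @examples
#' ratio_and_share(0.556, 1)$share_pct  # 30.9
#' @export
ratio_and_share <- function(delta, beta_pop, vcov = NULL) {
  if (beta_pop == 0) stop("population effect is zero; ratio undefined")
  ratio <- delta / beta_pop
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(1 / beta_pop, -delta / beta_pop^2)
    se <- sqrt(drop(g %*% vcov %*% g))
  }
  list(ratio = ratio, share_pct = 100 * ratio^2, se_ratio = se)
}
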