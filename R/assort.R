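# Mate-pair PGI correlation analysis: the phenotypic-assortment prediction
# r_y * r_p * r_m, percentile pair-bootstrap uncertainty, and the cumulative
# residualization ladder.

boot_pairs <- function(n_pairs, n_boot, seed, statistic) {
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(sample.int(n_pairs, replace = TRUE))
    }, numeric(1))
  })
}

percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

#' Mate-pair PGI correlation with bootstrap CI
#'
#' Pearson correlation of the two partners' PGIs with a percentile bootstrap
#' over mate pairs (the sampling unit is the pair).
#'
#' @param pgi_m,pgi_f the two partners' PGIs, one entry per pair
#'   (>= 30 pairs).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (recorded in the output).
#' @param level CI level.
#' @return List `(r, se, ci, n_pairs, n_boot, seed)`.
#' @export
mate_pair_pgi_correlation <- function(pgi_m, pgi_f, n_boot = 1000L,
                                      seed = 1L, level = 0.95) {
  n <- length(pgi_m)
  stopifnot(length(pgi_f) == n)
  if (n < 30L) stop("need at least 30 mate pairs")
  if (stats::sd(pgi_m) == 0 || stats::sd(pgi_f) == 0) {
    stop("zero variance in a partner's PGI")
  }
  r <- stats::cor(pgi_m, pgi_f)
  reps <- boot_pairs(n, n_boot, seed, function(i) {
    stats::cor(pgi_m[i], pgi_f[i])
  })
  list(r = r, se = stats::sd(reps), ci = percentile_ci(reps, level),
       n_pairs = n, n_boot = n_boot, seed = seed)
}

#' Mate-pair PGI correlation predicted under phenotypic assortment
#'
#' If mates match on the phenotype alone (and the PGI-phenotype relationship
#' is linear), the mate-pair PGI correlation equals the product
#' `r_y * r_p * r_m` of the mate-pair phenotypic correlation and the two
#' partner-specific phenotype-PGI correlations. All three ingredients and the
#' product's uncertainty are estimated on the same pairs by a joint pair
#' bootstrap.
#'
#' @param pairs data frame with columns `pgi_m`, `pgi_f`, `y_m`, `y_f`
#'   (one row per mate pair; `_m` = male/father, `_f` = female/mother).
#' @param n_boot,seed,level bootstrap settings.
#' @return List of class `mate_pair_stats`: `r_pgi` (observed, with `se_r_pgi`
#'   and `ci_r_pgi`), `r_y`, `r_p`, `r_m`, `predicted` (= `r_y*r_p*r_m`),
#'   `se_predicted`, `ci_predicted`, `n_pairs`.
#' @export
predicted_under_phenotypic_assortment <- function(pairs, n_boot = 1000L,
                                                  seed = 1L, level = 0.95) {
  need <- c("pgi_m", "pgi_f", "y_m", "y_f")
  stopifnot(all(need %in% names(pairs)))
  n <- nrow(pairs)
  prod_stat <- function(i) {
    stats::cor(pairs$y_m[i], pairs$y_f[i]) *
      stats::cor(pairs$y_m[i], pairs$pgi_m[i]) *
      stats::cor(pairs$y_f[i], pairs$pgi_f[i])
  }
  r_y <- stats::cor(pairs$y_m, pairs$y_f)
  r_p <- stats::cor(pairs$y_m, pairs$pgi_m)
  r_m <- stats::cor(pairs$y_f, pairs$pgi_f)
  obs <- mate_pair_pgi_correlation(pairs$pgi_m, pairs$pgi_f, n_boot,
                                   substream_seed(seed, "obs"), level)
  reps <- boot_pairs(n, n_boot, substream_seed(seed, "pred"), prod_stat)
  structure(list(r_pgi = obs$r, se_r_pgi = obs$se, ci_r_pgi = obs$ci,
                 r_y = r_y, r_p = r_p, r_m = r_m,
                 predicted = r_y * r_p * r_m,
                 se_predicted = stats::sd(reps),
                 ci_predicted = percentile_ci(reps, level),
                 n_pairs = n, n_boot = n_boot, seed = seed),
            class = "mate_pair_stats")
}

#' @export
print.mate_pair_stats <- function(x, ...) {
  cat(sprintf("<mate_pair_stats> observed r_pgi = %.3f (se %.3f); phenotypic-assortment prediction r_y*r_p*r_m = %.3f (se %.3f); %d pairs\n",
              x$r_pgi, x$se_r_pgi, x$predicted, x$se_predicted, x$n_pairs))
  invisible(x)
}

#' Residualization ladder of the mate-pair PGI correlation
#'
#' Re-estimates the mate-pair PGI correlation after residualizing each
#' partner's PGI on that partner's own covariates (never jointly), for a
#' sequence of cumulative regressor sets -- typically own phenotype, then
#' genetic PCs, then further phenotypes. Under pure phenotypic assortment the
#' correlation should drop to zero at the first rung.
#'
#' @param pairs data frame with `pgi_m`, `pgi_f` and covariate columns
#'   suffixed `_m` / `_f` (e.g. `y_m`, `y_f`, `pc1_m`, `pc1_f`).
#' @param regressor_sets list of character vectors of covariate base names
#'   (without suffix); sets are used cumulatively in the given order.
#' @param n_boot,seed,level bootstrap settings.
#' @return Data frame with one row per rung: `rung`, `regressors`, `r`, `se`,
#'   `ci_lo`, `ci_hi`. Rung 0 is the raw correlation.
#' @export
residualized_pgi_correlation <- function(pairs, regressor_sets,
                                         n_boot = 1000L, seed = 1L,
                                         level = 0.95) {
  stopifnot(is.list(regressor_sets), length(regressor_sets) >= 1L)
  n <- nrow(pairs)
  resid_one <- function(pgi, vars, suffix, idx = seq_len(n)) {
    X <- as.matrix(pairs[idx, paste0(vars, suffix), drop = FALSE])
    r <- drop(residualize(pgi[idx], X))
    if (stats::sd(r) < 1e-10 * stats::sd(pgi[idx])) {
      stop("residual PGI variance is zero; a regressor is collinear with ",
           "the PGI")
    }
    r
  }
  rungs <- vector("list", length(regressor_sets) + 1L)
  cum <- character(0)
  for (k in 0:length(regressor_sets)) {
    if (k > 0) cum <- unique(c(cum, regressor_sets[[k]]))
    vars <- cum
    stat <- function(i) {
      if (!length(vars)) {
        stats::cor(pairs$pgi_m[i], pairs$pgi_f[i])
      } else {
        stats::cor(resid_one(pairs$pgi_m, vars, "_m", i),
                   resid_one(pairs$pgi_f, vars, "_f", i))
      }
    }
    r <- stat(seq_len(n))
    reps <- boot_pairs(n, n_boot, substream_seed(seed, paste0("rung", k)),
                       stat)
    ci <- percentile_ci(reps, level)
    rungs[[k + 1L]] <- data.frame(
      rung = k,
      regressors = if (length(vars)) paste(vars, collapse = "+") else "(none)",
      r = r, se = stats::sd(reps), ci_lo = ci[1], ci_hi = ci[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rungs)
}

#' Percent reduction of a correlation after residualization
#'
#' `100 * (1 - r_resid / r_raw)`: e.g. a drop from 0.175 to 0.110 is a 37
#' percent reduction.
#'
#' @param r_raw raw correlation (nonzero).
#' @param r_resid residualized correlation.
#' @param digits optional rounding of the reported percentage.
#' @return Percentage reduction.
#' @export
percent_reduction <- function(r_raw, r_resid, digits = NULL) {
  if (r_raw == 0) stop("raw correlation is zero; reduction undefined")
  out <- 100 * (1 - r_resid / r_raw)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
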