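# Summary-statistic harmonization, meta-analysis, SE inflation and clumping.

FLIP <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) FLIP[a1] == a2

#' Default quality-control thresholds
#'
#' @param maf_min minimum minor-allele frequency retained in mean-chi-squared
#'   reporting.
#' @param n_min_fraction SNPs with `N` below this fraction of the maximum `N`
#'   are excluded from mean-chi-squared reporting.
#' @param drop_ambiguous_palindromic_above_freq palindromic (A/T, C/G) SNPs
#'   whose minor-allele frequency exceeds this value are strand-ambiguous and
#'   dropped during harmonization.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, n_min_fraction = 0.9,
                          drop_ambiguous_palindromic_above_freq = 0.4) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            n_min_fraction >= 0, n_min_fraction <= 1,
            drop_ambiguous_palindromic_above_freq > 0,
            drop_ambiguous_palindromic_above_freq <= 0.5)
  structure(list(maf_min = maf_min, n_min_fraction = n_min_fraction,
                 drop_ambiguous_palindromic_above_freq =
                   drop_ambiguous_palindromic_above_freq),
            class = "qc_thresholds")
}

#' Harmonize summary statistics against reference alleles
#'
#' Aligns each study's effect allele to the reference: records with swapped
#' alleles have their effect sign flipped and frequency complemented;
#' strand-flipped records are complemented and then aligned; palindromic SNPs
#' whose minor-allele frequency exceeds the ambiguity threshold are dropped
#' (strand cannot be resolved); any remaining allele mismatch is dropped with
#' a log entry. Harmonization is idempotent.
#'
#' @param statsets list of summary-statistic data frames (columns as produced
#'   by [run_gwas()]: at least `snp_id`, `a1`, `a2`, `freq_a1`, `beta`, `z`).
#' @param reference_alleles data frame with `snp_id`, `a1`, `a2`.
#' @param thresholds a [qc_thresholds()].
#' @return List of aligned data frames (rows dropped as described), with a
#'   character vector attribute `"log"` describing every dropped record.
#' @export
harmonize <- function(statsets, reference_alleles,
                      thresholds = qc_thresholds()) {
  stopifnot(is.list(statsets), all(c("snp_id", "a1", "a2") %in%
                                     names(reference_alleles)))
  ref <- reference_alleles
  log <- character(0)
  out <- lapply(seq_along(statsets), function(si) {
    s <- statsets[[si]]
    if (anyDuplicated(s$snp_id)) {
      stop("duplicate snp_id in statset ", si)
    }
    i <- match(s$snp_id, ref$snp_id)
    drop <- is.na(i)
    if (any(drop)) {
      log <<- c(log, paste0("set ", si, ": ", s$snp_id[drop],
                            " absent from reference"))
    }
    s <- s[!drop, , drop = FALSE]
    i <- i[!drop]
    ra1 <- ref$a1[i]; ra2 <- ref$a2[i]

    pal <- is_palindromic(s$a1, s$a2)
    maf <- pmin(s$freq_a1, 1 - s$freq_a1)
    amb <- pal & maf > thresholds$drop_ambiguous_palindromic_above_freq
    if (any(amb)) {
      log <<- c(log, paste0("set ", si, ": ", s$snp_id[amb],
                            " ambiguous palindromic"))
    }

    same <- s$a1 == ra1 & s$a2 == ra2
    swap <- s$a1 == ra2 & s$a2 == ra1
    f_same <- unname(FLIP[s$a1] == ra1 & FLIP[s$a2] == ra2) & !pal
    f_swap <- unname(FLIP[s$a1] == ra2 & FLIP[s$a2] == ra1) & !pal
    mism <- !(same | swap | f_same | f_swap)
    if (any(mism & !amb)) {
      log <<- c(log, paste0("set ", si, ": ", s$snp_id[mism & !amb],
                            " allele mismatch"))
    }

    flip_strand <- f_same | f_swap
    s$a1[flip_strand] <- unname(FLIP[s$a1[flip_strand]])
    s$a2[flip_strand] <- unname(FLIP[s$a2[flip_strand]])
    do_swap <- swap | f_swap
    if (any(do_swap)) {
      tmp <- s$a1[do_swap]
      s$a1[do_swap] <- s$a2[do_swap]
      s$a2[do_swap] <- tmp
      s$freq_a1[do_swap] <- 1 - s$freq_a1[do_swap]
      for (col in intersect(c("beta", "z"), names(s))) {
        s[[col]][do_swap] <- -s[[col]][do_swap]
      }
    }
    s[!(amb | mism), , drop = FALSE]
  })
  attr(out, "log") <- log
  out
}

#' Sample-size-weighted meta-analysis
#'
#' Combines per-study z statistics with weights proportional to the square
#' root of the study sample size (METAL convention):
#' `z_meta = sum(sqrt(N_i) z_i) / sqrt(sum(N_i))`, `N_meta = sum(N_i)`.
#' A SNP present in only a subset of studies is combined over the studies
#' that carry it, with `n` recording the realized total. The implied
#' standardized effect `beta = z / sqrt(N)` and `se = 1 / sqrt(N)` are
#' reported alongside.
#'
#' @param statsets list of harmonized summary-statistic data frames.
#' @return One summary-statistic data frame (`coding` retained when shared).
#' @export
meta_sample_size <- function(statsets) {
  stopifnot(length(statsets) >= 1L)
  all_snps <- unique(unlist(lapply(statsets, `[[`, "snp_id")))
  num <- stats::setNames(rep(0, length(all_snps)), all_snps)
  den <- num; ntot <- num; fsum <- num; k <- num
  meta_info <- NULL
  for (s in statsets) {
    i <- match(s$snp_id, all_snps)
    ok <- !is.na(s$z)
    num[i[ok]] <- num[i[ok]] + sqrt(s$n[ok]) * s$z[ok]
    den[i[ok]] <- den[i[ok]] + s$n[ok]
    ntot[i[ok]] <- ntot[i[ok]] + s$n[ok]
    fsum[i[ok]] <- fsum[i[ok]] + s$n[ok] * s$freq_a1[ok]
    k[i[ok]] <- k[i[ok]] + 1
    keep <- s[!duplicated(s$snp_id), intersect(
      c("snp_id", "chr", "pos", "a1", "a2", "coding"), names(s))]
    meta_info <- if (is.null(meta_info)) keep else
      rbind(meta_info, keep[!(keep$snp_id %in% meta_info$snp_id), ,
                            drop = FALSE])
  }
  if (any(k == 0)) stop("SNP present in zero studies with a usable z")
  z <- num / sqrt(den)
  info <- meta_info[match(all_snps, meta_info$snp_id), , drop = FALSE]
  out <- data.frame(
    snp_id = all_snps,
    chr = info$chr %||% 1L, pos = info$pos %||% seq_along(all_snps),
    a1 = info$a1, a2 = info$a2, freq_a1 = fsum / ntot, n = unname(ntot),
    beta = z / sqrt(ntot), se = 1 / sqrt(ntot), z = unname(z),
    p = z_to_p(z),
    coding = if ("coding" %in% names(info)) info$coding else NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Inverse-variance-weighted meta-analysis
#'
#' Classical fixed-effect combination over studies:
#' `beta = sum(beta_i / se_i^2) / sum(1 / se_i^2)`.
#'
#' @param statsets list of harmonized summary-statistic data frames sharing a
#'   SNP set.
#' @return A summary-statistic data frame.
#' @export
meta_inverse_variance <- function(statsets) {
  stopifnot(length(statsets) >= 1L)
  base <- statsets[[1]]
  w_sum <- rep(0, nrow(base)); bw_sum <- w_sum; ntot <- w_sum
  for (s in statsets) {
    i <- match(base$snp_id, s$snp_id)
    w <- 1 / s$se[i]^2
    ok <- !is.na(w)
    w_sum[ok] <- w_sum[ok] + w[ok]
    bw_sum[ok] <- bw_sum[ok] + (w * s$beta[i])[ok]
    ntot[ok] <- ntot[ok] + s$n[i][ok]
  }
  beta <- bw_sum / w_sum
  se <- sqrt(1 / w_sum)
  out <- base
  out$beta <- beta; out$se <- se; out$z <- beta / se
  out$p <- z_to_p(out$z); out$n <- ntot
  out
}

#' Convert summary statistics to the standardized effect scale
#'
#' Rewrites `beta` and `se` as the effect of a variance-one genotype on a
#' variance-one phenotype implied by the z statistic: `beta = z / sqrt(N)`,
#' `se = 1 / sqrt(N)`. This is the scale on which [fit_eb_prior()] and the
#' sample-size meta-analysis operate.
#'
#' @param stats summary-statistic data frame with `z` and `n`.
#' @return The data frame with `beta` and `se` replaced.
#' @export
standardized_effects <- function(stats) {
  stats$beta <- stats$z / sqrt(stats$n)
  stats$se <- 1 / sqrt(stats$n)
  stats
}

#' Inflate standard errors by the LD-score intercept
#'
#' Multiplies every standard error by `sqrt(intercept)` (and deflates z
#' accordingly, recomputing p), the standard correction for residual
#' confounding measured by the LD-score regression intercept. Mean
#' chi-squared divides by the intercept exactly.
#'
#' @param stats summary-statistic data frame.
#' @param intercept LD-score regression intercept (>= 1 expected; values in
#'   (0, 1) trigger a warning and no deflation by default).
#' @param allow_deflation apply intercepts below 1 as given.
#' @return The data frame with `se`, `z`, `p` updated.
#' @export
inflate_se <- function(stats, intercept, allow_deflation = FALSE) {
  if (!is.finite(intercept) || intercept <= 0) {
    stop("intercept must be positive")
  }
  if (intercept < 1 && !allow_deflation) {
    warning("intercept below 1; standard errors left unchanged")
    return(stats)
  }
  s <- sqrt(intercept)
  stats$se <- stats$se * s
  stats$z <- stats$z / s
  stats$p <- z_to_p(stats$z)
  stats
}

#' Iterative clumping of lead SNPs
#'
#' Greedy selection of approximately independent lead SNPs: repeatedly take
#' the smallest-p SNP below the p-value threshold, then remove every remaining
#' SNP in LD with it above the r-squared cutoff (no physical-distance cutoff).
#' Ties on p are broken by `(chr, pos, snp_id)`. Pairs absent from the LD
#' lookup are treated as r-squared 0.
#'
#' @param stats summary-statistic data frame (`snp_id`, `p`, `chr`, `pos`).
#' @param ld_lookup data frame `snp_a`, `snp_b`, `r2` (unordered pairs).
#' @param p_threshold inclusion threshold on p.
#' @param r2_threshold exclusion cutoff on pairwise r-squared.
#' @return Character vector of lead SNP ids in selection order.
#' @export
clump <- function(stats, ld_lookup, p_threshold = 5e-8, r2_threshold = 0.1) {
  cand <- stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  ord <- order(cand$p, cand$chr, cand$pos, cand$snp_id)
  cand <- cand[ord, , drop = FALSE]

  neighbours <- list()
  if (!is.null(ld_lookup) && nrow(ld_lookup)) {
    hi <- ld_lookup[ld_lookup$r2 > r2_threshold, , drop = FALSE]
    if (nrow(hi)) {
      edges <- rbind(data.frame(a = hi$snp_a, b = hi$snp_b),
                     data.frame(a = hi$snp_b, b = hi$snp_a))
      neighbours <- split(edges$b, edges$a)
    }
  }

  alive <- stats::setNames(rep(TRUE, nrow(cand)), cand$snp_id)
  leads <- character(0)
  for (s in cand$snp_id) {
    if (!alive[[s]]) next
    leads <- c(leads, s)
    alive[[s]] <- FALSE
    nb <- neighbours[[s]]
    if (!is.null(nb)) {
      hit <- intersect(nb, names(alive)[alive])
      alive[hit] <- FALSE
    }
  }
  leads
}

#' Mean chi-squared statistic after QC filters
#'
#' Average of `z^2` over SNPs passing the reporting filters: minor-allele
#' frequency above `maf_min` and sample size above `n_min_fraction` of the
#' largest per-SNP `N`.
#'
#' @param stats summary-statistic data frame.
#' @param thresholds a [qc_thresholds()].
#' @return Scalar mean chi-squared.
#' @export
mean_chisq <- function(stats, thresholds = qc_thresholds()) {
  maf <- pmin(stats$freq_a1, 1 - stats$freq_a1)
  keep <- !is.na(stats$z) & maf > thresholds$maf_min &
    stats$n > thresholds$n_min_fraction * max(stats$n)
  if (!any(keep)) stop("all SNPs removed by the QC filters")
  mean(stats$z[keep]^2)
}
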