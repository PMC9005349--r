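# End-to-end orchestration: simulate -> associate -> meta/QC -> LD-score
# regression -> PGI construction and evaluation -> family decomposition ->
# assortative-mating test -> winner's-curse adjustment, with a run manifest
# for reproducibility.

#' Default pipeline configuration
#'
#' A nested parameter list covering every stage. Any subset can be overridden
#' via `modifyList`-style arguments; all randomness derives from the single
#' root seed.
#'
#' @param seed root seed.
#' @param ... named stage blocks overriding the defaults (`simulate`, `gwas`,
#'   `meta`, `clump`, `ldsc`, `pgi`, `family`, `assort`, `shrink`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("simulate", "gwas", "meta", "clump", "ldsc", "pgi",
               "family", "assort", "shrink"),
    simulate = list(n_snps = 800L,
                    block_sizes = rep(c(1L, 2L, 3L, 4L, 10L), 40L),
                    within_block_r = 0.5,
                    n_founder_pairs = 400L, n_generations = 3L,
                    h2_add = 0.4, h2_dom = 0, indirect_scale = 0.1,
                    target_mate_r = 0.4),
    gwas = list(n_pcs = 5L),
    clump = list(p_threshold = 1e-3, r2_threshold = 0.1),
    pgi = list(p_thresholds = c(1e-3, 1)),
    shrink = list(lead_alpha = 1e-3),
    meta = list(), ldsc = list(), family = list(), assort = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  known <- c("simulate", "gwas", "meta", "clump", "ldsc", "pgi", "family",
             "assort", "shrink")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  needs_block <- c("simulate", "gwas", "clump", "pgi", "shrink")
  for (st in intersect(cfg$stages, needs_block)) {
    if (is.null(cfg[[st]])) {
      stop("run configuration is missing the '", st, "' parameter block")
    }
  }
  invisible(cfg)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the configured stages in dependency order and returns every
#' intermediate artifact plus a manifest of seeds and content fingerprints;
#' reruns with the same configuration give identical manifests.
#'
#' @param config a [run_config()].
#' @return List of class `pipeline_run`: `artifacts` (named list) and
#'   `manifest` (stage -> md5 fingerprint, plus seeds).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  art <- list()
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pgikit")))
  has <- function(s) s %in% config$stages

  if (has("simulate")) {
    sim_args <- utils::modifyList(config$simulate,
                                  list(seed = substream_seed(config$seed,
                                                             "simulate")))
    art$cohort <- simulate_cohort(do.call(sim_config, sim_args))
    manifest$simulate <- fingerprint(art$cohort$geno)
  }

  if (has("gwas")) {
    coh <- art$cohort
    adults <- coh$ped$generation < max(coh$ped$generation)
    G <- coh$geno[coh$ped$id[adults], , drop = FALSE]
    y <- coh$ped$y[adults]
    pcs <- if (config$gwas$n_pcs > 0) compute_pcs(G, config$gwas$n_pcs)
    covs <- make_covariates(sex = coh$ped$sex[adults], pcs = pcs)
    art$gwas_add <- run_gwas(G, y, covs, coding = "additive_012")
    art$gwas_dom <- run_gwas(G, y, covs, coding = "dominance_dev")
    manifest$gwas <- fingerprint(list(art$gwas_add$z, art$gwas_dom$z))
  }

  if (has("meta")) {
    ref <- art$gwas_add[, c("snp_id", "a1", "a2")]
    art$meta <- meta_sample_size(harmonize(list(art$gwas_add), ref))
    manifest$meta <- fingerprint(art$meta$z)
  }

  blocks <- art$cohort$architecture$block
  r_blk <- art$cohort$config$within_block_r
  ld_long <- NULL
  if (has("clump") || has("pgi")) {
    ld_long <- block_ld_lookup(art$meta$snp_id, blocks, r_blk^2)
  }

  if (has("clump")) {
    art$leads <- clump(art$meta, ld_long, config$clump$p_threshold,
                       config$clump$r2_threshold)
    manifest$clump <- fingerprint(art$leads)
  }

  if (has("ldsc")) {
    bs <- as.integer(table(blocks))
    ld <- compute_ld_scores(block_spec = list(block_sizes = bs, r = r_blk))
    N <- art$meta$n[1]
    art$ldsc_add <- ldsc_fit(art$meta$z^2, ld$l_add, N, nrow(art$meta),
                             mode = "additive")
    dom <- art$gwas_dom
    art$ldsc_dom <- ldsc_fit(dom$z^2, ld$l_dom, dom$n[1], nrow(dom),
                             mode = "dominance")
    manifest$ldsc <- fingerprint(c(art$ldsc_add$h2, art$ldsc_dom$h2))
  }

  if (has("pgi")) {
    coh <- art$cohort
    holdout <- coh$ped$generation == max(coh$ped$generation)
    Gh <- coh$geno[coh$ped$id[holdout], , drop = FALSE]
    art$weights <- lapply(config$pgi$p_thresholds, function(pt) {
      build_ct_weights(art$meta, ld_long, pt, config$clump$r2_threshold)
    })
    names(art$weights) <- paste0("ct_", config$pgi$p_thresholds)
    art$pgi_eval <- lapply(art$weights, function(w) {
      if (!nrow(w)) return(NULL)
      s <- score_pgi(Gh, w, effect_allele = "A")
      incremental_r2(coh$ped$y[holdout], s, covariates = NULL, n_boot = 200L,
                     seed = substream_seed(config$seed, "pgi_boot"))
    })
    manifest$pgi <- fingerprint(lapply(art$pgi_eval, function(e)
      e$delta_r2 %||% NA_real_))
  }

  if (has("family")) {
    coh <- art$cohort
    trio <- cohort_trios(coh)
    sib <- cohort_sibs(coh)
    art$trio_fit <- estimate_trio_effects(trio$y, trio$pgi_child,
                                          trio$pgi_father, trio$pgi_mother,
                                          trio$family_id)
    art$sib_fit <- estimate_sib_effects(sib$y, sib$pgi, sib$sibship_id)
    art$combined_fit <- combine_designs(list(art$sib_fit, art$trio_fit))
    manifest$family <- fingerprint(c(art$trio_fit$delta, art$sib_fit$delta))
  }

  if (has("assort")) {
    pairs <- cohort_mate_pairs(art$cohort)
    art$assort <- predicted_under_phenotypic_assortment(
      pairs, n_boot = 500L, seed = substream_seed(config$seed, "assort"))
    r_mate <- art$assort$r_pgi
    if (!is.null(art$combined_fit)) {
      tr <- population_transform(art$combined_fit$delta,
                                 art$combined_fit$alpha_f,
                                 art$combined_fit$alpha_m, r_mate,
                                 vcov = if (ncol(art$combined_fit$vcov) == 3)
                                   art$combined_fit$vcov)
      bp <- if (is.list(tr)) tr$beta_pop else tr
      vc <- if (is.list(tr)) tr$vcov
      art$ratio <- ratio_and_share(art$combined_fit$delta, bp, vc)
    }
    manifest$assort <- fingerprint(art$assort$r_pgi)
  }

  if (has("shrink")) {
    art$prior <- fit_eb_prior(art$meta,
                              intercept = art$ldsc_add$intercept %||% 1,
                              min_snps = min(1000L, nrow(art$meta)))
    lead <- art$meta[art$meta$p < config$shrink$lead_alpha, , drop = FALSE]
    art$adjusted <- data.frame(
      snp_id = lead$snp_id, beta_raw = lead$beta,
      beta_adj = winners_curse_adjust(lead$beta, lead$se, art$prior),
      p = lead$p)
    manifest$shrink <- fingerprint(art$adjusted$beta_adj)
  }

  structure(list(artifacts = art, manifest = manifest,
                 config = config),
            class = "pipeline_run")
}

# long-format LD lookup implied by exchangeable blocks (pairwise r2 constant
# within a block, zero across)
block_ld_lookup <- function(snp_id, blocks, r2) {
  if (r2 <= 0) {
    return(data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0)))
  }
  rows <- lapply(split(snp_id, blocks), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ], r2 = r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize a pipeline run as a report
#'
#' Collects the headline numbers of every stage -- SNP counts, lead loci,
#' mean chi-squared, LD-score fits, PGI incremental R-squared by method, the
#' family-effect decomposition and the mate-pair panel -- into a list that
#' serializes cleanly to JSON.
#'
#' @param run a [run_pipeline()] result (or its `artifacts` list).
#' @return List of class `pgikit_report` with a `panels` element; use
#'   [jsonlite::toJSON] or `as.character(run)` for serialized forms.
#' @export
render_report <- function(run) {
  art <- if (inherits(run, "pipeline_run")) run$artifacts else run
  if (!length(art)) stop("no artifacts to report")
  panels <- list()
  if (!is.null(art$cohort)) {
    panels$cohort <- list(
      n_individuals = nrow(art$cohort$ped),
      n_snps = ncol(art$cohort$geno),
      n_generations = max(art$cohort$ped$generation),
      n_mate_pairs = nrow(art$cohort$mate_pairs))
  }
  if (!is.null(art$meta)) {
    panels$meta <- list(n_snps = nrow(art$meta), n = art$meta$n[1],
                        mean_chisq = mean_chisq(art$meta))
  }
  if (!is.null(art$leads)) {
    panels$clump <- list(n_loci = length(art$leads))
  }
  if (!is.null(art$gwas_dom)) {
    panels$dominance <- list(
      mean_chisq = mean(art$gwas_dom$z^2, na.rm = TRUE))
  }
  if (!is.null(art$ldsc_add)) {
    panels$ldsc <- list(h2_add = art$ldsc_add$h2,
                        intercept_add = art$ldsc_add$intercept,
                        h2_dom = art$ldsc_dom$h2 %||% NA_real_)
  }
  if (!is.null(art$pgi_eval)) {
    panels$pgi <- lapply(art$pgi_eval, function(e) {
      if (is.null(e)) list(incremental_r2 = NA_real_) else
        list(incremental_r2 = e$delta_r2)
    })
  }
  if (!is.null(art$trio_fit)) {
    panels$family <- list(delta_trio = art$trio_fit$delta,
                          delta_sib = art$sib_fit$delta,
                          delta_combined = art$combined_fit$delta,
                          ratio = art$ratio$ratio %||% NA_real_,
                          direct_share_pct = art$ratio$share_pct %||% NA_real_)
  }
  if (!is.null(art$assort)) {
    panels$assort <- list(r_pgi = art$assort$r_pgi,
                          predicted = art$assort$predicted,
                          r_y = art$assort$r_y)
  }
  if (!is.null(art$prior)) {
    panels$shrinkage <- list(tau2 = art$prior$tau2,
                             n_lead_adjusted = nrow(art$adjusted))
  }
  structure(list(panels = panels), class = "pgikit_report")
}

#' @export
print.pgikit_report <- function(x, ...) {
  cat("<pgikit_report> panels:", paste(names(x$panels), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> artifacts:", paste(names(x$artifacts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a [render_report()] result.
#' @param path optional output file.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report$panels, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
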