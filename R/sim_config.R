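#' Configuration for the family-structured cohort simulator
#'
#' Collects and validates every knob of the generative model: genotypes in
#' exchangeable LD blocks, an additive + dominance-deviation + indirect
#' parental trait architecture, multi-generation mating with tunable
#' assortment on a phenotype/latent-factor/ancestry composite, optional
#' two-subpopulation allele-frequency divergence, and optional inbred
#' (full-sibling) matings.
#'
#' @param n_snps number of biallelic SNPs.
#' @param n_blocks number of LD blocks; SNPs are split as evenly as possible
#'   across blocks. `n_blocks = n_snps` gives unlinked SNPs.
#' @param block_sizes optional integer vector of block sizes summing to
#'   `n_snps` (overrides the even split; heterogeneous sizes give the
#'   LD-score variation that LD-score regression needs).
#' @param within_block_r pairwise genotype correlation inside a block, in
#'   `[0, 1)`. Cross-block correlation is 0 by construction.
#' @param freq_law length-2 interval from which founder allele frequencies are
#'   drawn uniformly (one frequency per block, shared by the block's SNPs so
#'   that within-block LD is exchangeable with exactly known r).
#' @param n_founder_pairs number of founder couples (>= 2). Each couple in
#'   every generation produces two children, one male and one female, so the
#'   population size is constant across generations.
#' @param n_generations total number of generations including the founders
#'   (>= 1; 1 means founders only, no families).
#' @param h2_add target additive heritability (variance of the additive
#'   genetic value; the founder-generation realized variance is scaled to hit
#'   it exactly).
#' @param h2_dom target dominance-deviation heritability, scaled likewise.
#' @param indirect_scale eta, the coefficient on the sum of the parents'
#'   additive genetic values entering the child's phenotype (genetic nurture).
#' @param mate_score_weights nonnegative weights `(w_phenotype, w_latent,
#'   w_ancestry)` of the standardized mating-score composite.
#' @param target_mate_r target mate-pair correlation of the mating score, in
#'   `[0, 1)`.
#' @param latent_cor correlation between the latent assortment factor and the
#'   standardized additive genetic value (relevant only when the latent weight
#'   is positive).
#' @param ancestry_divergence Balding-Nichols drift parameter (Fst) between
#'   two founder subpopulations; 0 means a single homogeneous population.
#' @param inbred_fraction fraction of matings per generation that are forced
#'   full-sibling matings (their offspring have pedigree F >= 1/4).
#' @param directional_dominance if `TRUE` all dominance deviations take the
#'   heterozygote-advantage sign, so inbreeding depresses the phenotype.
#' @param seed root seed; every internal stage draws a named substream from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_snps = 1000L,
                       n_blocks = 200L,
                       block_sizes = NULL,
                       within_block_r = 0,
                       freq_law = c(0.05, 0.5),
                       n_founder_pairs = 200L,
                       n_generations = 2L,
                       h2_add = 0.4,
                       h2_dom = 0,
                       indirect_scale = 0,
                       mate_score_weights = c(1, 0, 0),
                       target_mate_r = 0,
                       latent_cor = 0.5,
                       ancestry_divergence = 0,
                       inbred_fraction = 0,
                       directional_dominance = FALSE,
                       seed = 1L) {
  if (!is.null(block_sizes)) {
    block_sizes <- as.integer(block_sizes)
    if (sum(block_sizes) != n_snps || any(block_sizes < 1L)) {
      stop("block_sizes must be positive and sum to n_snps")
    }
    n_blocks <- length(block_sizes)
  }
  cfg <- list(
    n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
    block_sizes = block_sizes,
    within_block_r = within_block_r, freq_law = freq_law,
    n_founder_pairs = as.integer(n_founder_pairs),
    n_generations = as.integer(n_generations),
    h2_add = h2_add, h2_dom = h2_dom, indirect_scale = indirect_scale,
    mate_score_weights = mate_score_weights, target_mate_r = target_mate_r,
    latent_cor = latent_cor, ancestry_divergence = ancestry_divergence,
    inbred_fraction = inbred_fraction,
    directional_dominance = isTRUE(directional_dominance),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_snps >= 1L, cfg$n_blocks >= 1L, cfg$n_blocks <= cfg$n_snps,
    cfg$within_block_r >= 0, cfg$within_block_r < 1,
    length(cfg$freq_law) == 2L,
    all(cfg$freq_law > 0), all(cfg$freq_law < 1),
    cfg$freq_law[1] <= cfg$freq_law[2],
    cfg$n_generations >= 1L,
    cfg$h2_add >= 0, cfg$h2_dom >= 0,
    cfg$indirect_scale >= 0,
    length(cfg$mate_score_weights) == 3L, all(cfg$mate_score_weights >= 0),
    cfg$target_mate_r >= 0, cfg$target_mate_r < 1,
    abs(cfg$latent_cor) <= 1,
    cfg$ancestry_divergence >= 0, cfg$ancestry_divergence < 1,
    cfg$inbred_fraction >= 0, cfg$inbred_fraction <= 1
  )
  if (cfg$h2_add + cfg$h2_dom > 1) {
    stop("infeasible variance targets: h2_add + h2_dom > 1")
  }
  if (cfg$n_founder_pairs < 2L) stop("n_founder_pairs must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_snps, "SNPs in", x$n_blocks, "blocks (r =",
      x$within_block_r, ");", x$n_founder_pairs, "founder pairs x",
      x$n_generations, "generations\n")
  cat("  h2_add =", x$h2_add, " h2_dom =", x$h2_dom,
      " eta =", x$indirect_scale, " target_mate_r =", x$target_mate_r, "\n")
  invisible(x)
}
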