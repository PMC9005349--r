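# Family-structured cohort simulator.
#
# Genotypes live in exchangeable LD blocks: within a block every SNP shares
# the block allele frequency and each haplotype draws its alleles by copying
# a shared block indicator with probability sqrt(r) (fresh Bernoulli draw
# otherwise), which makes the pairwise allele -- and hence genotype --
# correlation exactly r inside a block and exactly 0 across blocks. LD is
# therefore analytically known, which the LD-score module exploits.
# Transmission copies whole parental haplotype blocks (free recombination
# between blocks, complete linkage within), so within-block LD is preserved
# across generations.

#' Orthogonal dominance-deviation coding
#'
#' Codes genotypes `{0, 1, 2}` as `{0, 2p, 4p - 2}` where `p` is the
#' effect-allele frequency. Under Hardy-Weinberg equilibrium this coding is
#' uncorrelated with allele count, so it isolates the within-locus departure
#' from additivity.
#'
#' @param g genotype vector or matrix (allele counts 0/1/2; `NA` allowed).
#' @param p effect-allele frequency: a scalar for a vector `g`, or a vector
#'   with one entry per column of a matrix `g`.
#' @return Numeric object of the same shape as `g`.
#' @export
dominance_coding <- function(g, p) {
  if (is.matrix(g)) {
    stopifnot(length(p) == ncol(g))
    p2 <- matrix(p, nrow(g), ncol(g), byrow = TRUE)
  } else {
    stopifnot(length(p) == 1L || length(p) == length(g))
    p2 <- p
  }
  out <- ifelse(g == 1, 2 * p2, ifelse(g == 2, 4 * p2 - 2, 0))
  out[is.na(g)] <- NA_real_
  out
}

# draw haplotypes for one LD block: n_hap x m matrix of 0/1 alleles with
# exchangeable pairwise correlation r (copy-probability sqrt(r))
draw_block_haplotypes <- function(n_hap, m, p, r) {
  phi <- sqrt(r)
  shared <- stats::rbinom(n_hap, 1L, p)
  if (phi == 0) {
    matrix(stats::rbinom(n_hap * m, 1L, p), n_hap, m)
  } else {
    copy <- matrix(stats::rbinom(n_hap * m, 1L, phi), n_hap, m)
    fresh <- matrix(stats::rbinom(n_hap * m, 1L, p), n_hap, m)
    copy * shared + (1L - copy) * fresh
  }
}

# additive genetic value on the standardized-genotype scale
additive_values <- function(G, beta, freq) {
  s <- sqrt(2 * freq * (1 - freq))
  Z <- sweep(sweep(G, 2L, 2 * freq, "-"), 2L, s, "/")
  drop(Z %*% beta)
}

dominance_values <- function(G, delta, freq) {
  drop(dominance_coding(G, freq) %*% delta)
}

#' Simulate a family-structured genotype/phenotype cohort
#'
#' Generates founders in Hardy-Weinberg equilibrium (optionally split into two
#' subpopulations with Balding-Nichols allele-frequency divergence), then
#' mates each generation with tunable assortment on a standardized composite
#' of phenotype, latent factor and ancestry, producing two children (one male,
#' one female) per couple. Phenotypes combine additive and dominance-deviation
#' genetic values, an indirect parental-effect term
#' `eta * (gv_add_father + gv_add_mother)`, and Gaussian noise. Pedigree
#' inbreeding coefficients are propagated exactly through a generation-wise
#' kinship recursion.
#'
#' @param config a [sim_config()].
#' @return A list of class `cohort` with elements
#'   \describe{
#'     \item{ped}{data frame, one row per individual: `id`, `sex`,
#'       `father_id`, `mother_id`, `generation`, `subpop`, `ancestry`, `F`
#'       (pedigree inbreeding coefficient), `y` (phenotype), `gv_add`,
#'       `gv_dom`, `latent`, `sibship_id`.}
#'     \item{geno}{integer matrix of allele counts, individuals by SNPs,
#'       rownames = `id`.}
#'     \item{mate_pairs}{data frame of couples (`id_m`, `id_f`, `generation`
#'       of the partners, realized mating-score correlation as an attribute).}
#'     \item{architecture}{`trait_architecture`: `beta_add` (standardized
#'       scale), `delta_dom` (orthogonal-coding scale), `eta`, `freq`
#'       (realized founder frequencies), `block`, `snp_id`.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' cfg <- sim_config(n_snps = 50, n_blocks = 10, n_founder_pairs = 30,
#'                   n_generations = 2, seed = 7)
#' coh <- simulate_cohort(cfg)
#' table(coh$ped$generation)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  m <- cfg$n_snps
  block <- if (!is.null(cfg$block_sizes)) {
    rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  } else {
    sort(rep(seq_len(cfg$n_blocks), length.out = m))
  }
  snp_id <- sprintf("rs%05d", seq_len(m))
  n_pairs <- cfg$n_founder_pairs
  n_gen_ind <- 2L * n_pairs

  # --- founders -------------------------------------------------------------
  two_pop <- cfg$ancestry_divergence > 0
  base_freq_block <- with_seed(substream_seed(cfg$seed, "freq"), {
    stats::runif(cfg$n_blocks, cfg$freq_law[1], cfg$freq_law[2])
  })
  # both sexes present in both subpopulations (sexes alternate within id
  # order, subpopulations split by halves)
  ancestry <- if (two_pop) {
    rep(c(0, 1), each = ceiling(n_gen_ind / 2))[seq_len(n_gen_ind)]
  } else {
    rep(0, n_gen_ind)
  }
  pop_freq <- with_seed(substream_seed(cfg$seed, "popfreq"), {
    if (two_pop) {
      Fst <- cfg$ancestry_divergence
      a <- base_freq_block * (1 - Fst) / Fst
      b <- (1 - base_freq_block) * (1 - Fst) / Fst
      cbind(pmin(pmax(stats::rbeta(cfg$n_blocks, a, b), 0.01), 0.99),
            pmin(pmax(stats::rbeta(cfg$n_blocks, a, b), 0.01), 0.99))
    } else {
      cbind(base_freq_block, base_freq_block)
    }
  })

  hap <- with_seed(substream_seed(cfg$seed, "founder_hap"), {
    H1 <- matrix(0L, n_gen_ind, m)
    H2 <- matrix(0L, n_gen_ind, m)
    for (b in seq_len(cfg$n_blocks)) {
      cols <- which(block == b)
      for (popi in 1:2) {
        rows <- which((ancestry >= 0.5) == (popi == 2))
        if (!length(rows)) next
        p <- pop_freq[b, popi]
        H1[rows, cols] <- draw_block_haplotypes(length(rows), length(cols), p,
                                                cfg$within_block_r)
        H2[rows, cols] <- draw_block_haplotypes(length(rows), length(cols), p,
                                                cfg$within_block_r)
      }
    }
    list(H1 = H1, H2 = H2)
  })
  G <- hap$H1 + hap$H2

  freq <- colMeans(G) / 2
  freq <- pmin(pmax(freq, 1 / (4 * n_gen_ind)), 1 - 1 / (4 * n_gen_ind))

  # --- trait architecture, scaled so founder realized variances hit targets -
  arch <- with_seed(substream_seed(cfg$seed, "arch"), {
    beta <- stats::rnorm(m)
    delta <- stats::rnorm(m)
    if (cfg$directional_dominance) delta <- abs(delta)
    list(beta = beta, delta = delta)
  })
  beta_add <- rep(0, m)
  delta_dom <- rep(0, m)
  if (cfg$h2_add > 0) {
    raw <- additive_values(G, arch$beta, freq)
    beta_add <- arch$beta * sqrt(cfg$h2_add / stats::var(raw))
  }
  if (cfg$h2_dom > 0) {
    raw <- dominance_values(G, arch$delta, freq)
    delta_dom <- arch$delta * sqrt(cfg$h2_dom / stats::var(raw))
  }
  architecture <- structure(
    list(beta_add = beta_add, delta_dom = delta_dom,
         eta = cfg$indirect_scale, freq = freq, block = block,
         snp_id = snp_id),
    class = "trait_architecture")

  sd_e <- sqrt(max(0, 1 - cfg$h2_add - cfg$h2_dom))
  lc <- cfg$latent_cor

  make_phenotype <- function(gv_add, gv_dom, parent_ind, gen, n) {
    with_seed(substream_seed(cfg$seed, paste0("env_g", gen)), {
      e <- stats::rnorm(n, 0, sd_e)
      zl <- stats::rnorm(n)
      gv_std <- if (stats::sd(gv_add) > 0) std(gv_add) else rep(0, n)
      latent <- lc * gv_std + sqrt(max(0, 1 - lc^2)) * zl
      y <- gv_add + gv_dom + parent_ind + e
      list(y = y, latent = latent)
    })
  }

  # --- bookkeeping for generation 1 ----------------------------------------
  ids <- sprintf("g1_i%04d", seq_len(n_gen_ind))
  sex <- rep(c("M", "F"), length.out = n_gen_ind)
  gv_add <- additive_values(G, beta_add, freq)
  gv_dom <- dominance_values(G, delta_dom, freq)
  ph <- make_phenotype(gv_add, gv_dom, rep(0, n_gen_ind), 1L, n_gen_ind)

  ped_list <- list(data.frame(
    id = ids, sex = sex, father_id = NA_character_, mother_id = NA_character_,
    generation = 1L, subpop = 1L + as.integer(ancestry >= 0.5),
    ancestry = ancestry, F = 0, y = ph$y, gv_add = gv_add, gv_dom = gv_dom,
    latent = ph$latent, sibship_id = NA_character_,
    stringsAsFactors = FALSE))
  geno_list <- list(G)
  rownames(geno_list[[1]]) <- ids
  mate_rows <- list()

  cur <- list(ids = ids, sex = sex, H1 = hap$H1, H2 = hap$H2,
              gv_add = gv_add, y = ph$y, latent = ph$latent,
              ancestry = ancestry, K = diag(0.5, n_gen_ind),
              sibship = rep(NA_character_, n_gen_ind))

  if (cfg$n_generations >= 2L) {
    for (gen in seq_len(cfg$n_generations - 1L)) {
      nxt <- breed_generation(cur, cfg, gen, block, architecture,
                              make_phenotype)
      ped_list[[gen + 1L]] <- nxt$ped
      gm <- nxt$G
      rownames(gm) <- nxt$cur$ids
      geno_list[[gen + 1L]] <- gm
      mate_rows[[gen]] <- nxt$pairs
      cur <- nxt$cur
    }
  }

  ped <- do.call(rbind, ped_list)
  geno <- do.call(rbind, geno_list)
  colnames(geno) <- snp_id
  mate_pairs <- if (length(mate_rows)) do.call(rbind, mate_rows) else
    data.frame(id_m = character(), id_f = character(), generation = integer())

  structure(list(ped = ped, geno = geno, mate_pairs = mate_pairs,
                 architecture = architecture, config = cfg),
            class = "cohort")
}

# one round of mating + reproduction; cur holds the current generation state
breed_generation <- function(cur, cfg, gen, block, arch, make_phenotype) {
  males <- which(cur$sex == "M")
  females <- which(cur$sex == "F")
  stopifnot(length(males) == length(females))
  n_pairs <- length(males)

  # forced full-sibling matings (only possible once sibships exist)
  sib_m <- integer(0); sib_f <- integer(0)
  if (cfg$inbred_fraction > 0 && gen > 1L) {
    n_inbred <- round(cfg$inbred_fraction * n_pairs)
    if (n_inbred > 0) {
      fams <- with_seed(substream_seed(cfg$seed, paste0("inbred_g", gen)), {
        sample(unique(cur$sibship[males]), n_inbred)
      })
      sib_m <- males[match(fams, cur$sibship[males])]
      sib_f <- females[match(fams, cur$sibship[females])]
    }
  }
  free_m <- setdiff(males, sib_m)
  free_f <- setdiff(females, sib_f)

  # mating-score composite
  w <- cfg$mate_score_weights
  score <- w[1] * std(cur$y, allow_constant = TRUE) +
    w[2] * std(cur$latent, allow_constant = TRUE) +
    w[3] * std(cur$ancestry, allow_constant = TRUE)
  if (stats::sd(score[c(free_m, free_f)]) == 0) score <- seq_along(cur$ids) * 0

  if (length(free_m)) {
    if (stats::sd(score[free_m]) == 0 || stats::sd(score[free_f]) == 0) {
      pairing <- with_seed(substream_seed(cfg$seed, paste0("pair_g", gen)),
                           sample(length(free_f)))
    } else {
      pairing <- assortative_pairing(score[free_m], score[free_f],
                                     cfg$target_mate_r,
                                     seed = substream_seed(cfg$seed,
                                                           paste0("pair_g", gen)))
    }
    fa <- c(free_m, sib_m)
    mo <- c(free_f[pairing], sib_f)
  } else {
    fa <- sib_m
    mo <- sib_f
  }
  realized_r <- if (length(fa) > 2 && stats::sd(score[fa]) > 0 &&
                    stats::sd(score[mo]) > 0) {
    stats::cor(score[fa], score[mo])
  } else NA_real_

  # two children per couple, one of each sex
  n_child <- 2L * n_pairs
  fa_c <- rep(fa, each = 2L)
  mo_c <- rep(mo, each = 2L)
  sexes <- rep(c("M", "F"), n_pairs)
  m <- ncol(cur$H1)
  n_blocks <- length(unique(block))
  block_cols <- split(seq_len(m), block)

  gametes <- with_seed(substream_seed(cfg$seed, paste0("meiosis_g", gen)), {
    pick_pat <- matrix(stats::runif(n_child * n_blocks) < 0.5, n_child, n_blocks)
    pick_mat <- matrix(stats::runif(n_child * n_blocks) < 0.5, n_child, n_blocks)
    C1 <- matrix(0L, n_child, m)
    C2 <- matrix(0L, n_child, m)
    for (b in seq_len(n_blocks)) {
      cols <- block_cols[[b]]
      sel_p <- pick_pat[, b]
      C1[sel_p, cols] <- cur$H1[fa_c[sel_p], cols]
      C1[!sel_p, cols] <- cur$H2[fa_c[!sel_p], cols]
      sel_m <- pick_mat[, b]
      C2[sel_m, cols] <- cur$H1[mo_c[sel_m], cols]
      C2[!sel_m, cols] <- cur$H2[mo_c[!sel_m], cols]
    }
    list(H1 = C1, H2 = C2)
  })
  G <- gametes$H1 + gametes$H2

  # kinship propagation: child F = kinship(father, mother)
  K <- cur$K
  Fc <- K[cbind(fa_c, mo_c)]
  Kc <- 0.25 * (K[fa_c, fa_c] + K[fa_c, mo_c] + K[mo_c, fa_c] + K[mo_c, mo_c])
  diag(Kc) <- 0.5 * (1 + Fc)

  gv_add <- additive_values(G, arch$beta_add, arch$freq)
  gv_dom <- dominance_values(G, arch$delta_dom, arch$freq)
  parent_ind <- arch$eta * (cur$gv_add[fa_c] + cur$gv_add[mo_c])
  ph <- make_phenotype(gv_add, gv_dom, parent_ind, gen + 1L, n_child)

  ids <- sprintf("g%d_i%04d", gen + 1L, seq_len(n_child))
  sibship <- sprintf("fam_g%d_p%04d", gen, rep(seq_len(n_pairs), each = 2L))
  ancestry <- (cur$ancestry[fa_c] + cur$ancestry[mo_c]) / 2

  ped <- data.frame(
    id = ids, sex = sexes, father_id = cur$ids[fa_c],
    mother_id = cur$ids[mo_c], generation = gen + 1L,
    subpop = 1L + as.integer(ancestry >= 0.5), ancestry = ancestry,
    F = Fc, y = ph$y, gv_add = gv_add, gv_dom = gv_dom, latent = ph$latent,
    sibship_id = sibship, stringsAsFactors = FALSE)

  pairs <- data.frame(id_m = cur$ids[fa], id_f = cur$ids[mo],
                      generation = gen)
  attr(pairs, "realized_score_r") <- realized_r

  list(ped = ped, G = G, pairs = pairs,
       cur = list(ids = ids, sex = sexes, H1 = gametes$H1, H2 = gametes$H2,
                  gv_add = gv_add, y = ph$y, latent = ph$latent,
                  ancestry = ancestry, K = Kc, sibship = sibship))
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$ped), "individuals,", ncol(x$geno), "SNPs,",
      max(x$ped$generation), "generation(s),", nrow(x$mate_pairs),
      "mate pairs\n")
  invisible(x)
}
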