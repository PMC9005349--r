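# Shared fixtures. Expensive simulated cohorts are built once per test run
# and cached; every fixture is generated in code from a fixed seed.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# heterogeneous LD-block sizes (needed for LD-score regression leverage)
mixed_block_sizes <- function(M, max_size = 9L, seed = 99L) {
  set.seed(seed)
  b <- sample(seq_len(max_size), 2L * M, replace = TRUE)
  b <- b[cumsum(b) <= M]
  if (sum(b) < M) b <- c(b, M - sum(b))
  b
}

# standard 3-generation family cohort with LD, assortment and indirect effects
family_cohort <- function() {
  cached("family_cohort", {
    simulate_cohort(sim_config(
      n_snps = 400L, n_blocks = 200L, within_block_r = 0.3,
      n_founder_pairs = 1500L, n_generations = 4L, h2_add = 0.4,
      indirect_scale = 0.15, target_mate_r = 0.4, seed = 202L))
  })
}

# unrelated founder panel used by association / LDSC / shrinkage tests
founder_panel <- function() {
  cached("founder_panel", {
    simulate_cohort(sim_config(
      n_snps = 2000L, block_sizes = mixed_block_sizes(2000L),
      within_block_r = 0.5, n_founder_pairs = 1000L, n_generations = 1L,
      h2_add = 0.5, h2_dom = 0, seed = 11L))
  })
}

# independent greedy-clumping reference: plain data-frame scan, O(n^2)
brute_clump <- function(stats, ld_lookup, p_threshold, r2_threshold) {
  df <- stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  leads <- character(0)
  r2_of <- function(a, b) {
    hit <- (ld_lookup$snp_a == a & ld_lookup$snp_b == b) |
      (ld_lookup$snp_a == b & ld_lookup$snp_b == a)
    if (any(hit)) max(ld_lookup$r2[hit]) else 0
  }
  while (nrow(df) > 0) {
    df <- df[order(df$p, df$chr, df$pos, df$snp_id), , drop = FALSE]
    top <- df$snp_id[1]
    leads <- c(leads, top)
    df <- df[-1, , drop = FALSE]
    if (nrow(df)) {
      keep <- vapply(df$snp_id, function(s) {
        r2_of(top, s) <= r2_threshold
      }, logical(1))
      df <- df[keep, , drop = FALSE]
    }
  }
  leads
}

# random small clumping instance
random_clump_instance <- function(n_max = 10L) {
  n <- sample(2:n_max, 1)
  ids <- sprintf("s%02d", seq_len(n))
  stats <- data.frame(snp_id = ids, chr = sample(1:2, n, TRUE),
                      pos = sample(1:1000, n), p = round(stats::runif(n), 3),
                      stringsAsFactors = FALSE)
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.4
  ld <- data.frame(snp_a = pairs[keep, 1], snp_b = pairs[keep, 2],
                   r2 = round(stats::runif(sum(keep)), 2),
                   stringsAsFactors = FALSE)
  list(stats = stats, ld = ld,
       p_threshold = sample(c(0.3, 0.6, 1.0), 1),
       r2_threshold = sample(c(0.1, 0.3), 1))
}

# Mendelian bounds: child allele count must be attainable from the parents
mendelian_violations <- function(cohort) {
  ped <- cohort$ped
  kids <- ped[!is.na(ped$father_id), , drop = FALSE]
  if (!nrow(kids)) return(0L)
  g <- cohort$geno
  gf <- g[kids$father_id, , drop = FALSE]
  gm <- g[kids$mother_id, , drop = FALSE]
  gc <- g[kids$id, , drop = FALSE]
  lo <- (gf == 2) + (gm == 2)
  hi <- 2L - (gf == 0) - (gm == 0)
  sum(gc < lo | gc > hi)
}
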