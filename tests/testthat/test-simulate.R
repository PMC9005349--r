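test_that("sim_config validates its invariants", {
  expect_error(sim_config(h2_add = 0.7, h2_dom = 0.4),
               "infeasible variance")
  expect_error(sim_config(n_founder_pairs = 1), "n_founder_pairs")
  expect_error(sim_config(target_mate_r = 1))
  expect_error(sim_config(freq_law = c(0, 0.5)))
  expect_error(sim_config(n_snps = 10, block_sizes = c(4, 4)),
               "sum to n_snps")
})

test_that("simulated genotypes are Mendelian-consistent and seeds reproduce", {
  coh <- family_cohort()
  expect_identical(mendelian_violations(coh), 0L)
  cfg <- sim_config(n_snps = 60, n_blocks = 20, within_block_r = 0.4,
                    n_founder_pairs = 40, n_generations = 3, h2_add = 0.3,
                    seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$ped, b$ped)
  expect_identical(mendelian_violations(a), 0L)
  expect_true(all(a$ped$F >= 0 & a$ped$F <= 0.5))
})

test_that("founder realized variances hit the heritability targets", {
  cfg <- sim_config(n_snps = 1200, n_blocks = 400, within_block_r = 0.3,
                    n_founder_pairs = 500, n_generations = 1,
                    h2_add = 0.35, h2_dom = 0.10, seed = 8)
  coh <- simulate_cohort(cfg)
  expect_equal(var(coh$ped$gv_add), 0.35, tolerance = 1e-10)
  expect_equal(var(coh$ped$gv_dom), 0.10, tolerance = 1e-10)
})

test_that("block LD structure matches the configured correlation", {
  cfg <- sim_config(n_snps = 40, n_blocks = 8, within_block_r = 0.4,
                    n_founder_pairs = 2500, n_generations = 1,
                    h2_add = 0.3, seed = 12)
  coh <- simulate_cohort(cfg)
  R <- cor(coh$geno)
  blk <- coh$architecture$block
  same <- outer(blk, blk, "==") & upper.tri(R)
  expect_equal(mean(R[same]), 0.4, tolerance = 0.03)
  expect_equal(mean(abs(R[!same & upper.tri(R)])), 0, tolerance = 0.03)
})

test_that("null architecture gives no phenotype-PGI correlation", {
  cfg <- sim_config(n_snps = 300, n_blocks = 300, n_founder_pairs = 1000,
                    n_generations = 1, h2_add = 0, h2_dom = 0,
                    indirect_scale = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  # PGI built from arbitrary nonzero weights must be independent of y
  w <- rep(1, ncol(coh$geno))
  pgi <- drop(coh$geno %*% w)
  r <- cor(pgi, coh$ped$y)
  expect_lt(abs(r), 3 / sqrt(nrow(coh$ped)))
})

test_that("no assortment leaves mate scores uncorrelated", {
  cfg <- sim_config(n_snps = 100, n_blocks = 100, n_founder_pairs = 1200,
                    n_generations = 2, h2_add = 0.4, target_mate_r = 0,
                    seed = 14)
  coh <- simulate_cohort(cfg)
  gv <- setNames(coh$ped$gv_add, coh$ped$id)
  mp <- coh$mate_pairs
  r <- cor(gv[mp$id_m], gv[mp$id_f])
  expect_lt(abs(r), 3 / sqrt(nrow(mp)))
})

test_that("ancestry-weighted assortment makes mates subpopulation-concordant", {
  cfg <- sim_config(n_snps = 150, n_blocks = 150, n_founder_pairs = 400,
                    n_generations = 2, h2_add = 0.3,
                    ancestry_divergence = 0.05,
                    mate_score_weights = c(0, 0, 1), target_mate_r = 0.8,
                    seed = 15)
  coh <- simulate_cohort(cfg)
  sp <- setNames(coh$ped$subpop, coh$ped$id)
  mp <- coh$mate_pairs
  conc <- mean(sp[mp$id_m] == sp[mp$id_f])
  # permutation null: concordance of randomly re-paired couples
  set.seed(1)
  null <- replicate(200, mean(sp[mp$id_m] == sample(sp[mp$id_f])))
  expect_gt(conc, quantile(null, 0.999))
})

test_that("forced sibling matings produce inbred offspring", {
  cfg <- sim_config(n_snps = 100, n_blocks = 100, n_founder_pairs = 300,
                    n_generations = 3, h2_add = 0.3, inbred_fraction = 0.2,
                    seed = 16)
  coh <- simulate_cohort(cfg)
  kids <- coh$ped[coh$ped$generation == 3, ]
  expect_equal(mean(kids$F >= 0.25), 0.2, tolerance = 0.02)
  # inbred children really are less heterozygous
  het <- rowMeans(coh$geno[kids$id, ] == 1)
  expect_lt(mean(het[kids$F >= 0.25]), mean(het[kids$F == 0]))
})

test_that("assortative pairing hits its target correlation", {
  set.seed(7)
  sm <- rnorm(6000); sf <- rnorm(6000)
  for (target in c(0.2, 0.43, 0.8)) {
    p <- assortative_pairing(sm, sf, target, seed = 3)
    expect_true(!anyDuplicated(p))
    expect_equal(attr(p, "realized_r"), target, tolerance = 0.02)
  }
  p0 <- assortative_pairing(sm, sf, 0, seed = 4)
  expect_lt(abs(attr(p0, "realized_r")), 3 / sqrt(6000))
  p1 <- assortative_pairing(1:100, 101:200, 1, seed = 5)
  expect_equal(cor(1:100, (101:200)[p1]), 1)
  # heavy ties in one score vector make an exact rank correlation of 1
  # unattainable
  set.seed(11)
  expect_warning(assortative_pairing(rep(1:5, 4), rnorm(20), 1, seed = 6),
                 "ties")
})
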