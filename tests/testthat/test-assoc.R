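test_that("a perfectly additive toy fits exactly", {
  G <- matrix(c(0, 1, 1, 2), ncol = 1)
  y <- c(0, 1, 1, 2)
  ss <- run_gwas(G, y)
  expect_equal(ss$beta, 1, tolerance = 1e-12)
  expect_equal(ss$se, 0, tolerance = 1e-10)
})

test_that("permuted phenotypes give uniform p-values", {
  coh <- founder_panel()
  set.seed(42)
  y_perm <- sample(coh$ped$y)
  ss <- run_gwas(coh$geno, y_perm)
  # within-block LD correlates tests; KS on one SNP per block keeps them
  # independent
  first <- !duplicated(coh$architecture$block)
  ks <- suppressWarnings(ks.test(ss$p[first], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ss$z^2, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("reported z matches beta/se and codings are tagged", {
  coh <- founder_panel()
  ss <- run_gwas(coh$geno[, 1:50], coh$ped$y)
  expect_equal(ss$z^2, (ss$beta / ss$se)^2, tolerance = 1e-12)
  expect_true(all(ss$coding == "additive_012"))
  ssd <- run_gwas(coh$geno[, 1:50], coh$ped$y, coding = "dominance_dev")
  expect_true(all(ssd$coding == "dominance_dev"))
})

test_that("additive and dominance codings are orthogonal under HWE", {
  # algebraic orthogonality at exact Hardy-Weinberg genotype counts
  for (p in c(0.1, 0.3, 0.5)) {
    n <- 1000
    g <- rep(c(0, 1, 2), round(n * c((1 - p)^2, 2 * p * (1 - p), p^2)))
    d <- dominance_coding(g, mean(g) / 2)
    expect_equal(cov(g, d), 0, tolerance = 1e-10)
  }
  # sampling version: standardized covariances are centered on zero
  coh <- founder_panel()
  G <- coh$geno[, seq(1, 2000, by = 40)]
  p_hat <- colMeans(G) / 2
  D <- dominance_coding(G, p_hat)
  n <- nrow(G)
  covs <- vapply(seq_len(ncol(G)), function(j) cov(G[, j], D[, j]),
                 numeric(1))
  mc_se <- vapply(seq_len(ncol(G)), function(j) {
    sd((G[, j] - mean(G[, j])) * (D[, j] - mean(D[, j]))) / sqrt(n)
  }, numeric(1))
  z <- covs / mc_se
  expect_lt(abs(median(z)), 3 / sqrt(length(z)) * 1.5)
  expect_lt(quantile(abs(z), 0.75), 2)
})

test_that("dominance scan of a purely additive trait is null", {
  coh <- founder_panel()  # h2_dom = 0
  ssd <- run_gwas(coh$geno, coh$ped$y, coding = "dominance_dev")
  expect_equal(mean(ssd$z^2, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("monomorphic SNPs are flagged without estimates", {
  G <- cbind(a = c(0, 1, 2, 1, 0, 2), b = rep(0, 6))
  ss <- run_gwas(G, rnorm(6))
  expect_equal(ss$note, c("", "monomorphic"))
  expect_true(is.na(ss$beta[2]))
})

test_that("principal components separate diverged subpopulations", {
  cfg <- sim_config(n_snps = 300, n_blocks = 300, n_founder_pairs = 150,
                    n_generations = 1, ancestry_divergence = 0.05,
                    h2_add = 0.3, seed = 4)
  coh <- simulate_cohort(cfg)
  pcs <- compute_pcs(coh$geno, 2)
  expect_gt(abs(cor(pcs[, 1], coh$ped$subpop)), 0.9)
  expect_equal(colSums(pcs^2), c(PC1 = 1, PC2 = 1), tolerance = 1e-8)
})

test_that("duplicated individuals share PC coordinates and k = 0 is empty", {
  set.seed(2)
  G <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  G2 <- rbind(G, G[1:5, ])
  pcs <- compute_pcs(G2, 3)
  expect_equal(pcs[41:45, ], pcs[1:5, ], tolerance = 1e-8)
  expect_equal(ncol(compute_pcs(G, 0)), 0L)
})

test_that("sex-stratified scans IVW-combine to the pooled result", {
  cfg <- sim_config(n_snps = 200, n_blocks = 200, n_founder_pairs = 1000,
                    n_generations = 1, h2_add = 0.5, seed = 6)
  coh <- simulate_cohort(cfg)
  strat <- sex_stratified_gwas(coh$geno, coh$ped$y, coh$ped$sex)
  comb <- meta_inverse_variance(list(strat$male, strat$female))
  pooled <- run_gwas(coh$geno, coh$ped$y)
  strong <- which(abs(pooled$z) > 3)
  expect_gt(length(strong), 3)
  expect_equal(comb$z[strong], pooled$z[strong], tolerance = 0.05)
  expect_error(sex_stratified_gwas(coh$geno, coh$ped$y,
                                   rep("M", nrow(coh$ped))),
               "both sexes")
})

test_that("the x_male02 coding contract is enforced", {
  set.seed(3)
  sex <- rep(c("M", "F"), each = 30)
  Gx <- rbind(matrix(2 * rbinom(30 * 5, 1, 0.4), 30, 5),
              matrix(rbinom(30 * 5, 2, 0.4), 30, 5))
  y <- rnorm(60)
  ss <- run_gwas(Gx, y, coding = "x_male02", sex = sex)
  expect_true(all(ss$coding == "x_male02"))
  Gbad <- Gx; Gbad[1, 1] <- 1
  expect_error(run_gwas(Gbad, y, coding = "x_male02", sex = sex),
               "\\{0, 2\\}")
  expect_error(run_gwas(Gx, y, coding = "x_male02"), "requires a sex")
})

test_that("covariate residualization matches full multiple regression", {
  set.seed(8)
  n <- 200
  G <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- G[, 2] * 0.3 + C[, 1] * 0.5 + rnorm(n)
  ss <- run_gwas(G, y, covariates = C)
  full <- summary(lm(y ~ G[, 2] + C))$coefficients
  expect_equal(ss$beta[2], full[2, 1], tolerance = 1e-10)
  expect_equal(ss$se[2], full[2, 2], tolerance = 1e-6)
})
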