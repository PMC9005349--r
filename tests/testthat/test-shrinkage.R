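null_stats <- function(m = 2000, n = 50000, seed = 1) {
  set.seed(seed)
  z <- rnorm(m)
  data.frame(snp_id = sprintf("s%d", 1:m), z = z, n = n,
             beta = z / sqrt(n), se = 1 / sqrt(n))
}

test_that("the empirical-Bayes prior is zero on null data and recovers tau2", {
  expect_warning(pr0 <- fit_eb_prior(null_stats(seed = 3)), "below 1")
  expect_equal(pr0$tau2, 0)

  set.seed(4)
  m <- 30000; n <- 50000; tau2 <- 2e-6
  b <- rnorm(m, 0, sqrt(tau2))
  z <- rnorm(m, b * sqrt(n), 1)
  st <- data.frame(z = z, n = n, beta = z / sqrt(n), se = 1 / sqrt(n))
  pr <- fit_eb_prior(st)
  expect_equal(pr$tau2, tau2, tolerance = 0.2)
  # duplicating every record leaves the moment estimate unchanged
  pr_dup <- fit_eb_prior(rbind(st, st))
  expect_equal(pr_dup$tau2, pr$tau2, tolerance = 1e-12)
  # the point-normal fit agrees on scale for a dense architecture
  prp <- fit_eb_prior(st, method = "point_normal")
  expect_lt(abs((1 - prp$pi0) * prp$tau2 - tau2), 0.5 * tau2)
})

test_that("posterior-mean shrinkage follows its closed form", {
  pr <- structure(list(tau2 = 4, pi0 = NA_real_, method = "normal"),
                  class = "eb_prior")
  # tau2 = se^2 halves the estimate
  expect_equal(winners_curse_adjust(1, 2, pr), 0.5)
  # a diffuse prior barely shrinks
  pr_wide <- structure(list(tau2 = 1e9, pi0 = NA_real_, method = "normal"),
                       class = "eb_prior")
  expect_equal(winners_curse_adjust(1, 2, pr_wide), 1, tolerance = 1e-6)
})

test_that("adjusted lead-SNP effects are unbiased where raw ones inflate", {
  set.seed(5)
  raw_bias <- c(); adj_bias <- c(); ses <- c()
  for (s in 1:8) {
    coh <- simulate_cohort(sim_config(
      n_snps = 2000, n_blocks = 2000, n_founder_pairs = 1000,
      n_generations = 1, h2_add = 0.5, seed = 100 + s))
    ss <- standardized_effects(run_gwas(coh$geno, coh$ped$y))
    pr <- fit_eb_prior(ss)
    sel <- which(ss$p < 1e-3)
    if (!length(sel)) next
    tru <- coh$architecture$beta_add  # unlinked: marginal = direct
    adj <- winners_curse_adjust(ss$beta[sel], ss$se[sel], pr)
    sgn <- sign(ss$beta[sel])
    raw_bias <- c(raw_bias, (ss$beta[sel] - tru[sel]) * sgn)
    adj_bias <- c(adj_bias, (adj - tru[sel]) * sgn)
  }
  mc_se <- sd(adj_bias) / sqrt(length(adj_bias))
  expect_gt(mean(raw_bias), 3 * sd(raw_bias) / sqrt(length(raw_bias)))
  expect_lt(abs(mean(adj_bias)), 2 * mc_se)
})

test_that("replication expectations have the pure-noise limits", {
  pr0 <- structure(list(tau2 = 0, pi0 = NA_real_, method = "normal"),
                   class = "eb_prior")
  disc <- data.frame(beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.02, 0.02))
  out <- replication_expectations(disc, pr0, N_rep = 1e5, alpha_rep = 0.04)
  expect_equal(out$expected_sign_concordance, 0.5, tolerance = 1e-12)
  expect_equal(out$expected_significant, 0.04, tolerance = 1e-12)
  expect_error(replication_expectations(disc, pr0, 1e5, alpha_rep = 2),
               "alpha_rep")
})

test_that("predicted replication rates match a full discovery-replication simulation", {
  set.seed(6)
  m <- 50000; n_disc <- 60000; n_rep <- 20000; tau2 <- 1.5e-6
  b <- rnorm(m, 0, sqrt(tau2))
  z_disc <- rnorm(m, b * sqrt(n_disc), 1)
  st <- data.frame(z = z_disc, n = n_disc, beta = z_disc / sqrt(n_disc),
                   se = 1 / sqrt(n_disc))
  pr <- fit_eb_prior(st)
  sel <- which(abs(z_disc) > qnorm(1 - 5e-4))
  expect_gt(length(sel), 50)
  pred <- replication_expectations(st[sel, ], pr, N_rep = n_rep,
                                  alpha_rep = 0.05)
  z_rep <- rnorm(length(sel), b[sel] * sqrt(n_rep), 1)
  sgn <- sign(z_disc[sel])
  real_sign <- mean(sgn * z_rep > 0)
  real_sig <- mean(sgn * z_rep > qnorm(0.95))
  mc <- sqrt(0.25 / length(sel))
  expect_lt(abs(real_sign - pred$expected_sign_concordance), 2 * mc + 0.01)
  expect_lt(abs(real_sig - pred$expected_significant), 2 * mc + 0.01)
})

test_that("individual-level inbreeding depression converts to months", {
  set.seed(7)
  n <- 4000
  F <- sample(c(0, 1 / 16, 1 / 4), n, replace = TRUE,
              prob = c(0.8, 0.1, 0.1))
  y <- 14 - 1.33 * F + rnorm(n, 0, 0.5)
  est <- estimate_id_individual(y, F)
  expect_equal(est$b, -1.33, tolerance = 3 * est$se / abs(est$b))
  expect_equal(est$first_cousin_offspring_effect, -1.33 / 16 * 12,
               tolerance = 0.25)
  expect_equal(sign(est$first_cousin_offspring_effect), sign(est$b))
  expect_error(estimate_id_individual(rnorm(10), rep(0, 10)), "constant")
})

test_that("summary-statistic ID matches the individual-level regression", {
  coh <- cached("id_cohort", {
    simulate_cohort(sim_config(
      n_snps = 800, n_blocks = 800, n_founder_pairs = 1200,
      n_generations = 3, h2_add = 0.2, h2_dom = 0.15,
      directional_dominance = TRUE, inbred_fraction = 0.15, seed = 31))
  })
  ped <- coh$ped
  kids <- ped$generation == 3
  ind <- estimate_id_individual(ped$y[kids], ped$F[kids])
  founders <- ped$generation == 1
  ssd <- run_gwas(coh$geno[ped$id[founders], ], ped$y[founders],
                  coding = "dominance_dev")
  sum_est <- estimate_id_sumstats(ssd)
  expect_lt(abs(ind$b - sum_est$b), 2 * sqrt(ind$se^2 + sum_est$se^2))
  # both see the generative slope -sum 2p(1-p) delta
  ar <- coh$architecture
  gen_b <- -sum(2 * ar$freq * (1 - ar$freq) * ar$delta_dom)
  expect_lt(abs(sum_est$b - gen_b), 3 * sum_est$se)
  expect_lt(ind$b, 0)  # directional dominance depresses the phenotype
  # coding tag and null checks
  expect_error(estimate_id_sumstats(transform(ssd, coding = "additive_012")),
               "dominance_dev")
  null_d <- transform(ssd, beta = 0)
  expect_equal(estimate_id_sumstats(null_d)$b, 0)
})
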