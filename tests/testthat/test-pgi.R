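test_that("clumping-and-thresholding weights compose with the clumper", {
  stats <- data.frame(snp_id = c("A", "B", "C"), chr = 1, pos = 1:3,
                      a1 = "A", a2 = "G", p = c(1e-10, 1e-9, 1e-8),
                      beta = c(0.5, 0.4, 0.3))
  ld <- data.frame(snp_a = c("A", "A", "B"), snp_b = c("B", "C", "C"),
                   r2 = c(0.2, 0.05, 0.2))
  w <- build_ct_weights(stats, ld, 5e-8)
  expect_equal(w$snp_id, c("A", "C"))
  expect_equal(w$weight, c(0.5, 0.3))
  # nested thresholds give nested survivor sets
  w_all <- build_ct_weights(stats, ld, 1)
  expect_true(all(w$snp_id %in% w_all$snp_id))
  expect_warning(build_ct_weights(stats, ld, 1e-20), "no SNP")
})

test_that("scoring is a dosage-weight inner product with flip handling", {
  G <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
              dimnames = list(NULL, c("s1", "s2")))
  w1 <- data.frame(snp_id = "s1", a1 = "A", weight = 1)
  expect_equal(score_pgi(G, w1, effect_allele = c("A", "A")), G[, "s1"])
  # a swapped-allele weight file gives identical scores after flipping
  w_sw <- data.frame(snp_id = "s1", a1 = "G", weight = -1)
  expect_equal(score_pgi(G, w_sw, effect_allele = c("A", "A"),
                         other_allele = c("G", "G")),
               G[, "s1"] - 2)
  expect_error(score_pgi(G, data.frame(snp_id = "zz", a1 = "A", weight = 1)),
               "no overlapping")
  # missing dosages are mean-imputed
  G2 <- G; G2[1, 1] <- NA
  s <- score_pgi(G2, w1)
  expect_equal(s[1], mean(G[2:3, 1]))
})

test_that("true-architecture weights recover the genetic value", {
  coh <- family_cohort()
  ar <- coh$architecture
  s <- sqrt(2 * ar$freq * (1 - ar$freq))
  w <- data.frame(snp_id = ar$snp_id, a1 = "A", weight = ar$beta_add / s)
  pgi <- score_pgi(coh$geno, w, effect_allele = "A")
  expect_gt(cor(pgi, coh$ped$gv_add), 0.99)
})

test_that("infinitesimal shrinkage has its closed forms and helps under LD", {
  st <- data.frame(snp_id = c("a", "b", "c"), a1 = "A",
                   beta = c(0.1, -0.2, 0.3), n = 1000)
  # unlinked: w = beta / (1 + M/(N h2))
  w <- build_inf_weights(st, blocks = 1:3, within_block_r = 0,
                         h2 = 0.3, M = 3)
  expect_equal(w$weight, st$beta / (1 + 3 / (1000 * 0.3)), tolerance = 1e-12)
  expect_true(all(w$method == "inf_shrink"))
  # one exchangeable block: matches the explicit linear solve
  w2 <- build_inf_weights(st, blocks = rep(1, 3), within_block_r = 0.4,
                          h2 = 0.3, M = 3)
  R <- matrix(0.4, 3, 3); diag(R) <- 1
  expect_equal(w2$weight,
               drop(solve(R + diag(3 / 300, 3), st$beta)), tolerance = 1e-12)
  # on a blocked-LD cohort the shrunk PGI tracks the genetic value at least
  # as well as raw-beta weights
  coh <- founder_panel()
  ss <- standardized_effects(run_gwas(coh$geno, coh$ped$y))
  blk <- coh$architecture$block
  wi <- build_inf_weights(ss, blk, 0.5, h2 = 0.5)
  raw <- data.frame(snp_id = ss$snp_id, a1 = ss$a1, weight = ss$beta)
  p_inf <- score_pgi(coh$geno, wi, effect_allele = "A")
  p_raw <- score_pgi(coh$geno, raw, effect_allele = "A")
  expect_gte(cor(p_inf, coh$ped$gv_add), cor(p_raw, coh$ped$gv_add) - 0.005)
})

test_that("incremental R2 matches its algebraic endpoints", {
  set.seed(4)
  n <- 400
  C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  pgi <- rnorm(n)
  y_indep <- rnorm(n)
  out <- incremental_r2(y_indep, pgi, C, n_boot = 100, seed = 1)
  expect_lt(out$delta_r2, 0.03)
  # y = pgi exactly: delta R2 = 1 - R2_baseline
  out2 <- incremental_r2(pgi, pgi, C, n_boot = 0)
  expect_equal(out2$delta_r2, 1 - out2$r2_without, tolerance = 1e-10)
  # generative correlation rho implies delta R2 about rho^2
  rho <- 0.4
  y <- rho * pgi + sqrt(1 - rho^2) * rnorm(n)
  out3 <- incremental_r2(y, pgi, covariates = NULL, n_boot = 200, seed = 2)
  expect_true(out3$ci[1] <= rho^2 & rho^2 <= out3$ci[2])
})

test_that("incremental Nagelkerke R2 is null-calibrated and monotone", {
  set.seed(5)
  n <- 1500
  pgi <- rnorm(n)
  y0 <- rbinom(n, 1, 0.3)
  for (link in c("logistic", "probit")) {
    out <- nagelkerke_incremental(y0, pgi, link = link)
    expect_lt(out$delta_r2, 0.01)
    expect_false(out$separation)
  }
  # liability-threshold outcome: delta R2 grows with the liability loading
  d <- vapply(c(0.2, 0.45, 0.7), function(rho) {
    liab <- rho * pgi + sqrt(1 - rho^2) * rnorm(n)
    yb <- as.integer(liab > quantile(liab, 0.7))
    nagelkerke_incremental(yb, pgi, link = "probit")$delta_r2
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  # intercept-only null model has Nagelkerke R2 zero
  out0 <- nagelkerke_incremental(y0, rep(0, n) + rnorm(n, 0, 1e-8))
  expect_equal(out0$r2_without, 0)
})

test_that("deciles partition the sample and track a monotone liability", {
  set.seed(6)
  n <- 2000
  pgi <- rnorm(n)
  liab <- 0.5 * pgi + rnorm(n)
  y <- as.integer(liab > 0.5)
  rep <- decile_report(pgi, y)
  expect_equal(sum(rep$n), n)
  expect_true(all(rep$n == n / 10))
  # prevalences nondecreasing up to CI noise: compare smoothed ends
  expect_gt(mean(rep$prevalence[8:10]), mean(rep$prevalence[1:3]))
  expect_true(all(rep$odds_ratio[1] == 1))
  expect_gt(rep$odds_ratio[10], rep$odds_ratio[2])
  # constant outcome: flat prevalences
  repc <- decile_report(pgi, rep(1L, n))
  expect_true(all(repc$prevalence == 1))
})

test_that("accuracy summaries reproduce the printed values", {
  expect_equal(weighted_mean_r2(c(15.8, 12.0), c(5653, 10843)), 13.3,
               tolerance = 0.05)
  expect_equal(weighted_mean_r2(c(17.0, 12.9), c(5653, 10843)), 14.3,
               tolerance = 0.05)
  expect_equal(weighted_mean_r2(c(10, 20), c(7, 7)), 15)
  expect_equal(relative_accuracy(1.3, 12.0), 11, tolerance = 0.5)
  expect_equal(relative_accuracy(2.3, 15.8), 15, tolerance = 0.5)
  expect_equal(relative_accuracy(5, 5), 100)
  expect_error(relative_accuracy(1, 0), "positive")
})

test_that("the expected-accuracy curve fits exactly and recovers truth", {
  # scale typical of polygenic prediction: asymptote A/B = 0.15, accuracy
  # still rising over N = 5e3..2e6
  A <- 3e-6; B <- 2e-5
  two <- data.frame(N = c(1e4, 1e6), R2 = A / (B + 1 / c(1e4, 1e6)))
  fit2 <- fit_expected_r2(two)
  expect_equal(fit2$A, A, tolerance = 1e-6)
  expect_equal(fit2$B, B, tolerance = 1e-6)
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-12)

  set.seed(7)
  N <- c(5e3, 2e4, 1e5, 5e5, 2e6)
  pts <- data.frame(N = N, R2 = A / (B + 1 / N) * (1 + rnorm(5, 0, 0.02)))
  fit <- fit_expected_r2(pts)
  expect_equal(fit$A, A, tolerance = 0.05)
  expect_equal(fit$B, B, tolerance = 0.1)
  # monotone in N with asymptote A/B
  grid <- fit$predict(10^seq(3, 9))
  expect_true(all(diff(grid) > 0))
  expect_equal(fit$predict(1e12), fit$asymptote, tolerance = 1e-4)
})

test_that("power and detectable R2 invert each other", {
  expect_equal(gwas_power(1000, 0, 0.05), 0.05, tolerance = 1e-12)
  for (N in c(5e3, 2.5e6)) {
    for (pw in c(0.5, 0.8, 0.95)) {
      r2 <- detectable_r2(N, pw, 5e-8)
      expect_equal(gwas_power(N, r2, 5e-8), pw, tolerance = 1e-6)
    }
  }
  expect_error(detectable_r2(1000, 1e-9, 0.05), "between alpha and 1")
})

test_that("analytic power matches Monte-Carlo rejection rates", {
  N <- 500; r2 <- 0.02; alpha <- 1e-3
  set.seed(8)
  nsim <- 10000
  x <- matrix(rnorm(N * nsim), N)
  y <- sqrt(r2) * x + sqrt(1 - r2) * matrix(rnorm(N * nsim), N)
  r <- colSums(scale(x) * scale(y)) / (N - 1)
  tstat <- r * sqrt((N - 2) / (1 - r^2))
  rej <- mean(2 * pt(-abs(tstat), N - 2) < alpha)
  expect_equal(rej, gwas_power(N, r2, alpha), tolerance = 0.02)
})
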