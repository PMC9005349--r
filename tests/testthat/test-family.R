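test_that("a phenotype equal to the child PGI yields delta 1, alpha 0", {
  set.seed(1)
  n <- 300
  pc <- rnorm(n); pf <- rnorm(n); pm <- rnorm(n)
  fit <- estimate_trio_effects(pc, pc, pf, pm)
  expect_equal(fit$delta, 1, tolerance = 1e-6)
  expect_equal(fit$alpha_f, 0, tolerance = 1e-6)
  expect_equal(fit$alpha_m, 0, tolerance = 1e-6)
})

test_that("trio regression recovers the generative direct and indirect effects", {
  coh <- family_cohort()  # h2_add = 0.4, eta = 0.15, assortment 0.4
  tr <- cohort_trios(coh)
  fit <- estimate_trio_effects(tr$y, tr$pgi_child, tr$pgi_father,
                               tr$pgi_mother, tr$family_id)
  # PGI standardized: true delta = sd(gv_add); alpha = eta * sd(gv_add)
  sd_gv <- sd(coh$ped$gv_add)
  expect_lt(abs(fit$delta - sd_gv), 2 * sqrt(fit$vcov[1, 1]))
  expect_lt(abs(fit$alpha_f - 0.15 * sd_gv), 2 * sqrt(fit$vcov[2, 2]))
  expect_lt(abs(fit$alpha_m - 0.15 * sd_gv), 2 * sqrt(fit$vcov[3, 3]))
})

test_that("sibling deviation regression recovers delta and is shift-invariant", {
  coh <- family_cohort()
  sb <- cohort_sibs(coh)
  fit <- estimate_sib_effects(sb$y, sb$pgi, sb$sibship_id)
  sd_gv <- sd(coh$ped$gv_add)
  expect_lt(abs(fit$delta - sd_gv), 2 * sqrt(fit$vcov[1, 1]))
  shifted <- estimate_sib_effects(sb$y, sb$pgi + 5, sb$sibship_id)
  expect_equal(shifted$delta, fit$delta, tolerance = 1e-8)
  # zero within-family variance (identical twins only) is degenerate
  twin_pgi <- rep(rnorm(50), each = 2)
  expect_error(
    suppressWarnings(estimate_sib_effects(rnorm(100), twin_pgi,
                                          rep(1:50, each = 2))),
    "within-family")
})

test_that("sib and trio direct effects agree under indirect effects", {
  coh <- family_cohort()
  tr <- cohort_trios(coh)
  sb <- cohort_sibs(coh)
  ft <- estimate_trio_effects(tr$y, tr$pgi_child, tr$pgi_father,
                              tr$pgi_mother, tr$family_id)
  fs <- estimate_sib_effects(sb$y, sb$pgi, sb$sibship_id)
  pooled_se <- sqrt(ft$vcov[1, 1] + fs$vcov[1, 1])
  expect_lt(abs(ft$delta - fs$delta), 2 * pooled_se)
})

test_that("the assortative-mating transform reproduces its arithmetic", {
  expect_equal(population_transform(0.3, 0, 0, 0), 0.3)
  expect_equal(population_transform(0.3, 0.1, 0.1, 0.2), 0.42)
  tr <- population_transform(0.3, 0.1, 0.1, 0.2, vcov = diag(3) * 1e-4)
  expect_equal(tr$beta_pop, 0.42)
  expect_equal(dim(tr$vcov), c(2L, 2L))
})

test_that("the transform matches the marginal slope in an assorted cohort", {
  coh <- family_cohort()
  tr <- cohort_trios(coh)
  fit <- estimate_trio_effects(tr$y, tr$pgi_child, tr$pgi_father,
                               tr$pgi_mother, tr$family_id)
  mp <- cohort_mate_pairs(coh, generation = 3)
  r_mate <- cor(mp$pgi_m, mp$pgi_f)
  beta_pop <- population_transform(fit$delta, fit$alpha_f, fit$alpha_m,
                                   r_mate)
  marg_fit <- lm(tr$y ~ tr$pgi_child)
  marg <- coef(marg_fit)[2]
  marg_se <- summary(marg_fit)$coefficients[2, 2]
  expect_lt(abs(beta_pop - marg), 2 * (marg_se + sqrt(fit$vcov[1, 1])))
})

test_that("random mating without indirect effects equates all three slopes", {
  cfg <- sim_config(n_snps = 300, n_blocks = 150, within_block_r = 0.3,
                    n_founder_pairs = 1200, n_generations = 3, h2_add = 0.4,
                    indirect_scale = 0, target_mate_r = 0, seed = 55)
  coh <- simulate_cohort(cfg)
  tr <- cohort_trios(coh)
  fit <- estimate_trio_effects(tr$y, tr$pgi_child, tr$pgi_father,
                               tr$pgi_mother, tr$family_id)
  marg <- coef(lm(tr$y ~ tr$pgi_child))[2]
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$delta - marg), 2 * se)
  bp <- population_transform(fit$delta, fit$alpha_f, fit$alpha_m, 0)
  expect_lt(abs(bp - marg), 2 * se)
})

test_that("design combination is an inverse-variance average", {
  e1 <- pgikit:::new_effect_estimate(0.3, NA, NA, matrix(0.01), "sib", 100)
  e2 <- pgikit:::new_effect_estimate(0.5, NA, NA, matrix(0.01), "sib", 100)
  expect_equal(combine_designs(list(e1)), e1)
  cmb <- combine_designs(list(e1, e2))
  expect_equal(cmb$delta, 0.4)
  expect_equal(cmb$vcov[1, 1], 0.005)
  # positive cross-design covariance widens the combined uncertainty
  cmb2 <- combine_designs(list(e1, e2), cross_cov = 0.005)
  expect_gt(cmb2$vcov[1, 1], cmb$vcov[1, 1])
})

test_that("ratio and share reproduce the printed direct-effect arithmetic", {
  expect_equal(ratio_and_share(0.556, 1)$share_pct, 30.9, tolerance = 0.05)
  expect_equal(ratio_and_share(0.910, 1)$share_pct, 82.8, tolerance = 0.05)
  expect_equal(ratio_and_share(1, 1)$share_pct, 100)
  expect_error(ratio_and_share(0.5, 0), "zero")
  rs <- ratio_and_share(0.5, 1, vcov = diag(2) * 1e-4)
  expect_true(is.finite(rs$se_ratio) && rs$se_ratio > 0)
  # monotone in the ratio on [0, 1]
  shares <- vapply(seq(0, 1, 0.1), function(r) {
    ratio_and_share(r, 1)$share_pct
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})
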