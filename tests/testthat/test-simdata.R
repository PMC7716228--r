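test_that("marker simulation respects coding, rates and determinism", {
  cfg <- sim_config(n_lines = 60, n_checks = 2, n_markers = 300,
                    n_subpops = 3, het_rate = 0, missing_rate = 0,
                    seed = 11)
  mk <- simulate_marker_matrix(cfg)
  expect_true(all(mk$geno %in% c(0L, 2L)))
  expect_identical(mk$geno, simulate_marker_matrix(cfg)$geno)

  cfg2 <- sim_config(n_lines = 200, n_checks = 0, n_markers = 2000,
                     n_subpops = 2, het_rate = 0.05, missing_rate = 0.1,
                     seed = 12)
  mk2 <- simulate_marker_matrix(cfg2)
  expect_equal(mean(is.na(mk2$geno)), 0.1, tolerance = 0.05)
  expect_equal(mean(mk2$complete == 1), 0.05, tolerance = 0.2)
})

test_that("realized allele frequencies stay inside the configured range", {
  cfg <- sim_config(n_lines = 400, n_checks = 0, n_markers = 1000,
                    n_subpops = 2, maf_range = c(0.15, 0.45),
                    het_rate = 0, missing_rate = 0, fst = 0.01, seed = 13)
  mk <- simulate_marker_matrix(cfg)
  maf <- marker_stats(mk$complete)$maf
  expect_gt(mean(maf >= 0.10 & maf <= 0.5), 0.99)
  expect_gt(mean(maf), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_lines = 0), "positive")
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_config(n_subpops = 50, n_lines = 10), "n_subpops")
  expect_error(sim_config(n_traits = 2,
                          trait_genetic_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("planted trait genetic correlation is reproduced", {
  St <- matrix(c(1, 0.67, 0.67, 1), 2)
  cfg <- sim_config(n_lines = 500, n_checks = 0, n_markers = 800,
                    n_subpops = 4, n_traits = 2, n_envs = 2,
                    trait_genetic_cov = St, het_rate = 0,
                    missing_rate = 0, seed = 14)
  mk <- simulate_marker_matrix(cfg)
  ph <- simulate_phenotypes(mk, cfg)
  gv <- ph$truth$genetic_values
  for (i in 1:2)
    expect_equal(cor(gv[, i, 1], gv[, i, 2]), 0.67, tolerance = 0.1)

  # independence case: diagonal trait covariance
  cfg0 <- sim_config(n_lines = 500, n_checks = 0, n_markers = 3000,
                     n_subpops = 2, n_traits = 2, n_envs = 1,
                     trait_genetic_cov = diag(2), het_rate = 0,
                     missing_rate = 0, fst = 0.01, seed = 15)
  mk0 <- simulate_marker_matrix(cfg0)
  gv0 <- simulate_phenotypes(mk0, cfg0)$truth$genetic_values
  expect_lt(abs(cor(gv0[, 1, 1], gv0[, 1, 2])), 0.1)
})

test_that("generated margins converge to the trait and environment targets", {
  St <- diag(3); St[St == 0] <- 0.5
  Se <- diag(3); Se[Se == 0] <- 0.3
  cfg <- sim_config(n_lines = 1000, n_checks = 0, n_markers = 1200,
                    n_subpops = 4, n_traits = 3, n_envs = 3,
                    trait_genetic_cov = St, env_genetic_cov = Se,
                    ge_variance = 1, het_rate = 0, missing_rate = 0,
                    seed = 16)
  mk <- simulate_marker_matrix(cfg)
  gv <- simulate_phenotypes(mk, cfg)$truth$genetic_values
  for (i in 1:3) {
    tc <- cor(gv[, i, ])
    expect_true(all(abs(tc - St) < 0.1))
  }
  for (l in 1:3) {
    ec <- cor(gv[, , l])
    expect_true(all(abs(ec - Se) < 0.1))
  }
})

test_that("realized heritability matches an ANOVA oracle on replicated lines", {
  # all-replicated design (checks in every block), no block variance, so a
  # one-way decomposition over lines is an unbiased oracle
  cfg <- sim_config(n_lines = 2, n_checks = 498, n_markers = 600,
                    n_subpops = 2, n_traits = 1, n_envs = 1, n_blocks = 3,
                    target_h2 = matrix(0.8, 1, 1), block_var_share = 0,
                    het_rate = 0, missing_rate = 0, seed = 17)
  mk <- simulate_marker_matrix(cfg)
  ph <- simulate_phenotypes(mk, cfg)
  d <- ph$pheno[ph$pheno$is_check, ]
  fit <- stats::aov(T1 ~ line, data = d)
  ms <- summary(fit)[[1]]$`Mean Sq`
  r <- 3
  sg <- (ms[1] - ms[2]) / r
  h2_hat <- sg / (sg + ms[2])
  expect_equal(h2_hat, 0.8, tolerance = 0.08)
  expect_equal(unname(ph$truth$realized_h2[1, 1]), 0.8, tolerance = 0.05)
})

test_that("augmented design places checks in every block, entries once", {
  cfg <- sim_config(n_lines = 40, n_checks = 3, n_markers = 100,
                    n_subpops = 2, n_envs = 2, n_blocks = 5, seed = 18)
  mk <- simulate_marker_matrix(cfg)
  ph <- simulate_phenotypes(mk, cfg)$pheno
  for (e in unique(ph$env)) {
    sub <- ph[ph$env == e, ]
    checks <- sub[sub$is_check, ]
    expect_equal(nrow(checks), 3 * 5)
    expect_true(all(table(checks$line, checks$block) == 1))
    entries <- sub[!sub$is_check, ]
    expect_true(all(table(entries$line) == 1))
  }
})
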