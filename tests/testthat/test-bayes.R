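test_that("mcmc configuration validates its invariants", {
  expect_error(mcmc_config(100, 100), "burn_in")
  expect_error(mcmc_config(100, 10, thin = 0), "thin")
  expect_s3_class(mcmc_config(100, 10), "mcmc_config")
})

test_that("masked cells approach true genetic values in the noise-free limit", {
  # near-zero residual variance, mostly main-effect genetics: a cell masked
  # in one environment is recoverable from the line's other environment
  p <- small_panel(n_lines = 120, n_markers = 600, n_traits = 1,
                   n_envs = 2, h2 = 1, ge_variance = 0.02, seed = 41,
                   block_var_share = 0)
  y <- p$Y[, , 1]
  mask <- seq(1, 120, by = 3)
  ytr <- y; ytr[mask, 1] <- NA
  fit <- fit_mgblup(ytr, p$grm, mcmc_config(1200, 400, seed = 1))
  truth <- p$truth$genetic_values[rownames(y), 1, 1]
  expect_gt(cor(fit$yhat[mask, 1], truth[mask]), 0.95)
})

test_that("an identity kernel gives no information beyond environment means", {
  p <- small_panel(n_lines = 100, n_markers = 400, n_traits = 1,
                   n_envs = 2, h2 = 0.5, seed = 42)
  y <- p$Y[, , 1]
  Id <- diag(nrow(y)); dimnames(Id) <- list(rownames(y), rownames(y))
  mask <- 1:30
  ytr <- y; ytr[mask, ] <- NA
  fit <- fit_mgblup(ytr, Id, mcmc_config(3000, 1000, seed = 2))
  dev <- sweep(fit$yhat[mask, ], 2, colMeans(ytr, na.rm = TRUE))
  expect_lt(mean(abs(dev)), 0.2 * sd(y))
})

test_that("posterior-mean predictions agree across chains with different seeds", {
  p <- small_panel(n_lines = 100, n_markers = 400, n_traits = 2,
                   n_envs = 2, h2 = 0.6, seed = 43)
  Ym <- p$Y; Ym[1:20, , ] <- NA
  f1 <- fit_bmtme(Ym, p$grm, mcmc_config(1500, 500, seed = 7))
  f2 <- fit_bmtme(Ym, p$grm, mcmc_config(1500, 500, seed = 8))
  expect_gt(cor(as.vector(f1$yhat), as.vector(f2$yhat)), 0.99)
  expect_lt(mean(abs(f1$yhat - f2$yhat)), 0.1 * sd(p$Y))
})

test_that("genetic correlations derive from posterior covariances", {
  fake <- structure(list(
    Sigma_t = matrix(c(1, 0.5, 0.5, 1), 2,
                     dimnames = list(c("A", "B"), c("A", "B"))),
    Sigma_E = diag(2)), class = "bmtme_fit")
  gc <- genetic_correlations(fake)
  expect_equal(gc$trait["A", "B"], 0.5)
  expect_equal(diag(gc$trait), c(A = 1, B = 1))

  fake$Sigma_t <- diag(c(2, 3))
  expect_equal(genetic_correlations(fake)$trait[1, 2], 0)
})

test_that("stacking scales stage-1 predictions with training statistics", {
  p <- small_panel(n_lines = 80, n_markers = 300, n_traits = 2,
                   n_envs = 2, h2 = 0.6, seed = 44)
  zhat <- p$Y            # pretend stage-1 reproduced the data
  zhat[, , 1] <- zhat[, , 1] * 2 + 10
  s1 <- list(zhat = zhat)
  Ym <- p$Y; Ym[1:15, , 1] <- NA
  f <- fit_bmors(Ym, p$grm, 1, mcmc_config(1000, 400, seed = 3),
                 stage1 = s1)
  train <- !is.na(Ym[, , 1])
  z1 <- zhat[, , 1]
  expect_equal(unname(f$scaling[1, "mu"]), mean(z1[train]))
  expect_equal(unname(f$scaling[1, "sd"]), sd(z1[train]))
  scaled <- (z1[train] - f$scaling[1, "mu"]) / f$scaling[1, "sd"]
  expect_equal(mean(scaled), 0, tolerance = 1e-10)
  expect_equal(sd(scaled), 1, tolerance = 1e-10)
})

test_that("stacking coefficients separate signal from noise traits", {
  p <- small_panel(n_lines = 150, n_markers = 500, n_traits = 3,
                   n_envs = 2, h2 = 0.6, seed = 45)
  # target equals trait 1's stage-1 prediction; traits 2-3 independent
  set.seed(46)
  zhat <- p$Y
  Ym <- p$Y
  Ym[, , 1] <- zhat[, , 1]
  f <- fit_bmors(Ym, p$grm, 1, mcmc_config(1500, 500, seed = 4),
                 stage1 = list(zhat = zhat))
  beta <- f$beta[-1]
  expect_gt(abs(beta[1]), 3 * max(abs(beta[-1])))

  # pure-noise target: every coefficient within 2 posterior sds of zero
  Yn <- p$Y
  Yn[, , 1] <- array(rnorm(length(Yn[, , 1])), dim = dim(Yn[, , 1]))
  zn <- zhat
  zn[, , 1] <- Yn[, , 1] + rnorm(length(Yn[, , 1]))   # weak self-signal only
  fn <- fit_bmors(Yn, p$grm, 2, mcmc_config(1500, 500, seed = 5),
                  stage1 = list(zhat = array(rnorm(length(zhat)),
                                             dim = dim(zhat),
                                             dimnames = dimnames(zhat))))
  expect_true(all(abs(fn$beta[-1]) <= 2 * fn$beta_sd[-1] + 1e-8))
})

test_that("held-out environments never contribute to training", {
  p <- small_panel(n_lines = 60, n_markers = 300, n_traits = 2,
                   n_envs = 3, h2 = 0.6, seed = 47)
  mc <- mcmc_config(500, 200, seed = 6)
  lo1 <- leave_one_env_out_bmors(p$Y, p$grm, mc)
  Y2 <- p$Y
  Y2[, 1, ] <- Y2[, 1, ] + matrix(rnorm(length(Y2[, 1, ]), sd = 5),
                                  nrow(Y2))
  lo2 <- leave_one_env_out_bmors(Y2, p$grm, mc)
  expect_equal(lo1$pred[, 1, ], lo2$pred[, 1, ])
  expect_error(leave_one_env_out_bmors(p$Y[, 1, , drop = FALSE], p$grm, mc),
               "at least 2")
})

test_that("environment-correlated simulations predict held-out environments better", {
  mc <- mcmc_config(600, 200, seed = 9)
  cors <- sapply(c(0.05, 0.95), function(ge_share) {
    p <- small_panel(n_lines = 100, n_markers = 400, n_traits = 1,
                     n_envs = 2, h2 = 0.8,
                     ge_variance = ge_share, seed = 48)
    lo <- leave_one_env_out_bmors(p$Y, p$grm, mc)
    mean(lo$cors)
  })
  # low G x E share = high between-environment genetic correlation
  expect_gt(cors[1], cors[2])
})
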