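test_that("strongly diverged subpopulations are recovered by clustering", {
  cfg <- sim_config(n_lines = 234, n_checks = 3, n_markers = 3000,
                    n_subpops = 10, fst = 0.5, het_rate = 0,
                    missing_rate = 0, seed = 61)
  mk <- simulate_marker_matrix(cfg)
  cm <- cluster_panel(mk$complete, k = 10, seed = 1)
  expect_gt(mclust::adjustedRandIndex(cm$assignment, mk$subpop), 0.9)
  expect_equal(unname(rowSums(cm$posterior)), rep(1, nrow(cm$posterior)),
               tolerance = 1e-8)

  # two blocks of identical lines separate perfectly
  base <- 2L * (runif(200) < 0.3)
  g2 <- rbind(matrix(base, 10, 200, byrow = TRUE),
              matrix(2 - base, 10, 200, byrow = TRUE))
  g2 <- g2 + matrix(rbinom(4000, 1, 0.02), 20)      # tiny jitter
  g2[g2 > 2] <- 2
  dimnames(g2) <- list(paste0("l", 1:20), paste0("m", 1:200))
  cm2 <- cluster_panel(g2, k = 2, seed = 2)
  expect_equal(mclust::adjustedRandIndex(cm2$assignment,
                                         rep(1:2, each = 10)), 1)
  expect_gt(min(apply(cm2$posterior, 1, max)), 0.99)

  expect_error(cluster_panel(g2, k = 30), "exceed")
})

test_that("fold assignment satisfies partition and balance invariants", {
  lines <- sprintf("L%03d", 1:237)
  fa <- make_folds(lines, f = 5, scheme = "random", seed = 3)
  expect_setequal(fa$line, lines)
  expect_equal(sort(as.vector(table(fa$fold))), c(47, 47, 47, 48, 48))

  cl <- factor(rep(paste0("Q", 1:10), length.out = 237))
  fs <- make_folds(lines, f = 5, scheme = "stratified", clusters = cl,
                   seed = 4)
  # a 14-line cluster spreads as {2,3,3,3,3} across the five folds
  cl14 <- factor(rep(1, 14))
  f14 <- make_folds(sprintf("x%02d", 1:14), f = 5, scheme = "stratified",
                    clusters = cl14, seed = 5)
  expect_equal(sort(as.vector(table(factor(f14$fold, levels = 1:5)))),
               c(2, 3, 3, 3, 3))

  expect_error(make_folds(lines[1:3], f = 5), "folds")
  expect_error(make_folds(lines, scheme = "stratified"), "cluster")
})

test_that("an oracle predictor scores perfectly and a mean-only model does not", {
  p <- small_panel(n_lines = 60, n_markers = 300, n_traits = 2,
                   n_envs = 2, h2 = 0.6, seed = 62)
  folds <- make_folds(rownames(p$grm), f = 4, seed = 6)
  oracle <- function(Ym, grm, ...) p$Y
  cv <- cross_validate(oracle, p$Y, p$grm, folds)
  expect_true(all(abs(cv$rp - 1) < 1e-12))

  set.seed(63)
  mean_model <- function(Ym, grm, ...) {
    out <- Ym
    for (i in seq_len(dim(Ym)[2])) for (l in seq_len(dim(Ym)[3]))
      out[, i, l] <- mean(Ym[, i, l], na.rm = TRUE) +
        rnorm(dim(Ym)[1], sd = 1e-6)
    out
  }
  cvm <- cross_validate(mean_model, p$Y, p$grm, folds)
  expect_lt(abs(mean(cvm$rp)), 0.25)
})

test_that("prediction accuracy follows the square-root-heritability formula", {
  expect_equal(prediction_accuracy(rep(0, 5), 0.3)$accuracy, 0)
  pa <- prediction_accuracy(rep(0.4, 5), 0.64)
  expect_equal(pa$accuracy, 0.5)
  expect_equal(pa$se, 0)
  pa2 <- prediction_accuracy(c(0.3, 0.5), 0.25)
  expect_equal(pa2$accuracy, 0.8)
  expect_equal(pa2$se, sd(c(0.3, 0.5)) / (sqrt(2) * 0.5))
  expect_error(prediction_accuracy(c(0.1, 0.2), 0), "positive")
})

test_that("response to selection matches its arithmetic and invariances", {
  r <- response_to_selection(1:10, 1:10, h2 = 0.5)
  expect_equal(r$S, 4.5)
  expect_equal(r$R, 2.25)
  expect_equal(r$selected, 10L)

  # invariance to shifting all GEBVs
  r2 <- response_to_selection(1:10 + 100, 1:10, h2 = 0.5)
  expect_equal(r2$R, r$R)

  # selecting on the phenotype itself maximizes S over all rankings
  set.seed(64)
  phen <- rnorm(10)
  best <- response_to_selection(phen, phen, h2 = 1)$S
  combs <- combn(10, 1)
  all_S <- apply(combs, 2, function(i) mean(phen[i]) - mean(phen))
  expect_equal(best, max(all_S))

  # permutation null: expected response is zero
  set.seed(65)
  Rs <- replicate(1000, {
    g <- sample(20)
    response_to_selection(g, phen[c(1:10, 1:10)], h2 = 0.8)$R
  })
  expect_lt(abs(mean(Rs)), 2 * sd(Rs) / sqrt(1000))
})

test_that("evaluation reports aggregate folds into accuracy and flag bad cells", {
  cv <- data.frame(fold = rep(1:5, 2), env = "E1",
                   trait = rep(c("A", "B"), each = 5),
                   rp = c(rep(0.4, 5), rep(0.2, 5)), n = 10)
  class(cv) <- c("cv_result", "data.frame")
  h2 <- matrix(c(0.64, 0.25), 2, 1, dimnames = list(c("A", "B"), "E1"))
  rep_ <- evaluation_report(cv, h2, model_name = "M")
  expect_equal(rep_$accuracy[rep_$trait == "A"], 0.5)
  expect_equal(rep_$accuracy[rep_$trait == "B"], 0.4)

  h2b <- h2; h2b["B", "E1"] <- 0
  expect_warning(rep2 <- evaluation_report(cv, h2b),
                 "accuracy undefined")
  expect_true(is.na(rep2$accuracy[rep2$trait == "B"]))
})
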