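test_that("marker statistics and filters follow the documented arithmetic", {
  g <- rbind(c(0, 0, 0, 2), c(2, 2, NA, 2), c(2, 2, NA, 2),
             c(NA, 2, 1, 2), c(NA, 2, 1, 2))
  dimnames(g) <- list(paste0("l", 1:5), paste0("m", 1:4))
  st <- marker_stats(g)
  expect_equal(st$missing, c(0.4, 0, 0.4, 0))
  expect_equal(st$maf[2], 0.2)          # dosages (0,2,2,2,2): 2/10 alleles
  expect_equal(st$het[3], 2 / 3)

  # boundary convention: values at the threshold are retained
  gb <- cbind(m1 = c(0, rep(2, 9)),                    # MAF exactly 0.10
              m2 = c(0, 1, rep(2, 8)),                 # het exactly 0.10
              m3 = c(rep(NA, 5), rep(2, 4), 0))        # missing exactly 0.5
  rownames(gb) <- paste0("l", 1:10)
  f <- filter_markers(gb, min_maf = 0.10, max_het = 0.10,
                      max_marker_missing = 0.5, max_line_missing = 0.9)
  expect_equal(colnames(f$geno), c("m1", "m2", "m3"))
})

test_that("seeded low-MAF markers are exactly the ones removed", {
  set.seed(21)
  n <- 60
  freqs <- c(runif(80, 0.15, 0.5), runif(20, 0.001, 0.02))
  g <- sapply(freqs, function(q) 2L * (runif(n) < q))
  colnames(g) <- sprintf("m%03d", seq_along(freqs))
  rownames(g) <- sprintf("l%02d", 1:n)
  # independent recount of which markers sit below the MAF threshold
  truth_low <- vapply(seq_along(freqs), function(j) {
    cnt <- sum(g[, j]) / (2 * n)
    min(cnt, 1 - cnt) < 0.05
  }, logical(1))
  f <- filter_markers(g, min_maf = 0.05)
  expect_setequal(setdiff(colnames(g), colnames(f$geno)),
                  colnames(g)[truth_low])
  expect_equal(f$report$removed[["maf"]], sum(truth_low))
})

test_that("filtering is idempotent and errors when nothing survives", {
  set.seed(22)
  g <- matrix(2L * (runif(600) < 0.3), 30, 20,
              dimnames = list(paste0("l", 1:30), paste0("m", 1:20)))
  g[sample(length(g), 30)] <- NA
  f1 <- filter_markers(g)
  f2 <- filter_markers(f1$geno)
  expect_identical(f1$geno, f2$geno)
  expect_equal(sum(f2$report$removed[c("marker_missing", "maf", "het")]), 0)

  mono <- matrix(2L, 10, 3,
                 dimnames = list(paste0("l", 1:10), paste0("m", 1:3)))
  expect_error(filter_markers(mono), "all markers removed")
})

test_that("allelic Fisher test matches enumeration and flags edge cases", {
  r <- allelic_fisher_test(c(rep(0, 10), rep(2, 10)))
  expect_equal(r$p_value, fisher_p_enum(r$table))
  expect_true(r$keep)                    # perfectly allelic site

  r2 <- allelic_fisher_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r2$p_value, 1.0)
  expect_false(r2$keep)

  expect_true(is.na(allelic_fisher_test(rep(0, 20))$keep))
  expect_true(is.na(allelic_fisher_test(rep(2, 20))$keep))
})

test_that("mean imputation fills gaps and beats zero-imputation", {
  g <- cbind(m1 = c(0, 2, NA), m2 = c(1, 1, 1))
  rownames(g) <- paste0("l", 1:3)
  gi <- impute_missing(g)
  expect_equal(gi["l3", "m1"], 1.0)
  expect_equal(gi[, "m2"], g[, "m2"])

  complete <- matrix(2L * (runif(5000) < runif(100, 0.1, 0.5)[
    rep(1:100, each = 50)]), 50, 100, byrow = FALSE)
  set.seed(23)
  complete <- sapply(runif(100, 0.1, 0.5),
                     function(q) 2L * (runif(50) < q))
  dimnames(complete) <- list(paste0("l", 1:50), paste0("m", 1:100))
  masked <- complete
  idx <- sample(length(masked), 500)
  masked[idx] <- NA
  imp <- impute_missing(masked)
  rmse_mean <- sqrt(mean((imp[idx] - complete[idx])^2))
  rmse_zero <- sqrt(mean((0 - complete[idx])^2))
  expect_lt(rmse_mean, rmse_zero)

  expect_identical(impute_missing(complete), complete)
  allna <- cbind(m1 = c(NA, NA), m2 = c(0, 2))
  rownames(allna) <- c("a", "b")
  expect_error(impute_missing(allna), "m1")
})

test_that("genomic relationship matrix has its closed form and invariances", {
  g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(build_grm(g),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = "p")

  set.seed(24)
  G0 <- sapply(runif(200, 0.1, 0.5), function(q) 2L * (runif(40) < q))
  dimnames(G0) <- list(paste0("l", 1:40), paste0("m", 1:200))
  G0 <- G0[, apply(G0, 2, sd) > 0]
  K <- build_grm(G0)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  expect_gt(mean(diag(K)), 0.5)
  expect_lt(mean(diag(K)), 1.5)

  # column-permutation invariance
  Kp <- build_grm(G0[, sample(ncol(G0))])
  expect_equal(K, Kp, tolerance = 1e-12)

  # duplicated line pair carries the largest off-diagonal relationship
  Gd <- rbind(G0, dup = G0[1, ])
  Kd <- build_grm(Gd)
  off <- Kd; diag(off) <- -Inf
  expect_equal(sort(unname(which(off == max(off), arr.ind = TRUE)[1, ])),
               c(1, 41))

  gz <- cbind(m1 = c(0, 2), mzero = c(2, 2))
  rownames(gz) <- c("a", "b")
  expect_error(build_grm(gz), "mzero")
})
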