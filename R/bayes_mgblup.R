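#' MCMC settings for the Bayesian prediction models
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in iterations discarded before posterior summarization.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param verbose print progress every 1000 iterations.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 15000, burn_in = 10000, thin = 1,
                        seed = NULL, verbose = FALSE) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, verbose = isTRUE(verbose)),
            class = "mcmc_config")
}

# eigendecomposition of a PSD kernel, with coordinates below tolerance
# treated as null space (their effect coordinates are pinned at zero)
kernel_eigen <- function(G, tol = 1e-10) {
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  if (min(ev$values) < -1e-6 * max(d))
    stop("relationship matrix is not positive semidefinite")
  pos <- d > tol * max(d)
  list(U = ev$vectors, d = d, pos = pos)
}

# scaled-inverse-chi-square draw: df0/S0 prior, ss = sum of squares, k = dof
rscinvchi2 <- function(df0, S0, ss, k) {
  (df0 * S0 + ss) / stats::rchisq(1, df = df0 + k)
}

#' Multi-environment GBLUP by Gibbs sampling
#'
#' Fits, for a single trait, the Bayesian linear mixed model
#' \deqn{y_{ij} = E_i + G_j + GE_{ij} + \varepsilon_{ij}}
#' with environment effects (flat prior), genetic main effects
#' \eqn{g \sim N(0, \sigma^2_G G)} on the genomic relationship kernel, and
#' genotype-by-environment deviations with the reaction-norm kernel — the
#' Hadamard product of the genetic kernel and the environment-incidence
#' kernel — which makes the deviations independent copies of the genetic
#' kernel within each environment. Variance components carry scaled
#' inverse-chi-square priors (df 5, scale half the phenotypic variance).
#' Missing cells are handled by data augmentation, so any pattern of masked
#' line-by-environment cells can be predicted with one code path.
#'
#' @param y lines x environments matrix of adjusted means (rownames = line
#'   IDs present in `grm`); `NA` cells are predicted.
#' @param grm genomic relationship matrix from [build_grm()].
#' @param mcmc an [mcmc_config()].
#' @return list of class `mgblup_fit`: `yhat` (posterior-mean fitted values,
#'   lines x environments), `env_effects`, `g` (genetic main effects),
#'   `ge`, `varcomp` (posterior means of sigma2_G, sigma2_GE, sigma2_e),
#'   and the configuration.
#' @export
fit_mgblup <- function(y, grm, mcmc = mcmc_config()) {
  if (is.null(rownames(y))) stop("y must carry line IDs as rownames")
  if (!all(rownames(y) %in% rownames(grm)))
    stop("line IDs of y must be a subset of the GRM IDs")
  G <- grm[rownames(y), rownames(y)]
  J <- nrow(y); I <- ncol(y)
  use_ge <- I >= 2
  if (!use_ge && I == 1)
    message("single environment: G x E term dropped")
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  eg <- kernel_eigen(G)
  U <- eg$U; d <- eg$d; pos <- eg$pos
  Jp <- sum(pos)

  obs <- !is.na(y)
  if (!any(obs)) stop("no observed cells")
  vy <- stats::var(y[obs])
  df0 <- 5; S0 <- 0.5 * vy

  # state
  Y <- y
  for (i in seq_len(I)) {
    mu_i <- mean(y[obs[, i], i])
    if (!is.finite(mu_i)) mu_i <- mean(y[obs])
    Y[!obs[, i], i] <- mu_i
  }
  beta <- colMeans(Y)
  cg <- numeric(J)                      # coords of g in eigenbasis
  cge <- matrix(0, J, I)                # coords of ge per environment
  s2g <- s2ge <- s2e <- vy / 3

  keep <- seq(mcmc$burn_in + 1L, mcmc$iterations, by = mcmc$thin)
  n_keep <- length(keep)
  acc_fit <- matrix(0, J, I)
  acc_g <- numeric(J); acc_beta <- numeric(I)
  acc_var <- c(sigma2_G = 0, sigma2_GE = 0, sigma2_e = 0)

  for (it in seq_len(mcmc$iterations)) {
    g <- U %*% cg
    ge <- if (use_ge) U %*% cge else matrix(0, J, I)

    # environment effects (flat prior)
    R <- Y - as.vector(g) - ge
    beta <- colMeans(R) + stats::rnorm(I, sd = sqrt(s2e / J))

    # genetic main effects in eigen coordinates
    R <- sweep(Y - ge, 2, beta)
    st <- crossprod(U, rowSums(R))                 # U' (sum over envs)
    prec <- I / s2e + 1 / (s2g * d)
    cg <- ifelse(pos, st / s2e / prec + stats::rnorm(J) / sqrt(prec), 0)
    g <- U %*% cg

    # G x E deviations, one draw per environment
    if (use_ge) {
      R <- sweep(Y - as.vector(g), 2, beta)
      stge <- crossprod(U, R)                      # J x I
      prec <- 1 / s2e + 1 / (s2ge * d)
      z <- matrix(stats::rnorm(J * I), J, I)
      cge <- (stge / s2e + z * sqrt(prec)) / prec
      cge[!pos, ] <- 0
      ge <- U %*% cge
    }

    # variance components
    s2g <- rscinvchi2(df0, S0, sum(cg[pos]^2 / d[pos]), Jp)
    if (use_ge)
      s2ge <- rscinvchi2(df0, S0, sum(sweep(cge[pos, , drop = FALSE]^2,
                                            1, d[pos], "/")), Jp * I)
    fitted <- sweep(as.vector(g) + ge, 2, beta, "+")
    s2e <- rscinvchi2(df0, S0, sum((Y - fitted)[obs]^2), sum(obs))

    # data augmentation for masked cells
    if (any(!obs))
      Y[!obs] <- fitted[!obs] + stats::rnorm(sum(!obs), sd = sqrt(s2e))

    if (it > mcmc$burn_in && ((it - mcmc$burn_in - 1L) %% mcmc$thin == 0L)) {
      acc_fit <- acc_fit + fitted
      acc_g <- acc_g + as.vector(g)
      acc_beta <- acc_beta + beta
      acc_var <- acc_var + c(s2g, if (use_ge) s2ge else 0, s2e)
    }
    if (mcmc$verbose && it %% 1000 == 0)
      message("iteration ", it, "/", mcmc$iterations)
  }

  yhat <- acc_fit / n_keep
  dimnames(yhat) <- dimnames(y)
  structure(list(
    yhat = yhat,
    env_effects = stats::setNames(acc_beta / n_keep, colnames(y)),
    g = stats::setNames(acc_g / n_keep, rownames(y)),
    ge = yhat - outer(acc_g / n_keep, acc_beta / n_keep, "+"),
    varcomp = acc_var / n_keep,
    observed = obs, mcmc = mcmc
  ), class = "mgblup_fit")
}

#' @export
print.mgblup_fit <- function(x, ...) {
  cat("MGBLUP fit:", nrow(x$yhat), "lines x", ncol(x$yhat), "environments\n")
  cat(sprintf("  sigma2_G = %.4g, sigma2_GE = %.4g, sigma2_e = %.4g\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  invisible(x)
}
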