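#' Bayesian multi-output regressor stacking (BMORS)
#'
#' Two-stage prediction of a target trait from all traits. Stage 1 fits the
#' single-trait multi-environment GBLUP ([fit_mgblup()]) to every trait,
#' with the same cells masked as in the target, and collects its fitted
#' values for all line-by-environment cells. Each trait's predictions are
#' scaled — mean subtracted, divided by the standard deviation, both
#' estimated on the training cells only — and the target trait is regressed
#' on the L scaled predictions in a Bayesian ridge meta-model
#' \deqn{y_{ij} = \beta_0 + \beta_1 \hat Z_{1ij} + \dots +
#'   \beta_L \hat Z_{Lij} + e_{ij}.}
#'
#' @param Y lines x environments x traits array; `NA` cells of the target
#'   trait are predicted (masked cells are masked for every stage-1 trait
#'   model as well, so no validation information leaks into training).
#' @param grm genomic relationship matrix.
#' @param target_trait name or index of the trait predicted by the
#'   second stage.
#' @param mcmc an [mcmc_config()]; stage 2 reuses `iterations`/`burn_in`.
#' @param stage1 optional precomputed stage-1 result (list with `zhat`,
#'   the lines x envs x traits array of stage-1 fitted values), so several
#'   target traits can share one stage-1 pass.
#' @return list of class `bmors_fit`: `yhat` (lines x envs predictions for
#'   the target), `beta` (posterior means, intercept first), `beta_sd`,
#'   `scaling` (per-trait training means/sds), `dropped` (traits with
#'   degenerate stage-1 predictions), `stage1`.
#' @export
fit_bmors <- function(Y, grm, target_trait, mcmc = mcmc_config(),
                      stage1 = NULL) {
  stopifnot(length(dim(Y)) == 3)
  traits <- dimnames(Y)[[3]] %||% as.character(seq_len(dim(Y)[3]))
  dimnames(Y)[[3]] <- traits
  if (is.numeric(target_trait)) target_trait <- traits[target_trait]
  if (!target_trait %in% traits) stop("unknown target trait: ", target_trait)
  L <- length(traits)

  if (is.null(stage1)) stage1 <- bmors_stage1(Y, grm, mcmc)
  zhat <- stage1$zhat

  ytar <- Y[, , target_trait]
  train <- !is.na(ytar)

  # scale each trait's stage-1 predictions with training-cell statistics
  scaling <- matrix(NA_real_, L, 2, dimnames = list(traits, c("mu", "sd")))
  Z <- matrix(NA_real_, length(ytar), L)
  dropped <- character(0)
  for (l in seq_len(L)) {
    zl <- zhat[, , l]
    mu <- mean(zl[train]); sdl <- stats::sd(zl[train])
    scaling[l, ] <- c(mu, sdl)
    if (!is.finite(sdl) || sdl < 1e-10) {
      dropped <- c(dropped, traits[l])
      next
    }
    Z[, l] <- (as.vector(zl) - mu) / sdl
  }
  if (length(dropped))
    warning("dropped degenerate stage-1 prediction(s): ",
            paste(dropped, collapse = ", "))
  keep_tr <- setdiff(traits, dropped)
  Z <- Z[, match(keep_tr, traits), drop = FALSE]
  colnames(Z) <- keep_tr

  coefs <- bayes_ridge(cbind(1, Z[as.vector(train), , drop = FALSE]),
                       ytar[train], mcmc)
  pred <- as.vector(cbind(1, Z) %*% coefs$beta)
  yhat <- matrix(pred, nrow(ytar), ncol(ytar), dimnames = dimnames(ytar))

  structure(list(
    yhat = yhat, target = target_trait,
    beta = stats::setNames(coefs$beta, c("(Intercept)", keep_tr)),
    beta_sd = stats::setNames(coefs$beta_sd, c("(Intercept)", keep_tr)),
    scaling = scaling, dropped = dropped, stage1 = stage1
  ), class = "bmors_fit")
}

# stage 1: per-trait MGBLUP fitted values for every cell
bmors_stage1 <- function(Y, grm, mcmc) {
  traits <- dimnames(Y)[[3]]
  zhat <- array(NA_real_, dim = dim(Y), dimnames = dimnames(Y))
  varcomp <- list()
  for (l in seq_along(traits)) {
    m <- if (is.null(mcmc$seed)) mcmc else
      mcmc_config(mcmc$iterations, mcmc$burn_in, mcmc$thin,
                  seed = mcmc$seed + l, verbose = mcmc$verbose)
    f <- fit_mgblup(Y[, , l], grm, m)
    zhat[, , l] <- f$yhat
    varcomp[[traits[l]]] <- f$varcomp
  }
  list(zhat = zhat, varcomp = varcomp)
}

# Gibbs sampler for a small Bayesian ridge regression: flat intercept,
# N(0, sigma2_b) slopes, scaled-inv-chi-square variances
bayes_ridge <- function(X, y, mcmc) {
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  p <- ncol(X); n <- nrow(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  df0 <- 5; S0 <- 0.5 * stats::var(y)
  s2e <- S0; s2b <- 1
  beta <- rep(0, p)
  iters <- max(mcmc$iterations, 2000)
  burn <- max(mcmc$burn_in, 1000)
  if (burn >= iters) burn <- iters %/% 2
  acc <- acc2 <- rep(0, p); nk <- 0
  prior_prec <- c(1e-8, rep(1, p - 1))              # flat intercept
  for (it in seq_len(iters)) {
    P <- XtX / s2e + diag(prior_prec / s2b, p)
    ch <- chol(P)
    mu <- backsolve(ch, backsolve(ch, Xty / s2e, transpose = TRUE))
    beta <- mu + backsolve(ch, stats::rnorm(p))
    r <- y - X %*% beta
    s2e <- rscinvchi2(df0, S0, sum(r^2), n)
    s2b <- rscinvchi2(df0, 0.5, sum(beta[-1]^2), p - 1)
    if (it > burn) { acc <- acc + beta; acc2 <- acc2 + beta^2; nk <- nk + 1 }
  }
  list(beta = acc / nk, beta_sd = sqrt(pmax(acc2 / nk - (acc / nk)^2, 0)))
}

#' Leave-one-environment-out prediction with BMORS
#'
#' For each environment in turn, all its cells (every trait) are masked,
#' the stacking model is trained on the remaining environments, and
#' predictions for the held-out environment are collected for every trait.
#'
#' @param Y lines x environments x traits array (complete).
#' @param grm genomic relationship matrix.
#' @param mcmc an [mcmc_config()].
#' @return list with `pred` (array like `Y` holding out-of-environment
#'   predictions) and `cors` (environment x trait predictive correlations).
#' @export
leave_one_env_out_bmors <- function(Y, grm, mcmc = mcmc_config()) {
  stopifnot(length(dim(Y)) == 3)
  I <- dim(Y)[2]
  if (I < 2) stop("need at least 2 environments")
  traits <- dimnames(Y)[[3]]
  envs <- dimnames(Y)[[2]] %||% as.character(seq_len(I))
  pred <- array(NA_real_, dim = dim(Y), dimnames = dimnames(Y))
  cors <- matrix(NA_real_, I, dim(Y)[3], dimnames = list(envs, traits))
  for (i in seq_len(I)) {
    Ymask <- Y
    Ymask[, i, ] <- NA
    s1 <- bmors_stage1(Ymask, grm, mcmc)
    for (l in seq_along(traits)) {
      f <- fit_bmors(Ymask, grm, traits[l], mcmc, stage1 = s1)
      pred[, i, l] <- f$yhat[, i]
      cors[i, l] <- stats::cor(pred[, i, l], Y[, i, l],
                               use = "complete.obs")
    }
  }
  list(pred = pred, cors = cors)
}
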