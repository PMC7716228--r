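#' Bayesian multi-trait multi-environment model (Gibbs sampler)
#'
#' Fits the matrix-variate mixed model
#' \deqn{Y = X\beta + Z_1 b_1 + Z_2 b_2 + E}
#' where `Y` stacks the line-by-environment cells of L traits, `X` carries
#' environment intercepts per trait (flat prior), genotype-by-trait effects
#' `b1 ~ MN(0, G, Sigma_t)` ride on the genomic relationship matrix with an
#' unstructured trait covariance, genotype-by-environment-by-trait effects
#' `b2 ~ MN(0, Sigma_E \%x\% G, Sigma_t)` add environment-specific
#' deviations with an unstructured environment covariance, and residual rows
#' are iid `N(0, Re)`. `Sigma_t`, `Sigma_E` and `Re` carry inverse-Wishart
#' priors (df = dim + 2, identity scale). All full conditionals are
#' conjugate; the eigendecomposition of `G` is computed once and the
#' per-row normal updates are vectorized through a simultaneous
#' diagonalization of the trait precision matrices. Masked cells are handled
#' by data augmentation (sampled each sweep from their conditional normal
#' given any observed traits in the same row), so cross-validation and
#' leave-one-environment-out prediction share one code path.
#'
#' @param Y either a 3-d array (lines x environments x traits, `NA` cells
#'   predicted) or a `blue_table` from [fit_blues()].
#' @param grm genomic relationship matrix covering the lines of `Y`.
#' @param mcmc an [mcmc_config()].
#' @return list of class `bmtme_fit` with posterior means `yhat` (array,
#'   lines x envs x traits), `beta` (envs x traits), `b1` (lines x traits),
#'   `Sigma_t`, `Sigma_E`, `Re`, posterior sds of the covariance entries,
#'   the derived genetic correlation matrices, and `n_jitter` (count of
#'   jitter retries on non-positive-definite draws).
#' @export
fit_bmtme <- function(Y, grm, mcmc = mcmc_config()) {
  if (inherits(Y, "blue_table")) Y <- blue_array(Y)
  stopifnot(length(dim(Y)) == 3)
  lines <- dimnames(Y)[[1]]
  if (is.null(lines) || !all(lines %in% rownames(grm)))
    stop("Y line IDs must be present in the GRM")
  J <- dim(Y)[1]; I <- dim(Y)[2]; L <- dim(Y)[3]
  G <- grm[lines, lines]
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  eg <- kernel_eigen(G)
  U <- eg$U
  d <- pmax(eg$d, 1e-8 * max(eg$d))      # bent spectrum for whitening
  nu_t <- L + 2; nu_e <- I + 2; nu_r <- L + 2
  n <- J * I

  # flatten to n x L, env-major rows (env outer, line inner)
  Ym <- matrix(aperm(Y, c(1, 2, 3)), n, L)
  ienv <- rep(seq_len(I), each = J)
  obs <- !is.na(Ym)
  cell_mu <- matrix(0, I, L)
  for (i in seq_len(I)) for (l in seq_len(L)) {
    o <- obs[ienv == i, l]
    v <- Ym[ienv == i, l][o]
    cell_mu[i, l] <- if (length(v)) mean(v) else mean(Ym[, l], na.rm = TRUE)
  }
  for (l in seq_len(L)) {
    nas <- which(!obs[, l])
    Ym[nas, l] <- cell_mu[ienv[nas], l]
  }

  # missingness patterns, grouped once
  mispat <- apply(!obs, 1, function(v) paste(which(v), collapse = ","))
  pat_groups <- lapply(unique(mispat[mispat != ""]), function(pat) {
    mis <- as.integer(strsplit(pat, ",")[[1]])
    list(rows = which(mispat == pat), mis = mis,
         ob = setdiff(seq_len(L), mis))
  })

  beta <- cell_mu
  b1 <- matrix(0, J, L)
  b2 <- matrix(0, n, L)
  St <- diag(apply(Ym, 2, stats::var) / 3, L)
  Se <- diag(I)
  Re <- diag(apply(Ym, 2, stats::var) / 3, L)
  n_jitter <- 0L

  keep <- seq(mcmc$burn_in + 1L, mcmc$iterations, by = mcmc$thin)
  n_keep <- length(keep)
  acc <- list(fit = matrix(0, n, L), beta = matrix(0, I, L),
              b1 = matrix(0, J, L), St = matrix(0, L, L),
              Se = matrix(0, I, I), Re = matrix(0, L, L),
              St2 = matrix(0, L, L), Se2 = matrix(0, I, I))

  # simultaneous diagonalization of A = St^-1 (prior) and B = Re^-1
  # (likelihood): returns W with B = W W', A = W Lam W', plus W^-T
  whiten_pair <- function(St, Re) {
    A <- chol2inv(chol_jitter(St)); B <- chol2inv(chol_jitter(Re))
    Lb <- chol(B)                                  # B = Lb' Lb
    Sm <- backsolve(Lb, t(backsolve(Lb, A, transpose = TRUE)),
                    transpose = TRUE)
    Sm <- (Sm + t(Sm)) / 2
    evs <- eigen(Sm, symmetric = TRUE)
    W <- t(Lb) %*% evs$vectors
    list(W = W, Winv = t(evs$vectors) %*% solve(t(Lb)),
         lam = pmax(evs$values, 0))
  }
  chol_jitter <- function(m) {
    for (k in 0:6) {
      r <- tryCatch(chol(m + diag(10^(k - 10) * (k > 0), nrow(m))),
                    error = function(e) NULL)
      if (!is.null(r)) {
        if (k > 0) n_jitter <<- n_jitter + 1L
        return(r)
      }
    }
    stop("covariance draw not positive definite after jitter retries")
  }
  # sample rows: row r ~ N(P_r^-1 Re^-1 resid_r, P_r^-1),
  # P_r = St^-1 * a_r + Re^-1 * m_r  (a_r prior scale, m_r replication)
  draw_rows <- function(resid_sum, a, m, wp) {
    V <- resid_sum %*% wp$W                        # rows W' s_r
    den <- outer(a, wp$lam) + m                    # nrow x L
    Cw <- V / den + matrix(stats::rnorm(length(V)), nrow(V)) / sqrt(den)
    Cw %*% wp$Winv                                 # rows c_r
  }

  for (it in seq_len(mcmc$iterations)) {
    fit_re <- b1[rep(seq_len(J), I), , drop = FALSE] + b2

    # beta: env x trait intercepts, flat prior
    Rr <- Ym - fit_re
    Lre <- chol_jitter(Re)
    for (i in seq_len(I)) {
      beta[i, ] <- colMeans(Rr[ienv == i, , drop = FALSE]) +
        drop(crossprod(Lre, stats::rnorm(L))) / sqrt(J)
    }
    Xb <- beta[ienv, , drop = FALSE]

    # b1 | . : transformed rows have prior N(0, d_j St), I replicates
    R1 <- Ym - Xb - b2
    S1 <- crossprod(U, rowsum(R1, rep(seq_len(J), I)))   # U' (sum over envs)
    wp <- whiten_pair(St, Re)
    C1 <- draw_rows(S1, 1 / d, I, wp)
    b1 <- U %*% C1

    # b2 | . : rows transformed by (Ve ox U)', prior scale s_i d_j
    R2 <- Ym - Xb - b1[rep(seq_len(J), I), , drop = FALSE]
    ee <- eigen(Se, symmetric = TRUE)
    se_d <- pmax(ee$values, 1e-8)
    T2 <- tensor_rows(R2, J, I, t(U), t(ee$vectors))
    a2 <- 1 / (se_d[rep(seq_len(I), each = J)] * d[rep(seq_len(J), I)])
    C2 <- draw_rows(T2, a2, 1, wp)
    b2 <- tensor_rows(C2, J, I, U, ee$vectors)
    # line-whitened, env-untransformed coords for the Sigma updates
    C2g <- tensor_rows(C2, J, I, diag(1, J), ee$vectors)

    # Sigma_t | b1, b2: inverse-Wishart
    S_b1 <- crossprod(C1 / sqrt(d))
    Se_i <- chol2inv(chol_jitter(Se))
    W2 <- tensor_rows(C2, J, I, diag(1 / sqrt(d), J),
                      ee$vectors %*% diag(1 / sqrt(se_d), I))
    S_b2 <- crossprod(W2)
    St <- rinvwishart(nu_t + J + n, diag(L) + S_b1 + S_b2)

    # Sigma_E | b2: whiten lines (G) and traits (St)
    St_half_inv <- backsolve(chol_jitter(St), diag(L))
    W3 <- (C2g / sqrt(d[rep(seq_len(J), I)])) %*% St_half_inv
    SE_scatter <- matrix(0, I, I)
    W3a <- array(W3, dim = c(J, I, L))
    for (l in seq_len(L))
      SE_scatter <- SE_scatter + crossprod(W3a[, , l])
    Se <- rinvwishart(nu_e + J * L, diag(I) + SE_scatter)

    # Re | residuals
    fitted <- Xb + b1[rep(seq_len(J), I), , drop = FALSE] + b2
    Er <- Ym - fitted
    Re <- rinvwishart(nu_r + n, diag(L) + crossprod(Er))

    # data augmentation: redraw masked cells row by missingness pattern
    if (length(pat_groups)) Ym <- impute_rows(Ym, fitted, pat_groups, Re)

    if (it > mcmc$burn_in && ((it - mcmc$burn_in - 1L) %% mcmc$thin == 0L)) {
      acc$fit <- acc$fit + fitted
      acc$beta <- acc$beta + beta
      acc$b1 <- acc$b1 + b1
      acc$St <- acc$St + St;  acc$St2 <- acc$St2 + St^2
      acc$Se <- acc$Se + Se;  acc$Se2 <- acc$Se2 + Se^2
      acc$Re <- acc$Re + Re
    }
    if (mcmc$verbose && it %% 1000 == 0)
      message("iteration ", it, "/", mcmc$iterations)
  }

  yhat <- array(acc$fit / n_keep, dim = c(J, I, L), dimnames = dimnames(Y))
  St_m <- acc$St / n_keep; Se_m <- acc$Se / n_keep
  dimnames(St_m) <- list(dimnames(Y)[[3]], dimnames(Y)[[3]])
  dimnames(Se_m) <- list(dimnames(Y)[[2]], dimnames(Y)[[2]])
  Re_m <- acc$Re / n_keep
  dimnames(Re_m) <- dimnames(St_m)
  fit <- structure(list(
    yhat = yhat,
    beta = acc$beta / n_keep,
    b1 = `dimnames<-`(acc$b1 / n_keep, list(lines, dimnames(Y)[[3]])),
    Sigma_t = St_m, Sigma_E = Se_m, Re = Re_m,
    Sigma_t_sd = sqrt(pmax(acc$St2 / n_keep - St_m^2, 0)),
    Sigma_E_sd = sqrt(pmax(acc$Se2 / n_keep - Se_m^2, 0)),
    observed = array(obs, dim = dim(Y)),
    n_jitter = n_jitter, mcmc = mcmc
  ), class = "bmtme_fit")
  fit$genetic_correlations <- genetic_correlations(fit)
  fit
}

# apply row transforms across the line dimension (A, J x J) and the
# environment dimension (B, I x I) of an (J*I) x L env-major matrix
tensor_rows <- function(M, J, I, A, B) {
  L <- ncol(M)
  arr <- array(M, dim = c(J, I, L))
  m1 <- A %*% matrix(arr, J, I * L)                # contract line dim
  arr <- array(m1, dim = c(J, I, L))
  arr <- aperm(arr, c(2, 1, 3))
  m2 <- B %*% matrix(arr, I, J * L)                # contract env dim
  arr <- aperm(array(m2, dim = c(I, J, L)), c(2, 1, 3))
  matrix(arr, J * I, L)
}

rinvwishart <- function(df, S) {
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

# conditional-normal redraw of missing entries given observed traits in the
# same row, grouped by missingness pattern
impute_rows <- function(Ym, fitted, pat_groups, Re) {
  for (pg in pat_groups) {
    rows <- pg$rows
    mis <- pg$mis
    ob <- pg$ob
    if (length(ob) == 0) {
      Ym[rows, ] <- fitted[rows, , drop = FALSE] +
        matrix(stats::rnorm(length(rows) * ncol(Ym)), length(rows)) %*%
        chol(Re)
    } else {
      Roo <- Re[ob, ob, drop = FALSE]
      Rmo <- Re[mis, ob, drop = FALSE]
      K <- Rmo %*% chol2inv(chol(Roo))
      cond_cov <- Re[mis, mis, drop = FALSE] - K %*% t(Rmo)
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      dev <- Ym[rows, ob, drop = FALSE] - fitted[rows, ob, drop = FALSE]
      mu <- fitted[rows, mis, drop = FALSE] + dev %*% t(K)
      Ym[rows, mis] <- mu +
        matrix(stats::rnorm(length(rows) * length(mis)), length(rows)) %*%
        chol(cond_cov + diag(1e-10, length(mis)))
    }
  }
  Ym
}

#' Reshape a blue_table into the 3-d response array used by [fit_bmtme()]
#'
#' @param blues a `blue_table` from [fit_blues()].
#' @return array lines x environments x traits.
#' @export
blue_array <- function(blues) {
  lines <- sort(unique(blues$line))
  envs <- unique(blues$env)
  traits <- unique(blues$trait)
  arr <- array(NA_real_, dim = c(length(lines), length(envs), length(traits)),
               dimnames = list(lines, envs, traits))
  arr[cbind(match(blues$line, lines), match(blues$env, envs),
            match(blues$trait, traits))] <- blues$blue
  arr
}

#' Genetic correlation matrices from a BMTME fit
#'
#' Trait correlations are the posterior-mean trait genetic covariance
#' converted to a correlation matrix,
#' \eqn{r_G(a,b) = \sigma_G(a,b) / \sqrt{\sigma^2_G(a)\,\sigma^2_G(b)}}.
#' Environment correlations are those of the total genetic values
#' `b1 + b2`, whose covariance between environments i and f is proportional
#' to `1 + Sigma_E[i, f]`.
#'
#' @param fit a `bmtme_fit`.
#' @return list with `trait` (L x L) and `env` (I x I) correlation matrices.
#' @export
genetic_correlations <- function(fit) {
  St <- fit$Sigma_t
  if (any(diag(St) <= 0)) {
    warning("trait(s) with zero genetic variance; correlations undefined")
    bad <- diag(St) <= 0
    St[bad, ] <- St[, bad] <- NA_real_
    diag(St)[bad] <- 1
  }
  tc <- stats::cov2cor(St)
  Se_tot <- 1 + fit$Sigma_E
  ec <- Se_tot / sqrt(diag(Se_tot) %o% diag(Se_tot))
  dimnames(ec) <- dimnames(fit$Sigma_E)
  list(trait = tc, env = ec)
}

#' @export
print.bmtme_fit <- function(x, ...) {
  d <- dim(x$yhat)
  cat("BMTME fit:", d[1], "lines x", d[2], "environments x", d[3],
      "traits\n")
  cat("posterior-mean trait genetic correlations:\n")
  print(round(x$genetic_correlations$trait, 2))
  if (x$n_jitter > 0) cat("jitter retries:", x$n_jitter, "\n")
  invisible(x)
}
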