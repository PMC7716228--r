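#' Simulation configuration for a structured multi-trait wheat panel
#'
#' Builds the parameter set for the synthetic genotype/phenotype generator.
#' Defaults emulate a facultative soft-wheat diversity panel of 237 inbred
#' lines in 10 subpopulations genotyped at 27,957 GBS SNPs and phenotyped
#' for four yield-component traits (GY, HI, SF, TGW) in four environments
#' under an augmented block design with three repeated checks.
#'
#' The generating model is the one the downstream prediction models assume:
#' line genetic values arise from Gaussian (infinitesimal) marker effects
#' with an unstructured trait covariance `trait_genetic_cov`, plus
#' genotype-by-environment deviations whose covariance is
#' `env_genetic_cov %x% trait_genetic_cov` and whose share of the total
#' genetic variance is `ge_variance`. Residual variance for each
#' trait-by-environment cell is solved from the realized genetic variance so
#' that broad-sense heritability matches `target_h2` in expectation.
#'
#' @param n_lines number of unreplicated entries in the panel.
#' @param n_checks number of repeated check lines (replicated in every block).
#' @param n_markers number of biallelic SNPs.
#' @param n_subpops number of subpopulations (Balding-Nichols divergence).
#' @param n_traits,n_envs numbers of traits (L) and environments (I).
#' @param n_blocks incomplete blocks per environment.
#' @param trait_genetic_cov L x L genetic covariance (correlation scale) of
#'   trait main effects.
#' @param env_genetic_cov I x I correlation matrix of the G x E deviations.
#' @param residual_cov L x L residual correlation matrix.
#' @param ge_variance fraction of genetic variance assigned to the G x E term.
#' @param target_h2 L x I matrix of target broad-sense heritabilities.
#' @param trait_sd per-trait phenotypic standard deviation (trait units).
#' @param trait_means L x I matrix of environment means per trait.
#' @param block_var_share fraction of phenotypic variance due to blocks.
#' @param maf_range interval in (0, 0.5] for ancestral allele frequencies.
#' @param het_rate expected heterozygote frequency (inbred panels: small).
#' @param missing_rate expected per-marker missing-call rate.
#' @param fst Balding-Nichols divergence of subpopulation allele frequencies.
#' @param dth_effect per-trait regression slope on the days-to-heading
#'   covariate (trait units per day).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 237, n_checks = 3, n_markers = 27957,
                       n_subpops = 10, n_traits = 4, n_envs = 4,
                       n_blocks = 12,
                       trait_genetic_cov = NULL, env_genetic_cov = NULL,
                       residual_cov = NULL, ge_variance = 0.8,
                       target_h2 = NULL, trait_sd = NULL, trait_means = NULL,
                       block_var_share = 0.1,
                       maf_range = c(0.05, 0.5), het_rate = 0.02,
                       missing_rate = 0.10, fst = 0.10,
                       dth_effect = NULL, seed = NULL) {
  L <- n_traits
  I <- n_envs
  if (any(c(n_lines, n_markers, n_subpops, L, I, n_blocks) <= 0))
    stop("all dimensions must be positive")
  if (n_subpops > n_lines) stop("n_subpops must not exceed n_lines")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")

  traits <- if (L == 4) c("GY", "HI", "SF", "TGW") else paste0("T", seq_len(L))
  envs <- paste0("env", seq_len(I))

  if (is.null(trait_genetic_cov)) {
    trait_genetic_cov <- if (L == 4) {
      m <- diag(4)
      m[upper.tri(m)] <- c(0.67, 0.17, 0.17, 0.18, 0.10, -0.32)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    } else {
      m <- matrix(0.3, L, L); diag(m) <- 1; m
    }
  }
  if (is.null(env_genetic_cov)) {
    env_genetic_cov <- if (I == 4) {
      # chosen so total env-margin genetic correlations land near 0.16-0.26
      # given ge_variance = 0.8 (see methods vignette)
      m <- diag(4)
      m[upper.tri(m)] <- c(0.05, -0.01, 0.07, -0.04, -0.01, -0.05)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    } else {
      m <- matrix(0.02, I, I); diag(m) <- 1; m
    }
  }
  if (is.null(residual_cov)) {
    residual_cov <- if (L == 4) {
      m <- diag(4)
      m[upper.tri(m)] <- c(0.40, 0.20, 0.15, 0.15, 0.10, -0.10)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    } else diag(L)
  }
  if (is.null(target_h2)) {
    target_h2 <- if (L == 4 && I == 4) {
      matrix(c(0.71, 0.80, 0.36, 0.24,
               0.78, 0.74, 0.43, 0.26,
               0.38, 0.68, 0.22, 0.32,
               0.48, 0.87, 0.58, 0.44), nrow = 4, byrow = TRUE)
    } else matrix(0.5, L, I)
  }
  if (is.null(trait_sd)) {
    trait_sd <- if (L == 4) c(0.7, 3.5, 17, 3.2) else rep(1, L)
  }
  if (is.null(trait_means)) {
    trait_means <- if (L == 4 && I == 4) {
      matrix(c(2.0, 3.8, 3.3, 5.3,
               30.5, 37.4, 34.3, 42.7,
               63.9, 98.3, 83.2, 94.6,
               34.7, 34.1, 39.4, 40.9), nrow = 4, byrow = TRUE)
    } else matrix(0, L, I)
  }
  if (is.null(dth_effect)) {
    dth_effect <- if (L == 4) c(-0.02, -0.10, 0.30, 0.05) else rep(0, L)
  }

  check_cov <- function(m, d, name) {
    m <- as.matrix(m)
    if (!isTRUE(all.equal(dim(m), c(d, d))))
      stop(name, " must be ", d, " x ", d)
    if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(name, " must be positive semidefinite")
    m
  }
  trait_genetic_cov <- check_cov(trait_genetic_cov, L, "trait_genetic_cov")
  env_genetic_cov <- check_cov(env_genetic_cov, I, "env_genetic_cov")
  residual_cov <- check_cov(residual_cov, L, "residual_cov")
  target_h2 <- as.matrix(target_h2)
  if (!isTRUE(all.equal(dim(target_h2), c(L, I))))
    stop("target_h2 must be n_traits x n_envs")
  if (any(target_h2 < 0 | target_h2 > 1)) stop("target_h2 entries in [0,1]")
  if (ge_variance < 0 || ge_variance > 1) stop("ge_variance in [0,1]")
  if (het_rate < 0 || het_rate > 1 || missing_rate < 0 || missing_rate >= 1)
    stop("het_rate/missing_rate must be valid fractions")

  dimnames(target_h2) <- dimnames(trait_means) <- list(traits, envs)
  names(trait_sd) <- names(dth_effect) <- traits

  structure(list(
    n_lines = n_lines, n_checks = n_checks, n_markers = n_markers,
    n_subpops = n_subpops, n_traits = L, n_envs = I, n_blocks = n_blocks,
    traits = traits, envs = envs,
    trait_genetic_cov = trait_genetic_cov, env_genetic_cov = env_genetic_cov,
    residual_cov = residual_cov, ge_variance = ge_variance,
    target_h2 = target_h2, trait_sd = trait_sd, trait_means = trait_means,
    block_var_share = block_var_share,
    maf_range = maf_range, het_rate = het_rate, missing_rate = missing_rate,
    fst = fst, dth_effect = dth_effect, seed = seed
  ), class = "sim_config")
}

#' Simulate a structured biallelic SNP panel
#'
#' Draws genotypes for an inbred panel with subpopulation structure under the
#' Balding-Nichols model: an ancestral minor-allele frequency is drawn
#' uniformly from `maf_range` per marker, and each subpopulation's frequency
#' from a Beta distribution with divergence `fst`. Lines are homozygous with
#' probability `1 - het_rate` and calls are masked at `missing_rate`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `sim_markers` with elements `geno` (lines x
#'   markers dosage matrix in \{0,1,2\} with `NA` for missing calls),
#'   `complete` (the same matrix before masking), `subpop` (factor of true
#'   subpopulation labels), and `config`.
#' @export
simulate_marker_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_lines + config$n_checks
  p <- config$n_markers
  K <- config$n_subpops
  fst <- max(config$fst, 1e-6)

  line_ids <- c(sprintf("L%03d", seq_len(config$n_lines)),
                if (config$n_checks > 0)
                  sprintf("CHK%d", seq_len(config$n_checks)))
  marker_ids <- sprintf("S%05d", seq_len(p))
  subpop <- factor(paste0("Q", 1 + (seq_len(n) - 1L) %% K),
                   levels = paste0("Q", seq_len(K)))

  anc <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  shape <- (1 - fst) / fst
  # subpop-specific frequencies, K x p
  freq <- matrix(stats::rbeta(K * p, rep(anc, each = K) * shape,
                              rep(1 - anc, each = K) * shape), nrow = K)

  f <- freq[as.integer(subpop), , drop = FALSE]            # n x p
  hom <- matrix(stats::runif(n * p) < f, n, p) * 2L        # inbred call 0/2
  geno <- hom
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * p) < config$het_rate, n, p)
    geno[het] <- 1L
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(line_ids, marker_ids)
  complete <- geno
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    geno[miss] <- NA_integer_
  }
  structure(list(geno = geno, complete = complete, subpop = subpop,
                 config = config),
            class = "sim_markers")
}

#' Simulate multi-trait multi-environment phenotypes with known truth
#'
#' Generates phenotype records under the variance structure the prediction
#' models assume: genetic main effects from Gaussian marker effects with
#' trait covariance `trait_genetic_cov`, G x E deviations with covariance
#' `env_genetic_cov %x% trait_genetic_cov` carrying a `ge_variance` share of
#' the genetic variance, random block effects, a days-to-heading covariate
#' with per-trait slopes, and residuals with correlation `residual_cov`
#' scaled per trait-by-environment cell so realized broad-sense heritability
#' matches `target_h2`. The field layout is an augmented design: every check
#' appears once in each block, entries appear in one block per environment.
#'
#' @param markers a `sim_markers` object (its `complete` matrix is used) or a
#'   complete dosage matrix with line IDs as rownames.
#' @param config the [sim_config()] used for the markers.
#' @return A list of class `sim_phenotypes` with `pheno` (long data frame:
#'   env, line, block, is_check, DTH, one column per trait) and `truth`
#'   (genetic value array lines x envs x traits, marker effects, subpopulation
#'   labels, realized per-cell heritability, DTH values).
#' @export
simulate_phenotypes <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- if (inherits(markers, "sim_markers")) markers$complete else markers
  if (anyNA(geno)) stop("markers must be complete (impute first)")
  n <- nrow(geno)
  if (n != config$n_lines + config$n_checks)
    stop("marker matrix rows do not match config dimensions")
  L <- config$n_traits
  I <- config$n_envs
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  # standardized marker matrix; monomorphic columns carry no signal
  p <- ncol(geno)
  cm <- colMeans(geno)
  csd <- apply(geno, 2, stats::sd)
  csd[csd == 0] <- 1
  X <- sweep(sweep(geno, 2, cm), 2, csd, "/")

  # genetic main effects: g_main = X B Lt', rows of B iid N(0, 1/p)
  Lt <- chol_psd(config$trait_genetic_cov)
  B0 <- matrix(stats::rnorm(p * L, sd = sqrt(1 / p)), p, L)
  g_main <- X %*% B0 %*% t(Lt)                            # n x L, cov ~ Sigma_t

  # G x E deviations: columns (env, trait) with covariance Sigma_E ox Sigma_t
  Le <- chol_psd(config$env_genetic_cov)
  B1 <- matrix(stats::rnorm(p * I * L, sd = sqrt(1 / p)), p, I * L)
  g_dev <- X %*% B1 %*% t(Le %x% Lt)                      # n x (I*L)

  s <- config$ge_variance
  gv <- array(NA_real_, dim = c(n, I, L),
              dimnames = list(rownames(geno), config$envs, config$traits))
  for (i in seq_len(I)) {
    cols <- (i - 1L) * L + seq_len(L)
    gv[, i, ] <- sqrt(1 - s) * g_main + sqrt(s) * g_dev[, cols, drop = FALSE]
  }

  # scale genetic values so each cell's genetic variance is h2 * trait_sd^2
  realized_h2 <- matrix(NA_real_, L, I,
                        dimnames = list(config$traits, config$envs))
  sigma_e <- matrix(NA_real_, L, I)
  for (i in seq_len(I)) for (l in seq_len(L)) {
    h2 <- config$target_h2[l, i]
    sdt <- config$trait_sd[l]
    emp <- stats::sd(gv[, i, l])
    if (emp > 0) gv[, i, l] <- gv[, i, l] * sqrt(h2) * sdt / emp
    sigma_e[l, i] <- sqrt(max(1 - h2, 0)) * sdt
  }

  # field book: checks in every block, entries once per environment
  n_entries <- config$n_lines
  n_checks <- config$n_checks
  entry_ids <- rownames(geno)[seq_len(n_entries)]
  check_ids <- if (n_checks > 0) rownames(geno)[n_entries + seq_len(n_checks)]
  dth <- stats::rnorm(n, mean = 100, sd = 5)
  names(dth) <- rownames(geno)

  Re_chol <- chol_psd(config$residual_cov)
  rows <- vector("list", I)
  for (i in seq_len(I)) {
    blk_entry <- rep(seq_len(config$n_blocks), length.out = n_entries)
    blk_entry <- sample(blk_entry)                 # random layout per env
    fb <- data.frame(
      line = c(entry_ids,
               if (n_checks > 0) rep(check_ids, each = config$n_blocks)),
      block = c(blk_entry,
                if (n_checks > 0) rep(seq_len(config$n_blocks), n_checks)),
      is_check = rep(c(FALSE, TRUE), c(n_entries, n_checks * config$n_blocks)),
      stringsAsFactors = FALSE
    )
    m <- nrow(fb)
    blk_eff <- matrix(stats::rnorm(config$n_blocks * L), config$n_blocks, L)
    resid <- matrix(stats::rnorm(m * L), m, L) %*% t(Re_chol)
    y <- matrix(NA_real_, m, L)
    idx <- match(fb$line, rownames(geno))
    # heading date is recorded per plot: line mean plus environmental scatter
    dth_plot <- dth[idx] + stats::rnorm(m, sd = 2)
    for (l in seq_len(L)) {
      sd_b <- sqrt(config$block_var_share) * config$trait_sd[l]
      y[, l] <- config$trait_means[l, i] +
        gv[idx, i, l] +
        sd_b * blk_eff[fb$block, l] +
        config$dth_effect[l] * (dth_plot - 100) +
        sigma_e[l, i] * resid[, l]
    }
    colnames(y) <- config$traits
    rows[[i]] <- cbind(data.frame(env = config$envs[i],
                                  line = fb$line,
                                  block = paste0("B", fb$block),
                                  is_check = fb$is_check,
                                  DTH = round(dth_plot, 1),
                                  stringsAsFactors = FALSE),
                       as.data.frame(y))
    for (l in seq_len(L)) {
      vg <- stats::var(gv[, i, l])
      realized_h2[l, i] <- vg / (vg + sigma_e[l, i]^2)
    }
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL

  truth <- list(genetic_values = gv,
                marker_effects = list(main = B0, ge = B1),
                subpop = if (inherits(markers, "sim_markers")) markers$subpop,
                realized_h2 = realized_h2,
                dth = dth,
                config = config)
  structure(list(pheno = pheno, truth = truth), class = "sim_phenotypes")
}

# Cholesky factor that tolerates PSD (singular) covariance matrices.
chol_psd <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(m)) %*% t(ev$vectors)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:",
      x$n_lines, "entries +", x$n_checks, "checks,",
      x$n_markers, "markers,", x$n_subpops, "subpopulations\n")
  cat(" ", x$n_traits, "traits x", x$n_envs, "environments,",
      x$n_blocks, "blocks/env, Fst =", x$fst, "\n")
  invisible(x)
}
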