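#' Adjusted genotype means (BLUEs) from the multi-environment mixed model
#'
#' Fits, per trait, a linear mixed model with genotype as a fixed effect and
#' environment, block-within-environment and genotype-by-environment as
#' independent random effects:
#' \deqn{y_{ijk} = \mu + G_j + E_i + B_{i(k)} + GE_{ji} + e_{ijk}.}
#' Optionally the days-to-heading covariate is included as an additional
#' fixed effect to adjust for phenology. Per-environment adjusted means are
#' assembled from the genotype fixed-effect solutions plus the environment
#' and genotype-by-environment BLUPs (`scope = "per_env"`); with
#' `scope = "overall"` only the genotype solutions are returned, one value
#' per line.
#'
#' @param pheno long-format phenotype records: columns `env`, `line`,
#'   `block`, `DTH` (if `adjust_dth`), and one column per trait.
#' @param traits character vector of trait column names; defaults to all
#'   numeric columns other than `DTH`.
#' @param adjust_dth include days-to-heading as a fixed covariate.
#' @param scope `"per_env"` (line x environment table) or `"overall"`.
#' @param method `"joint"` fits the across-environment model above and
#'   assembles per-environment values from the genotype solutions plus the
#'   environment and genotype-by-environment BLUPs; `"by_env"` fits the
#'   single-environment model (genotype fixed, block random) separately in
#'   each environment, which keeps all environment-specific genetic signal
#'   (the joint model's interaction BLUPs are shrunken when entries are
#'   unreplicated within environments).
#' @return A `blue_table`: data frame with columns `line`, `env` (`"all"`
#'   under `scope = "overall"`), `trait`, `blue`, `se` (standard error of
#'   the genotype fixed effect).
#' @export
fit_blues <- function(pheno, traits = NULL, adjust_dth = TRUE,
                      scope = c("per_env", "overall"),
                      method = c("joint", "by_env")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (method == "by_env" && scope == "per_env")
    return(fit_blues_by_env(pheno, traits, adjust_dth))
  traits <- traits %||% setdiff(names(pheno)[vapply(pheno, is.numeric,
                                                    logical(1))], "DTH")
  need <- c("env", "line", "block", if (adjust_dth) "DTH")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(pheno$line)) < 2) stop("need at least 2 genotypes")
  if (!any(duplicated(pheno[, c("line")])))
    stop("no genotype is replicated across environments or blocks; ",
         "fixed genotype effects are not separable from error")

  df <- pheno
  df$line <- factor(df$line)
  df$env <- factor(df$env)
  df$block <- factor(paste(df$env, df$block, sep = ":"))
  if (adjust_dth) df$DTH <- df$DTH - mean(df$DTH, na.rm = TRUE)
  multi_env <- nlevels(df$env) > 1

  out <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    df$.y <- df[[traits[t]]]
    rhs <- paste(c("0 + line", if (adjust_dth) "DTH",
                   if (multi_env) "(1 | env)", "(1 | block)",
                   if (multi_env) "(1 | line:env)"), collapse = " + ")
    fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = df,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    fe <- lme4::fixef(fit)
    g_idx <- grep("^line", names(fe))
    g <- fe[g_idx]
    names(g) <- sub("^line", "", names(g))
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[g_idx]
    if (scope == "overall" || !multi_env) {
      env_lab <- if (multi_env) "all" else as.character(unique(df$env))
      out[[t]] <- data.frame(line = names(g), env = env_lab,
                             trait = traits[t], blue = unname(g),
                             se = unname(se), row.names = NULL)
    } else {
      re <- lme4::ranef(fit)
      env_eff <- stats::setNames(re$env[, 1], rownames(re$env))
      ge <- re$`line:env`
      ge_key <- rownames(ge)
      grid <- expand.grid(line = names(g), env = levels(df$env),
                          stringsAsFactors = FALSE)
      ge_val <- ge[match(paste(grid$line, grid$env, sep = ":"), ge_key), 1]
      ge_val[is.na(ge_val)] <- 0
      out[[t]] <- data.frame(
        line = grid$line, env = grid$env, trait = traits[t],
        blue = unname(g[grid$line]) + unname(env_eff[grid$env]) + ge_val,
        se = unname(se[grid$line]), row.names = NULL)
    }
  }
  structure(do.call(rbind, out), class = c("blue_table", "data.frame"))
}

# stage-wise per-environment adjusted means: genotype fixed, block random,
# fitted separately within each environment
fit_blues_by_env <- function(pheno, traits, adjust_dth) {
  traits <- traits %||% setdiff(names(pheno)[vapply(pheno, is.numeric,
                                                    logical(1))], "DTH")
  out <- list()
  for (e in unique(pheno$env)) {
    sub <- pheno[pheno$env == e, , drop = FALSE]
    sub$line <- factor(sub$line)
    sub$block <- factor(sub$block)
    if (adjust_dth) sub$DTH <- sub$DTH - mean(sub$DTH, na.rm = TRUE)
    for (tr in traits) {
      sub$.y <- sub[[tr]]
      rhs <- paste(c("0 + line", if (adjust_dth) "DTH", "(1 | block)"),
                   collapse = " + ")
      fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = sub,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
      fe <- lme4::fixef(fit)
      g_idx <- grep("^line", names(fe))
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))[g_idx]
      out[[length(out) + 1L]] <- data.frame(
        line = sub("^line", "", names(fe)[g_idx]), env = e, trait = tr,
        blue = unname(fe[g_idx]), se = unname(se), row.names = NULL)
    }
  }
  structure(do.call(rbind, out), class = c("blue_table", "data.frame"))
}

#' Reshape a blue_table into a line x environment matrix for one trait
#'
#' @param blues a `blue_table` from [fit_blues()].
#' @param trait trait name to extract.
#' @return numeric matrix, lines in rows, environments in columns.
#' @export
blues_matrix <- function(blues, trait) {
  b <- blues[blues$trait == trait, , drop = FALSE]
  if (nrow(b) == 0) stop("trait not found: ", trait)
  lines <- sort(unique(b$line))
  envs <- unique(b$env)
  m <- matrix(NA_real_, length(lines), length(envs),
              dimnames = list(lines, envs))
  m[cbind(match(b$line, lines), match(b$env, envs))] <- b$blue
  m
}

#' Broad-sense heritability within one environment
#'
#' Fits the single-environment model with genotype and block as random
#' effects by REML,
#' \deqn{y_{jk} = \mu + G_j + B_k + e_{jk},}
#' and returns \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e)}.
#' Replication (at minimum, check lines repeated across blocks) is required
#' to separate genotypic from residual variance.
#'
#' @param pheno phenotype records for a single environment (columns `line`,
#'   `block`, the trait, and `DTH` if `adjust_dth`).
#' @param trait trait column name.
#' @param adjust_dth include days-to-heading as a fixed covariate.
#' @return list of class `variance_components`: `sigma2_G`, `sigma2_B`,
#'   `sigma2_e`, `H2`, `cv` (percent, `100 * sigma_e / mean`).
#' @export
estimate_heritability <- function(pheno, trait, adjust_dth = FALSE) {
  if (length(unique(pheno$env %||% "one")) > 1)
    stop("estimate_heritability expects records from a single environment")
  if (!any(duplicated(pheno$line)))
    stop("no genotype is replicated; sigma2_G is unidentifiable")
  df <- data.frame(.y = pheno[[trait]], line = factor(pheno$line),
                   block = factor(pheno$block))
  rhs <- "(1 | line) + (1 | block)"
  if (adjust_dth) { df$DTH <- pheno$DTH; rhs <- paste("DTH +", rhs) }
  fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = df,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "line"]
  s2b <- vc$vcov[vc$grp == "block"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  structure(list(sigma2_G = s2g, sigma2_B = s2b, sigma2_e = s2e,
                 H2 = s2g / (s2g + s2e),
                 cv = 100 * sqrt(s2e) / mean(df$.y, na.rm = TRUE)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma2_G = %.4g, sigma2_B = %.4g, sigma2_e = %.4g\n",
              x$sigma2_G, x$sigma2_B, x$sigma2_e))
  cat(sprintf("H2 = %.3f, CV = %.1f%%\n", x$H2, x$cv))
  invisible(x)
}

#' Per-environment heritability table across all traits
#'
#' Convenience wrapper applying [estimate_heritability()] to every
#' trait-by-environment cell of a long phenotype data frame.
#'
#' @inheritParams fit_blues
#' @return matrix of H2 values, traits in rows, environments in columns.
#' @export
heritability_table <- function(pheno, traits = NULL, adjust_dth = FALSE) {
  traits <- traits %||% setdiff(names(pheno)[vapply(pheno, is.numeric,
                                                    logical(1))], "DTH")
  envs <- unique(pheno$env)
  h2 <- matrix(NA_real_, length(traits), length(envs),
               dimnames = list(traits, envs))
  for (e in envs) {
    sub <- pheno[pheno$env == e, , drop = FALSE]
    for (t in traits)
      h2[t, e] <- estimate_heritability(sub, t, adjust_dth = adjust_dth)$H2
  }
  h2
}

#' Pearson correlations among traits from adjusted means
#'
#' Pairwise Pearson correlations of line-level adjusted means pooled across
#' environments. Cells involving a constant trait are set to `NA` with a
#' warning.
#'
#' @param blues a `blue_table` from [fit_blues()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_pearson <- function(blues) {
  traits <- unique(blues$trait)
  if (length(unique(blues$line)) < 3) stop("need at least 3 lines")
  wide <- sapply(traits, function(t) {
    b <- blues[blues$trait == t, ]
    b$blue[order(b$line, b$env)]
  })
  const <- apply(wide, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  r <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  if (any(const)) {
    warning("constant trait(s): ", paste(traits[const], collapse = ", "))
    r[const, ] <- r[, const] <- NA_real_
  }
  diag(r) <- 1
  dimnames(r) <- list(traits, traits)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
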