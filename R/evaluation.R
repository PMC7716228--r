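#' Population-structure clustering of a marker panel
#'
#' Discriminant analysis of principal components: the standardized marker
#' matrix is reduced to the principal components explaining a configurable
#' variance fraction, lines are partitioned into `k` groups by k-means on
#' the retained components, and linear discriminant functions fit to that
#' partition provide posterior membership probabilities. The number of
#' retained components is additionally capped at a third of the panel size
#' so the discriminant step stays well conditioned.
#'
#' @param geno complete lines x markers dosage matrix.
#' @param k number of genetic groups (default 10).
#' @param var_fraction variance fraction retained in the principal
#'   component reduction (default 0.9).
#' @param nstart k-means restarts.
#' @param seed integer seed for the k-means initialization.
#' @return list of class `cluster_model`: `assignment` (factor, argmax
#'   posterior), `posterior` (lines x k), `kmeans_cluster`, `scores`
#'   (retained PC scores), `n_components`, `var_explained`.
#' @export
cluster_panel <- function(geno, k = 10, var_fraction = 0.9, nstart = 25,
                          seed = NULL) {
  n <- nrow(geno)
  if (k > n) stop("k must not exceed the number of lines")
  if (!is.null(seed)) set.seed(seed)
  csd <- apply(geno, 2, stats::sd)
  X <- scale(geno[, csd > 0, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(which(cum >= var_fraction)[1], k)
  cap <- max(floor(n / 3), k)
  if (ncomp > cap) ncomp <- cap
  if (ncomp < k - 1)
    warning("fewer informative components than k - 1; ",
            "discriminant functions truncated")
  S <- pc$x[, seq_len(ncomp), drop = FALSE]
  km <- stats::kmeans(S, centers = k, nstart = nstart, iter.max = 50)
  ld <- MASS::lda(S, grouping = factor(km$cluster))
  post <- stats::predict(ld, S)$posterior
  assignment <- factor(colnames(post)[max.col(post)],
                       levels = colnames(post))
  names(assignment) <- rownames(geno)
  rownames(post) <- rownames(geno)
  structure(list(assignment = assignment, posterior = post,
                 kmeans_cluster = km$cluster, scores = S,
                 n_components = ncomp, var_explained = cum[ncomp]),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("DAPC-style clustering:", length(levels(x$assignment)), "groups on",
      x$n_components, "components",
      sprintf("(%.0f%% variance)\n", 100 * x$var_explained))
  print(table(x$assignment))
  invisible(x)
}

#' Cross-validation fold assignment
#'
#' Random scheme: lines are shuffled and dealt cyclically across folds.
#' Stratified scheme: lines are shuffled within each cluster and dealt
#' cyclically, the cyclic counter carrying over between clusters, so fold
#' sizes differ by at most one overall and by at most one within every
#' cluster.
#'
#' @param lines vector of line IDs.
#' @param f number of folds (default 5).
#' @param scheme `"random"` or `"stratified"`.
#' @param clusters factor of cluster labels (required when stratified).
#' @param seed integer seed.
#' @return data frame of class `fold_assignment` with columns `line` and
#'   `fold`; the scheme and seed are attached as attributes.
#' @export
make_folds <- function(lines, f = 5, scheme = c("random", "stratified"),
                       clusters = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  n <- length(lines)
  if (f > n) stop("more folds than lines")
  if (scheme == "stratified" && is.null(clusters))
    stop("stratified folds require cluster labels")
  if (!is.null(seed)) set.seed(seed)
  fold_cycle <- sample.int(f)                 # random fold order, then cyclic
  fold <- integer(n)
  ptr <- 0L
  groups <- if (scheme == "random") list(seq_len(n)) else
    split(seq_len(n), clusters)
  for (g in groups) {
    g <- g[sample.int(length(g))]
    fold[g] <- fold_cycle[(ptr + seq_along(g) - 1L) %% f + 1L]
    ptr <- ptr + length(g)
  }
  structure(data.frame(line = lines, fold = fold),
            class = c("fold_assignment", "data.frame"),
            scheme = scheme, f = f, seed = seed)
}

#' Cross-validate a masked-cell prediction model
#'
#' For each fold, the validation lines' response cells are masked (by
#' default in every environment and trait), the model handle is fitted on
#' the remainder, and the Pearson correlation of observed and predicted
#' values is recorded per environment and trait.
#'
#' @param model a handle `function(Y_masked, grm, ...)` returning an array
#'   shaped like `Y` with predictions (at least) for the masked cells; see
#'   [model_mgblup()], [model_bmtme()], [model_bmors()].
#' @param Y lines x environments x traits response array.
#' @param grm genomic relationship matrix.
#' @param folds a [make_folds()] assignment covering the rows of `Y`.
#' @param mask_all_envs mask validation lines in all environments (default)
#'   or per environment in turn.
#' @param ... passed to the model handle.
#' @return data frame of class `cv_result`: fold, env, trait, `rp`
#'   (predictive correlation; `NA` with a warning for folds with fewer
#'   than 3 validation lines), `n`.
#' @export
cross_validate <- function(model, Y, grm, folds, mask_all_envs = TRUE, ...) {
  stopifnot(length(dim(Y)) == 3)
  lines <- dimnames(Y)[[1]]
  fmap <- folds$fold[match(lines, folds$line)]
  if (anyNA(fmap)) stop("fold assignment does not cover all lines of Y")
  envs <- dimnames(Y)[[2]]; traits <- dimnames(Y)[[3]]
  env_sets <- if (mask_all_envs) list(seq_along(envs)) else
    as.list(seq_along(envs))
  out <- list()
  for (k in sort(unique(fmap))) {
    val <- fmap == k
    for (es in env_sets) {
      Ym <- Y
      Ym[val, es, ] <- NA
      pred <- model(Ym, grm, ...)
      for (i in es) for (l in seq_along(traits)) {
        o <- Y[val, i, l]; p <- pred[val, i, l]
        ok <- is.finite(o) & is.finite(p)
        if (sum(ok) < 3) {
          warning("fold ", k, ", env ", envs[i],
                  ": fewer than 3 validation lines")
          rp <- NA_real_
        } else rp <- stats::cor(o[ok], p[ok])
        out[[length(out) + 1L]] <- data.frame(
          fold = k, env = envs[i], trait = traits[l], rp = rp,
          n = sum(ok))
      }
    }
  }
  structure(do.call(rbind, out), class = c("cv_result", "data.frame"))
}

#' Model handles for [cross_validate()]
#'
#' Each returns a `function(Y_masked, grm)` closure fitting the respective
#' model and returning its prediction array.
#'
#' @param mcmc an [mcmc_config()].
#' @return a model handle.
#' @export
model_mgblup <- function(mcmc = mcmc_config()) {
  function(Y, grm, ...) {
    pred <- array(NA_real_, dim = dim(Y), dimnames = dimnames(Y))
    for (l in seq_len(dim(Y)[3]))
      pred[, , l] <- fit_mgblup(Y[, , l], grm, mcmc)$yhat
    pred
  }
}

#' @rdname model_mgblup
#' @export
model_bmtme <- function(mcmc = mcmc_config()) {
  function(Y, grm, ...) fit_bmtme(Y, grm, mcmc)$yhat
}

#' @rdname model_mgblup
#' @export
model_bmors <- function(mcmc = mcmc_config()) {
  function(Y, grm, ...) {
    s1 <- bmors_stage1(Y, grm, mcmc)
    pred <- array(NA_real_, dim = dim(Y), dimnames = dimnames(Y))
    for (l in seq_len(dim(Y)[3]))
      pred[, , l] <- fit_bmors(Y, grm, l, mcmc, stage1 = s1)$yhat
    pred
  }
}

#' Prediction accuracy from fold-level predictive correlations
#'
#' Converts the mean predictive correlation (predictive ability) across
#' folds into prediction accuracy by dividing by the square root of the
#' trait heritability, \eqn{r_{GY} = \bar r_p / \sqrt{H^2}}, with standard
#' error \eqn{SE = \sigma_{r_p} / (\sqrt{f}\,\sqrt{H^2})}. Values may
#' exceed 1 for low-heritability environments and are reported as computed.
#'
#' @param rp vector of per-fold predictive correlations.
#' @param h2 broad-sense heritability of the trait in the environment.
#' @return list with `accuracy`, `se`, `rp_mean`, `rp_sd`, `f`.
#' @export
prediction_accuracy <- function(rp, h2) {
  if (!is.finite(h2) || h2 <= 0) stop("H2 must be positive")
  rp <- rp[is.finite(rp)]
  f <- length(rp)
  if (f < 2) stop("need at least 2 folds")
  list(accuracy = mean(rp) / sqrt(h2),
       se = stats::sd(rp) / (sqrt(f) * sqrt(h2)),
       rp_mean = mean(rp), rp_sd = stats::sd(rp), f = f)
}

#' Response to selection from genomic predictions
#'
#' Ranks lines by their genomic estimated breeding values, selects the top
#' `ceiling(intensity * n)` (ties broken by position for reproducibility),
#' and computes the selection differential
#' \eqn{S = \bar y_{selected} - \bar y_{all}} on the observed phenotype and
#' the response \eqn{R = H^2 S}.
#'
#' @param gebv numeric vector of predicted breeding values.
#' @param phenotype observed phenotype, aligned with `gebv`.
#' @param h2 broad-sense heritability.
#' @param intensity selected fraction in (0, 1) (default 0.10).
#' @return list with `R`, `S`, `selected` (indices), `n_selected`.
#' @export
response_to_selection <- function(gebv, phenotype, h2, intensity = 0.10) {
  if (length(gebv) != length(phenotype)) stop("gebv/phenotype mismatch")
  if (intensity <= 0 || intensity >= 1) stop("intensity must be in (0, 1)")
  n <- length(gebv)
  n_sel <- ceiling(intensity * n)
  sel <- order(-gebv, seq_len(n))[seq_len(n_sel)]   # stable tie-break
  S <- mean(phenotype[sel]) - mean(phenotype)
  list(R = h2 * S, S = S, selected = sel, n_selected = n_sel)
}

#' Summarize cross-validation into an evaluation report
#'
#' Aggregates fold-level predictive correlations into per environment x
#' trait predictive ability, accuracy with its standard error, and (for the
#' trait given by `rts_trait`) the response to selection averaged across
#' folds with standard error \eqn{\sigma_R / \sqrt{f}}.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param h2 matrix of heritabilities (traits x environments).
#' @param model_name label recorded in the report.
#' @param scheme fold scheme label.
#' @return data frame of class `evaluation_report`.
#' @export
evaluation_report <- function(cv, h2, model_name = "model",
                              scheme = "random") {
  cells <- unique(cv[, c("env", "trait")])
  out <- lapply(seq_len(nrow(cells)), function(r) {
    e <- cells$env[r]; tr <- cells$trait[r]
    rp <- cv$rp[cv$env == e & cv$trait == tr]
    if (is.finite(h2[tr, e]) && h2[tr, e] > 0) {
      acc <- prediction_accuracy(rp, h2[tr, e])
    } else {
      warning("H2 not positive for ", tr, " in ", e,
              "; accuracy undefined")
      acc <- list(rp_mean = mean(rp, na.rm = TRUE), accuracy = NA_real_,
                  se = NA_real_)
    }
    data.frame(model = model_name, scheme = scheme, env = e, trait = tr,
               rp = acc$rp_mean, accuracy = acc$accuracy, se = acc$se)
  })
  structure(do.call(rbind, out),
            class = c("evaluation_report", "data.frame"))
}
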