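#' Configuration for an end-to-end prediction run
#'
#' Collects every setting of the analysis workflow: input paths (or a
#' [sim_config()] for synthetic data), QC thresholds, model list, MCMC
#' settings, cross-validation scheme, selection intensity and the
#' days-to-heading adjustment flag. All randomness flows from `seed`,
#' split deterministically per stage.
#'
#' @param phenotypes,genotypes input file paths, or `NULL` when `sim` is
#'   given.
#' @param sim a [sim_config()] generating the inputs in memory.
#' @param out_dir output directory for stage artifacts.
#' @param models subset of `"MGBLUP"`, `"BMTME"`, `"BMORS"`.
#' @param qc named list overriding [filter_markers()] thresholds.
#' @param mcmc an [mcmc_config()].
#' @param cv_scheme `"random"` or `"stratified"`.
#' @param folds number of cross-validation folds.
#' @param n_clusters genetic groups for the stratified scheme.
#' @param intensity selected fraction for response to selection.
#' @param rts_trait trait used for response to selection.
#' @param adjust_dth adjust adjusted means for days to heading.
#' @param seed root seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(phenotypes = NULL, genotypes = NULL, sim = NULL,
                       out_dir = tempfile("mtgp_run_"),
                       models = c("MGBLUP", "BMTME", "BMORS"),
                       qc = list(), mcmc = mcmc_config(),
                       cv_scheme = c("random", "stratified"), folds = 5,
                       n_clusters = 10, intensity = 0.10,
                       rts_trait = "GY", adjust_dth = TRUE, seed = 1) {
  cv_scheme <- match.arg(cv_scheme)
  models <- match.arg(models, c("MGBLUP", "BMTME", "BMORS"),
                      several.ok = TRUE)
  if (is.null(sim) && (is.null(phenotypes) || is.null(genotypes)))
    stop("supply input paths or a sim_config")
  structure(list(phenotypes = phenotypes, genotypes = genotypes, sim = sim,
                 out_dir = out_dir, models = models, qc = qc, mcmc = mcmc,
                 cv_scheme = cv_scheme, folds = folds,
                 n_clusters = n_clusters, intensity = intensity,
                 rts_trait = rts_trait, adjust_dth = adjust_dth,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full multi-trait genomic prediction workflow
#'
#' Executes the stages in order — genotype QC and imputation, relationship
#' matrix, adjusted means and per-environment heritability, population
#' clustering (stratified scheme), fold assignment, cross-validated model
#' fits, accuracy and response to selection — persisting each stage's
#' outputs as CSV under `config$out_dir` together with a JSON manifest
#' (seeds, configuration, stage row counts) sufficient to re-execute the
#' run bit-identically on one thread.
#'
#' @param config a [run_config()].
#' @return list with `report` (evaluation rows per model x env x trait),
#'   `rts` (response-to-selection rows), `h2`, `qc`, `paths`; invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage_log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log[[stage]] <<- round(as.numeric(Sys.time() - t0,
                                            units = "secs"), 2)
    res
  }

  inputs <- tick("input", {
    if (!is.null(config$sim)) {
      sc <- config$sim
      sc$seed <- sc$seed %||% seed
      mk <- simulate_marker_matrix(sc)
      ph <- simulate_phenotypes(mk, sc)
      list(geno = mk$geno, pheno = ph$pheno, truth = ph$truth)
    } else {
      list(geno = read_genotypes(config$genotypes),
           pheno = read_phenotypes(config$phenotypes), truth = NULL)
    }
  })

  qcres <- tick("qc", do.call(filter_markers,
                              c(list(inputs$geno), config$qc)))
  geno <- tick("impute", impute_missing(qcres$geno))
  grm <- tick("grm", build_grm(geno))

  blues <- tick("blues", fit_blues(inputs$pheno,
                                   adjust_dth = config$adjust_dth))
  traits <- unique(blues$trait)
  h2 <- tick("heritability",
             heritability_table(inputs$pheno, traits = traits))
  Y <- blue_array(blues)
  keep <- intersect(dimnames(Y)[[1]], rownames(grm))
  Y <- Y[keep, , , drop = FALSE]

  clusters <- NULL
  if (config$cv_scheme == "stratified")
    clusters <- tick("clusters",
                     cluster_panel(geno[keep, , drop = FALSE],
                                   k = config$n_clusters,
                                   seed = seed + 1L)$assignment)
  folds <- tick("folds", make_folds(keep, f = config$folds,
                                    scheme = config$cv_scheme,
                                    clusters = clusters,
                                    seed = seed + 2L))

  handles <- list(
    MGBLUP = function(mc) model_mgblup(mc),
    BMTME = function(mc) model_bmtme(mc),
    BMORS = function(mc) model_bmors(mc))
  report <- list(); rts_rows <- list(); cv_all <- list()
  for (mod in config$models) {
    mc <- mcmc_config(config$mcmc$iterations, config$mcmc$burn_in,
                      config$mcmc$thin,
                      seed = seed + 10L + match(mod, config$models),
                      verbose = config$mcmc$verbose)
    cv <- tick(paste0("cv_", mod),
               cross_validate(handles[[mod]](mc), Y, grm, folds))
    cv_all[[mod]] <- cv
    report[[mod]] <- evaluation_report(cv, h2, model_name = mod,
                                       scheme = config$cv_scheme)
    rts_rows[[mod]] <- tick(paste0("rts_", mod),
                            rts_by_env(handles[[mod]](mc), Y, grm, folds,
                                       h2, config$rts_trait,
                                       config$intensity, mod,
                                       config$cv_scheme))
  }
  report <- do.call(rbind, report)
  rts <- do.call(rbind, rts_rows)

  paths <- c(qc = file.path(config$out_dir, "qc_marker_stats.csv"),
             blues = file.path(config$out_dir, "blues.csv"),
             h2 = file.path(config$out_dir, "heritability.csv"),
             folds = file.path(config$out_dir, "folds.csv"),
             report = file.path(config$out_dir, "evaluation_report.csv"),
             rts = file.path(config$out_dir, "response_to_selection.csv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(qcres$report$marker_stats, paths["qc"],
                   row.names = FALSE)
  utils::write.csv(blues, paths["blues"], row.names = FALSE)
  utils::write.csv(data.frame(trait = rownames(h2), h2,
                              check.names = FALSE), paths["h2"],
                   row.names = FALSE)
  utils::write.csv(folds, paths["folds"], row.names = FALSE)
  utils::write.csv(report, paths["report"], row.names = FALSE)
  utils::write.csv(rts, paths["rts"], row.names = FALSE)
  manifest <- list(
    package = "mtgp",
    version = as.character(utils::packageVersion("mtgp")),
    seed = seed,
    models = config$models, cv_scheme = config$cv_scheme,
    folds = config$folds, intensity = config$intensity,
    adjust_dth = config$adjust_dth,
    mcmc = config$mcmc[c("iterations", "burn_in", "thin")],
    qc = qcres$report$removed, retained = qcres$report$retained,
    stage_seconds = stage_log)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(report = report, rts = rts, h2 = h2,
                 qc = qcres$report, cv = cv_all, folds = folds,
                 blues = blues, grm = grm, paths = paths,
                 truth = inputs$truth))
}

# per-environment response to selection for one model across CV folds
rts_by_env <- function(model, Y, grm, folds, h2, trait, intensity,
                       model_name, scheme) {
  traits <- dimnames(Y)[[3]]
  if (!trait %in% traits) return(NULL)
  l <- match(trait, traits)
  lines <- dimnames(Y)[[1]]
  fmap <- folds$fold[match(lines, folds$line)]
  envs <- dimnames(Y)[[2]]
  R_fold <- matrix(NA_real_, length(unique(fmap)), length(envs),
                   dimnames = list(NULL, envs))
  for (k in sort(unique(fmap))) {
    val <- fmap == k
    Ym <- Y; Ym[val, , ] <- NA
    pred <- model(Ym, grm)
    for (i in seq_along(envs)) {
      o <- Y[val, i, l]; p <- pred[val, i, l]
      ok <- is.finite(o) & is.finite(p)
      if (sum(ok) >= 3)
        R_fold[k, i] <- response_to_selection(p[ok], o[ok],
                                              h2[trait, envs[i]],
                                              intensity)$R
    }
  }
  do.call(rbind, lapply(seq_along(envs), function(i) {
    r <- R_fold[, i]; r <- r[is.finite(r)]
    data.frame(model = model_name, scheme = scheme, env = envs[i],
               trait = trait, R = mean(r), se_R = stats::sd(r) / sqrt(length(r)))
  }))
}
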