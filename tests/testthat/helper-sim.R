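# shared fixtures: small simulated panels built in code

# complete dosage matrix + phenotypes for a compact panel
small_panel <- function(n_lines = 150, n_markers = 800, n_traits = 2,
                        n_envs = 2, h2 = 0.5, ge_variance = 0.3,
                        trait_cor = NULL, fst = 0.15, seed = 101,
                        n_subpops = 4, n_checks = 0,
                        block_var_share = 0.1) {
  L <- n_traits
  St <- diag(L)
  if (!is.null(trait_cor)) St[St == 0] <- trait_cor
  cfg <- sim_config(n_lines = n_lines, n_checks = n_checks,
                    n_markers = n_markers, n_subpops = n_subpops,
                    n_traits = L, n_envs = n_envs,
                    trait_genetic_cov = St,
                    target_h2 = matrix(h2, L, n_envs),
                    ge_variance = ge_variance, het_rate = 0,
                    missing_rate = 0, fst = fst, n_blocks = 4,
                    block_var_share = block_var_share, seed = seed)
  mk <- simulate_marker_matrix(cfg)
  ph <- simulate_phenotypes(mk, cfg)
  poly <- apply(mk$complete, 2, stats::sd) > 0
  grm <- build_grm(mk$complete[, poly, drop = FALSE])
  Y <- array(NA_real_,
             c(nrow(grm), n_envs, L),
             dimnames = list(rownames(grm), cfg$envs, cfg$traits))
  for (tr in cfg$traits)
    Y[, , tr] <- with(ph$pheno,
                      tapply(get(tr), list(line, env), mean))[rownames(grm), ]
  list(cfg = cfg, markers = mk, pheno = ph$pheno, truth = ph$truth,
       grm = grm, Y = Y)
}

# two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins (independent oracle for the packaged test)
fisher_p_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(a_obs, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
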