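---
title: "Multi-trait multi-environment genomic prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait multi-environment genomic prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breeding programs select simultaneously on grain yield (GY, t/ha) and the
yield-component traits that drive it — harvest index (HI, %), spike
fertility (SF, grains per gram of spike chaff) and thousand grain weight
(TGW, g). These traits are genetically correlated, their heritabilities
differ widely across water regimes, and trials are run in several
environments at once. `mtgp` implements the full analysis chain for
predicting such traits from genome-wide SNPs in an inbred wheat panel:
genotype QC, adjusted means, heritability, three Bayesian whole-genome
prediction models, two feed-forward neural-network models,
structure-stratified cross-validation, and response to selection. A
synthetic-data generator with known genetic architecture makes every stage
testable by parameter recovery.

## Phenotype stage

Adjusted genotype means (BLUEs) come from the mixed model

$$y_{ijk} = \mu + G_j + E_i + B_{i(k)} + GE_{ji} + e_{ijk},$$

with genotype fixed and environment, block-within-environment and
genotype-by-environment random (`lme4`). Days to heading can enter as a
fixed covariate; it is centered first, so BLUEs are reported at the mean
phenology. Broad-sense heritability per environment uses the
single-environment model with genotype and block random (REML) and
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e)$.

Two routes to per-environment BLUEs are provided, because the design here
is genuinely open. The joint route (`method = "joint"`) assembles
genotype solutions plus environment and interaction BLUPs from the model
above; with unreplicated entries the interaction BLUPs are strongly
shrunken, which stabilizes the values but transfers most
environment-specific signal into the shared genotype effect. The
stage-wise route (`method = "by_env"`) fits genotype-fixed, block-random
models separately per environment; it keeps all environment-specific
signal at the price of noisier values. Multi-trait genetic correlations
are best estimated from the joint route (the quantity of interest is the
trait covariance of genotype main effects); environment-correlation
structure is better preserved by the stage-wise route.

## Prediction models

**MGBLUP.** For one trait, $y_{ij} = E_i + G_j + GE_{ij} + \varepsilon_{ij}$
with $g \sim N(0, \sigma^2_G G)$ on the genomic relationship matrix
$G = XX'/p$ (markers centered and scaled to unit sample standard
deviation) and a reaction-norm G×E term: the Hadamard product of the
genetic kernel and the environment-incidence kernel, i.e. independent
copies of $\sigma^2_{GE} G$ within each environment. All variance
components carry scaled inverse-$\chi^2$ priors with df 5 and scale half
the phenotypic variance — weakly informative conjugate defaults. The
sampler works in the eigenbasis of $G$, so each sweep is a handful of
matrix–vector products.

**BMTME.** The matrix-variate model
$Y = X\beta + Z_1 b_1 + Z_2 b_2 + E$ with
$b_1 \sim MN(0, G, \Sigma_t)$ (genotype × trait),
$b_2 \sim MN(0, \Sigma_E \otimes G, \Sigma_t)$
(genotype × environment × trait) and residual rows iid $N(0, R_e)$.
$\Sigma_t$, $\Sigma_E$, $R_e$ carry inverse-Wishart priors with df
dim + 2 and identity scale; $\beta$ is flat. All full conditionals are
conjugate. Two numerical devices keep the sampler fast: the
eigendecomposition of $G$ is computed once, and the per-row normal
updates are vectorized through a simultaneous diagonalization of the
trait-level precision pair ($\Sigma_t^{-1}$, $R_e^{-1}$), so no per-row
matrix factorizations are needed. Non-positive-definite draws are retried
with a logged jitter. Trait genetic correlations are
$r_G(a,b) = \sigma_G(a,b)/\sqrt{\sigma^2_G(a)\sigma^2_G(b)}$ from the
posterior-mean $\Sigma_t$; environment correlations derive from the total
genetic covariance $1 + \Sigma_E$ of $b_1 + b_2$. Because the
inverse-Wishart scale is the identity, responses should be standardized
per trait (the worked pipeline standardizes per trait-by-environment
cell); correlations are invariant to this scaling.

**BMORS.** Two-stage stacking: stage 1 fits MGBLUP per trait (with the
same cells masked as the target, so no validation information leaks);
stage 2 regresses the target trait on the $L$ stage-1 predictions, each
scaled by training-cell mean and standard deviation, in a Bayesian ridge
meta-model. Leave-one-environment-out prediction masks every trait of one
environment and shares one stage-1 pass across target traits.

**Missing cells.** All samplers handle masked line-by-environment cells
by data augmentation — masked responses are redrawn each sweep from their
conditional normal given any observed traits in the same row — so
cross-validation, leave-one-environment-out and ordinary prediction share
one code path.

**Neural networks.** The single-trait (SMDL) and multi-trait (MMDL)
models are densely connected networks with three hidden layers of equal
width, rectified-linear activations, 25% inverted dropout after each
hidden layer and linear outputs, trained on (summed) mean squared error.
The optimizer, step size and batch size are not pinned down by the model
description, so defaults are Adam, $10^{-3}$, batch 32, all exposed in
`net_spec()`. Environments are encoded as one-hot indicators appended to
the marker matrix so one network serves all environments; this is a
recorded assumption. Responses are standardized per trait and
de-standardized at prediction, making training equivariant to affine
transformations of the response. With a fixed seed on one thread the fit
is bit-reproducible.

**Hyperparameter search.** A full factorial over hidden-layer width
(5–70 by 5) and epochs (10–80 by 10) — 112 cells — scored by
cross-validated mean predictive correlation. At each epoch level a
quadratic-plateau curve in the number of neurons
($y = a + bx + cx^2$ below the join $x_0 = -b/2c$, constant beyond, with
continuity and zero slope at the join) localizes where added width stops
paying. The join is profiled on a grid and refined by golden-section
search; for each candidate join the remaining parameters reduce to a
linear solve, which is robust and has no starting-value sensitivity.
Degenerate cases are flagged: constant data (`flat`), convex curvature
(`degenerate`, argmax fallback), join at the edge of the searched range
(`boundary`).

## Evaluation

**Clustering.** Population structure is summarized DAPC-style: PCA of the
standardized markers (components covering 90% of variance by default,
capped at a third of the panel size to keep the discriminant step well
conditioned), k-means into k = 10 groups, then linear discriminant
functions for posterior memberships.

**Folds.** Five-fold assignments are dealt cyclically after shuffling —
within clusters for the stratified scheme, with the cyclic counter
carried across clusters — so fold sizes differ by at most one overall
*and* within every cluster, by construction rather than by rejection
sampling.

**Accuracy.** Predictive ability is the Pearson correlation of observed
and predicted values per environment and trait, averaged over folds.
Accuracy divides by $\sqrt{H^2}$ — the standard conversion from ability
to accuracy; with low-heritability environments it can exceed 1 and is
reported as computed. Its standard error is
$\sigma_{r_p}/(\sqrt{f}\sqrt{H^2})$, reading the $fH^2$ denominator as
$\sqrt{f}\sqrt{H^2}$. Negative fold correlations are averaged as-is.

**Response to selection.** Lines are ranked by GEBV, the top
$\lceil 0.10\,n \rceil$ selected (ties broken by position for
reproducibility), $S$ is the phenotypic mean difference between selected
lines and the panel, and $R = H^2 S$, with SE $\sigma_R/\sqrt{f}$ across
folds.

## The synthetic generator

The generator emulates the statistical structure of a soft-wheat
multi-environment panel: 237 entries plus 3 repeated checks in 10
subpopulations (Balding–Nichols allele-frequency divergence, default
Fst 0.10), 27,957 biallelic GBS SNPs with low heterozygosity (2%) and 10%
missing calls, four traits in four environments with per-cell
heritabilities spanning 0.22–0.87, trait genetic correlations such as
+0.67 (GY–HI) and −0.32 (SF–TGW), environment-margin genetic correlations
near 0.16–0.26, and an augmented design with 12 blocks per environment.
Genetic values combine infinitesimal (Gaussian) marker effects with trait
covariance $\Sigma_t$ and G×E deviations with covariance
$\Sigma_E \otimes \Sigma_t$; the G×E share defaults to 0.8, which places
the realized between-environment correlation $(1-s) + s\,\rho_E$ in the
target band. Residual variance per trait-by-environment cell is solved
from the realized genetic variance so heritability hits its target in
expectation; days to heading is a line-level covariate with plot-level
scatter and configurable per-trait slopes, so the phenology adjustment is
exercisable without being confounded with genotype.

What the generator does **not** emulate: linkage disequilibrium beyond
subpopulation allele-frequency structure, non-Gaussian (major-gene)
architectures, spatial field trend, and outliers. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimation machinery under the assumed model, not robustness to every
feature of real field data. The marker-effect distribution is an explicit
assumption: the data the analysis emulates do not identify it, and the
infinitesimal default is the conventional choice behind GBLUP-type
kernels.

## Numerical choices and problem sizes

Eigenvalues of relationship kernels are floored at $10^{-8}$ of the
largest (coordinates in the null space are pinned at zero); covariance
draws that fail a Cholesky factorization are retried with escalating
jitter and counted. Strict QC inequalities carry a $10^{-9}$ guard so
exact boundary values (e.g. MAF exactly 5%) are never removed by
floating-point noise. MCMC defaults are 15,000 iterations with 10,000
burn-in and no thinning; the test-suite and worked examples use
500–4,000-iteration chains on panels of 60–240 lines and 300–28,000
markers, sizes chosen so each check completes in seconds while leaving
the Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

Accuracy above 1 is possible (and reported) when $H^2$ is small; BLUE
standard errors from the joint route ignore the uncertainty of the
interaction BLUPs; the naive per-marker mean imputation carries only
allele-frequency information and is not a substitute for LD-aware
imputation at high missingness; and the BMORS meta-model assumes the
stage-1 scaling constants transfer from training to validation cells,
which holds under random masking but can drift under systematic masking
patterns.
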