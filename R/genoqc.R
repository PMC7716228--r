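#' Per-marker summary statistics
#'
#' Computes minor-allele frequency, missing-call rate and heterozygote
#' frequency for every marker of a dosage matrix. Allele frequency is
#' `mean(dosage)/2` over observed calls; MAF folds it to `[0, 0.5]`.
#'
#' @param geno lines x markers dosage matrix in \{0,1,2\} with `NA` missing.
#' @return data frame with columns `marker`, `maf`, `missing`, `het`.
#' @export
marker_stats <- function(geno) {
  nobs <- colSums(!is.na(geno))
  pbar <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(pbar, 1 - pbar)
  het <- colMeans(geno == 1, na.rm = TRUE)
  data.frame(marker = colnames(geno),
             maf = ifelse(nobs > 0, maf, NA_real_),
             missing = 1 - nobs / nrow(geno),
             het = ifelse(nobs > 0, het, NA_real_),
             row.names = NULL)
}

#' Filter a marker matrix on missingness, MAF and heterozygosity
#'
#' Applies the panel QC rules in a fixed order: (1) drop lines with more than
#' `max_line_missing` missing calls, (2) drop markers with more than
#' `max_marker_missing` missing calls, (3) drop markers with minor allele
#' frequency below `min_maf`, (4) drop markers with heterozygote frequency
#' above `max_het` (inbred lines should be nearly homozygous). All removals
#' use strict inequalities, so boundary values are retained. Marker
#' statistics are recomputed after the line filter.
#'
#' @param geno lines x markers dosage matrix with `NA` missing.
#' @param max_marker_missing,min_maf,max_het,max_line_missing thresholds.
#' @return list with `geno` (the filtered matrix) and `report` (class
#'   `qc_report`: per-rule removal counts and per-marker statistics).
#' @export
filter_markers <- function(geno, max_marker_missing = 0.5, min_maf = 0.05,
                           max_het = 0.10, max_line_missing = 0.85) {
  if (length(geno) == 0) stop("empty marker matrix")
  n0 <- nrow(geno); p0 <- ncol(geno)

  eps <- 1e-9                       # guard strict boundaries against fp error
  line_missing <- rowMeans(is.na(geno))
  drop_lines <- line_missing > max_line_missing + eps
  geno <- geno[!drop_lines, , drop = FALSE]

  st <- marker_stats(geno)
  drop_missing <- st$missing > max_marker_missing + eps
  drop_maf <- !drop_missing & !is.na(st$maf) & st$maf < min_maf - eps
  drop_mono <- !drop_missing & is.na(st$maf)       # no observed calls at all
  drop_het <- !drop_missing & !drop_maf & !drop_mono &
    !is.na(st$het) & st$het > max_het + eps
  keep <- !(drop_missing | drop_maf | drop_mono | drop_het)
  if (!any(keep)) stop("all markers removed by QC filters")

  report <- structure(list(
    n_lines_in = n0, n_markers_in = p0,
    removed = c(line_missing = sum(drop_lines),
                marker_missing = sum(drop_missing | drop_mono),
                maf = sum(drop_maf),
                het = sum(drop_het)),
    retained = c(lines = nrow(geno), markers = sum(keep)),
    thresholds = c(max_marker_missing = max_marker_missing,
                   min_maf = min_maf, max_het = max_het,
                   max_line_missing = max_line_missing),
    marker_stats = st,
    kept = keep
  ), class = "qc_report")

  list(geno = geno[, keep, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC:", x$n_lines_in, "lines x", x$n_markers_in, "markers in\n")
  cat("  removed  lines (missingness):", x$removed[["line_missing"]], "\n")
  cat("  removed  markers missingness:", x$removed[["marker_missing"]],
      "| MAF:", x$removed[["maf"]], "| heterozygosity:",
      x$removed[["het"]], "\n")
  cat("  retained", x$retained[["lines"]], "lines x",
      x$retained[["markers"]], "markers\n")
  invisible(x)
}

#' Fisher exact test of allelic independence at a SNP site
#'
#' Cross-classifies the lines of an inbred panel by carriage of each allele
#' (heterozygotes carry both) and applies a two-sided Fisher exact test to
#' the resulting 2 x 2 table. At a genuine biallelic site the two alleles
#' segregate as alternatives, so carriage of one strongly predicts absence
#' of the other and independence is rejected; sites where the alleles look
#' independent are typically artifacts of homoeologous or duplicated
#' sequence. The SNP is deemed allelic (kept) when the null is rejected at
#' `alpha`.
#'
#' @param calls dosage vector in \{0,1,2\} (`NA` allowed) for one marker,
#'   dosage counting copies of the minor allele; alternatively a ready-made
#'   2 x 2 contingency table.
#' @param alpha rejection level for the independence null (default 0.001).
#' @return list with `p_value`, `keep` (logical; `NA` when the test is
#'   undefined, e.g. a monomorphic marker), and the 2 x 2 `table`.
#' @export
allelic_fisher_test <- function(calls, alpha = 0.001) {
  if (is.matrix(calls)) {
    tab <- calls
    if (!all(dim(tab) == 2)) stop("table input must be 2 x 2")
  } else {
    calls <- calls[!is.na(calls)]
    tab <- matrix(c(sum(calls == 1), sum(calls == 2),
                    sum(calls == 0), 0),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(carry_minor = c("yes", "no"),
                                  carry_major = c("yes", "no")))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = NA_real_, keep = NA, table = tab))
  }
  p <- stats::fisher.test(tab)$p.value
  list(p_value = p, keep = p < alpha, table = tab)
}

#' Impute missing marker calls by the per-marker mean
#'
#' Replaces missing dosages with the mean of the observed calls for that
#' marker, optionally rounded back onto \{0,1,2\}. Observed calls are never
#' altered. This is a deliberately naive single-site imputation: it carries
#' the allele-frequency information and nothing else, and is adequate for
#' relationship-matrix construction at low missingness.
#'
#' @param geno lines x markers dosage matrix with `NA` missing.
#' @param method `"mean"` (default, fractional dosages) or `"rounded_mean"`.
#' @return the completed matrix.
#' @export
impute_missing <- function(geno, method = c("mean", "rounded_mean")) {
  method <- match.arg(method)
  if (!anyNA(geno)) return(geno)
  nobs <- colSums(!is.na(geno))
  if (any(nobs == 0))
    stop("marker(s) with no observed calls: ",
         paste(colnames(geno)[nobs == 0], collapse = ", "))
  fill <- colMeans(geno, na.rm = TRUE)
  if (method == "rounded_mean") fill <- pmin(pmax(round(fill), 0), 2)
  idx <- which(is.na(geno), arr.ind = TRUE)
  out <- geno
  storage.mode(out) <- "double"
  out[idx] <- fill[idx[, 2]]
  out
}

#' Genomic relationship matrix from standardized markers
#'
#' Centers each marker to mean zero, scales it to unit sample standard
#' deviation, and returns `G = X X' / p` where `p` is the number of markers.
#' `G` is symmetric positive semidefinite with `mean(diag(G))` near 1.
#'
#' @param geno complete lines x markers dosage matrix.
#' @return n x n relationship matrix with line IDs as dimnames and the
#'   marker count as attribute `"p"`.
#' @export
build_grm <- function(geno) {
  if (anyNA(geno)) stop("marker matrix must be complete (impute first)")
  csd <- apply(geno, 2, stats::sd)
  if (any(csd == 0))
    stop("zero-variance marker(s): ",
         paste(utils::head(colnames(geno)[csd == 0], 5), collapse = ", "))
  X <- scale(geno, center = TRUE, scale = csd)
  G <- tcrossprod(X) / ncol(geno)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "p") <- ncol(geno)
  G
}
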