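#' Read long-format phenotype records
#'
#' Reads a delimited phenotype file with one row per plot: environment,
#' line, block, check flag, days to heading, and one column per trait
#' (expected traits and units: GY t/ha, HI %, SF grains per g chaff,
#' TGW g). Column names can be remapped through `col_map`, matching is
#' case-insensitive, and duplicate (env, line, block) keys are an error.
#'
#' @param path CSV (or other delimited) file with a header row.
#' @param col_map named character vector mapping standard names
#'   (`env`, `line`, `block`, `is_check`, `DTH`, trait names) to the
#'   file's column names.
#' @param traits trait columns expected; defaults to GY, HI, SF, TGW
#'   intersected with what the file provides.
#' @param sep field separator (default `,`).
#' @return data frame of phenotype records.
#' @export
read_phenotypes <- function(path, col_map = NULL,
                            traits = c("GY", "HI", "SF", "TGW"),
                            sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  find <- function(std) {
    if (!is.null(col_map) && std %in% names(col_map))
      return(match(col_map[[std]], nm))
    match(tolower(std), tolower(nm))
  }
  need <- c("env", "line", "block")
  idx <- vapply(need, find, integer(1))
  if (anyNA(idx))
    stop("missing required column(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  out <- data.frame(env = as.character(raw[[idx[1]]]),
                    line = as.character(raw[[idx[2]]]),
                    block = as.character(raw[[idx[3]]]),
                    stringsAsFactors = FALSE)
  ic <- find("is_check")
  out$is_check <- if (!is.na(ic)) as.logical(raw[[ic]]) else FALSE
  dth <- find("DTH")
  if (!is.na(dth)) out$DTH <- as.numeric(raw[[dth]])
  present <- traits[!is.na(vapply(traits, find, integer(1)))]
  if (length(present) == 0)
    stop("no trait columns found (looked for ",
         paste(traits, collapse = ", "), ")")
  for (tr in present) out[[tr]] <- as.numeric(raw[[find(tr)]])
  dup <- duplicated(out[, c("env", "line", "block")])
  if (any(dup))
    stop("duplicate (env, line, block) keys: ", sum(dup), " row(s)")
  message(nrow(out), " phenotype records, ", length(unique(out$env)),
          " environments, ", length(unique(out$line)), " lines; ",
          sum(is.na(out[present])), " missing trait values")
  out
}

#' Read a genotype matrix from delimited text or VCF
#'
#' Delimited text: a header row of marker IDs and one row per line (first
#' field the line ID). The dosage coding is auto-detected — \{0,1,2\} is
#' kept, \{-1,0,1\} is shifted, and IUPAC-style nucleotide calls are mapped
#' to minor-allele dosage per marker — and the decision is logged. VCF:
#' biallelic SNPs are converted to minor-allele dosage; multiallelic
#' records are skipped with a count.
#'
#' @param path file path (`.vcf`/`.vcf.gz` triggers VCF parsing).
#' @param sep field separator for delimited text (default tab).
#' @return lines x markers numeric dosage matrix with `NA` for missing.
#' @export
read_genotypes <- function(path, sep = "\t") {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_genotypes_vcf(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, row.names = 1,
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(raw)
  vals <- unique(as.vector(m))
  vals <- vals[!is.na(vals) & vals != ""]
  suppressWarnings(numvals <- as.numeric(vals))
  if (!anyNA(numvals)) {
    storage.mode(m) <- "numeric"
    if (all(numvals %in% c(0, 1, 2))) {
      message("genotype coding detected: {0,1,2} dosage")
    } else if (all(numvals %in% c(-1, 0, 1))) {
      message("genotype coding detected: {-1,0,1}, shifted to {0,1,2}")
      m <- m + 1
    } else stop("unrecognized numeric genotype coding: ",
                paste(utils::head(sort(numvals), 6), collapse = ", "))
    return(m)
  }
  message("genotype coding detected: nucleotide calls, ",
          "mapping to minor-allele dosage")
  iupac_het <- c("R", "Y", "S", "W", "K", "M")
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    v <- toupper(m[, j])
    v[v %in% c("N", "NA", ".", "-", "")] <- NA
    hom <- v %in% c("A", "C", "G", "T")
    alleles <- names(sort(table(v[hom]), decreasing = TRUE))
    if (length(alleles) == 0) next
    minor <- if (length(alleles) >= 2) alleles[2] else NA
    out[hom & v == alleles[1], j] <- 0
    if (!is.na(minor)) out[hom & v == minor, j] <- 2
    out[v %in% iupac_het, j] <- 1
  }
  out
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  m <- t(dos)                                        # lines x markers
  # fold to minor-allele dosage
  pbar <- colMeans(m, na.rm = TRUE) / 2
  flip <- !is.na(pbar) & pbar > 0.5
  m[, flip] <- 2 - m[, flip]
  m
}

#' Write a genotype matrix in the tab-delimited dialect of [read_genotypes()]
#'
#' @param geno lines x markers dosage matrix.
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write phenotype records as CSV
#'
#' @param pheno phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
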