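#' Genotype dosage matrix
#'
#' Container for a biallelic SNP dosage matrix (individuals x markers) coded
#' 0/1/2 as the count of the ALTERNATIVE allele (0 = reference homozygote,
#' 1 = heterozygote, 2 = alternative homozygote), with missing calls allowed.
#' Per-marker alternative-allele frequencies and call rates are computed on
#' the non-missing calls.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns;
#'   values in \{0, 1, 2, NA\} unless `validate = FALSE` (mean-imputed
#'   matrices hold fractional dosages).
#' @param individual_ids,marker_ids unique labels; default to dimnames.
#' @param validate check that all values are in \{0, 1, 2, NA\}.
#' @return an object of class `genotype_matrix` with fields `dosages`,
#'   `individual_ids`, `marker_ids`, `allele_freqs`, `call_rates`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("a", "b"), c("m1", "m2"))))
#' g$allele_freqs
#' @export
genotype_matrix <- function(dosages, individual_ids = rownames(dosages),
                            marker_ids = colnames(dosages), validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(dosages)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids: ",
    paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids: ",
    paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  stopifnot(length(individual_ids) == nrow(dosages),
            length(marker_ids) == ncol(dosages))
  if (validate) {
    bad <- which(!(dosages %in% c(0, 1, 2) | is.na(dosages)))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(dosages)) + 1
      j <- ((bad[1] - 1) %/% nrow(dosages)) + 1
      stop(sprintf("invalid dosage %s at individual '%s', marker '%s' (must be 0, 1, 2 or NA)",
                   format(dosages[bad[1]]), individual_ids[i], marker_ids[j]))
    }
  }
  dimnames(dosages) <- list(individual_ids, marker_ids)
  out <- list(
    dosages = dosages,
    individual_ids = individual_ids,
    marker_ids = marker_ids,
    allele_freqs = colMeans(dosages, na.rm = TRUE) / 2,
    call_rates = colMeans(!is.na(dosages))
  )
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers\n",
              length(x$individual_ids), length(x$marker_ids)))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%; mean alt-allele frequency: %.3f\n",
              100 * miss, mean(x$allele_freqs, na.rm = TRUE)))
  if (isTRUE(attr(x, "imputed"))) cat("  (mean-imputed)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read a genotype dosage matrix
#'
#' Delimited format: tab-separated, header row of marker ids, first column of
#' individual ids, cells in \{0, 1, 2, NA\}. VCF format: plain-text VCF
#' restricted to biallelic sites with a GT field; the dosage counts
#' alternative alleles and missing GT becomes NA.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vcf"`.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                             colClasses = "character", na.strings = "NA")
    ids <- tab[[1]]
    if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m))
    ok <- num %in% c(0, 1, 2) | is.na(num)
    bad <- union(bad, which(!ok))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(m)) + 1
      j <- ((bad[1] - 1) %/% nrow(m)) + 1
      stop(sprintf("malformed genotype value '%s' at row '%s', column '%s'",
                   m[bad[1]], ids[i], colnames(m)[j]))
    }
    dimnames(num) <- list(ids, colnames(m))
    genotype_matrix(num)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(vcf)
    multi <- grepl(",", alt)
    if (any(multi)) {
      site <- paste(vcfR::getCHROM(vcf)[multi][1], vcfR::getPOS(vcf)[multi][1], sep = ":")
      stop("multiallelic VCF record at site ", site, "; only biallelic sites are supported")
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- colnames(gt)
    mk <- rownames(gt)
    if (is.null(mk) || anyNA(mk)) {
      mk <- paste(vcfR::getCHROM(vcf), vcfR::getPOS(vcf), sep = "_")
    }
    # count "1" alleles in GT strings like 0/1, 1|1; "." -> missing
    dos <- matrix(NA_real_, ncol(gt), nrow(gt), dimnames = list(ids, mk))
    clean <- gsub("\\|", "/", gt)
    known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2, "0" = 0, "1" = 1)
    vals <- known[clean]
    dos[] <- t(matrix(vals, nrow(gt), ncol(gt)))
    genotype_matrix(dos)
  }
}

#' Write a genotype matrix as tab-separated text
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(id = g$individual_ids, g$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter markers on minor allele frequency and call rate
#'
#' Keeps markers with `min(p, 1-p) >= min_maf` and call rate
#' `>= min_call_rate`; marker order is preserved. Markers with no calls at
#' all never pass.
#'
#' @param g a [genotype_matrix].
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @param min_call_rate minimum fraction of non-missing calls in `[0, 1]`.
#' @param quiet suppress the kept/dropped message.
#' @return the filtered [genotype_matrix].
#' @export
filter_markers <- function(g, min_maf = 0.05, min_call_rate = 0.6, quiet = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"),
            min_maf >= 0, min_maf <= 0.5, min_call_rate >= 0, min_call_rate <= 1)
  p <- g$allele_freqs
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf & g$call_rates >= min_call_rate
  if (!any(keep)) stop("all markers removed by filtering; lower min_maf/min_call_rate")
  if (!quiet) message(sprintf("filter_markers: kept %d of %d markers (dropped %d)",
                              sum(keep), length(keep), sum(!keep)))
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE], validate = FALSE)
  attr(out, "imputed") <- attr(g, "imputed")
  out
}

#' Mean-impute missing genotype calls
#'
#' Each missing cell is replaced by that marker's mean dosage over the
#' non-missing calls (a continuous value). Allele frequencies are unchanged
#' by construction.
#'
#' @param g a [genotype_matrix]; no marker may be entirely missing
#'   (filter first).
#' @return a complete [genotype_matrix] flagged as imputed.
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (!anyNA(d)) return(g)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu)) stop("marker(s) with no non-missing calls: ",
                      paste(utils::head(g$marker_ids[is.na(mu)], 5), collapse = ", "))
  idx <- which(is.na(d))
  d[idx] <- mu[((idx - 1) %/% nrow(d)) + 1]
  out <- genotype_matrix(d, validate = FALSE)
  attr(out, "imputed") <- TRUE
  out
}

#' Genotype and relationship-matrix summaries
#'
#' Observed heterozygosity (fraction of dosage-1 calls among non-missing
#' calls) and histograms of the diagonal (self-relatedness) and off-diagonal
#' relatedness of a relationship matrix.
#'
#' @param g a [genotype_matrix].
#' @param rel optional [rel_matrix] over the same individuals.
#' @param breaks passed to [graphics::hist] (computed, not drawn).
#' @return a list with `heterozygosity`, and when `rel` is given, `diag_hist`
#'   and `offdiag_hist` (objects of class `histogram`).
#' @export
grm_summaries <- function(g, rel = NULL, breaks = 30) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  het <- sum(d == 1, na.rm = TRUE) / sum(!is.na(d))
  out <- list(heterozygosity = het)
  if (!is.null(rel)) {
    v <- as.matrix(rel)
    out$diag_hist <- graphics::hist(diag(v), breaks = breaks, plot = FALSE)
    out$offdiag_hist <- graphics::hist(v[lower.tri(v)], breaks = breaks, plot = FALSE)
  }
  out
}
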