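#' Labelled symmetric relationship matrix
#'
#' @param values dense symmetric numeric matrix (checked within 1e-10).
#' @param labels ordered individual ids (default rownames).
#' @param kind one of `"pedigree_A"`, `"vanraden_G"`, `"weighted_Gw"`,
#'   `"custom"`.
#' @param jitter nonnegative scalar already added to the diagonal (0 if none).
#' @return an object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, labels = rownames(values),
                       kind = c("custom", "pedigree_A", "vanraden_G", "weighted_Gw"),
                       jitter = 0) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  check_symmetric(values, 1e-10, "relationship matrix")
  if (is.null(labels)) labels <- paste0("ind", seq_len(nrow(values)))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(values), jitter >= 0)
  if (anyDuplicated(labels)) stop("duplicate labels in relationship matrix")
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind, jitter = jitter),
            class = "rel_matrix")
}

#' @export
as.matrix.rel_matrix <- function(x, ...) x$values

#' @export
dim.rel_matrix <- function(x) dim(x$values)

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (%s): %d x %d, mean diagonal %.3f, jitter %g\n",
              x$kind, nrow(x$values), ncol(x$values), mean(diag(x$values)), x$jitter))
  invisible(x)
}

#' Subset a relationship matrix by labels
#' @param x a [rel_matrix]; @param ids labels to keep, in the given order.
#' @return a [rel_matrix].
#' @export
subset_rel <- function(x, ids) {
  stopifnot(inherits(x, "rel_matrix"))
  miss <- setdiff(ids, x$labels)
  if (length(miss)) stop("labels not in matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  rel_matrix(x$values[ids, ids, drop = FALSE], labels = ids, kind = x$kind, jitter = x$jitter)
}

# centered dosages and the VanRaden scaling pieces; frequencies always come
# from the analysed sample itself
centered_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosages)) stop("genotypes contain missing values; run impute_mean() first")
  p <- g$allele_freqs
  Z <- sweep(g$dosages, 2, 2 * p, `-`)
  list(Z = Z, p = p, denom = 2 * sum(p * (1 - p)))
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` with `Z = M - 2p` columnwise and
#' `p` the alternative-allele frequency computed from this sample.
#'
#' @param g a complete [genotype_matrix] (impute first), at least two
#'   polymorphic markers recommended.
#' @param jitter nonnegative value added to the diagonal (default 0; rank
#'   deficiency is handled inside [gblup] so no jitter is normally needed).
#' @return a [rel_matrix] of kind `"vanraden_G"`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2), 2, 1))
#' as.matrix(build_G(g))  # [[2, -2], [-2, 2]]
#' @export
build_G <- function(g, jitter = 0) {
  cg <- centered_genotypes(g)
  if (cg$denom <= 0) stop("all markers are monomorphic (zero VanRaden denominator)")
  G <- tcrossprod(cg$Z) / cg$denom
  if (jitter > 0) G <- G + diag(jitter, nrow(G))
  rel_matrix(G, labels = g$individual_ids, kind = "vanraden_G", jitter = jitter)
}

#' Weighted genomic relationship matrix
#'
#' `G_w = Z W Z' / sum(w_i)` with `W = diag(w)`; no heterozygosity factor in
#' the denominator, so with 0/1 weights this is the cross-product over
#' selected markers divided by the selected count. Its scale therefore
#' differs from the VanRaden `G` (mean diagonal near the mean `2p(1-p)` over
#' selected markers); correlations and prediction accuracies are unaffected.
#' Set `vanraden_scale = TRUE` to divide by `2 * sum(w_i p_i (1 - p_i))`
#' instead.
#'
#' @param g a complete [genotype_matrix].
#' @param w nonnegative weights, one per marker, `sum(w) > 0`.
#' @param vanraden_scale use the VanRaden denominator over selected markers.
#' @param jitter nonnegative value added to the diagonal.
#' @return a [rel_matrix] of kind `"weighted_Gw"`.
#' @export
build_Gw <- function(g, w, vanraden_scale = FALSE, jitter = 0) {
  cg <- centered_genotypes(g)
  w <- as.numeric(w)
  if (length(w) != ncol(g$dosages)) stop("weight vector length must equal the marker count")
  if (any(w < 0)) stop("negative marker weights are not allowed")
  if (sum(w) <= 0) stop("sum of marker weights is zero")
  denom <- if (vanraden_scale) 2 * sum(w * cg$p * (1 - cg$p)) else sum(w)
  if (denom <= 0) stop("zero denominator: selected markers are all monomorphic")
  Gw <- tcrossprod(sweep(cg$Z, 2, sqrt(w), `*`)) / denom
  if (jitter > 0) Gw <- Gw + diag(jitter, nrow(Gw))
  rel_matrix(Gw, labels = g$individual_ids, kind = "weighted_Gw", jitter = jitter)
}

#' Add diagonal jitter until a matrix factorizes
#'
#' Adds `eps` to the diagonal when the smallest eigenvalue is below `tol`,
#' recording the amount in the `jitter` field.
#'
#' @param x a [rel_matrix]; @param eps jitter step (default 1e-6);
#' @param tol eigenvalue tolerance (default 1e-8).
#' @return a positive semidefinite [rel_matrix].
#' @export
ensure_pd <- function(x, eps = 1e-6, tol = 1e-8) {
  stopifnot(inherits(x, "rel_matrix"))
  lam <- min(eigen(x$values, symmetric = TRUE, only.values = TRUE)$values)
  add <- 0
  while (lam + add < tol) add <- add + eps
  if (add > 0) {
    x$values <- x$values + diag(add, nrow(x$values))
    x$jitter <- x$jitter + add
  }
  x
}

#' Correlation between two relationship matrices
#'
#' Product-moment correlation of the vectorized lower triangle including the
#' diagonal (the comparison used to relate all-marker and selected-marker
#' genomic relationship matrices).
#'
#' @param a,b [rel_matrix] objects with identical labels in the same order.
#' @return a correlation in `[-1, 1]`.
#' @export
matrix_correlation <- function(a, b) {
  stopifnot(inherits(a, "rel_matrix"), inherits(b, "rel_matrix"))
  if (!identical(a$labels, b$labels)) stop("relationship matrices have different labels")
  keep <- lower.tri(a$values, diag = TRUE)
  stats::cor(a$values[keep], b$values[keep])
}

#' Write a labelled square matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that a read-back
#' round-trips bit-identically; labels containing the delimiter are quoted.
#'
#' @param m a [rel_matrix] or a labelled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  kind <- "custom"; jit <- 0
  if (inherits(m, "rel_matrix")) { kind <- m$kind; jit <- m$jitter; m <- m$values }
  check_symmetric(m, 1e-10, "matrix to write")
  tab <- data.frame(id = rownames(m),
                    matrix(vapply(m, function(v) format(v, digits = 17), ""),
                           nrow(m), ncol(m)),
                    check.names = FALSE)
  names(tab) <- c("id", colnames(m))
  utils::write.table(tab, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix written by [write_square_matrix]
#'
#' @param path file path.
#' @param kind relationship-matrix kind to stamp on the result.
#' @return a [rel_matrix].
#' @export
read_square_matrix <- function(path, kind = "custom") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- (m + t(m)) / 2  # symmetrize away printing round-off (none at 17 digits)
  rel_matrix(m, labels = tab[[1]], kind = kind)
}
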