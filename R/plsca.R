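#' Two-block canonical partial least squares (PLS-CA)
#'
#' Extracts paired latent variables maximizing the covariance between a
#' scaled marker block `X` and a scaled trait block `Y`. Per component k the
#' loading pair `(u_k, v_k)` is the leading singular pair of the deflated
#' cross-product `X_k' Y_k` (unit norms); the latent scores are
#' `t_k = X_k u_k`, `s_k = Y_k v_k`, and both blocks are canonically deflated
#' on their own scores, which makes within-block scores orthogonal across
#' components. Signs are fixed so the largest-magnitude entry of `v_k` is
#' positive.
#'
#' @param X numeric matrix, individuals x markers.
#' @param Y numeric matrix (or vector), individuals x traits, row-aligned
#'   with `X`.
#' @param ncomp number of components, at most `ncol(Y)`.
#' @param scale columns of both blocks are standardized to zero mean, unit
#'   variance (constant columns are an error). Disable only for pre-scaled
#'   input.
#' @return an object of class `plsca` with elements `u` (markers x
#'   components), `v` (traits x components), `scores_x`, `scores_y`,
#'   `score_cov` (per-component covariance of the paired scores), and the
#'   centering/scaling vectors used.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 20), 50)
#' Y <- cbind(X[, 1] - X[, 2] + rnorm(50, sd = .1), rnorm(50))
#' fit <- plsca(X, Y, ncomp = 2)
#' head(fit$u[, 1])
#' @export
plsca <- function(X, Y, ncomp = ncol(as.matrix(Y)), scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (ncomp > ncol(Y)) stop("ncomp (", ncomp, ") exceeds the number of traits (", ncol(Y), ")")
  if (ncomp < 1) stop("ncomp must be at least 1")
  if (anyNA(X) || anyNA(Y)) stop("PLS-CA requires complete X and Y blocks")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows")
  xc <- colMeans(X); ys <- colMeans(Y)
  if (scale) {
    xs <- apply(X, 2, stats::sd); yscl <- apply(Y, 2, stats::sd)
    if (any(xs == 0)) stop("constant marker column(s): ",
      paste(utils::head(colnames(X, do.NULL = FALSE)[xs == 0], 5), collapse = ", "))
    if (any(yscl == 0)) stop("constant trait column(s): ",
      paste(utils::head(colnames(Y, do.NULL = FALSE)[yscl == 0], 5), collapse = ", "))
    Xk <- sweep(sweep(X, 2, xc, `-`), 2, xs, `/`)
    Yk <- sweep(sweep(Y, 2, ys, `-`), 2, yscl, `/`)
  } else {
    xs <- rep(1, ncol(X)); yscl <- rep(1, ncol(Y))
    Xk <- sweep(X, 2, xc, `-`); Yk <- sweep(Y, 2, ys, `-`)
  }
  u <- matrix(NA_real_, ncol(X), ncomp,
              dimnames = list(colnames(X), paste0("C", seq_len(ncomp))))
  v <- matrix(NA_real_, ncol(Y), ncomp,
              dimnames = list(colnames(Y), paste0("C", seq_len(ncomp))))
  Tx <- matrix(NA_real_, n, ncomp); Sy <- matrix(NA_real_, n, ncomp)
  score_cov <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    M <- crossprod(Xk, Yk)
    sv <- svd(M, nu = 1, nv = 1)
    uk <- sv$u[, 1]; vk <- sv$v[, 1]
    j <- which.max(abs(vk))
    if (vk[j] < 0) { uk <- -uk; vk <- -vk }
    tk <- drop(Xk %*% uk); sk <- drop(Yk %*% vk)
    u[, k] <- uk; v[, k] <- vk
    Tx[, k] <- tk; Sy[, k] <- sk
    score_cov[k] <- sum(tk * sk) / (n - 1)
    # canonical deflation: each block regressed on its own score
    Xk <- Xk - tcrossprod(tk, crossprod(Xk, tk)) / sum(tk^2)
    Yk <- Yk - tcrossprod(sk, crossprod(Yk, sk)) / sum(sk^2)
  }
  structure(list(u = u, v = v, scores_x = Tx, scores_y = Sy,
                 score_cov = score_cov, ncomp = ncomp,
                 x_center = xc, x_scale = xs, y_center = ys, y_scale = yscl),
            class = "plsca")
}

#' @export
print.plsca <- function(x, ...) {
  cat(sprintf("plsca: %d marker x %d trait block, %d component(s)\n",
              nrow(x$u), nrow(x$v), x$ncomp))
  cat("  score covariances:", paste(signif(x$score_cov, 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-tailed percentile marker selection
#'
#' Selects markers whose loadings are at or above the empirical percentile
#' threshold, i.e. the positive tail (positive-pleiotropy scenario). The
#' threshold is the linearly interpolated order statistic at position
#' `h = 1 + (p/100)(n-1)`; ties at the threshold are all included. For
#' distinct loadings the selected count is `n - ceiling(h) + 1` when `h` is
#' an integer and `n - floor(h)` otherwise, so for example 9,697 loadings
#' truncated at the 90th percentile select 970 markers.
#'
#' @param loadings numeric vector of marker loadings for one component
#'   (length at least 2).
#' @param percentile integer percentile in (0, 100); the customary grid is
#'   90, 80, 70, 60, 50.
#' @return integer indices of the selected markers.
#' @export
select_one_tailed <- function(loadings, percentile) {
  n <- length(loadings)
  if (n < 2) stop("need at least 2 loadings")
  stopifnot(percentile > 0, percentile < 100)
  thr <- stats::quantile(loadings, percentile / 100, type = 7, names = FALSE)
  which(loadings >= thr)
}

#' Two-tailed percentile marker selection
#'
#' Union of the positive tail at `percentile` and the negative tail at
#' `100 - percentile` (both tails of the loading distribution, capturing
#' negative pleiotropy). At the 50th percentile with distinct loadings the
#' two tails meet at the median and all markers are selected.
#'
#' @inheritParams select_one_tailed
#' @return integer indices of the selected markers.
#' @export
select_two_tailed <- function(loadings, percentile) {
  n <- length(loadings)
  if (n < 2) stop("need at least 2 loadings")
  stopifnot(percentile > 0, percentile < 100)
  hi <- stats::quantile(loadings, percentile / 100, type = 7, names = FALSE)
  lo <- stats::quantile(loadings, (100 - percentile) / 100, type = 7, names = FALSE)
  which(loadings >= hi | loadings <= lo)
}

#' Combine per-component marker selections into 0/1 weights
#'
#' A marker receives weight 1 if it is selected in any of the included
#' components (set union), 0 otherwise; counts are therefore nondecreasing
#' in the number of components and in decreasing percentile.
#'
#' @param selections list of integer index sets, one per component.
#' @param n_markers total number of markers.
#' @param marker_ids optional names for the weight vector.
#' @return an object of class `marker_weights`: a named 0/1 numeric vector
#'   with attributes `n_selected` and `scenario`.
#' @export
combine_components <- function(selections, n_markers, marker_ids = NULL) {
  stopifnot(length(selections) >= 1)
  idx <- sort(unique(unlist(selections)))
  if (!length(idx)) stop("empty marker selection")
  if (any(idx < 1 | idx > n_markers)) stop("selection indices out of range")
  w <- numeric(n_markers)
  w[idx] <- 1
  if (!is.null(marker_ids)) names(w) <- marker_ids
  structure(w, n_selected = length(idx), class = c("marker_weights", "numeric"))
}

#' @export
print.marker_weights <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("marker_weights: %d of %d markers selected",
              attr(x, "n_selected"), length(x)))
  if (!is.null(sc)) cat(sprintf(" (%s, percentile %d, %d component(s))",
                                sc$mode, sc$percentile, sc$ncomp))
  cat("\n")
  invisible(x)
}

#' PLS-CA marker weights for a selection scenario
#'
#' Fits [plsca] with `ncomp` components, applies the percentile tail rule of
#' the scenario per component, and combines the per-component selections
#' into binary weights. One-tailed mode selects the highest positive
#' loadings (positive pleiotropy); two-tailed mode selects both tails.
#'
#' @param X individuals x markers dosage matrix (complete).
#' @param Y individuals x traits matrix of corrected phenotypes, row-aligned.
#' @param mode `"one_tailed"` or `"two_tailed"`.
#' @param percentile percentile in (0, 100).
#' @param ncomp number of PLS-CA components to include.
#' @param fit an optional pre-computed [plsca] fit to reuse across scenarios.
#' @return a `marker_weights` vector (see [combine_components]).
#' @export
scenario_weights <- function(X, Y, mode = c("one_tailed", "two_tailed"),
                             percentile = 90, ncomp = 1, fit = NULL) {
  mode <- match.arg(mode)
  if (is.null(fit)) fit <- plsca(X, Y, ncomp = ncomp)
  if (fit$ncomp < ncomp) stop("supplied plsca fit has fewer components than requested")
  sel <- lapply(seq_len(ncomp), function(k) {
    if (mode == "one_tailed") select_one_tailed(fit$u[, k], percentile)
    else select_two_tailed(fit$u[, k], percentile)
  })
  w <- combine_components(sel, n_markers = nrow(fit$u), marker_ids = rownames(fit$u))
  attr(w, "scenario") <- list(mode = mode, percentile = as.integer(percentile),
                              ncomp = as.integer(ncomp))
  w
}
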