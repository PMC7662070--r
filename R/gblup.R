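#' Bayesian GBLUP via Gibbs sampling
#'
#' Fits the mixed model `Y = X B + a + e` at the genotype level, where the
#' rows of `a` are additive genetic values with covariance
#' `Sigma_a %x% K` (Kronecker product; `K` is a pedigree A, VanRaden G, or
#' weighted G_w relationship matrix) and the rows of `e` are i.i.d.
#' `N(0, Sigma_e)`. With one trait this is classic (G)BLUP with variances
#' `sigma_a^2 K` and `sigma_e^2 I`, optionally extended with an extra
#' i.i.d. random effect (e.g. block-in-replicate). Estimation is by Gibbs
#' sampling with inverse-Wishart full conditionals for `Sigma_a` and
#' `Sigma_e` and a flat prior on fixed effects; the genetic values are
#' sampled in the eigenbasis of `K`, where their full conditional factorizes
#' over eigen-coordinates, so rank-deficient kernels are handled exactly
#' (zero-eigenvalue directions carry no genetic variance). Missing phenotype
#' cells — including individuals left entirely unphenotyped for prediction or
#' cross-validation masking — are imputed by data augmentation, so masked
#' individuals receive genomic breeding values purely through relatedness.
#'
#' Heritability is reported per retained sample as
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` and genetic correlations as
#' `r_G = sigma_axy / sqrt(sigma_ax^2 sigma_ay^2)`, then summarized
#' (sample-wise first, averaged after). Model fit is measured by the
#' deviance information criterion on the conditional likelihood
#' `p(Y | B, a, Sigma_e)` over observed cells.
#'
#' @param Y named numeric vector (one trait) or matrix with rownames
#'   (individuals x traits). Individuals present in `kernel` but absent from
#'   `Y`'s rows are treated as unphenotyped and predicted. `NA` cells allowed.
#' @param kernel a [rel_matrix] (or labelled symmetric matrix) covering all
#'   phenotyped individuals.
#' @param X optional fixed-effect design matrix with rownames matching kernel
#'   labels; default is a trait-wise intercept (the corrected phenotypes the
#'   two-stage flow feeds in need nothing more).
#' @param random optional factor (named by individual id, or aligned with the
#'   kernel labels) adding an i.i.d. random effect; single-trait models only.
#' @param niter,burnin,thin MCMC settings. Defaults are desk-scale
#'   (20,000 / 5,000 / 10); production-scale settings such as
#'   300,000 / 50,000 / 10 are passed the same way.
#' @param prior list overriding the weakly informative defaults: `nu_a`,
#'   `S_a`, `nu_e`, `S_e` (inverse-Wishart df and scale), `nu_b`, `s_b`
#'   (scaled-inverse-chi-squared for the extra effect). Defaults:
#'   `nu_a = nu_e = n_traits + 2`, scales centred so that each of the
#'   genetic and residual components has prior mean equal to half the
#'   phenotypic variance.
#' @param fix list fixing components instead of sampling them (testing and
#'   closed-form checks): any of `Sigma_a`, `Sigma_e`, `sigma_b`.
#' @param seed integer seed; fixed seed gives bit-identical chains.
#' @param keep_samples retain the per-draw samples in the fit object.
#' @param verbose print progress every 1000 iterations.
#' @return an object of class `gblup`; see [summary.gblup], [predict.gblup].
#' @examples
#' K <- rel_matrix(diag(10) * 0.5 + 0.5, kind = "custom")
#' y <- stats::setNames(rnorm(10), rownames(as.matrix(K)))
#' fit <- gblup(y, K, niter = 2200, burnin = 200, thin = 10, seed = 1)
#' fit
#' @export
gblup <- function(Y, kernel, X = NULL, random = NULL,
                  niter = 20000, burnin = 5000, thin = 10,
                  prior = NULL, fix = list(), seed = NULL,
                  keep_samples = TRUE, verbose = FALSE) {
  cl <- match.call()
  stopifnot(burnin < niter, thin >= 1)
  if (inherits(kernel, "rel_matrix")) {
    Kmat <- kernel$values
  } else {
    Kmat <- as.matrix(kernel)
    check_symmetric(Kmat, 1e-10, "kernel")
    if (is.null(rownames(Kmat))) rownames(Kmat) <- colnames(Kmat) <- paste0("ind", seq_len(nrow(Kmat)))
  }
  ids <- rownames(Kmat)
  n <- length(ids)

  # --- align phenotypes to kernel labels -------------------------------
  if (is.null(dim(Y))) {
    Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "trait"))
  }
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) {
    if (nrow(Y) != n) stop("unnamed Y must have one row per kernel label")
    rownames(Y) <- ids
  }
  extra <- setdiff(rownames(Y), ids)
  if (length(extra)) stop("phenotyped individuals missing from kernel: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  t_n <- ncol(Y)
  traits <- colnames(Y) %||% paste0("trait", seq_len(t_n))
  colnames(Y) <- traits
  Yfull <- matrix(NA_real_, n, t_n, dimnames = list(ids, traits))
  Yfull[rownames(Y), ] <- Y
  nobs_trait <- colSums(!is.na(Yfull))
  if (any(nobs_trait < 2)) stop("fewer than 2 non-missing records for trait(s): ",
                                paste(traits[nobs_trait < 2], collapse = ", "))

  # --- fixed design -----------------------------------------------------
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (!is.null(rownames(X))) X <- X[ids, , drop = FALSE]
    stopifnot(nrow(X) == n)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")

  # --- extra i.i.d. random effect (single-trait only) -------------------
  has_b <- !is.null(random)
  if (has_b) {
    if (t_n > 1) stop("the extra i.i.d. random effect is supported for single-trait models only")
    random <- if (!is.null(names(random))) factor(random[ids]) else factor(random)
    stopifnot(length(random) == n)
    blev <- levels(random)
    q <- length(blev)
    bidx <- as.integer(random)
    nb <- tabulate(bidx, q)
  }

  # --- priors -----------------------------------------------------------
  varP <- apply(Yfull, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(varP) | varP <= 0)) stop("phenotypic variance is zero or undefined for trait(s): ",
    paste(traits[!is.finite(varP) | varP <= 0], collapse = ", "))
  prior <- prior %||% list()
  nu_a <- prior$nu_a %||% (t_n + 2)
  nu_e <- prior$nu_e %||% (t_n + 2)
  S_a <- prior$S_a %||% (diag(0.5 * varP, t_n) * (nu_a - t_n - 1))
  S_e <- prior$S_e %||% (diag(0.5 * varP, t_n) * (nu_e - t_n - 1))
  S_a <- as.matrix(S_a); S_e <- as.matrix(S_e)
  nu_b <- prior$nu_b %||% 3
  s_b <- prior$s_b %||% (0.25 * varP[1])
  fix_a <- !is.null(fix$Sigma_a); fix_e <- !is.null(fix$Sigma_e); fix_b <- !is.null(fix$sigma_b)

  # --- kernel eigendecomposition ---------------------------------------
  ee <- eigen(Kmat, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  if (max(d) <= 0) stop("kernel is not positive semidefinite")
  d[d < max(d) * 1e-12] <- 0
  U <- ee$vectors
  npos <- sum(d > 0)
  Xt <- crossprod(U, X)
  XtXinv <- solve(crossprod(X))
  Lx <- t(chol(XtXinv))
  if (has_b) {
    Wmat <- matrix(0, n, q); Wmat[cbind(seq_len(n), bidx)] <- 1
    Wt <- crossprod(U, Wmat)
  }

  # --- missing-data bookkeeping ----------------------------------------
  obs <- !is.na(Yfull)
  mis_rows <- which(rowSums(!obs) > 0)
  has_mis <- length(mis_rows) > 0
  if (has_mis) {
    Umis <- U[mis_rows, , drop = FALSE]
    Xmis <- X[mis_rows, , drop = FALSE]
    pat_key <- apply(!obs[mis_rows, , drop = FALSE], 1, paste, collapse = "")
    patterns <- lapply(split(seq_along(mis_rows), pat_key), function(ri) {
      m <- which(!obs[mis_rows[ri[1]], ])
      list(rows_local = ri, rows_global = mis_rows[ri], m = m,
           o = setdiff(seq_len(t_n), m))
    })
  }
  Ycur <- Yfull
  trmean <- colMeans(Yfull, na.rm = TRUE)
  for (j in seq_len(t_n)) Ycur[!obs[, j], j] <- trmean[j]
  Ytil <- crossprod(U, Ycur)

  # --- state ------------------------------------------------------------
  if (!is.null(seed)) set.seed(seed)
  Sigma_a <- if (fix_a) as.matrix(fix$Sigma_a) else diag(0.5 * varP, t_n)
  Sigma_e <- if (fix_e) as.matrix(fix$Sigma_e) else diag(0.5 * varP, t_n)
  B <- matrix(0, p, t_n)
  if ("(Intercept)" %in% colnames(X)) B[match("(Intercept)", colnames(X)), ] <- trmean
  At <- matrix(0, n, t_n)
  if (has_b) { b <- numeric(q); sigma_b <- if (fix_b) fix$sigma_b else 0.25 * varP[1] }
  sqd <- sqrt(d)
  pos <- d > 0

  keep <- seq(burnin + thin, niter, by = thin)
  K_n <- length(keep)
  if (K_n < 1) stop("no retained samples; increase niter or decrease burnin/thin")
  samp <- list(
    Sigma_a = array(NA_real_, c(t_n, t_n, K_n), dimnames = list(traits, traits, NULL)),
    Sigma_e = array(NA_real_, c(t_n, t_n, K_n), dimnames = list(traits, traits, NULL)),
    B = array(NA_real_, c(p, t_n, K_n), dimnames = list(colnames(X), traits, NULL)),
    deviance = numeric(K_n)
  )
  if (has_b) samp$sigma_b <- numeric(K_n)
  At_sum <- matrix(0, n, t_n)
  B_sum <- matrix(0, p, t_n)
  Se_sum <- matrix(0, t_n, t_n)
  ki <- 0L
  nonpd_redraws <- 0L
  log2pi <- log(2 * pi)

  for (it in seq_len(niter)) {
    Le <- t(chol(Sigma_e))
    Linv <- forwardsolve(Le, diag(t_n))

    # 1. data augmentation for missing cells
    if (has_mis) {
      Amis <- Umis %*% At
      Mu <- Xmis %*% B + Amis
      Yold <- Ycur[mis_rows, , drop = FALSE]
      Ynew <- Yold
      for (pt in patterns) {
        r <- pt$rows_local; m <- pt$m; o <- pt$o; nr <- length(r)
        if (length(o)) {
          Soo_inv <- solve(Sigma_e[o, o, drop = FALSE])
          Cmo <- Sigma_e[m, o, drop = FALSE] %*% Soo_inv
          condvar <- Sigma_e[m, m, drop = FALSE] -
            Cmo %*% Sigma_e[o, m, drop = FALSE]
          eo <- Ycur[pt$rows_global, o, drop = FALSE] - Mu[r, o, drop = FALSE]
          cmean <- Mu[r, m, drop = FALSE] + eo %*% t(Cmo)
        } else {
          condvar <- Sigma_e
          cmean <- Mu[r, m, drop = FALSE]
        }
        Lc <- t(chol((condvar + t(condvar)) / 2))
        Ynew[r, m] <- cmean + matrix(stats::rnorm(nr * length(m)), nr) %*% t(Lc)
      }
      Ycur[mis_rows, ] <- Ynew
      Ytil <- Ytil + crossprod(Umis, Ynew - Yold)
    }

    # 2. fixed effects (flat prior)
    R0 <- Ytil - At
    if (has_b) R0 <- R0 - Wt %*% b
    Bhat <- XtXinv %*% crossprod(Xt, R0)
    B <- Bhat + Lx %*% matrix(stats::rnorm(p * t_n), p) %*% t(Le)

    # 3. genetic values, factorized over eigen-coordinates
    Rt <- R0 + At - Xt %*% B  # = Ytil - XtB (- Wtb)
    Cm <- Linv %*% Sigma_a %*% t(Linv)
    ec <- eigen((Cm + t(Cm)) / 2, symmetric = TRUE)
    lam <- pmax(ec$values, 0)
    Q <- ec$vectors
    Rw <- Rt %*% t(Linv) %*% Q
    S <- outer(d, lam, function(di, lj) di * lj / (1 + di * lj))
    W <- S * Rw + sqrt(S) * matrix(stats::rnorm(n * t_n), n)
    At <- W %*% t(Le %*% Q)

    # 4. extra i.i.d. random effect (single trait)
    if (has_b) {
      a_orig <- U %*% At
      r <- Ycur[, 1] - X %*% B[, 1] - a_orig[, 1]
      sums <- tapply(r, bidx, sum)
      sums <- as.numeric(sums[as.character(seq_len(q))])
      sums[is.na(sums)] <- 0
      pv <- 1 / (nb / Sigma_e[1, 1] + 1 / sigma_b)
      b <- stats::rnorm(q, pv * sums / Sigma_e[1, 1], sqrt(pv))
      if (!fix_b) {
        sigma_b <- (nu_b * s_b + sum(b^2)) / stats::rchisq(1, nu_b + q)
      }
    }

    # 5. genetic covariance
    if (!fix_a) {
      Ats <- At[pos, , drop = FALSE] / sqd[pos]
      Sc <- S_a + crossprod(Ats)
      Sigma_a <- riwish(nu_a + npos, Sc)
      while (!all(is.finite(Sigma_a)) || min(eigen(Sigma_a, symmetric = TRUE,
                                                  only.values = TRUE)$values) <= 0) {
        nonpd_redraws <- nonpd_redraws + 1L
        Sigma_a <- riwish(nu_a + npos, Sc)
      }
    }

    # 6. residual covariance
    Et <- Ytil - Xt %*% B - At
    if (has_b) Et <- Et - Wt %*% b
    if (!fix_e) {
      Sc <- S_e + crossprod(Et)
      Sigma_e <- riwish(nu_e + n, Sc)
      while (!all(is.finite(Sigma_e)) || min(eigen(Sigma_e, symmetric = TRUE,
                                                   only.values = TRUE)$values) <= 0) {
        nonpd_redraws <- nonpd_redraws + 1L
        Sigma_e <- riwish(nu_e + n, Sc)
      }
    }

    # 7. record retained draws
    if (it > burnin && (it - burnin) %% thin == 0) {
      ki <- ki + 1L
      samp$Sigma_a[, , ki] <- Sigma_a
      samp$Sigma_e[, , ki] <- Sigma_e
      samp$B[, , ki] <- B
      if (has_b) samp$sigma_b[ki] <- sigma_b
      At_sum <- At_sum + At
      B_sum <- B_sum + B
      Se_sum <- Se_sum + Sigma_e
      mu_extra <- if (has_b) Wmat %*% b else NULL
      samp$deviance[ki] <- deviance_retained(Ytil, Xt, B, At, Sigma_e,
                                             Ycur, X, U, obs, mis_rows, patterns_or_null(has_mis, patterns),
                                             mu_extra, Wt_or_null(has_b, if (has_b) Wt %*% b else NULL))
    }
    if (verbose && it %% 1000 == 0) message("iteration ", it, "/", niter)
  }

  a_mean <- U %*% (At_sum / K_n)
  dimnames(a_mean) <- list(ids, traits)
  B_mean <- B_sum / K_n
  dimnames(B_mean) <- list(colnames(X), traits)
  Se_mean <- Se_sum / K_n
  fitted <- X %*% B_mean + a_mean
  resid <- Yfull - fitted
  d_at_mean <- normal_deviance(Yfull, fitted, Se_mean)
  dic <- compute_dic(samp$deviance, d_at_mean)

  post <- summarize_posterior(samp, min_retained = min(200, K_n))
  out <- list(call = cl, ids = ids, traits = traits,
              n = n, n_traits = t_n,
              niter = niter, burnin = burnin, thin = thin, seed = seed,
              n_retained = K_n,
              posterior = post,
              gebv = a_mean, fixef = B_mean, fitted = fitted,
              residuals = resid,
              dic = dic$dic, pD = dic$pD, deviance_at_mean = d_at_mean,
              kernel_kind = if (inherits(kernel, "rel_matrix")) kernel$kind else "custom",
              nonpd_redraws = nonpd_redraws,
              ess = ess_components(samp))
  if (has_b) out$sigma_b <- mean(samp$sigma_b)
  if (keep_samples) out$samples <- samp
  class(out) <- "gblup"
  out
}

patterns_or_null <- function(has, patterns) if (has) patterns else NULL
Wt_or_null <- function(has, x) if (has) x else NULL

# inverse-Wishart draw
riwish <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  V <- solve(W)
  (V + t(V)) / 2
}

# conditional deviance over observed cells, computed mostly in the eigenbasis
deviance_retained <- function(Ytil, Xt, B, At, Sigma_e, Ycur, X, U, obs,
                              mis_rows, patterns, mu_extra, Wtb_til) {
  n <- nrow(Ytil); t_n <- ncol(Ytil)
  Le <- t(chol(Sigma_e))
  Linv <- forwardsolve(Le, diag(t_n))
  logdet <- 2 * sum(log(diag(Le)))
  Et <- Ytil - Xt %*% B - At
  if (!is.null(Wtb_til)) Et <- Et - Wtb_til
  total <- sum((Et %*% t(Linv))^2)
  D <- n * t_n * log(2 * pi) + n * logdet + total
  if (length(mis_rows)) {
    # remove the augmented rows' complete-vector contribution, then add back
    # their observed-cell contribution
    Amis <- U[mis_rows, , drop = FALSE] %*% At
    Emis <- Ycur[mis_rows, , drop = FALSE] - X[mis_rows, , drop = FALSE] %*% B - Amis
    if (!is.null(mu_extra)) Emis <- Emis - mu_extra[mis_rows, , drop = FALSE]
    D <- D - (length(mis_rows) * (t_n * log(2 * pi) + logdet) +
              sum((Emis %*% t(Linv))^2))
    for (pt in patterns) {
      o <- pt$o
      if (!length(o)) next
      Lo <- t(chol(Sigma_e[o, o, drop = FALSE]))
      Eo <- Emis[pt$rows_local, o, drop = FALSE]
      quad <- sum(forwardsolve(Lo, t(Eo))^2)
      D <- D + length(pt$rows_local) * (length(o) * log(2 * pi) + 2 * sum(log(diag(Lo)))) + quad
    }
  }
  D
}

#' Normal deviance over observed cells
#'
#' `-2 log p(Y | Mu, Sigma_e)` under row-wise `N(mu_i, Sigma_e)`, summed over
#' rows and restricted per row to the observed cells (missing cells are
#' marginalized, i.e. simply dropped).
#'
#' @param Y observed matrix with `NA` for missing cells.
#' @param Mu matrix of means, same shape.
#' @param Sigma_e residual covariance.
#' @return the deviance, a scalar.
#' @export
normal_deviance <- function(Y, Mu, Sigma_e) {
  Y <- as.matrix(Y); Mu <- as.matrix(Mu); Sigma_e <- as.matrix(Sigma_e)
  stopifnot(identical(dim(Y), dim(Mu)), nrow(Sigma_e) == ncol(Y))
  D <- 0
  pat <- apply(is.na(Y), 1, paste, collapse = "")
  for (key in unique(pat)) {
    rows <- which(pat == key)
    o <- which(!is.na(Y[rows[1], ]))
    if (!length(o)) next
    Lo <- t(chol(Sigma_e[o, o, drop = FALSE]))
    E <- Y[rows, o, drop = FALSE] - Mu[rows, o, drop = FALSE]
    quad <- sum(forwardsolve(Lo, t(E))^2)
    D <- D + length(rows) * (length(o) * log(2 * pi) + 2 * sum(log(diag(Lo)))) + quad
  }
  D
}

#' Deviance information criterion from sampled deviances
#'
#' `DIC = 2 * mean(D) - D(theta_bar)` and the effective number of parameters
#' `pD = mean(D) - D(theta_bar)`, where `D(theta_bar)` is the deviance at the
#' posterior means of the conditional-likelihood parameters.
#'
#' @param deviances per-retained-sample conditional deviances.
#' @param deviance_at_mean deviance evaluated at the posterior means.
#' @return list with elements `dic` and `pD`.
#' @export
compute_dic <- function(deviances, deviance_at_mean) {
  dbar <- mean(deviances)
  list(dic = 2 * dbar - deviance_at_mean, pD = dbar - deviance_at_mean)
}

#' Summarize retained Gibbs samples
#'
#' Heritability and genetic correlations are computed per retained draw from
#' the sampled `Sigma_a`, `Sigma_e` and then averaged (never from averaged
#' covariance components), with equal-tailed 95% credible intervals.
#'
#' @param samples list with arrays `Sigma_a` and `Sigma_e`
#'   (traits x traits x draws), as stored by [gblup].
#' @param level credible-interval level.
#' @param min_retained minimum number of retained draws required (default
#'   200).
#' @return list with posterior means/SDs/intervals for `Sigma_a`, `Sigma_e`,
#'   per-trait `h2` and the `r_G` matrix.
#' @export
summarize_posterior <- function(samples, level = 0.95, min_retained = 200) {
  Sa <- samples$Sigma_a; Se <- samples$Sigma_e
  K <- dim(Sa)[3]
  if (K < min_retained) stop("only ", K, " retained samples; at least ",
                             min_retained, " required for summaries")
  t_n <- dim(Sa)[1]
  traits <- dimnames(Sa)[[1]] %||% paste0("trait", seq_len(t_n))
  dSa <- matrix(apply(Sa, 3, function(m) diag(matrix(m, t_n))), nrow = t_n)
  dSe <- matrix(apply(Se, 3, function(m) diag(matrix(m, t_n))), nrow = t_n)
  h2 <- dSa / (dSa + dSe)
  rG <- array(apply(Sa, 3, function(m) stats::cov2cor(matrix(m, t_n))), c(t_n, t_n, K))
  alpha <- (1 - level) / 2
  qs <- function(x) stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
  list(
    Sigma_a = list(mean = apply(Sa, 1:2, mean), sd = apply(Sa, 1:2, stats::sd),
                   lower = apply(Sa, 1:2, function(x) qs(x)[1]),
                   upper = apply(Sa, 1:2, function(x) qs(x)[2])),
    Sigma_e = list(mean = apply(Se, 1:2, mean), sd = apply(Se, 1:2, stats::sd),
                   lower = apply(Se, 1:2, function(x) qs(x)[1]),
                   upper = apply(Se, 1:2, function(x) qs(x)[2])),
    h2 = data.frame(trait = traits, mean = rowMeans(h2),
                    sd = apply(h2, 1, stats::sd),
                    lower = apply(h2, 1, function(x) qs(x)[1]),
                    upper = apply(h2, 1, function(x) qs(x)[2]),
                    row.names = NULL),
    rG = list(mean = apply(rG, 1:2, mean), sd = apply(rG, 1:2, stats::sd),
              lower = apply(rG, 1:2, function(x) qs(x)[1]),
              upper = apply(rG, 1:2, function(x) qs(x)[2])),
    n_retained = K, level = level
  )
}

# crude effective sample size from the empirical autocorrelation function,
# truncated at the first nonpositive lag
ess_one <- function(x) {
  K <- length(x)
  if (stats::sd(x) == 0) return(K)
  ac <- stats::acf(x, lag.max = min(K - 1, 100), plot = FALSE)$acf[-1]
  cut <- which(ac <= 0)[1]
  if (!is.na(cut)) ac <- ac[seq_len(cut - 1)]
  K / (1 + 2 * sum(ac))
}

ess_components <- function(samp) {
  t_n <- dim(samp$Sigma_a)[1]
  vals <- c(
    sapply(seq_len(t_n), function(j) ess_one(samp$Sigma_a[j, j, ])),
    sapply(seq_len(t_n), function(j) ess_one(samp$Sigma_e[j, j, ]))
  )
  names(vals) <- c(paste0("Sigma_a.", seq_len(t_n)), paste0("Sigma_e.", seq_len(t_n)))
  vals
}
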