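#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("Bayesian %s fit (%d individual(s), %d trait(s), kernel: %s)\n",
              if (x$n_traits > 1) "multi-trait GBLUP" else "GBLUP",
              x$n, x$n_traits, x$kernel_kind))
  cat(sprintf("  MCMC: %d iterations, burn-in %d, thin %d, %d retained\n",
              x$niter, x$burnin, x$thin, x$n_retained))
  h2 <- x$posterior$h2
  cat("  posterior h2: ",
      paste(sprintf("%s = %.3f", h2$trait, h2$mean), collapse = ", "), "\n", sep = "")
  cat(sprintf("  DIC = %.2f (pD = %.1f)\n", x$dic, x$pD))
  invisible(x)
}

#' Posterior summary of a GBLUP fit
#'
#' Prints posterior means, SDs and credible intervals for heritabilities,
#' genetic correlations and the genetic/residual covariance matrices, plus
#' DIC and sampler diagnostics.
#'
#' @param object a [gblup] fit.
#' @param ... unused.
#' @return `object$posterior`, invisibly.
#' @export
summary.gblup <- function(object, ...) {
  p <- object$posterior
  cat("Posterior genetic parameters (", p$n_retained, " retained draws, ",
      round(100 * p$level), "% intervals)\n\n", sep = "")
  h2 <- p$h2
  cat("Heritability:\n")
  print(data.frame(trait = h2$trait, mean = round(h2$mean, 3), sd = round(h2$sd, 3),
                   lower = round(h2$lower, 3), upper = round(h2$upper, 3)), row.names = FALSE)
  if (object$n_traits > 1) {
    cat("\nGenetic correlations (posterior mean):\n")
    print(round(p$rG$mean, 3))
  }
  cat("\nGenetic covariance Sigma_a (posterior mean):\n")
  print(round(p$Sigma_a$mean, 4))
  cat("\nResidual covariance Sigma_e (posterior mean):\n")
  print(round(p$Sigma_e$mean, 4))
  cat(sprintf("\nDIC = %.2f, pD = %.2f\n", object$dic, object$pD))
  cat("Effective sample sizes: ",
      paste(sprintf("%s %.0f", names(object$ess), object$ess), collapse = ", "), "\n")
  if (object$nonpd_redraws > 0)
    cat("non-PD covariance draws rejected and redrawn:", object$nonpd_redraws, "\n")
  invisible(p)
}

#' @export
coef.gblup <- function(object, ...) object$fixef

#' Genomic estimated breeding values from a GBLUP fit
#'
#' Posterior mean breeding values; individuals whose phenotypes were masked
#' (or absent) are predicted purely through relatedness.
#'
#' @param object a [gblup] fit.
#' @param ids optional subset of individual ids.
#' @param ... unused.
#' @return matrix of GEBVs, individuals x traits.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  g <- object$gebv
  if (is.null(ids)) return(g)
  miss <- setdiff(ids, rownames(g))
  if (length(miss)) stop("unknown individual(s): ", paste(utils::head(miss, 5), collapse = ", "))
  g[ids, , drop = FALSE]
}

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' Trace plots of variance-component chains
#'
#' @param x a [gblup] fit with `keep_samples = TRUE`.
#' @param ... passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @export
plot.gblup <- function(x, ...) {
  if (is.null(x$samples)) stop("fit was run with keep_samples = FALSE")
  t_n <- x$n_traits
  va <- t(apply(x$samples$Sigma_a, 3, diag))
  ve <- t(apply(x$samples$Sigma_e, 3, diag))
  if (t_n == 1) { va <- t(va); ve <- t(ve) }
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(va, type = "l", lty = 1, xlab = "retained draw",
                    ylab = "genetic variance", main = "Sigma_a diagonal", ...)
  graphics::matplot(ve, type = "l", lty = 1, xlab = "retained draw",
                    ylab = "residual variance", main = "Sigma_e diagonal", ...)
  invisible(x)
}
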