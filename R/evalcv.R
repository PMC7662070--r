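#' K-fold cross-validation plan
#'
#' Uniformly random partition of the individuals into folds whose sizes
#' differ by at most one; deterministic under the seed.
#'
#' @param ids individual ids.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return a `cv_plan`: list with `folds` (integer fold per id, named),
#'   `n_folds`, `seed`.
#' @examples
#' plan <- make_folds(paste0("i", 1:691), 10, seed = 1)
#' table(plan$folds)  # nine folds of 69 and one of 70
#' @export
make_folds <- function(ids, n_folds = 10, seed = 1) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_folds > n) stop("n_folds exceeds the number of individuals")
  set.seed(seed)
  fold <- rep(seq_len(n_folds), length.out = n)[sample.int(n)]
  structure(list(folds = stats::setNames(fold, ids), n_folds = n_folds, seed = seed),
            class = "cv_plan")
}

#' Per-fold prediction accuracy
#'
#' Accuracy per trait is the product-moment correlation between the
#' reference breeding values and the cross-validated GEBVs of each fold's
#' validation individuals, computed per fold and then averaged (the SD is
#' across folds). Folds with fewer than 3 validation individuals give `NA`
#' with a warning.
#'
#' @param reference matrix of reference values (true breeding values on
#'   simulated data, or full-data EBVs on real data), individuals x traits.
#' @param predicted matrix of cross-validated GEBVs, same labels.
#' @param plan a [make_folds] plan.
#' @return list with `per_fold` (folds x traits), `mean`, `sd` per trait.
#' @export
accuracy_by_fold <- function(reference, predicted, plan) {
  reference <- as.matrix(reference); predicted <- as.matrix(predicted)
  ids <- names(plan$folds)
  stopifnot(all(ids %in% rownames(reference)), all(ids %in% rownames(predicted)))
  t_n <- ncol(reference)
  acc <- matrix(NA_real_, plan$n_folds, t_n,
                dimnames = list(NULL, colnames(reference)))
  for (f in seq_len(plan$n_folds)) {
    val <- ids[plan$folds == f]
    if (length(val) < 3) {
      warning("fold ", f, " has fewer than 3 validation individuals; accuracy undefined")
      next
    }
    for (j in seq_len(t_n)) {
      acc[f, j] <- stats::cor(reference[val, j], predicted[val, j])
    }
  }
  list(per_fold = acc,
       mean = colMeans(acc, na.rm = TRUE),
       sd = apply(acc, 2, stats::sd, na.rm = TRUE))
}

#' Cross-validated genomic prediction for one scenario
#'
#' For each fold: marker weights are estimated by PLS-CA on the TRAINING
#' individuals only (selection scenarios), the weighted relationship matrix
#' is built over all individuals' genotypes, the multi-trait (or univariate)
#' model is fitted with the validation individuals' phenotypes masked, and
#' their GEBVs are collected. Validation phenotypes can never reach the
#' marker-selection step (asserted internally).
#'
#' @param Y corrected phenotype matrix (genotypes x traits, rownames = ids).
#' @param genotypes complete [genotype_matrix] over the same ids (used for
#'   marker selection and genomic kernels).
#' @param plan a [make_folds] plan over the ids.
#' @param scenario list: `model` one of `"BLUP"`, `"GBLUP"`, `"MVBLUP"`,
#'   `"MVGBLUP"` (benchmarks) or `"selection"` with `mode`
#'   (`"one_tailed"`/`"two_tailed"`), `percentile` and `ncomp`.
#' @param A pedigree-based [rel_matrix] (required for BLUP/MVBLUP).
#' @param reference reference values for accuracy (true breeding values on
#'   simulated data; full-data pedigree EBVs on real data).
#' @param mcmc list of MCMC settings `niter`, `burnin`, `thin` (defaults
#'   3000 / 500 / 5 per fold).
#' @param seed integer seed; fold fits use substreams derived from it.
#' @param vanraden_scale passed to [build_Gw].
#' @return a `scenario_result`: list with the scenario, per-fold accuracies,
#'   per-trait mean and SD, the assembled cross-validated GEBV matrix,
#'   per-fold selected marker counts, and per-fold weights.
#' @export
run_cv <- function(Y, genotypes, plan, scenario, A = NULL, reference = NULL,
                   mcmc = list(niter = 3000, burnin = 500, thin = 5),
                   seed = 1, vanraden_scale = FALSE) {
  Y <- as.matrix(Y)
  ids <- names(plan$folds)
  stopifnot(all(ids %in% rownames(Y)))
  Y <- Y[ids, , drop = FALSE]
  model <- scenario$model %||% "selection"
  univar <- model %in% c("BLUP", "GBLUP")
  if (univar && ncol(Y) > 1) stop("benchmark ", model, " is univariate; run per trait or pass one trait")
  needs_geno <- model %in% c("GBLUP", "MVGBLUP", "selection")
  if (needs_geno) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    if (anyNA(genotypes$dosages)) stop("genotypes must be complete; run impute_mean() first")
    stopifnot(all(ids %in% genotypes$individual_ids))
    gsub <- genotype_matrix(genotypes$dosages[ids, , drop = FALSE], validate = FALSE)
  }
  if (model %in% c("BLUP", "MVBLUP")) {
    if (is.null(A)) stop("scenario ", model, " needs the pedigree relationship matrix A")
    A <- subset_rel(A, ids)
  }
  full_kernel <- switch(model,
    BLUP = A, MVBLUP = A,
    GBLUP = build_G(gsub), MVGBLUP = build_G(gsub),
    selection = NULL)

  gebv <- matrix(NA_real_, length(ids), ncol(Y), dimnames = list(ids, colnames(Y)))
  n_selected <- integer(plan$n_folds)
  weights_by_fold <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    val <- ids[plan$folds == f]
    train <- setdiff(ids, val)
    if (model == "selection") {
      # leakage guard: marker selection sees training rows only
      stopifnot(length(intersect(train, val)) == 0)
      Xtrain <- gsub$dosages[train, , drop = FALSE]
      keep <- apply(Xtrain, 2, stats::var) > 0  # monomorphic-in-fold markers carry no signal
      w_sub <- scenario_weights(Xtrain[, keep, drop = FALSE], Y[train, , drop = FALSE],
                                mode = scenario$mode, percentile = scenario$percentile,
                                ncomp = scenario$ncomp)
      w <- numeric(ncol(gsub$dosages)); names(w) <- gsub$marker_ids
      w[keep] <- as.numeric(w_sub)
      n_selected[f] <- attr(w_sub, "n_selected")
      weights_by_fold[[f]] <- w
      kernel <- build_Gw(gsub, w, vanraden_scale = vanraden_scale)
    } else {
      kernel <- full_kernel
      n_selected[f] <- if (needs_geno) ncol(gsub$dosages) else NA_integer_
    }
    Ymask <- Y
    Ymask[val, ] <- NA
    fit <- gblup(Ymask, kernel,
                 niter = mcmc$niter %||% 3000, burnin = mcmc$burnin %||% 500,
                 thin = mcmc$thin %||% 5,
                 seed = substream_seed(seed, paste0("cvfold", f)),
                 keep_samples = FALSE)
    gebv[val, ] <- fit$gebv[val, , drop = FALSE]
  }
  acc <- if (!is.null(reference)) accuracy_by_fold(reference, gebv, plan) else NULL
  structure(list(scenario = scenario, model = model,
                 accuracy = acc, gebv = gebv,
                 n_selected = n_selected,
                 weights_by_fold = if (model == "selection") weights_by_fold else NULL,
                 plan = plan),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- x$scenario
  desc <- if (x$model == "selection")
    sprintf("selection (%s, P%d, C%d)", sc$mode, sc$percentile, sc$ncomp) else x$model
  cat("scenario_result:", desc, "\n")
  if (!is.null(x$accuracy)) {
    cat("  accuracy (mean across folds):",
        paste(sprintf("%s = %.3f (%.3f)", names(x$accuracy$mean),
                      x$accuracy$mean, x$accuracy$sd), collapse = ", "), "\n")
  }
  if (x$model == "selection")
    cat("  selected markers per fold:", paste(x$n_selected, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the scenario grid
#'
#' The four benchmarks (BLUP, GBLUP, MVBLUP, MVGBLUP) plus every
#' mode x percentile x components cell.
#'
#' @param modes character subset of `c("one_tailed", "two_tailed")`.
#' @param percentiles integer percentiles (customarily 90, 80, 70, 60, 50).
#' @param components component counts.
#' @return data.frame with columns scenario, model, mode, percentile, ncomp.
#' @export
scenario_grid <- function(modes = c("one_tailed", "two_tailed"),
                          percentiles = c(90, 80, 70, 60, 50),
                          components = 1:2) {
  bench <- data.frame(scenario = c("BLUP", "GBLUP", "MVBLUP", "MVGBLUP"),
                      model = c("BLUP", "GBLUP", "MVBLUP", "MVGBLUP"),
                      mode = NA_character_, percentile = NA_integer_,
                      ncomp = NA_integer_, stringsAsFactors = FALSE)
  cells <- expand.grid(mode = modes, percentile = as.integer(percentiles),
                       ncomp = as.integer(components),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$model <- "selection"
  cells$scenario <- sprintf("%s_P%d_C%d",
                            ifelse(cells$mode == "one_tailed", "MVGBLUP1", "MVGBLUP2"),
                            100 - cells$percentile, cells$ncomp)
  rbind(bench, cells[, c("scenario", "model", "mode", "percentile", "ncomp")])
}

#' Run the full scenario grid with cross-validation and DIC ranking
#'
#' Executes every scenario in the grid: cross-validated accuracy via
#' [run_cv] plus a full-data fit for the deviance information criterion
#' (the model-choice step). Cell failures are recorded and the grid
#' continues. Results are sorted by DIC with the best scenario first.
#'
#' @param Y corrected phenotype matrix (ids x traits).
#' @param genotypes complete [genotype_matrix].
#' @param plan a [make_folds] plan.
#' @param grid a [scenario_grid] data.frame (benchmarks are skipped when `A`
#'   is missing for pedigree scenarios or `Y` has several traits for
#'   univariate benchmarks — univariate benchmarks use the first trait).
#' @param A optional pedigree [rel_matrix].
#' @param reference reference values for accuracy.
#' @param mcmc,seed,vanraden_scale passed to [run_cv] and the full-data fits.
#' @return data.frame of class `scenario_table`: one row per scenario with
#'   n_selected (full data), DIC, pD, per-trait accuracy mean and SD, and an
#'   `error` column for failed cells; the per-scenario `scenario_result`s
#'   are attached as attribute `results`.
#' @export
run_scenario_grid <- function(Y, genotypes, plan, grid = scenario_grid(),
                              A = NULL, reference = NULL,
                              mcmc = list(niter = 3000, burnin = 500, thin = 5),
                              seed = 1, vanraden_scale = FALSE) {
  Y <- as.matrix(Y)
  traits <- colnames(Y) %||% paste0("trait", seq_len(ncol(Y)))
  ids <- names(plan$folds)
  rows <- vector("list", nrow(grid))
  results <- vector("list", nrow(grid))
  names(results) <- grid$scenario
  gsub <- genotype_matrix(genotypes$dosages[ids, , drop = FALSE], validate = FALSE)
  Xall <- gsub$dosages
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- data.frame(scenario = g$scenario, model = g$model, mode = g$mode,
                      percentile = g$percentile, ncomp = g$ncomp,
                      n_selected = NA_integer_, dic = NA_real_, pD = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    for (tr in traits) { row[[paste0("acc_", tr)]] <- NA_real_; row[[paste0("sd_", tr)]] <- NA_real_ }
    res <- tryCatch({
      Yuse <- if (g$model %in% c("BLUP", "GBLUP")) Y[, 1, drop = FALSE] else Y
      refuse <- if (!is.null(reference)) {
        if (g$model %in% c("BLUP", "GBLUP")) as.matrix(reference)[, 1, drop = FALSE] else reference
      } else NULL
      sc <- if (g$model == "selection")
        list(model = "selection", mode = g$mode, percentile = g$percentile, ncomp = g$ncomp)
      else list(model = g$model)
      cvres <- run_cv(Yuse, gsub, plan, sc, A = A, reference = refuse,
                      mcmc = mcmc, seed = seed, vanraden_scale = vanraden_scale)
      # full-data fit for DIC (the model-choice step uses the non-CV fit)
      if (g$model == "selection") {
        keep <- apply(Xall, 2, stats::var) > 0
        w_sub <- scenario_weights(Xall[, keep, drop = FALSE], Yuse[ids, , drop = FALSE],
                                  mode = g$mode, percentile = g$percentile, ncomp = g$ncomp)
        w <- numeric(ncol(Xall)); w[keep] <- as.numeric(w_sub)
        kernel <- build_Gw(gsub, w, vanraden_scale = vanraden_scale)
        row$n_selected <- attr(w_sub, "n_selected")
      } else {
        kernel <- switch(g$model, BLUP = , MVBLUP = subset_rel(A, ids),
                         GBLUP = , MVGBLUP = build_G(gsub))
        row$n_selected <- if (g$model %in% c("GBLUP", "MVGBLUP")) ncol(Xall) else NA_integer_
      }
      fit <- gblup(Yuse[ids, , drop = FALSE], kernel,
                   niter = mcmc$niter %||% 3000, burnin = mcmc$burnin %||% 500,
                   thin = mcmc$thin %||% 5,
                   seed = substream_seed(seed, paste0("full_", g$scenario)),
                   keep_samples = FALSE)
      row$dic <- fit$dic; row$pD <- fit$pD
      if (!is.null(cvres$accuracy)) {
        for (tr in colnames(Yuse)) {
          row[[paste0("acc_", tr)]] <- cvres$accuracy$mean[[tr]]
          row[[paste0("sd_", tr)]] <- cvres$accuracy$sd[[tr]]
        }
      }
      cvres
    }, error = function(e) { row$error <<- conditionMessage(e); NULL })
    rows[[i]] <- row
    results[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$dic), ]
  rownames(out) <- NULL
  attr(out, "results") <- results
  attr(out, "best") <- out$scenario[which.min(out$dic)]
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' Correlations of accuracy with DIC and selected marker count
#'
#' Per trait, the product-moment correlation across selection scenarios of
#' the mean prediction accuracy with the full-data DIC, and with the number
#' of selected markers. Constant columns give `NA` with a warning.
#'
#' @param results a `scenario_table` from [run_scenario_grid] (or any
#'   data.frame with columns dic, n_selected and acc_* columns).
#' @param selection_only restrict to marker-selection scenarios.
#' @return data.frame with columns trait, cor_dic, cor_n_markers.
#' @export
accuracy_dic_correlations <- function(results, selection_only = TRUE) {
  df <- as.data.frame(results)
  if (selection_only && "model" %in% names(df)) df <- df[df$model == "selection", , drop = FALSE]
  df <- df[!is.na(df$dic), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 scenarios")
  acc_cols <- grep("^acc_", names(df), value = TRUE)
  safe_cor <- function(x, y, what) {
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0) {
      warning("constant column; correlation with ", what, " undefined")
      return(NA_real_)
    }
    stats::cor(x, y, use = "complete.obs")
  }
  data.frame(trait = sub("^acc_", "", acc_cols),
             cor_dic = vapply(acc_cols, function(a) safe_cor(df[[a]], df$dic, "DIC"), 0),
             cor_n_markers = vapply(acc_cols, function(a) safe_cor(df[[a]], df$n_selected, "marker count"), 0),
             row.names = NULL)
}
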