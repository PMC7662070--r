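#' Read a phenotype/design table
#'
#' Tab-separated table with a header. `role_map` assigns each used column a
#' role: exactly one `"id"` column, any number of `"factor"` columns
#' (replicate, block-in-replicate, seed orchard, genotype/clone, ...), and at
#' least one `"trait"` column (numeric, `NA` allowed). Unmapped columns are
#' dropped with a warning.
#'
#' @param path file path.
#' @param role_map named character vector, names are column names and values
#'   are roles in `c("id", "factor", "trait")`.
#' @return a `data.frame` of class `phenotype_table` with attributes
#'   `id_col`, `factor_cols`, `trait_cols`.
#' @export
read_phenotypes <- function(path, role_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = "NA")
  phenotype_table(tab, role_map)
}

#' Construct a phenotype table from a data frame
#'
#' @param tab data frame.
#' @param role_map see [read_phenotypes].
#' @return a `phenotype_table`.
#' @export
phenotype_table <- function(tab, role_map) {
  stopifnot(is.character(role_map) || is.factor(role_map))
  role_map <- vapply(role_map, as.character, "")
  bad <- setdiff(role_map, c("id", "factor", "trait"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  id_col <- names(role_map)[role_map == "id"]
  if (length(id_col) != 1) stop("role_map must assign exactly one 'id' column")
  miss <- setdiff(names(role_map), names(tab))
  if (length(miss)) stop("columns not in table: ", paste(miss, collapse = ", "))
  unmapped <- setdiff(names(tab), names(role_map))
  if (length(unmapped)) warning("ignoring unmapped column(s): ",
                                paste(unmapped, collapse = ", "))
  factor_cols <- names(role_map)[role_map == "factor"]
  trait_cols <- names(role_map)[role_map == "trait"]
  if (!length(trait_cols)) stop("role_map must assign at least one 'trait' column")
  out <- tab[, names(role_map), drop = FALSE]
  out[[id_col]] <- as.character(out[[id_col]])
  for (f in factor_cols) out[[f]] <- factor(out[[f]])
  for (tr in trait_cols) {
    v <- out[[tr]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad)) stop(sprintf("non-numeric trait value '%s' in column '%s', row %d",
                                  v[bad[1]], tr, bad[1]))
    out[[tr]] <- num
  }
  structure(out, id_col = id_col, factor_cols = factor_cols, trait_cols = trait_cols,
            class = c("phenotype_table", "data.frame"))
}

#' Correct phenotypes for design effects
#'
#' Ordinary least squares fit of `y = X beta + e` per trait, where `X`
#' carries an intercept and the declared design factors. Two modes:
#' \describe{
#'   \item{residual_plus_intercept}{returns intercept + residual per
#'     observation, then averages to one record per genotype when a genotype
#'     factor with replicated ramets is given — the "corrected phenotypes"
#'     used for marker selection and kernel models.}
#'   \item{genotype_blues}{adds the genotype/clone factor to the design and
#'     returns the estimated genotype effects re-centred to the grand mean
#'     (one record per genotype) — clonal BLUEs.}
#' }
#'
#' @param pheno a [phenotype_table] (or data.frame with the same attributes).
#' @param factors character vector of design factor columns to correct for
#'   (subset of the table's factor columns); may be empty.
#' @param genotype name of the genotype/clone factor column (required for
#'   `genotype_blues`; used for averaging in the other mode when present).
#' @param mode correction mode, see above.
#' @return numeric matrix, genotypes (or ids) x traits, of corrected values.
#' @export
correct_phenotypes <- function(pheno, factors = character(),
                               genotype = NULL,
                               mode = c("residual_plus_intercept", "genotype_blues")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pheno, "phenotype_table"))
  id_col <- attr(pheno, "id_col")
  trait_cols <- attr(pheno, "trait_cols")
  all_factors <- attr(pheno, "factor_cols")
  if (length(setdiff(factors, all_factors)))
    stop("not declared as factors: ", paste(setdiff(factors, all_factors), collapse = ", "))
  if (mode == "genotype_blues") {
    if (is.null(genotype)) stop("genotype_blues mode requires a genotype factor")
    if (!genotype %in% all_factors) stop("'", genotype, "' is not a declared factor column")
  }
  group <- if (!is.null(genotype)) as.character(pheno[[genotype]]) else pheno[[id_col]]
  groups <- unique(group)
  out <- matrix(NA_real_, length(groups), length(trait_cols),
                dimnames = list(groups, trait_cols))
  for (tr in trait_cols) {
    y <- pheno[[tr]]
    obs <- !is.na(y)
    if (!any(obs)) { warning("trait '", tr, "' entirely missing; skipped"); next }
    dat <- droplevels(pheno[obs, , drop = FALSE])
    if (mode == "residual_plus_intercept") {
      form <- if (length(factors))
        stats::reformulate(factors, response = tr) else stats::as.formula(paste(tr, "~ 1"))
      fit <- stats::lm(form, data = dat)
      check_aliased(fit, tr)
      corrected <- stats::coef(fit)[["(Intercept)"]] + stats::resid(fit)
      agg <- tapply(corrected, group[obs], mean)
      out[names(agg), tr] <- agg
    } else {
      # explicit dummy coding so single-level factors cannot trip contrasts
      gfac <- droplevels(factor(dat[[genotype]]))
      D <- matrix(0, nrow(dat), nlevels(gfac),
                  dimnames = list(NULL, levels(gfac)))
      D[cbind(seq_len(nrow(dat)), as.integer(gfac))] <- 1
      for (f in setdiff(factors, genotype)) {
        ff <- droplevels(factor(dat[[f]]))
        if (nlevels(ff) >= 2) {
          Df <- stats::model.matrix(~ff)[, -1, drop = FALSE]
          colnames(Df) <- paste0(f, levels(ff)[-1])
          D <- cbind(D, Df)
        }
      }
      fit <- stats::lm.fit(D, dat[[tr]])
      if (fit$rank < ncol(D)) {
        stop("rank-deficient design for trait '", tr, "'; aliased columns: ",
             paste(colnames(D)[is.na(fit$coefficients)], collapse = ", "))
      }
      geff <- fit$coefficients[levels(gfac)]
      blue <- geff - mean(geff) + mean(dat[[tr]])
      out[names(blue), tr] <- blue
    }
  }
  out
}

check_aliased <- function(fit, trait) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design for trait '", trait, "'; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  invisible(TRUE)
}
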