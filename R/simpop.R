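#' Configuration for the family-structured population simulator
#'
#' Defines a breeding-trial-like population: unrelated founders with
#' marker-wise allele frequencies drawn uniformly, offspring generated by
#' Mendelian gene dropping through either full-sib families (controlled
#' crosses, as in a clonally replicated pine trial) or open-pollinated
#' half-sib families (each offspring gets a random pollen parent, recorded as
#' unknown), optional clonal replication (ramets), pleiotropic QTL
#' architectures with target per-trait heritabilities and a target genetic
#' correlation matrix, replicate/block design effects, and missing genotype
#' calls. Markers are unlinked: family co-segregation, not linkage, supplies
#' the relatedness signal genomic prediction exploits here.
#'
#' @param n_founders number of unrelated founders.
#' @param mating list: `type` is `"full_sib"` (with `n_families`,
#'   `n_per_family`) or `"half_sib_op"` (with `n_dams`, `n_per_dam`).
#' @param n_ramets clonal replicates per offspring genotype (>= 1).
#' @param n_markers marker count.
#' @param founder_freq length-2 vector, uniform bounds (0, 1) for founder
#'   alternative-allele frequencies.
#' @param n_qtl number of QTLs, sampled without replacement from the markers.
#' @param pleiotropy fraction of QTLs affecting more than one trait.
#' @param sign_flip probability that a pleiotropic QTL's effect on a
#'   secondary trait has its sign flipped (negative pleiotropy).
#' @param h2 per-trait target narrow-sense heritability in (0, 1), defined on
#'   design-corrected phenotypes (phenotypic variance is normalized to 1 per
#'   trait, so the additive variance equals `h2`).
#' @param rG target genetic correlation matrix (symmetric, unit diagonal,
#'   positive semidefinite).
#' @param residual_cor optional residual correlation matrix (default
#'   identity).
#' @param design list: `n_replicates`, `n_blocks_per_replicate`, `rep_sd`,
#'   `block_sd` (standard deviations of the replicate and block-in-replicate
#'   effects).
#' @param missing_rate genotype missingness rate in `[0, 1)`.
#' @param seed master seed for the simulation substreams.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 60,
                       mating = list(type = "full_sib", n_families = 30, n_per_family = 20),
                       n_ramets = 1,
                       n_markers = 2000,
                       founder_freq = c(0.1, 0.9),
                       n_qtl = 200,
                       pleiotropy = 0.5,
                       sign_flip = 0.3,
                       h2 = c(0.3, 0.3),
                       rG = diag(length(h2)),
                       residual_cor = NULL,
                       design = list(n_replicates = 2, n_blocks_per_replicate = 4,
                                     rep_sd = 0.5, block_sd = 0.3),
                       missing_rate = 0,
                       seed = 1) {
  rG <- as.matrix(rG)
  t_n <- length(h2)
  if (founder_freq[1] <= 0 || founder_freq[2] >= 1 || founder_freq[1] > founder_freq[2])
    stop("founder_freq bounds must satisfy 0 < lo <= hi < 1")
  stopifnot(n_founders >= 2, n_markers >= 1, n_qtl >= 1, n_qtl <= n_markers,
            n_ramets >= 1, missing_rate >= 0, missing_rate < 1,
            pleiotropy >= 0, pleiotropy <= 1, sign_flip >= 0, sign_flip <= 1,
            all(h2 > 0), all(h2 < 1),
            nrow(rG) == t_n, ncol(rG) == t_n)
  if (max(abs(diag(rG) - 1)) > 1e-12 || max(abs(rG - t(rG))) > 1e-12)
    stop("rG must be symmetric with unit diagonal")
  if (min(eigen(rG, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("rG is not positive semidefinite")
  if (!is.null(residual_cor)) {
    residual_cor <- as.matrix(residual_cor)
    stopifnot(nrow(residual_cor) == t_n)
  }
  mt <- mating$type %||% "full_sib"
  if (!mt %in% c("full_sib", "half_sib_op")) stop("mating$type must be 'full_sib' or 'half_sib_op'")
  structure(list(n_founders = n_founders, mating = mating, n_ramets = n_ramets,
                 n_markers = n_markers, founder_freq = founder_freq, n_qtl = n_qtl,
                 pleiotropy = pleiotropy, sign_flip = sign_flip, h2 = h2, rG = rG,
                 residual_cor = residual_cor, design = design,
                 missing_rate = missing_rate, seed = seed,
                 n_traits = t_n), class = "sim_config")
}

#' Mendelian gene dropping for one cross
#'
#' Offspring dosages from two parents' dosage vectors: each parent transmits
#' one allele per marker, independently across markers; a heterozygote
#' transmits the alternative allele with probability 1/2, a homozygote
#' deterministically.
#'
#' @param sire,dam numeric dosage vectors in \{0, 1, 2\} of equal length.
#' @param n_offspring number of offspring to generate.
#' @return matrix of offspring dosages, `n_offspring` x markers.
#' @examples
#' mendelian_cross(2, 0)  # always heterozygous
#' @export
mendelian_cross <- function(sire, dam, n_offspring = 1) {
  stopifnot(length(sire) == length(dam))
  m <- length(sire)
  matrix(stats::rbinom(n_offspring * m, 1, rep(sire / 2, each = n_offspring)) +
         stats::rbinom(n_offspring * m, 1, rep(dam / 2, each = n_offspring)),
         n_offspring, m)
}

#' Simulate founder and offspring genotypes with a pedigree
#'
#' Founders are drawn marker-wise `Binomial(2, p)` with `p ~ U(lo, hi)`;
#' offspring inherit one allele per marker from each parent, independently
#' across markers (unlinked loci). Missing calls are then applied uniformly
#' at random at `missing_rate`. The returned genotype matrix covers the
#' offspring (the phenotyped generation); the complete (pre-missingness)
#' dosages are kept alongside for ground truth.
#'
#' @param config a [sim_config].
#' @return list with `genotypes` (a [genotype_matrix] with missing calls),
#'   `complete` (the complete offspring dosage matrix), `pedigree` (a
#'   [pedigree] over founders and offspring; open-pollinated sires are
#'   unknown), and `founder_freqs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genotypes"))
  m <- config$n_markers
  p <- stats::runif(m, config$founder_freq[1], config$founder_freq[2])
  nf <- config$n_founders
  founders <- matrix(stats::rbinom(nf * m, 2, rep(p, each = nf)), nf, m)
  fid <- sprintf("FND%03d", seq_len(nf))
  rownames(founders) <- fid

  gamete <- function(parent_rows) {
    # one allele per marker; a heterozygote transmits alt with prob 1/2
    matrix(stats::rbinom(length(parent_rows), 1, parent_rows / 2),
           nrow(parent_rows), ncol(parent_rows))
  }

  mt <- config$mating
  if (mt$type == "full_sib") {
    nfam <- mt$n_families; npf <- mt$n_per_family
    if (2 * nfam > nf * (nf - 1)) stop("not enough founders for distinct crosses")
    crosses <- t(replicate(nfam, sample.int(nf, 2)))
    n_off <- nfam * npf
    sire_i <- rep(crosses[, 1], each = npf)
    dam_i <- rep(crosses[, 2], each = npf)
    oid <- sprintf("F%02dI%03d", rep(seq_len(nfam), each = npf), rep(seq_len(npf), nfam))
    ped_sire <- fid[sire_i]
    ped_dam <- fid[dam_i]
  } else {
    ndam <- mt$n_dams; npd <- mt$n_per_dam
    if (ndam >= nf) stop("n_dams must be smaller than n_founders")
    dams <- sample.int(nf, ndam)
    males <- setdiff(seq_len(nf), dams)
    n_off <- ndam * npd
    dam_i <- rep(dams, each = npd)
    sire_i <- sample(males, n_off, replace = TRUE)  # random pollen parent
    oid <- sprintf("D%02dI%03d", rep(seq_len(ndam), each = npd), rep(seq_len(npd), ndam))
    ped_sire <- rep(NA_character_, n_off)  # pollen parent unrecorded
    ped_dam <- fid[dam_i]
  }
  off <- gamete(founders[sire_i, , drop = FALSE]) + gamete(founders[dam_i, , drop = FALSE])
  rownames(off) <- oid
  colnames(off) <- sprintf("M%05d", seq_len(m))

  ped <- suppressWarnings(pedigree(c(fid, oid),
                                   c(rep(NA, nf), ped_sire),
                                   c(rep(NA, nf), ped_dam)))
  observed <- off
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(observed)) < config$missing_rate
    observed[mask] <- NA
  }
  list(genotypes = genotype_matrix(observed),
       complete = off,
       pedigree = ped,
       founder_freqs = p)
}

#' Build a pleiotropic QTL effect matrix matched to target genetic covariance
#'
#' QTLs are sampled without replacement from the markers. Each QTL affects a
#' single random trait, except a `pleiotropy` fraction which affect all
#' traits with a shared effect size whose sign on each secondary trait is
#' flipped with probability `sign_flip` (negative pleiotropy). Raw effects
#' are then linearly rescaled through the empirical covariance of the true
#' breeding values so that the realized genetic covariance matches
#' `diag(sqrt(h2)) %*% rG %*% diag(sqrt(h2))` (phenotypic variance is 1 per
#' trait). When `pleiotropy = 0` and `rG` is diagonal the rescaling is
#' per-trait only, preserving the one-QTL-one-trait structure exactly;
#' otherwise an exact lower-triangular transform is used.
#'
#' @param config a [sim_config].
#' @param complete complete offspring dosage matrix (from
#'   [simulate_genotypes]).
#' @return list with `qtl_idx`, `effects` (QTLs x traits), `bv` (true
#'   breeding values, centred, individuals x traits), and `Sigma_a_realized`.
#' @export
build_effects <- function(config, complete) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "effects"))
  t_n <- config$n_traits
  m <- ncol(complete)
  poly <- which(apply(complete, 2, stats::var) > 0)
  if (length(poly) < config$n_qtl) stop("not enough polymorphic markers for n_qtl")
  qtl <- sort(sample(poly, config$n_qtl))
  q <- length(qtl)
  alpha <- matrix(0, q, t_n)
  plei <- stats::runif(q) < config$pleiotropy
  for (j in seq_len(q)) {
    if (t_n == 1 || !plei[j]) {
      tr <- sample.int(t_n, 1)
      alpha[j, tr] <- stats::rnorm(1)
    } else {
      base <- stats::rnorm(1)
      signs <- c(1, ifelse(stats::runif(t_n - 1) < config$sign_flip, -1, 1))
      primary <- sample.int(t_n, 1)
      ord <- c(primary, setdiff(seq_len(t_n), primary))
      alpha[j, ord] <- base * signs
    }
  }
  Zq <- scale(complete[, qtl, drop = FALSE], scale = FALSE)
  bv_raw <- Zq %*% alpha
  C <- stats::cov(bv_raw)
  sig_a <- sqrt(config$h2)  # phenotypic variance normalized to 1
  target <- diag(sig_a, t_n) %*% config$rG %*% diag(sig_a, t_n)
  diag_only <- config$pleiotropy == 0 &&
    (t_n == 1 || max(abs(config$rG[upper.tri(config$rG)])) == 0)
  if (diag_only) {
    Tm <- diag(sqrt(diag(target) / diag(C)), t_n)
  } else {
    Lc <- t(chol(C))
    Lt <- t(chol(target))
    Tm <- Lt %*% solve(Lc)
  }
  effects <- alpha %*% t(Tm)
  bv <- Zq %*% effects
  rownames(bv) <- rownames(complete)
  colnames(bv) <- colnames(effects) <- paste0("T", seq_len(t_n))
  list(qtl_idx = qtl, effects = effects, bv = bv,
       Sigma_a_realized = stats::cov(bv))
}

#' Simulate phenotypes from breeding values, design effects and residuals
#'
#' Each offspring genotype contributes `n_ramets` records. A record is
#' `replicate effect + block-in-replicate effect + breeding value +
#' residual`; ramets of the same genotype share the breeding value and
#' differ in residual and design placement (ramet r goes to replicate
#' `1 + (r-1) mod n_replicates` and a random block inside it). Residual
#' covariance is solved from the target heritabilities given the realized
#' genetic variances: `sigma_e^2 = sigma_a^2 (1 - h2) / h2` per trait, with
#' correlations from `residual_cor` (default none).
#'
#' @param sim output of [simulate_genotypes].
#' @param eff output of [build_effects].
#' @param config the [sim_config].
#' @return list with `phenotypes` (a [phenotype_table] with columns id,
#'   genotype, replicate, block and one column per trait) and `truth`
#'   (true breeding values, QTL effects, realized `Sigma_a`, `Sigma_e`,
#'   realized per-trait h2).
#' @export
simulate_phenotypes <- function(sim, eff, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "phenotypes"))
  bv <- eff$bv
  n <- nrow(bv); t_n <- ncol(bv)
  nr <- config$n_ramets
  des <- config$design
  n_rep <- des$n_replicates %||% 1
  n_blk <- des$n_blocks_per_replicate %||% 1
  rep_sd <- des$rep_sd %||% 0
  block_sd <- des$block_sd %||% 0

  sig_a2 <- diag(eff$Sigma_a_realized)
  sig_e2 <- sig_a2 * (1 - config$h2) / config$h2
  Rcor <- config$residual_cor %||% diag(t_n)
  Sigma_e <- diag(sqrt(sig_e2), t_n) %*% Rcor %*% diag(sqrt(sig_e2), t_n)
  Le <- t(chol((Sigma_e + t(Sigma_e)) / 2))

  rep_eff <- stats::rnorm(n_rep, 0, rep_sd)
  blk_eff <- matrix(stats::rnorm(n_rep * n_blk, 0, block_sd), n_rep, n_blk)

  N <- n * nr
  geno <- rep(rownames(bv), each = nr)
  ramet <- rep(seq_len(nr), n)
  # spread each genotype's ramets over distinct replicates, starting from a
  # random offset so single-ramet trials still fill every replicate
  offset <- rep(sample.int(n_rep, n, replace = TRUE), each = nr)
  repl <- 1 + (ramet - 1 + offset) %% n_rep
  blk <- sample.int(n_blk, N, replace = TRUE)
  resid <- matrix(stats::rnorm(N * t_n), N) %*% t(Le)
  Ypheno <- bv[geno, , drop = FALSE] + resid +
    rep_eff[repl] + blk_eff[cbind(repl, blk)]
  tab <- data.frame(id = if (nr == 1) geno else paste0(geno, "_r", ramet),
                    genotype = geno,
                    replicate = factor(repl),
                    block = factor(paste(repl, blk, sep = ".")),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(Ypheno))
  roles <- c(id = "id", genotype = "factor", replicate = "factor", block = "factor",
             stats::setNames(rep("trait", t_n), colnames(bv)))
  names(roles)[1:4] <- c("id", "genotype", "replicate", "block")
  pheno <- phenotype_table(tab, roles)
  truth <- list(bv = bv, qtl_idx = eff$qtl_idx, effects = eff$effects,
                Sigma_a = eff$Sigma_a_realized, Sigma_e = Sigma_e,
                h2_realized = sig_a2 / (sig_a2 + sig_e2))
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete family-structured dataset with known truth
#'
#' Chains [simulate_genotypes], [build_effects] and [simulate_phenotypes];
#' identical configs give identical output (all randomness flows from
#' `config$seed` through named substreams).
#'
#' @param config a [sim_config].
#' @return list with `genotypes` (with missing calls), `complete_dosages`,
#'   `pedigree`, `phenotypes`, `truth`, and the `config`.
#' @export
simulate_population <- function(config) {
  sim <- simulate_genotypes(config)
  eff <- build_effects(config, sim$complete)
  ph <- simulate_phenotypes(sim, eff, config)
  list(genotypes = sim$genotypes, complete_dosages = sim$complete,
       pedigree = sim$pedigree, phenotypes = ph$phenotypes,
       truth = ph$truth, config = config)
}
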