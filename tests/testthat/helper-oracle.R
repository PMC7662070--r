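# Independent oracle: multi-trait Gibbs sampler without the eigenbasis trick.
# Breeding values are drawn jointly from their full (n*t x n*t) conditional,
# built explicitly from Kronecker products. Only feasible for tiny n.
naive_mt_gibbs <- function(Y, K, niter, burnin, thin, seed,
                           nu_a = ncol(Y) + 2, nu_e = ncol(Y) + 2,
                           S_a = NULL, S_e = NULL) {
  set.seed(seed)
  n <- nrow(Y); t_n <- ncol(Y)
  varP <- apply(Y, 2, stats::var)
  if (is.null(S_a)) S_a <- diag(0.5 * varP, t_n) * (nu_a - t_n - 1)
  if (is.null(S_e)) S_e <- diag(0.5 * varP, t_n) * (nu_e - t_n - 1)
  Kinv <- solve(K)
  Sigma_a <- diag(0.5 * varP, t_n); Sigma_e <- diag(0.5 * varP, t_n)
  beta <- colMeans(Y)
  a <- matrix(0, n, t_n)
  In <- diag(n)
  riw <- function(df, S) { V <- solve(stats::rWishart(1, df, solve(S))[, , 1]); (V + t(V)) / 2 }
  keep <- seq(burnin + thin, niter, by = thin)
  Sa_sum <- matrix(0, t_n, t_n); Se_sum <- matrix(0, t_n, t_n); a_sum <- matrix(0, n, t_n)
  kcount <- 0
  for (it in seq_len(niter)) {
    # a | rest: precision Sigma_a^-1 (x) K^-1 + Sigma_e^-1 (x) I
    P <- kronecker(solve(Sigma_a), Kinv) + kronecker(solve(Sigma_e), In)
    rhs <- as.vector((sweep(Y, 2, beta) ) %*% solve(Sigma_e))
    Lp <- chol(P)
    mu <- backsolve(Lp, forwardsolve(t(Lp), rhs))
    av <- mu + backsolve(Lp, stats::rnorm(n * t_n))
    a <- matrix(av, n, t_n)
    # beta | rest (flat prior, intercept only)
    R <- Y - a
    Lb <- t(chol(Sigma_e / n))
    beta <- colMeans(R) + drop(Lb %*% stats::rnorm(t_n))
    # Sigma_a | a
    Sigma_a <- riw(nu_a + n, S_a + t(a) %*% Kinv %*% a)
    # Sigma_e | resid
    E <- Y - matrix(beta, n, t_n, byrow = TRUE) - a
    Sigma_e <- riw(nu_e + n, S_e + crossprod(E))
    if (it > burnin && (it - burnin) %% thin == 0) {
      Sa_sum <- Sa_sum + Sigma_a; Se_sum <- Se_sum + Sigma_e; a_sum <- a_sum + a
      kcount <- kcount + 1
    }
  }
  list(Sigma_a = Sa_sum / kcount, Sigma_e = Se_sum / kcount, a = a_sum / kcount)
}

# small complete genotype fixture
toy_genotypes <- function() {
  genotype_matrix(matrix(c(0, 2,
                           1, NA), 2, 2, byrow = TRUE,
                         dimnames = list(c("i1", "i2"), c("m1", "m2"))))
}

# family-structured simulated dataset reused across tests
small_population <- function(seed = 5, h2 = c(0.3, 0.5), rg = 0.45,
                             n_families = 15, n_per_family = 15,
                             n_markers = 600, n_qtl = 60) {
  R <- matrix(c(1, rg, rg, 1), 2)
  cfg <- sim_config(n_founders = 2 * n_families,
                    mating = list(type = "full_sib", n_families = n_families,
                                  n_per_family = n_per_family),
                    n_markers = n_markers, n_qtl = n_qtl,
                    pleiotropy = 0.5, sign_flip = 0.3, h2 = h2, rG = R,
                    design = list(n_replicates = 1, n_blocks_per_replicate = 1,
                                  rep_sd = 0, block_sd = 0),
                    missing_rate = 0, seed = seed)
  simulate_population(cfg)
}
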