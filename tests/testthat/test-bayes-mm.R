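test_that("phenotype correction removes design effects", {
  tab <- data.frame(id = paste0("i", 1:8),
                    geno = rep(paste0("g", 1:4), each = 2),
                    rep = rep(c("1", "2"), 4),
                    y = c(1, 2, 3, 4, 2, 3, 1, 2))
  roles <- c(id = "id", geno = "factor", rep = "factor", y = "trait")
  ph <- phenotype_table(tab, roles)

  # intercept-only correction is the identity (per observation), then averaged
  corr0 <- correct_phenotypes(ph, factors = character())
  expect_equal(unname(corr0[tab$id, "y"]), tab$y)

  # a pure replicate shift in a balanced design is removed exactly
  tab2 <- tab; tab2$y <- rnorm(8); tab2$y[tab2$rep == "2"] <- tab2$y[tab2$rep == "2"] + 5
  ph2 <- phenotype_table(tab2, roles)
  corr <- correct_phenotypes(ph2, factors = "rep")
  diffs <- tapply(corr[tab2$id, "y"], tab2$rep, mean)
  expect_equal(unname(diff(diffs)), 0, tolerance = 1e-12)

  # clonal BLUEs: 4 ramets {1,2,3,4} with intercept only -> 2.5
  tab3 <- data.frame(id = paste0("r", 1:4), clone = "c1", y = 1:4)
  ph3 <- phenotype_table(tab3, c(id = "id", clone = "factor", y = "trait"))
  blue <- correct_phenotypes(ph3, genotype = "clone", mode = "genotype_blues")
  expect_equal(unname(blue["c1", "y"]), 2.5)

  # aliased design columns are an error naming the offender
  tab4 <- tab; tab4$rep2 <- tab$rep
  ph4 <- phenotype_table(tab4, c(roles, rep2 = "factor"))
  expect_error(correct_phenotypes(ph4, factors = c("rep", "rep2")), "aliased")
})

test_that("posterior summaries apply the printed formulas sample-wise", {
  K <- 250
  Sa <- array(1, c(1, 1, K)); Se <- array(3, c(1, 1, K))
  s <- summarize_posterior(list(Sigma_a = Sa, Sigma_e = Se))
  expect_equal(s$h2$mean, 0.25)
  expect_equal(s$h2$sd, 0)

  Sa2 <- array(c(1, 0.5, 0.5, 1), c(2, 2, K))
  Se2 <- array(diag(2), c(2, 2, K))
  s2 <- summarize_posterior(list(Sigma_a = Sa2, Sigma_e = Se2))
  expect_equal(s2$rG$mean[1, 2], 0.5)

  # sample-wise h2 differs from the ratio of posterior means on skewed draws
  set.seed(41)
  sa <- rexp(K, 1); se <- rexp(K, 1)
  Sa3 <- array(sa, c(1, 1, K)); Se3 <- array(se, c(1, 1, K))
  s3 <- summarize_posterior(list(Sigma_a = Sa3, Sigma_e = Se3))
  expect_equal(s3$h2$mean, mean(sa / (sa + se)))
  expect_false(isTRUE(all.equal(s3$h2$mean, mean(sa) / (mean(sa) + mean(se)))))

  expect_error(summarize_posterior(list(Sigma_a = Sa[, , 1:50, drop = FALSE],
                                        Sigma_e = Se[, , 1:50, drop = FALSE])),
               "retained")
})

test_that("deviance and DIC follow their definitions", {
  # hand-computed univariate normal deviance on 3 points
  y <- matrix(c(1.2, -0.4, 2.2), 3, 1)
  mu <- matrix(c(1.0, 0.0, 2.0), 3, 1)
  s2 <- 0.7
  byhand <- -2 * sum(dnorm(y, mu, sqrt(s2), log = TRUE))
  expect_equal(normal_deviance(y, mu, matrix(s2)), byhand, tolerance = 1e-10)

  # bivariate with a missing cell: only observed cells contribute
  Y2 <- rbind(c(1, 2), c(0.5, NA))
  M2 <- rbind(c(0.8, 1.5), c(0, 0))
  S2 <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  e1 <- Y2[1, ] - M2[1, ]
  d1 <- 2 * log(2 * pi) + log(det(S2)) + drop(e1 %*% solve(S2) %*% e1)
  d2 <- log(2 * pi) + log(S2[1, 1]) + (Y2[2, 1] - M2[2, 1])^2 / S2[1, 1]
  expect_equal(normal_deviance(Y2, M2, S2), d1 + d2, tolerance = 1e-10)

  # a point-mass posterior has pD = 0 and DIC = D(theta)
  dic <- compute_dic(rep(byhand, 100), byhand)
  expect_equal(dic$pD, 0)
  expect_equal(dic$dic, byhand)
})

test_that("with variances fixed the posterior mean of beta matches GLS", {
  set.seed(42)
  pop <- small_population(seed = 43, n_families = 12, n_per_family = 10,
                          n_markers = 400, n_qtl = 50)
  A <- subset_rel(build_A(pop$pedigree), pop$genotypes$individual_ids)
  n <- nrow(as.matrix(A))
  X <- cbind("(Intercept)" = 1, cov = rnorm(n))
  rownames(X) <- pop$genotypes$individual_ids
  sg <- 0.4; se <- 0.6
  beta_true <- c(2, 0.5)
  Km <- as.matrix(A)
  L <- t(chol(Km + diag(1e-8, n)))
  y <- drop(X %*% beta_true + sqrt(sg) * (L %*% rnorm(n)) + rnorm(n, 0, sqrt(se)))
  names(y) <- rownames(X)
  V <- sg * Km + se * diag(n)
  gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  fit <- gblup(y, A, X = X, niter = 6000, burnin = 1000, thin = 5, seed = 7,
               fix = list(Sigma_a = sg, Sigma_e = se))
  bmean <- apply(fit$samples$B, 1, mean)
  bse <- apply(fit$samples$B, 1, sd) / sqrt(100)  # generous MC error bound
  expect_lt(max(abs(bmean - drop(gls)) / (10 * bse + 1e-6)), 1)
})

test_that("a structured kernel on pure noise concentrates h2 near zero", {
  # the null needs an identifiable structure: with a family-patterned kernel
  # and i.i.d. phenotypes, the genetic variance must go to zero
  pop <- small_population(seed = 90, n_families = 25, n_per_family = 16,
                          n_markers = 400, n_qtl = 50)
  A <- subset_rel(build_A(pop$pedigree), pop$genotypes$individual_ids)
  set.seed(44)
  y <- setNames(rnorm(400), pop$genotypes$individual_ids)
  fit <- gblup(y, A, niter = 4000, burnin = 1000, thin = 3, seed = 8)
  expect_lt(fit$posterior$h2$mean, 0.15)
})

test_that("the eigenbasis sampler agrees with a naive full-covariance sampler", {
  set.seed(45)
  ped <- pedigree(c("s1", "d1", "s2", "d2", paste0("o", 1:16)),
                  c(rep(0, 4), rep(c("s1", "s2"), each = 8)),
                  c(rep(0, 4), rep(c("d1", "d2"), each = 8)))
  A <- build_A(ped)
  ids <- paste0("o", 1:16)
  A <- subset_rel(A, ids)
  Km <- as.matrix(A) + diag(1e-6, 16)
  L <- t(chol(Km))
  Sa_true <- matrix(c(0.5, 0.2, 0.2, 0.5), 2)
  a <- (L %*% matrix(rnorm(32), 16)) %*% chol(Sa_true)
  Y <- a + matrix(rnorm(32, 0, sqrt(0.5)), 16)
  rownames(Y) <- ids
  Kpd <- rel_matrix(Km, labels = ids)

  fit <- gblup(Y, Kpd, niter = 30000, burnin = 5000, thin = 5, seed = 9)
  oracle <- naive_mt_gibbs(Y, Km, niter = 30000, burnin = 5000, thin = 5, seed = 10)
  expect_equal(fit$posterior$Sigma_a$mean, oracle$Sigma_a, tolerance = 0.12,
               ignore_attr = TRUE)
  expect_equal(fit$posterior$Sigma_e$mean, oracle$Sigma_e, tolerance = 0.12,
               ignore_attr = TRUE)
  expect_gt(cor(as.vector(fit$gebv), as.vector(oracle$a)), 0.98)
})

test_that("duplicated traits force a genetic correlation near one", {
  set.seed(46)
  pop <- small_population(seed = 47, n_families = 20, n_per_family = 15,
                          n_markers = 500, n_qtl = 60, h2 = c(0.5, 0.5))
  G <- build_G(pop$genotypes)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  Y2 <- cbind(t1 = Yc[, 1], t2 = Yc[, 1] + rnorm(nrow(Yc), 0, 0.01))
  fit <- gblup(Y2, G, niter = 6000, burnin = 1500, thin = 5, seed = 11)
  expect_gt(fit$posterior$rG$mean[1, 2], 0.98)
})

test_that("structurally missing individuals do not perturb the others", {
  pop <- small_population(seed = 48, n_families = 14, n_per_family = 12,
                          n_markers = 500, n_qtl = 60)
  G <- build_G(pop$genotypes)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  ids <- rownames(Yc)
  masked <- ids[1:20]
  kept <- setdiff(ids, masked)

  fit_sub <- gblup(Yc[kept, ], subset_rel(G, kept),
                   niter = 6000, burnin = 1000, thin = 5, seed = 12)
  Ymask <- Yc; Ymask[masked, ] <- NA
  fit_aug <- gblup(Ymask, G, niter = 6000, burnin = 1000, thin = 5, seed = 12)
  expect_gt(cor(as.vector(fit_sub$gebv[kept, ]), as.vector(fit_aug$gebv[kept, ])), 0.98)
  # masked individuals still receive relatedness-driven predictions
  expect_gt(cor(fit_aug$gebv[masked, 2], pop$truth$bv[masked, 2]), 0.2)
})

test_that("chains are reproducible under a fixed seed", {
  pop <- small_population(seed = 49, n_families = 8, n_per_family = 8,
                          n_markers = 200, n_qtl = 30)
  G <- build_G(pop$genotypes)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  f1 <- gblup(Yc, G, niter = 2500, burnin = 400, thin = 3, seed = 13)
  f2 <- gblup(Yc, G, niter = 2500, burnin = 400, thin = 3, seed = 13)
  expect_identical(f1$samples$Sigma_a, f2$samples$Sigma_a)
  expect_identical(f1$gebv, f2$gebv)
})

test_that("adding a duplicated irrelevant trait does not reduce pD", {
  pop <- small_population(seed = 50, n_families = 10, n_per_family = 10,
                          n_markers = 300, n_qtl = 40)
  G <- build_G(pop$genotypes)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  set.seed(51)
  Y3 <- cbind(Yc, dup = Yc[, 2] + rnorm(nrow(Yc), 0, 0.02))
  f2 <- gblup(Yc, G, niter = 4000, burnin = 1000, thin = 5, seed = 14)
  f3 <- gblup(Y3, G, niter = 4000, burnin = 1000, thin = 5, seed = 14)
  expect_gte(f3$pD, f2$pD)
})

test_that("the univariate sampler recovers heritability with a pedigree kernel", {
  set.seed(52)
  h2_hat <- sapply(1:6, function(r) {
    pop <- small_population(seed = 60 + r, h2 = c(0.5, 0.5), rg = 0,
                            n_families = 20, n_per_family = 20,
                            n_markers = 400, n_qtl = 80)
    A <- subset_rel(build_A(pop$pedigree), pop$genotypes$individual_ids)
    Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
    fit <- gblup(Yc[, 1], A, niter = 4000, burnin = 1000, thin = 3,
                 seed = 60 + r)
    fit$posterior$h2$mean
  })
  expect_equal(mean(h2_hat), 0.5, tolerance = 0.1)
})

test_that("the extra i.i.d. random effect recovers a block variance", {
  set.seed(53)
  pop <- small_population(seed = 54, h2 = c(0.4, 0.4), rg = 0,
                          n_families = 20, n_per_family = 15,
                          n_markers = 400, n_qtl = 60)
  A <- subset_rel(build_A(pop$pedigree), pop$genotypes$individual_ids)
  ids <- pop$genotypes$individual_ids
  blocks <- factor(sample(1:15, length(ids), replace = TRUE))
  names(blocks) <- ids
  beff <- rnorm(15, 0, sqrt(0.3))
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  y <- Yc[, 1] + beff[as.integer(blocks[rownames(Yc)])]
  fit <- gblup(y, A, random = blocks, niter = 6000, burnin = 1500, thin = 5,
               seed = 15)
  expect_lt(abs(fit$sigma_b - 0.3), 0.15)
  expect_error(gblup(Yc, A, random = blocks), "single-trait")
})
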