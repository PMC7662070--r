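test_that("fold assignment partitions ids with near-equal sizes", {
  plan <- make_folds(paste0("i", 1:691), 10, seed = 1)
  sizes <- sort(as.integer(table(plan$folds)))
  expect_equal(sizes, c(rep(69, 9), 70))
  expect_setequal(names(plan$folds), paste0("i", 1:691))

  plan2 <- make_folds(paste0("i", 1:691), 10, seed = 1)
  expect_identical(plan$folds, plan2$folds)
  expect_false(identical(plan$folds, make_folds(paste0("i", 1:691), 10, seed = 2)$folds))

  expect_error(make_folds(letters[1:5], 6), "exceeds")
  expect_error(make_folds(letters[1:5], 1), "at least 2")
})

test_that("accuracy aggregation is per fold, then averaged", {
  set.seed(61)
  ids <- paste0("i", 1:60)
  ref <- matrix(rnorm(120), 60, 2, dimnames = list(ids, c("a", "b")))
  plan <- make_folds(ids, 5, seed = 3)
  perfect <- accuracy_by_fold(ref, ref, plan)
  expect_equal(unname(perfect$mean), c(1, 1))
  expect_equal(unname(perfect$sd), c(0, 0))

  pred <- ref + matrix(rnorm(120), 60, 2)
  acc <- accuracy_by_fold(ref, pred, plan)
  manual <- sapply(1:5, function(f) {
    v <- ids[plan$folds == f]; cor(ref[v, 1], pred[v, 1])
  })
  expect_equal(unname(acc$mean[1]), mean(manual))
  expect_equal(unname(acc$sd[1]), sd(manual))

  tiny <- make_folds(ids[1:8], 4, seed = 4)
  w <- capture_warnings(res <- accuracy_by_fold(ref[1:8, ], pred[1:8, ], tiny))
  expect_true(any(grepl("fewer than 3", w)))
  expect_true(all(is.na(res$per_fold)))
})

test_that("the signed-rank test matches its exact and approximate references", {
  expect_warning(res <- wilcoxon_signed_rank(1:10, 1:10), "zero")
  expect_equal(res$p.value, 1)

  res <- wilcoxon_signed_rank(1:10 + 0.5, 1:10)
  expect_equal(res$p.value, 2 / 1024)

  set.seed(62)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }
  # beyond the exact range: normal approximation with continuity correction
  x <- rnorm(40); y <- rnorm(40)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)

  # null calibration at a reduced scale (the acceptance suite runs 10,000)
  set.seed(63)
  rej <- mean(replicate(2000, {
    wilcoxon_signed_rank(rnorm(10), rnorm(10))$p.value <= 0.05
  }))
  expect_gt(rej, 0.025); expect_lt(rej, 0.075)
})

test_that("the scenario grid enumerates benchmarks plus all cells", {
  g <- scenario_grid(modes = c("one_tailed", "two_tailed"),
                     percentiles = c(90, 80, 70, 60, 50), components = 1:5)
  expect_equal(nrow(g), 2 * 5 * 5 + 4)
  expect_equal(sum(g$model == "selection"), 50)
  expect_true(all(c("BLUP", "GBLUP", "MVBLUP", "MVGBLUP") %in% g$scenario))
})

test_that("accuracy-DIC correlations follow the direct formula", {
  tab <- data.frame(model = "selection",
                    dic = c(100, 90, 80), n_selected = c(10, 20, 30),
                    acc_T1 = c(0.1, 0.2, 0.3))
  out <- accuracy_dic_correlations(tab)
  expect_equal(out$cor_dic, -1)
  expect_equal(out$cor_n_markers, 1)

  tab2 <- data.frame(model = "selection", dic = c(5, 1, 3),
                     n_selected = c(7, 2, 9), acc_T1 = c(0.5, 0.1, 0.4))
  out2 <- accuracy_dic_correlations(tab2)
  expect_equal(out2$cor_dic, cor(tab2$acc_T1, tab2$dic))
  expect_equal(out2$cor_n_markers, cor(tab2$acc_T1, tab2$n_selected))

  tab3 <- tab; tab3$acc_T1 <- 0.2
  w <- capture_warnings(out3 <- accuracy_dic_correlations(tab3))
  expect_true(any(grepl("constant", w)))
  expect_true(is.na(out3$cor_dic))
  expect_error(accuracy_dic_correlations(tab[1:2, ]), "at least 3")
})

test_that("validation phenotypes cannot influence in-fold marker weights", {
  pop <- small_population(seed = 64, n_families = 10, n_per_family = 10,
                          n_markers = 300, n_qtl = 40)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  plan <- make_folds(rownames(Yc), 4, seed = 5)
  sc <- list(model = "selection", mode = "one_tailed", percentile = 80, ncomp = 1)
  mc <- list(niter = 600, burnin = 100, thin = 2)

  r1 <- run_cv(Yc, pop$genotypes, plan, sc, mcmc = mc, seed = 6)
  Ycorrupt <- Yc
  val1 <- names(plan$folds)[plan$folds == 1]
  Ycorrupt[val1, ] <- 1e3 * matrix(rnorm(length(val1) * 2), length(val1))
  r2 <- run_cv(Ycorrupt, pop$genotypes, plan, sc, mcmc = mc, seed = 6)
  expect_identical(r1$weights_by_fold[[1]], r2$weights_by_fold[[1]])

  # and identical runs are bit-identical under a fixed seed
  r3 <- run_cv(Yc, pop$genotypes, plan, sc, mcmc = mc, seed = 6)
  expect_identical(r1$gebv, r3$gebv)
  expect_identical(r1$n_selected, r3$n_selected)
})

test_that("all-marker two-tailed selection reproduces the all-marker benchmark", {
  pop <- small_population(seed = 65, n_families = 12, n_per_family = 12,
                          n_markers = 400, n_qtl = 50)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  plan <- make_folds(rownames(Yc), 4, seed = 7)
  mc <- list(niter = 2000, burnin = 400, thin = 4)
  base <- run_cv(Yc, pop$genotypes, plan, list(model = "MVGBLUP"),
                 reference = pop$truth$bv, mcmc = mc, seed = 8)
  allsel <- run_cv(Yc, pop$genotypes, plan,
                   list(model = "selection", mode = "two_tailed",
                        percentile = 50, ncomp = 1),
                   reference = pop$truth$bv, mcmc = mc, seed = 8)
  # kernels are proportional, so accuracies agree up to Monte-Carlo noise
  expect_lt(max(abs(base$accuracy$mean - allsel$accuracy$mean)), 0.05)
})

test_that("permuted phenotypes give accuracies centred at zero", {
  pop <- small_population(seed = 66, n_families = 30, n_per_family = 20,
                          n_markers = 600, n_qtl = 50, h2 = c(0.3, 0.3), rg = 0)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  set.seed(9)
  Yp <- Yc[sample.int(nrow(Yc)), , drop = FALSE]
  rownames(Yp) <- rownames(Yc)
  plan <- make_folds(rownames(Yc), 5, seed = 10)
  res <- run_cv(Yp, pop$genotypes, plan, list(model = "MVGBLUP"),
                reference = pop$truth$bv,
                mcmc = list(niter = 1500, burnin = 300, thin = 3), seed = 11)
  expect_lt(abs(mean(res$accuracy$mean)), 0.1)
  expect_lt(max(abs(res$accuracy$mean)), 0.25)
})

test_that("the multivariate model lifts a low-heritability trait", {
  # strongly correlated high-heritability companions lift the h2 = 0.1 trait
  set.seed(67)
  wins <- sapply(1:5, function(r) {
    R <- diag(3); R[1, 2] <- R[2, 1] <- 0.8; R[1, 3] <- R[3, 1] <- 0.8
    R[2, 3] <- R[3, 2] <- 0.7
    cfg <- sim_config(n_founders = 60,
                      mating = list(type = "full_sib", n_families = 30, n_per_family = 20),
                      n_markers = 1000, n_qtl = 50, pleiotropy = 0.6, sign_flip = 0.1,
                      h2 = c(0.1, 0.4, 0.4), rG = R,
                      design = list(n_replicates = 1, n_blocks_per_replicate = 1,
                                    rep_sd = 0, block_sd = 0),
                      missing_rate = 0, seed = 270 + r)
    pop <- simulate_population(cfg)
    Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
    plan <- make_folds(rownames(Yc), 5, seed = 270 + r)
    mc <- list(niter = 2000, burnin = 400, thin = 4)
    mv <- run_cv(Yc, pop$genotypes, plan, list(model = "MVGBLUP"),
                 reference = pop$truth$bv, mcmc = mc, seed = 270 + r)
    uv <- run_cv(Yc[, 1, drop = FALSE], pop$genotypes, plan, list(model = "GBLUP"),
                 reference = pop$truth$bv[, 1, drop = FALSE],
                 mcmc = mc, seed = 270 + r)
    mv$accuracy$mean[1] > uv$accuracy$mean[1]
  })
  expect_gte(sum(wins), 4)
})

test_that("the scenario grid runner ranks by DIC and survives cell failures", {
  pop <- small_population(seed = 68, n_families = 10, n_per_family = 10,
                          n_markers = 300, n_qtl = 40)
  Yc <- correct_phenotypes(pop$phenotypes, genotype = "genotype")
  A <- subset_rel(build_A(pop$pedigree), rownames(Yc))
  plan <- make_folds(rownames(Yc), 3, seed = 12)
  grid <- scenario_grid(modes = "two_tailed", percentiles = 80, components = 1)
  grid <- grid[grid$scenario %in% c("MVBLUP", "MVGBLUP", "MVGBLUP2_P20_C1", "BLUP"), ]
  tab <- run_cv_grid <- run_scenario_grid(Yc, pop$genotypes, plan, grid, A = A,
                                          reference = pop$truth$bv,
                                          mcmc = list(niter = 800, burnin = 200, thin = 2),
                                          seed = 13)
  expect_s3_class(tab, "scenario_table")
  expect_equal(nrow(tab), 4)
  done <- tab[!is.na(tab$dic), ]
  expect_equal(done$dic, sort(done$dic))
  expect_true(all(c("acc_T1", "sd_T1") %in% names(tab)))

  # a failing cell (missing A) is recorded, others proceed
  tab2 <- suppressWarnings(run_scenario_grid(Yc, pop$genotypes, plan, grid, A = NULL,
                                             reference = pop$truth$bv,
                                             mcmc = list(niter = 600, burnin = 150, thin = 2),
                                             seed = 13))
  expect_true(any(!is.na(tab2$error)))
  expect_true(any(is.na(tab2$error)))
})
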