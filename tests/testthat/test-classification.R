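# Inclusion filter, z-score, PCA, folds, SVM cross-validation, grid
# search and the feature-set sweep

test_that("inclusion filter reproduces the study-collective labels", {
  man <- apply_inclusion_filter(load_manifest(table1_path()))
  expect_equal(sum(man$label == "necrosis"), 6L)
  expect_equal(sum(man$label == "vital_tumor"), 4L)
  expect_equal(sum(man$label == "healthy"), 4L)
  expect_equal(sum(man$label == "excluded"), 0L)
  edge <- data.frame(pct_vital_tumor = c(50, 0, 59, 60, 0),
                     pct_necrosis = c(50, 0, 41, 40, 60),
                     pct_healthy = c(0, 100, 0, 0, 40))
  lab <- apply_inclusion_filter(edge)$label
  expect_equal(lab, c("excluded", "healthy", "excluded", "vital_tumor",
                      "necrosis"))
})

test_that("z-score normalization centers, scales, and transfers to held-out data", {
  x <- octex:::.with_seed(1, matrix(rnorm(200, 5, 3), 20, 10))
  x[, 3] <- 7                                   # zero-variance column
  z <- zscore_normalize(x)
  expect_equal(unname(colMeans(z$x)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z$x[, -3], 2, sd)), rep(1, 9), tolerance = 1e-12)
  expect_equal(z$x[, 3], rep(0, 20))
  z2 <- zscore_normalize(z$x)
  expect_equal(z2$x, z$x, tolerance = 1e-12)    # idempotent
  held <- octex:::.with_seed(2, matrix(rnorm(50, 5, 3), 5, 10))
  a <- zscore_normalize(held, z$center, z$scale)$x
  expect_equal(a, sweep(sweep(held, 2, z$center), 2, z$scale, "/"))
  expect_error(zscore_normalize(x[1, , drop = FALSE]), "2 rows")
})

test_that("PCA loadings are orthonormal with closed-form 2-D agreement", {
  # known covariance: leading eigenvector analytically
  S <- matrix(c(4, 1.5, 1.5, 1), 2, 2)
  ev <- eigen(S)
  x2 <- octex:::.with_seed(3,
    matrix(rnorm(4000), 2000, 2) %*% chol(S))
  fit2 <- pca_reduce(x2, 1)
  v <- fit2$loadings[, 1] * sign(fit2$loadings[1, 1])
  emp <- eigen(stats::cov(x2))$vectors[, 1]
  emp <- emp * sign(emp[1])
  expect_equal(v, emp, tolerance = 1e-10)
  expect_equal(abs(sum(v * ev$vectors[, 1])), 1, tolerance = 0.05)

  x <- octex:::.with_seed(4, matrix(rnorm(600), 60, 10) %*%
                            diag(sqrt(10:1)))
  fit <- pca_reduce(x, 0.95)
  L <- fit$loadings
  expect_equal(t(L) %*% L, diag(fit$n_components), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$variance_explained) <= 1e-12))
  expect_lte(sum(fit$variance_explained), fit$total_variance + 1e-9)
  expect_gte(sum(fit$variance_explained) / fit$total_variance, 0.95)
  k_minus1 <- sum(fit$variance_explained[-fit$n_components])
  expect_lt(k_minus1 / fit$total_variance, 0.95)  # minimal component count

  full <- pca_reduce(x, 1.0)
  recon <- full$scores %*% t(full$loadings)
  recon <- sweep(recon, 2, full$center, "+")
  expect_equal(recon, x, tolerance = 1e-8)
  expect_error(pca_reduce(x, 1.5), "pca_var")
})

test_that("folds are disjoint, exhaustive, stratified and reproducible", {
  labels <- rep(c("a", "b"), c(37, 63))
  f <- make_folds(labels, 10, seed = 5)
  expect_length(f, 100L)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) %in% 9:11))
  for (k in 1:10)                     # stratification within one of each
    expect_true(abs(sum(labels[f == k] == "a") - 3.7) <= 1)
  expect_identical(f, make_folds(labels, 10, seed = 5))
  expect_false(identical(f, make_folds(labels, 10, seed = 6)))
  set.seed(123)                               # global RNG untouched
  rs <- get(".Random.seed", envir = globalenv())
  make_folds(labels, 10, seed = 7)
  expect_identical(get(".Random.seed", envir = globalenv()), rs)
  expect_error(make_folds(labels[1:5], 10), "folds")
})

test_that("SVM cross-validation separates blobs and collapses under permutation", {
  n <- 60
  x <- octex:::.with_seed(6, rbind(matrix(rnorm(n * 2, 0, 0.3), n),
                                   matrix(rnorm(n * 2, 8, 0.3), n)))
  y <- rep(c("a", "b"), each = n)
  folds <- make_folds(y, 10, seed = 1)
  acc <- svm_cv_accuracy(x, y, cost = 1e4, gamma = 1e-2, folds,
                         zscore = TRUE, pca_var = 1.0)
  expect_equal(acc, 100)
  accs <- octex:::.with_seed(8, vapply(1:10, function(i) {
    yp <- sample(y)
    svm_cv_accuracy(x, yp, 1e4, 1e-2, make_folds(yp, 10, seed = i),
                    zscore = TRUE, pca_var = 1.0)
  }, numeric(1)))
  expect_lt(abs(mean(accs) - 50), 5)
  # identical rows with conflicting labels cannot beat the majority
  # fraction (class counts divisible by folds, so every fold is exact)
  xd <- matrix(1, 40, 3)
  yd <- rep(c("a", "b"), c(30, 10))
  accd <- svm_cv_accuracy(xd, yd, 10, 0.1, make_folds(yd, 5, seed = 2),
                          zscore = FALSE, pca_var = NULL)
  expect_lte(accd, 100 * 30 / 40 + 1e-9)
  expect_error(svm_cv_accuracy(x, rep("a", nrow(x)), 1, 0.1,
                               rep(1:5, length.out = nrow(x))),
               "two classes")
})

test_that("per-fold preprocessing differs from the leaky global fit", {
  # fold-specific mean shifts on a nuisance column: fitting z-score/PCA on
  # all rows absorbs shift structure the per-fold fit cannot see
  n <- 80
  x <- octex:::.with_seed(9, matrix(rnorm(n * 4), n, 4))
  y <- rep(c("a", "b"), each = n / 2)
  x[, 1] <- x[, 1] + 3 * (y == "b")
  folds <- make_folds(y, 5, seed = 3)
  for (k in 1:5) x[folds == k, 2] <- x[folds == k, 2] + 4 * k
  acc_clean <- svm_cv_accuracy(x, y, 100, 1, folds, pca_var = 0.95)
  acc_leaky <- svm_cv_accuracy(x, y, 100, 1, folds, pca_var = 0.95,
                               per_fold = FALSE)
  expect_false(isTRUE(all.equal(acc_clean, acc_leaky)))
})

test_that("grid search covers the configured lattice with correct best point", {
  cfg_def <- classification_config()
  expect_length(cfg_def$c_grid, 17L)
  expect_length(cfg_def$gamma_grid, 11L)
  expect_equal(range(cfg_def$c_grid), c(1, 1e16))
  expect_equal(range(cfg_def$gamma_grid), c(1e-8, 1e2))
  expect_error(classification_config(c_grid = c(0.1, 1)), "cost")
  expect_error(classification_config(gamma_grid = c(1e-9)), "gamma")

  tab <- random_feature_table(60, seed = 10)
  shift <- 4 * (tab$label == "necrosis")
  tab[, unlist(feature_schema(), use.names = FALSE)] <-
    tab[, unlist(feature_schema(), use.names = FALSE)] + shift
  cfg <- classification_config(c_grid = 10^c(0, 4, 8),
                               gamma_grid = 10^c(-4, -2, 0),
                               n_folds = 5, fold_seed = 11, pca_var = 0.9)
  res <- grid_search(tab, cfg)
  expect_equal(dim(res$accuracy_grid), c(3L, 3L))
  expect_true(all(res$accuracy_grid >= 0 & res$accuracy_grid <= 100))
  expect_equal(res$best_accuracy, max(res$accuracy_grid))
  expect_equal(res$accuracy_grid[match(res$best_c, cfg$c_grid),
                                 match(res$best_gamma, cfg$gamma_grid)],
               res$best_accuracy)
  # tie-break: no grid point with the same accuracy precedes (c, gamma)
  hits <- which(t(res$accuracy_grid) == res$best_accuracy)
  first <- hits[1] - 1
  expect_equal(res$best_c, cfg$c_grid[first %/% 3 + 1])
  expect_equal(res$best_gamma, cfg$gamma_grid[first %% 3 + 1])
  expect_true(all(res$region_above_threshold$accuracy >= cfg$threshold))
})

test_that("grid accuracy is invariant to row order at a fixed fold seed", {
  tab <- random_feature_table(40, seed = 12)
  sch <- unlist(feature_schema(), use.names = FALSE)
  tab[, sch] <- tab[, sch] + 3 * (tab$label == "necrosis")
  cfg <- classification_config(c_grid = c(1, 1e4), gamma_grid = c(1e-3, 1e-1),
                               n_folds = 5, fold_seed = 13, pca_var = 0.9)
  r1 <- grid_search(tab, cfg)
  perm <- octex:::.with_seed(14, sample(nrow(tab)))
  r2 <- grid_search(tab[perm, ], cfg)
  expect_identical(r1$accuracy_grid, r2$accuracy_grid)
})

test_that("the feature-set sweep ranks signal-bearing families first", {
  # signal lives only in the LBP block
  tab <- random_feature_table(48, seed = 15)
  lbp_cols <- feature_schema()$lbp
  tab[, lbp_cols] <- tab[, lbp_cols] + 2.5 * (tab$label == "necrosis")
  cfg <- classification_config(c_grid = c(1, 1e6), gamma_grid = c(1e-4, 1e-1),
                               n_folds = 4, fold_seed = 16, pca_var = 0.9)
  sw <- run_feature_set_sweep(tab, cfg, comparisons = "necrosis_vs_healthy")
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 30L)                 # 15 subsets x 2 z-score modes
  expect_equal(length(unique(sw$families)), 15L)
  has_lbp <- grepl("LBP", sw$families)
  expect_gt(min(sw$averaged[has_lbp]), max(sw$averaged[!has_lbp]))
})
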