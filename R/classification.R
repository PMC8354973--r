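# Sample inclusion filter, z-score / PCA preprocessing and RBF-SVM grid
# search with tenfold cross-validation.

#' Label samples by histological composition
#'
#' A sample is labeled `vital_tumor` if it contains at least 60% vital
#' tumor, `necrosis` if at least 60% necrotic tissue, `healthy` if at
#' least 90% healthy tissue, and `excluded` otherwise. (The two tumor
#' thresholds cannot be met simultaneously since percentages sum to 100;
#' vital tumor takes precedence.)
#'
#' @param records manifest data.frame from [load_manifest()].
#' @return the records with the `label` column filled in.
#' @export
apply_inclusion_filter <- function(records) {
  stopifnot(all(c("pct_vital_tumor", "pct_necrosis", "pct_healthy")
                %in% names(records)))
  lab <- rep("excluded", nrow(records))
  lab[records$pct_healthy >= 90] <- "healthy"
  lab[records$pct_necrosis >= 60] <- "necrosis"
  lab[records$pct_vital_tumor >= 60] <- "vital_tumor"
  records$label <- lab
  records
}

#' Classification configuration
#'
#' @param feature_families non-empty subset of `c("lbp", "rl", "h", "l")`.
#' @param zscore apply z-score normalization before PCA (default `TRUE`).
#' @param pca_var fraction of variance retained by PCA in (0, 1], or an
#'   explicit integer component count (default 0.95).
#' @param c_grid SVM cost values, within `[1, 1e16]`; default decade steps
#'   `10^(0:16)`.
#' @param gamma_grid RBF kernel widths, within `[1e-8, 1e2]`; default
#'   decade steps `10^(-8:2)`.
#' @param n_folds number of cross-validation folds (default 10).
#' @param fold_seed RNG seed for the fold assignment.
#' @param comparison which two-class problem to solve:
#'   `"tumorous_vs_healthy"` pools vital tumor and necrosis against
#'   healthy; the other two compare a single tumor class against healthy.
#' @param fold_level `"bscan"` allocates individual B-scan rows to folds
#'   (the default); `"sample"` keeps all B-scans of a tissue sample in the
#'   same fold (leave-samples-out).
#' @param per_fold_preprocess fit z-score and PCA on the training rows of
#'   each fold only (default `TRUE`); `FALSE` fits them once on the full
#'   table, which leaks test statistics into training and is provided for
#'   comparison only.
#' @param threshold accuracy threshold in percent delimiting the
#'   high-accuracy region of the grid (default 90).
#' @return list of class `classification_config`.
#' @export
classification_config <- function(feature_families = c("lbp", "rl", "h", "l"),
                                  zscore = TRUE, pca_var = 0.95,
                                  c_grid = 10^(0:16),
                                  gamma_grid = 10^(-8:2),
                                  n_folds = 10L, fold_seed = 1L,
                                  comparison = c("tumorous_vs_healthy",
                                                 "necrosis_vs_healthy",
                                                 "vital_vs_healthy"),
                                  fold_level = c("bscan", "sample"),
                                  per_fold_preprocess = TRUE,
                                  threshold = 90) {
  feature_families <- match.arg(feature_families,
                                c("lbp", "rl", "h", "l"), several.ok = TRUE)
  if (length(feature_families) == 0L)
    stop("`feature_families` must be non-empty")
  if (any(c_grid < 1 | c_grid > 1e16))
    stop("cost values must lie in [1, 1e16]")
  if (any(gamma_grid < 1e-8 | gamma_grid > 1e2))
    stop("gamma values must lie in [1e-8, 1e2]")
  if (pca_var <= 0 || (pca_var > 1 && pca_var != round(pca_var)))
    stop("`pca_var` must be in (0, 1] or an integer component count")
  structure(list(feature_families = feature_families, zscore = zscore,
                 pca_var = pca_var, c_grid = sort(c_grid),
                 gamma_grid = sort(gamma_grid),
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed),
                 comparison = match.arg(comparison),
                 fold_level = match.arg(fold_level),
                 per_fold_preprocess = per_fold_preprocess,
                 threshold = threshold),
            class = "classification_config")
}

# run expr with a private RNG state so callers' streams are untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified cross-validation folds
#'
#' Assigns each row to exactly one of `n_folds` folds; folds are disjoint,
#' exhaustive, and stratified by class label.
#'
#' @param labels class label per row.
#' @param n_folds number of folds.
#' @param seed RNG seed (the global RNG state is left untouched).
#' @return integer fold id (1..n_folds) per row.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  n <- length(labels)
  if (n < n_folds)
    stop("cannot build ", n_folds, " folds from ", n, " rows")
  folds <- integer(n)
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Z-score normalization
#'
#' Centers every feature column to mean 0 and scales it to standard
#' deviation 1. Zero-variance columns map to all-zeros. When `center` and
#' `scale` are supplied (statistics fitted on training data), they are
#' applied instead of being re-fitted, so held-out data can be transformed
#' without leakage.
#'
#' @param x numeric matrix (rows = B-scans).
#' @param center,scale optional fitted statistics to apply.
#' @return list with `x` (normalized matrix), `center` and `scale`.
#' @export
zscore_normalize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) {
    if (nrow(x) < 2L)
      stop("z-score normalization requires at least 2 rows")
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1  # zero-variance columns become all-zero
  }
  out <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  list(x = out, center = center, scale = scale)
}

#' Principal component analysis for dimensionality reduction
#'
#' Fits PCA (centered, unscaled) and retains the smallest number of
#' components whose cumulative explained variance reaches `pca_var`, or an
#' explicit component count.
#'
#' @param x numeric matrix.
#' @param pca_var retained variance fraction in (0, 1] (1 keeps all
#'   components) or an explicit integer component count > 1.
#' @return list of class `pca_fit`: `scores`, `loadings` (orthonormal
#'   columns), `center`, `variance_explained` (per retained component, in
#'   original variance units, non-increasing), `n_components`,
#'   `total_variance`.
#' @export
pca_reduce <- function(x, pca_var = 0.95) {
  x <- as.matrix(x)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_comp <- p$sdev^2
  total <- sum(var_comp)
  if (pca_var > 1) {
    if (pca_var != round(pca_var))
      stop("`pca_var` must be a variance fraction in (0, 1] or an integer",
           " component count > 1")
    k <- as.integer(min(pca_var, length(var_comp)))
  } else {
    if (pca_var <= 0)
      stop("`pca_var` must be a variance fraction in (0, 1] or an integer",
           " component count > 1")
    k <- which(cumsum(var_comp) / total >= pca_var - 1e-12)[1L]
    if (is.na(k)) k <- length(var_comp)
  }
  if (nrow(x) <= k)
    stop("PCA needs more rows (", nrow(x), ") than retained components (",
         k, ")")
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 center = p$center,
                 variance_explained = var_comp[seq_len(k)],
                 n_components = k, total_variance = total),
            class = "pca_fit")
}

#' Project new data onto a fitted PCA basis
#' @param fit a `pca_fit`.
#' @param x numeric matrix with the same columns as the training data.
#' @return score matrix.
#' @export
pca_project <- function(fit, x) {
  sweep(as.matrix(x), 2L, fit$center, "-") %*% fit$loadings
}

# preprocess train/test matrices: z-score (optional) then PCA
.preprocess_fold <- function(xtr, xte, zscore, pca_var) {
  if (zscore) {
    z <- zscore_normalize(xtr)
    xtr <- z$x
    xte <- zscore_normalize(xte, z$center, z$scale)$x
  }
  fit <- pca_reduce(xtr, pca_var)
  list(train = fit$scores, test = pca_project(fit, xte))
}

#' Cross-validated SVM accuracy at one grid point
#'
#' For each fold, z-score statistics (if enabled) and the PCA basis are
#' fitted on the training rows only and applied to the held-out rows; an
#' RBF-kernel SVM with the given cost and kernel width is trained and the
#' held-out rows are predicted. The per-fold accuracies (fraction of
#' correctly classified B-scans) are averaged and returned in percent.
#'
#' @param x numeric feature matrix (rows = B-scans).
#' @param labels two-class label per row.
#' @param cost SVM cost parameter.
#' @param gamma RBF kernel width.
#' @param folds integer fold id per row (see [make_folds()]).
#' @param zscore apply z-score normalization (default `TRUE`).
#' @param pca_var PCA retained variance / component count; `NULL` skips
#'   PCA.
#' @param per_fold fit preprocessing per training fold (default `TRUE`);
#'   `FALSE` fits once on all rows (leaky; for comparison only).
#' @return mean cross-validated accuracy in percent.
#' @export
svm_cv_accuracy <- function(x, labels, cost, gamma, folds,
                            zscore = TRUE, pca_var = 0.95,
                            per_fold = TRUE) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required, got ",
         paste(levels(labels), collapse = ", "))
  stopifnot(length(folds) == nrow(x), length(labels) == nrow(x))
  if (!per_fold) {
    if (zscore) x <- zscore_normalize(x)$x
    if (!is.null(pca_var)) x <- pca_reduce(x, pca_var)$scores
  }
  accs <- c()
  for (f in sort(unique(folds))) {
    te <- folds == f
    ytr <- labels[!te]
    if (nlevels(droplevels(ytr)) < 2L) {
      warning("fold ", f, " has single-class training data; skipped")
      next
    }
    if (per_fold && !is.null(pca_var)) {
      pp <- .preprocess_fold(x[!te, , drop = FALSE], x[te, , drop = FALSE],
                             zscore, pca_var)
      xtr <- pp$train; xte <- pp$test
    } else if (per_fold && zscore) {
      z <- zscore_normalize(x[!te, , drop = FALSE])
      xtr <- z$x
      xte <- zscore_normalize(x[te, , drop = FALSE], z$center, z$scale)$x
    } else {
      xtr <- x[!te, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    }
    m <- e1071::svm(xtr, ytr, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    pred <- stats::predict(m, xte)
    accs <- c(accs, mean(pred == labels[te]))
  }
  if (length(accs) == 0L) stop("no usable folds")
  100 * mean(accs)
}

#' Restrict a feature table to one two-class comparison
#'
#' Maps the three tissue labels onto the requested binary problem and
#' drops rows outside it: `necrosis_vs_healthy` and `vital_vs_healthy`
#' keep the named tumor class, `tumorous_vs_healthy` pools vital tumor and
#' necrosis into class `tumorous`.
#'
#' @param table feature table with a `label` column.
#' @param comparison one of `"tumorous_vs_healthy"`,
#'   `"necrosis_vs_healthy"`, `"vital_vs_healthy"`.
#' @return the subset table with a binary `label` column.
#' @export
comparison_subset <- function(table,
                              comparison = c("tumorous_vs_healthy",
                                             "necrosis_vs_healthy",
                                             "vital_vs_healthy")) {
  comparison <- match.arg(comparison)
  lab <- table$label
  keep <- switch(comparison,
    tumorous_vs_healthy = lab %in% c("vital_tumor", "necrosis", "healthy"),
    necrosis_vs_healthy = lab %in% c("necrosis", "healthy"),
    vital_vs_healthy = lab %in% c("vital_tumor", "healthy"))
  out <- table[keep, , drop = FALSE]
  if (comparison == "tumorous_vs_healthy")
    out$label[out$label != "healthy"] <- "tumorous"
  rownames(out) <- NULL
  out
}

#' Grid search over SVM cost and kernel width
#'
#' Evaluates [svm_cv_accuracy()] at every point of the (cost, gamma) grid
#' with a fold assignment fixed across grid points. Rows are put into a
#' canonical order (by sample id, then B-scan index) before folding, so
#' the result does not depend on the input row order.
#'
#' @param table feature table with binary `label` column (see
#'   [comparison_subset()]).
#' @param config a [classification_config()].
#' @return object of class `grid_search_result`: `accuracy_grid`
#'   (cost x gamma matrix, percent), `best_c`, `best_gamma`,
#'   `best_accuracy`, `region_above_threshold` (data.frame of grid points
#'   with accuracy >= `config$threshold`), `threshold`, `folds`.
#' @export
grid_search <- function(table, config = classification_config()) {
  table <- table[order(table$sample_id, table$bscan_index), , drop = FALSE]
  x <- feature_matrix(table, config$feature_families)
  labels <- table$label
  if (length(unique(labels)) != 2L)
    stop("grid search requires a binary-labeled table; got labels: ",
         paste(unique(labels), collapse = ", "))
  if (config$fold_level == "sample") {
    ids <- sort(unique(table$sample_id))
    id_lab <- table$label[match(ids, table$sample_id)]
    id_folds <- make_folds(id_lab, min(config$n_folds, length(ids)),
                           config$fold_seed)
    folds <- id_folds[match(table$sample_id, ids)]
  } else {
    folds <- make_folds(labels, config$n_folds, config$fold_seed)
  }
  nc <- length(config$c_grid); ng <- length(config$gamma_grid)
  grid <- matrix(NA_real_, nc, ng,
                 dimnames = list(format(config$c_grid, trim = TRUE),
                                 format(config$gamma_grid, trim = TRUE)))
  for (i in seq_len(nc))
    for (j in seq_len(ng))
      grid[i, j] <- svm_cv_accuracy(
        x, labels, cost = config$c_grid[i], gamma = config$gamma_grid[j],
        folds = folds, zscore = config$zscore, pca_var = config$pca_var,
        per_fold = config$per_fold_preprocess)
  # ties broken toward smallest cost, then smallest gamma
  best_idx <- which.max(t(grid))  # row-major traversal of `grid`
  bi <- (best_idx - 1L) %/% ng + 1L
  bj <- (best_idx - 1L) %% ng + 1L
  above <- which(grid >= config$threshold, arr.ind = TRUE)
  structure(list(
    accuracy_grid = grid,
    best_c = config$c_grid[bi],
    best_gamma = config$gamma_grid[bj],
    best_accuracy = grid[bi, bj],
    region_above_threshold = data.frame(
      c = config$c_grid[above[, 1L]],
      gamma = config$gamma_grid[above[, 2L]],
      accuracy = grid[above]),
    threshold = config$threshold,
    folds = folds),
    class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid_search_result: %d x %d grid, best accuracy %.2f%% at c=%g, gamma=%g\n",
              nrow(x$accuracy_grid), ncol(x$accuracy_grid),
              x$best_accuracy, x$best_c, x$best_gamma))
  cat(sprintf("  %d grid point(s) at or above %.0f%%\n",
              nrow(x$region_above_threshold), x$threshold))
  invisible(x)
}

#' Sweep over all feature-family subsets
#'
#' Runs [grid_search()] for each of the 15 non-empty subsets of the four
#' feature families, with and without z-score normalization, for one or
#' several two-class comparisons, and tabulates the best grid accuracy of
#' each combination. When several comparisons are run, a per-subset
#' average across comparisons is appended.
#'
#' @param table feature table with the three-class `label` column.
#' @param config a [classification_config()]; its `feature_families`,
#'   `zscore` and `comparison` fields are overridden by the sweep.
#' @param comparisons comparisons to sweep (default: the config's one).
#' @return data.frame of class `sweep_result` with columns `families`,
#'   `zscore`, one accuracy column per comparison, and `averaged`.
#' @export
run_feature_set_sweep <- function(table, config = classification_config(),
                                  comparisons = config$comparison) {
  fams <- c("lbp", "rl", "h", "l")
  subsets <- unlist(lapply(seq_along(fams), function(k)
    utils::combn(fams, k, simplify = FALSE)), recursive = FALSE)
  rows <- list()
  for (s in subsets) {
    for (z in c(FALSE, TRUE)) {
      accs <- vapply(comparisons, function(cmp) {
        cfg <- config
        cfg$feature_families <- s
        cfg$zscore <- z
        cfg$comparison <- cmp
        grid_search(comparison_subset(table, cmp), cfg)$best_accuracy
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        families = paste(toupper(s), collapse = "+"),
        zscore = z, t(accs), averaged = mean(accs))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(comparisons))] <- comparisons
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
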