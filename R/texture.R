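# Four texture-feature families on 32x32 tiles: local binary patterns,
# gray-level run-length statistics, Haralick co-occurrence features and
# Laws texture energies, averaged per B-scan.

#' Texture extraction parameters
#'
#' @param gray_levels quantization levels for the co-occurrence and
#'   run-length matrices (default 16). Tiles with fewer distinct
#'   intensities than `gray_levels` are quantized to their number of
#'   distinct values, so that e.g. a two-valued tile occupies two adjacent
#'   levels.
#' @param glcm_offsets list of `(dr, dc)` displacements for the
#'   co-occurrence matrix; default horizontal `(0,1)` and vertical `(1,0)`,
#'   symmetrized and averaged.
#' @param rl_directions run directions in degrees, subset of `c(0, 90)`;
#'   0 = runs along rows (lateral), 90 = along columns (depth). Matrices
#'   are averaged over directions.
#' @param lbp_radius,lbp_neighbors local-binary-pattern geometry; only the
#'   classic radius-1 8-neighbor variant (256 histogram bins) is supported.
#' @return list of class `texture_config`.
#' @export
texture_config <- function(gray_levels = 16L,
                           glcm_offsets = list(c(0L, 1L), c(1L, 0L)),
                           rl_directions = c(0, 90),
                           lbp_radius = 1L, lbp_neighbors = 8L) {
  if (gray_levels < 2L) stop("`gray_levels` must be >= 2")
  if (lbp_radius != 1L || lbp_neighbors != 8L)
    stop("only the radius-1, 8-neighbor LBP variant is supported")
  if (!all(rl_directions %in% c(0, 90)))
    stop("`rl_directions` must be a subset of c(0, 90)")
  for (off in glcm_offsets)
    if (all(off == 0L)) stop("co-occurrence offsets must be non-zero")
  structure(list(gray_levels = as.integer(gray_levels),
                 glcm_offsets = glcm_offsets,
                 rl_directions = rl_directions,
                 lbp_radius = 1L, lbp_neighbors = 8L),
            class = "texture_config")
}

.TILE <- 32L

.check_tile <- function(tile) {
  if (!is.matrix(tile) || nrow(tile) != .TILE || ncol(tile) != .TILE)
    stop("tile must be a ", .TILE, " x ", .TILE, " matrix")
}

#' Quantize a tile to discrete gray levels
#'
#' Uniform binning of the tile's min-max intensity range into
#' `min(gray_levels, number of distinct values)` levels `1..L`. A constant
#' tile maps to a single level.
#'
#' @param tile numeric matrix.
#' @param gray_levels maximum number of levels.
#' @return integer matrix of levels with attribute `"n_levels"`.
#' @export
quantize_tile <- function(tile, gray_levels = 16L) {
  v <- as.vector(tile)
  L <- min(as.integer(gray_levels), length(unique(v)))
  if (L <= 1L) {
    q <- matrix(1L, nrow(tile), ncol(tile))
    attr(q, "n_levels") <- 1L
    return(q)
  }
  mn <- min(v); mx <- max(v)
  q <- pmin(as.integer(floor((tile - mn) / (mx - mn) * L)) + 1L, L)
  q <- matrix(q, nrow(tile))
  attr(q, "n_levels") <- L
  q
}

# ---- local binary patterns --------------------------------------------

# clockwise from top-left; first neighbor is the most significant bit
.LBP_OFFSETS <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
                     c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
.LBP_WEIGHTS <- 2L^(7:0)

#' Local binary pattern histogram (256 features)
#'
#' For every interior pixel of the tile, an 8-bit code is formed from its
#' 8 neighbors taken clockwise from the top-left (bit set iff neighbor >=
#' center; the top-left neighbor is the most significant bit). The
#' normalized 256-bin histogram over all 30 x 30 interior pixels is
#' returned. A constant tile therefore puts all mass in bin 255.
#'
#' @param tile 32 x 32 numeric matrix.
#' @return numeric vector of length 256 summing to 1.
#' @export
lbp_features <- function(tile) {
  .check_tile(tile)
  inner <- 2:(.TILE - 1L)
  ctr <- tile[inner, inner]
  code <- matrix(0L, length(inner), length(inner))
  for (k in seq_along(.LBP_OFFSETS)) {
    off <- .LBP_OFFSETS[[k]]
    nb <- tile[inner + off[1L], inner + off[2L]]
    code <- code + .LBP_WEIGHTS[k] * (nb >= ctr)
  }
  h <- tabulate(as.vector(code) + 1L, nbins = 256L)
  h / sum(h)
}

# ---- run-length features ----------------------------------------------

# gray-level run-length matrix (levels x max run length) for runs along
# the rows of `q`
.glrlm_rows <- function(q, n_levels, max_len) {
  nr <- nrow(q)
  # flatten row-wise with a 0 separator so runs cannot cross rows
  v <- as.vector(rbind(t(q), 0L))
  r <- rle(v)
  keep <- r$values != 0L
  lev <- r$values[keep]
  len <- r$lengths[keep]
  counts <- tabulate((len - 1L) * n_levels + lev, nbins = n_levels * max_len)
  matrix(counts, nrow = n_levels, ncol = max_len)
}

#' Gray-level run-length statistics (7 features)
#'
#' Quantizes the tile ([quantize_tile()]), builds gray-level run-length
#' matrices for the configured directions, averages them, and emits seven
#' statistics: short-run emphasis (SRE), long-run emphasis (LRE),
#' gray-level non-uniformity (GLN), run-length non-uniformity (RLN), run
#' percentage (RP), and low-/high-gray-level run emphasis (LGRE, HGRE).
#'
#' @param tile 32 x 32 numeric matrix.
#' @param config a [texture_config()].
#' @return named numeric vector of length 7.
#' @export
runlength_features <- function(tile, config = texture_config()) {
  .check_tile(tile)
  q <- quantize_tile(tile, config$gray_levels)
  L <- attr(q, "n_levels")
  max_len <- .TILE
  mats <- lapply(config$rl_directions, function(d) {
    if (d == 0) .glrlm_rows(q, L, max_len) else .glrlm_rows(t(q), L, max_len)
  })
  M <- Reduce(`+`, mats) / length(mats)
  n_runs <- sum(M)
  n_pix <- length(q)
  j2 <- matrix((1:max_len)^2, L, max_len, byrow = TRUE)
  i2 <- matrix((1:L)^2, L, max_len)
  c(rl_sre = sum(M / j2) / n_runs,
    rl_lre = sum(M * j2) / n_runs,
    rl_gln = sum(rowSums(M)^2) / n_runs,
    rl_rln = sum(colSums(M)^2) / n_runs,
    rl_rp = n_runs / n_pix,
    rl_lgre = sum(M / i2) / n_runs,
    rl_hgre = sum(M * i2) / n_runs)
}

# ---- Haralick features -------------------------------------------------

#' Haralick co-occurrence features (5 features)
#'
#' Quantizes the tile, accumulates symmetric normalized gray-level
#' co-occurrence matrices for the configured offsets, averages them, and
#' emits energy (angular second moment), contrast, correlation,
#' homogeneity (inverse difference moment) and entropy (natural log).
#' Correlation is defined as 0 when either marginal variance is 0.
#'
#' @param tile 32 x 32 numeric matrix.
#' @param config a [texture_config()].
#' @return named numeric vector of length 5.
#' @export
haralick_features <- function(tile, config = texture_config()) {
  .check_tile(tile)
  q <- quantize_tile(tile, config$gray_levels)
  L <- attr(q, "n_levels")
  nr <- nrow(q); nc <- ncol(q)
  glcms <- lapply(config$glcm_offsets, function(off) {
    dr <- off[1L]; dc <- off[2L]
    rs <- seq_len(nr - abs(dr)); cs <- seq_len(nc - abs(dc))
    a <- q[rs + max(dr, 0L), cs + max(dc, 0L)]
    b <- q[rs + max(-dr, 0L), cs + max(-dc, 0L)]
    counts <- tabulate((a - 1L) * L + b, nbins = L * L)
    C <- matrix(counts, L, L)
    C <- C + t(C)
    C / sum(C)
  })
  P <- Reduce(`+`, glcms) / length(glcms)
  i <- matrix(1:L, L, L)
  j <- t(i)
  pi_m <- rowSums(P)
  mu_i <- sum((1:L) * pi_m)
  var_i <- sum((1:L - mu_i)^2 * pi_m)
  # symmetric GLCM: both marginals coincide
  corr <- if (var_i > 0) sum((i - mu_i) * (j - mu_i) * P) / var_i else 0
  nz <- P[P > 0]
  c(h_energy = sum(P^2),
    h_contrast = sum(P * (i - j)^2),
    h_correlation = corr,
    h_homogeneity = sum(P / (1 + (i - j)^2)),
    h_entropy = -sum(nz * log(nz)))
}

# ---- Laws texture energies ---------------------------------------------

.LAWS_VECTORS <- list(
  L5 = c(1, 4, 6, 4, 1),      # level
  E5 = c(-1, -2, 0, 2, 1),    # edge
  S5 = c(-1, 0, 2, 0, -1),    # spot
  R5 = c(1, -4, 6, -4, 1),    # ripple
  W5 = c(-1, 2, 0, -2, 1)     # wave
)

# mask set: vertical vector first (applied along rows/depth)
.LAWS_MASKS <- list(
  l_e5l5 = c("E5", "L5"), l_s5l5 = c("S5", "L5"),
  l_r5l5 = c("R5", "L5"), l_w5l5 = c("W5", "L5"),
  l_e5e5 = c("E5", "E5"), l_s5s5 = c("S5", "S5"),
  l_r5r5 = c("R5", "R5"), l_s5e5 = c("S5", "E5")
)

# valid separable correlation of a 32x32 tile with outer(v_row, v_col):
# banded matrices A (28x32) and B (28x32) give A %*% X %*% t(B)
.laws_band <- function(v, n = .TILE) {
  m <- n - length(v) + 1L
  A <- matrix(0, m, n)
  for (k in seq_along(v))
    A[cbind(seq_len(m), seq_len(m) + k - 1L)] <- v[k]
  A
}

#' Laws texture energy measures (8 features)
#'
#' Removes the tile mean, filters with eight 5 x 5 separable Laws masks
#' built from the level/edge/spot/ripple/wave vectors (E5L5, S5L5, R5L5,
#' W5L5, E5E5, S5S5, R5R5, S5E5; first symbol along depth), and emits the
#' mean absolute response over the 28 x 28 valid interior for each mask.
#'
#' @param tile 32 x 32 numeric matrix.
#' @return named numeric vector of length 8.
#' @export
laws_features <- function(tile) {
  .check_tile(tile)
  x <- tile - mean(tile)
  vapply(.LAWS_MASKS, function(mk) {
    A <- .laws_band(.LAWS_VECTORS[[mk[1L]]])
    B <- .laws_band(.LAWS_VECTORS[[mk[2L]]])
    mean(abs(A %*% x %*% t(B)))
  }, numeric(1))
}

# ---- per-B-scan aggregation -------------------------------------------

#' All texture features of one tile
#'
#' @param tile 32 x 32 numeric matrix.
#' @param config a [texture_config()].
#' @return named numeric vector of length 276 in schema order.
#' @export
tile_features <- function(tile, config = texture_config()) {
  lbp <- lbp_features(tile)
  names(lbp) <- feature_schema()$lbp
  c(lbp, runlength_features(tile, config), haralick_features(tile, config),
    laws_features(tile))
}

#' Average texture features over one B-scan
#'
#' Every one of the 276 features is the arithmetic mean of that feature
#' over all kept tiles of the B-scan.
#'
#' @param tileset a non-empty `tile_set`.
#' @param config a [texture_config()].
#' @return object of class `feature_vector`: list with blocks `lbp` (256),
#'   `rl` (7), `haralick` (5), `laws` (8) and `n_tiles_averaged`.
#' @export
bscan_features <- function(tileset, config = texture_config()) {
  stopifnot(inherits(tileset, "tile_set"))
  if (tileset$n_kept == 0L)
    stop("no valid tiles in B-scan ", tileset$bscan_index,
         "; exclude it upstream")
  acc <- 0
  for (tl in tileset$tiles)
    acc <- acc + tile_features(tl$block, config)
  avg <- acc / tileset$n_kept
  sch <- feature_schema()
  structure(list(lbp = avg[sch$lbp], rl = avg[sch$rl],
                 haralick = avg[sch$h], laws = avg[sch$l],
                 n_tiles_averaged = tileset$n_kept),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector: 256 LBP + 7 RL + 5 H + 8 L features, averaged over %d tiles\n",
              x$n_tiles_averaged))
  invisible(x)
}

#' Flatten a feature vector to schema order
#' @param fv a `feature_vector`.
#' @return named numeric vector of length 276.
#' @export
as_feature_row <- function(fv) {
  stopifnot(inherits(fv, "feature_vector"))
  c(fv$lbp, fv$rl, fv$haralick, fv$laws)
}

#' Extract a feature table from a segmented volume
#'
#' One row per B-scan with at least one valid tile; B-scans without valid
#' tiles are skipped and listed in the attribute `"excluded"`.
#'
#' @param volume an `oct_volume`.
#' @param tilesets list of `tile_set` aligned with the volume's B-scans
#'   (from [segment_volume()]).
#' @param config a [texture_config()].
#' @param label class label stored with every row (may be `NA`).
#' @param sample_id overrides the volume's sample id if given.
#' @return a feature table (see [validate_feature_table()]).
#' @export
extract_features <- function(volume, tilesets, config = texture_config(),
                             label = NA_character_, sample_id = NULL) {
  stopifnot(inherits(volume, "oct_volume"),
            length(tilesets) == n_bscans(volume))
  if (is.null(sample_id)) sample_id <- volume$sample_id
  keep <- vapply(tilesets, function(t) t$n_kept > 0L, logical(1))
  rows <- lapply(which(keep), function(i)
    as_feature_row(bscan_features(tilesets[[i]], config)))
  feat <- do.call(rbind, rows)
  if (is.null(feat))
    feat <- matrix(numeric(0), 0L, 276L,
                   dimnames = list(NULL, unlist(feature_schema(),
                                                use.names = FALSE)))
  out <- data.frame(sample_id = rep(sample_id, sum(keep)),
                    bscan_index = which(keep),
                    label = rep(label, sum(keep)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feat))
  rownames(out) <- NULL
  out <- validate_feature_table(out)
  attr(out, "excluded") <- which(!keep)
  out
}
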