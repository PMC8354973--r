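# Segmentation of OCT B-scans: median filter -> Canny edges -> Otsu
# threshold -> ROI below the detected air/tissue surface -> 32x32 tiling.

#' Median filter a B-scan
#'
#' Each output pixel is the median of its `kernel` x `kernel` neighborhood;
#' image borders are handled by edge replication.
#'
#' @param bscan numeric or integer matrix.
#' @param kernel odd window size, >= 3. Default 5, which suppresses OCT
#'   speckle without blurring the surface edge at megapixel B-scan scale.
#' @return numeric matrix of the same dimensions.
#' @export
median_filter <- function(bscan, kernel = 5L) {
  stopifnot(is.matrix(bscan))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer >= 3, got ", kernel)
  .median_filter_cpp(matrix(as.numeric(bscan), nrow(bscan)), kernel)
}

# Separable correlation with edge-replicated borders; kr along rows
# (depth), kc along columns (lateral). Either may be NULL to skip.
.sepfilter <- function(img, kr = NULL, kc = NULL) {
  out <- img
  if (!is.null(kr)) {
    h <- (length(kr) - 1L) %/% 2L
    n <- nrow(out)
    pad <- out[pmin(pmax(seq_len(n + 2L * h) - h, 1L), n), , drop = FALSE]
    acc <- matrix(0, n, ncol(out))
    for (k in seq_along(kr))
      acc <- acc + kr[k] * pad[seq_len(n) + (k - 1L), , drop = FALSE]
    out <- acc
  }
  if (!is.null(kc)) {
    h <- (length(kc) - 1L) %/% 2L
    n <- ncol(out)
    pad <- out[, pmin(pmax(seq_len(n + 2L * h) - h, 1L), n), drop = FALSE]
    acc <- matrix(0, nrow(out), n)
    for (k in seq_along(kc))
      acc <- acc + kc[k] * pad[, seq_len(n) + (k - 1L), drop = FALSE]
    out <- acc
  }
  out
}

.gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)
}

#' Canny edge detection
#'
#' Standard Canny chain: Gaussian pre-smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' two-threshold hysteresis. The hysteresis thresholds are given as
#' fractions of the maximum gradient magnitude after suppression.
#'
#' @param bscan numeric matrix.
#' @param low_frac,high_frac hysteresis thresholds in (0, 1) with
#'   `low_frac < high_frac`. Defaults 0.1 / 0.2.
#' @param sigma Gaussian pre-smoothing standard deviation (pixels).
#' @return logical matrix: the thin edge map.
#' @export
detect_edges <- function(bscan, low_frac = 0.1, high_frac = 0.2, sigma = 2) {
  stopifnot(is.matrix(bscan))
  if (low_frac <= 0 || low_frac >= 1 || high_frac <= 0 || high_frac >= 1)
    stop("hysteresis fractions must lie in (0, 1)")
  if (low_frac >= high_frac)
    stop("`low_frac` must be smaller than `high_frac`")
  img <- matrix(as.numeric(bscan), nrow(bscan))
  if (sigma > 0) {
    g <- .gaussian_kernel(sigma)
    img <- .sepfilter(img, g, g)
  }
  # Sobel: gy = derivative along rows (depth), gx = along columns.
  gy <- .sepfilter(img, kr = c(-1, 0, 1), kc = c(1, 2, 1))
  gx <- .sepfilter(img, kr = c(1, 2, 1), kc = c(-1, 0, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0)
    return(matrix(FALSE, nrow(img), ncol(img)))

  # quantize gradient direction into 4 sectors and compare against the two
  # neighbors along that direction
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  nr <- nrow(mag); nc <- ncol(mag)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rsrc <- rs + dr; csrc <- cs + dc
    rok <- rsrc >= 1L & rsrc <= nr; cok <- csrc >= 1L & csrc <= nc
    out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
    out
  }
  # sector 0: gradient ~ horizontal -> neighbors left/right (columns)
  # sector 1: diagonal; sector 2: vertical (rows); sector 3: anti-diagonal
  nbr <- list(list(c(0L, 1L), c(0L, -1L)),
              list(c(1L, 1L), c(-1L, -1L)),
              list(c(1L, 0L), c(-1L, 0L)),
              list(c(1L, -1L), c(-1L, 1L)))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    n1 <- shift(mag, nbr[[s + 1L]][[1L]][1L], nbr[[s + 1L]][[1L]][2L])
    n2 <- shift(mag, nbr[[s + 1L]][[2L]][1L], nbr[[s + 1L]][[2L]][2L])
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  nms <- ifelse(keep, mag, 0)
  mx <- max(nms)
  strong <- nms >= high_frac * mx
  weak <- nms >= low_frac * mx
  .hysteresis_cpp(strong, weak)
}

#' Otsu threshold
#'
#' Selects the class split that maximizes the between-class variance of
#' the intensity histogram; the foreground is all pixels strictly above
#' the returned threshold. Splits are evaluated at the occupied intensity
#' levels (ties broken toward the lowest split) and the reported threshold
#' is the midpoint between the chosen level and the next occupied one, so
#' for a two-valued image it falls strictly between the two values.
#'
#' @param bscan integer-valued matrix with at least two distinct values.
#' @return list with `threshold` (intensity) and `mask` (logical matrix of
#'   foreground pixels).
#' @export
otsu_threshold <- function(bscan) {
  stopifnot(is.matrix(bscan))
  v <- as.integer(round(bscan))
  u <- sort(unique(v))
  if (length(u) < 2L)
    stop("Otsu threshold undefined for a constant image")
  counts <- as.numeric(tabulate(match(v, u), nbins = length(u)))
  n <- sum(counts)
  w0 <- cumsum(counts) / n                 # P(value <= u[i])
  mu <- cumsum(counts * u) / n             # partial mean
  mu_t <- mu[length(mu)]
  # between-class variance when splitting just above occupied level u[i]
  w0 <- w0[-length(u)]; mu <- mu[-length(u)]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  i <- which.max(bcv)                      # first maximum on ties
  thr <- floor((u[i] + u[i + 1L]) / 2)
  list(threshold = thr, mask = bscan > thr)
}

#' Build the region of interest below the tissue surface
#'
#' Fuses the Canny edge map and the Otsu foreground into a per-B-scan ROI:
#' per column the surface row is the topmost edge pixel if any, else the
#' topmost foreground pixel, else missing; gaps are bridged by linear
#' interpolation between flanking columns (nearest-value extension at the
#' image borders), the surface profile is median-smoothed, and the mask is
#' the largest 8-connected foreground component at or below the surface.
#'
#' @param edge_map logical matrix from [detect_edges()].
#' @param foreground_mask logical matrix from [otsu_threshold()].
#' @param surface_smooth odd window for the running-median smoothing of the
#'   surface profile (default 9 columns).
#' @return object of class `roi_mask`: list with `mask` (logical matrix)
#'   and `surface` (integer row per column, `NA` where no surface exists).
#' @export
build_roi <- function(edge_map, foreground_mask, surface_smooth = 9L) {
  stopifnot(is.matrix(edge_map), is.matrix(foreground_mask),
            identical(dim(edge_map), dim(foreground_mask)))
  nr <- nrow(edge_map); nc <- ncol(edge_map)
  first_true <- function(m) {
    # topmost TRUE row per column, NA if none
    idx <- max.col(t(m * (nr:1)), ties.method = "first")
    idx[colSums(m) == 0L] <- NA_integer_
    as.integer(idx)
  }
  surf <- first_true(edge_map)
  fg_surf <- first_true(foreground_mask)
  surf[is.na(surf)] <- fg_surf[is.na(surf)]
  if (all(is.na(surf))) {
    return(structure(list(mask = matrix(FALSE, nr, nc),
                          surface = rep(NA_integer_, nc)),
                     class = "roi_mask"))
  }
  known <- which(!is.na(surf))
  if (length(known) < nc)
    surf <- stats::approx(known, surf[known], xout = seq_len(nc),
                          rule = 2)$y
  k <- min(as.integer(surface_smooth), nc)
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= 3L) surf <- stats::runmed(surf, k, endrule = "median")
  surf <- as.integer(pmin(pmax(round(surf), 1L), nr))
  comp <- .largest_component_cpp(foreground_mask)
  below <- outer(seq_len(nr), surf, ">=")
  structure(list(mask = comp & below, surface = surf), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d, %d ROI pixels, surface defined for %d/%d columns\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              sum(!is.na(x$surface)), ncol(x$mask)))
  invisible(x)
}

#' Tile a B-scan into valid 32 x 32 sub-images
#'
#' Non-overlapping tiles on a fixed grid anchored at the image origin;
#' trailing partial tiles are dropped. Tiles in the uppermost
#' `top_tile_rows_removed` tile rows are excluded (reconstruction artifacts
#' near the image top), and a tile is kept iff at least `min_overlap` of
#' its pixels lie inside the ROI.
#'
#' @param bscan integer matrix.
#' @param roi an `roi_mask` of the same dimensions.
#' @param tile tile side in pixels (default 32).
#' @param min_overlap minimum fraction of tile pixels inside the ROI
#'   (default 0.9).
#' @param top_tile_rows_removed number of top tile rows discarded
#'   (default 3, i.e. image rows 1..96 for 32-pixel tiles).
#' @return object of class `tile_set`: list with `tiles` (each a list of
#'   `row_origin`, `col_origin`, `block`), `bscan_index`,
#'   `n_candidate_tiles` and `n_kept`. Origins are 1-based pixel indices of
#'   the tile's top-left corner.
#' @export
tile_bscan <- function(bscan, roi, tile = 32L, min_overlap = 0.9,
                       top_tile_rows_removed = 3L) {
  stopifnot(is.matrix(bscan), inherits(roi, "roi_mask"),
            identical(dim(bscan), dim(roi$mask)))
  tile <- as.integer(tile)
  if (tile > nrow(bscan) || tile > ncol(bscan))
    stop("tile size ", tile, " exceeds B-scan dimensions ",
         paste(dim(bscan), collapse = "x"))
  row0 <- seq(1L, nrow(bscan) - tile + 1L, by = tile)
  col0 <- seq(1L, ncol(bscan) - tile + 1L, by = tile)
  n_candidate <- length(row0) * length(col0)
  if (top_tile_rows_removed > 0L)
    row0 <- row0[-seq_len(min(top_tile_rows_removed, length(row0)))]
  tiles <- list()
  area <- tile * tile
  # column sums of the mask per tile strip keep this O(pixels)
  for (r in row0) {
    rs <- r:(r + tile - 1L)
    strip <- roi$mask[rs, , drop = FALSE]
    csum <- colSums(strip)
    for (cc in col0) {
      frac <- sum(csum[cc:(cc + tile - 1L)]) / area
      if (frac >= min_overlap) {
        tiles[[length(tiles) + 1L]] <-
          list(row_origin = r, col_origin = cc,
               block = bscan[rs, cc:(cc + tile - 1L), drop = FALSE])
      }
    }
  }
  structure(list(tiles = tiles, bscan_index = NA_integer_,
                 n_candidate_tiles = n_candidate,
                 n_kept = length(tiles)),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set (B-scan %s): %d/%d tiles kept\n",
              ifelse(is.na(x$bscan_index), "?", x$bscan_index),
              x$n_kept, x$n_candidate_tiles))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param median_kernel median-filter window (odd, default 5).
#' @param canny_low,canny_high hysteresis fractions (defaults 0.1 / 0.2).
#' @param canny_sigma Gaussian pre-smoothing sigma (default 2).
#' @param tile tile side (default 32).
#' @param min_overlap minimum ROI overlap per tile (default 0.9).
#' @param top_tile_rows_removed top tile rows discarded (default 3).
#' @param otsu_on_filtered apply Otsu to the median-filtered B-scan
#'   (default) rather than the raw image.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(median_kernel = 5L, canny_low = 0.1,
                                canny_high = 0.2, canny_sigma = 2,
                                tile = 32L, min_overlap = 0.9,
                                top_tile_rows_removed = 3L,
                                otsu_on_filtered = TRUE) {
  structure(list(median_kernel = as.integer(median_kernel),
                 canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma, tile = as.integer(tile),
                 min_overlap = min_overlap,
                 top_tile_rows_removed = as.integer(top_tile_rows_removed),
                 otsu_on_filtered = otsu_on_filtered),
            class = "segmentation_params")
}

#' Segment one B-scan
#'
#' Runs the full chain (median filter, Canny, Otsu, ROI fusion, tiling) on
#' a single B-scan. A constant B-scan (Otsu undefined) yields an empty
#' tile set rather than an error.
#'
#' @param bscan integer matrix.
#' @param params a [segmentation_params()] list.
#' @return a `tile_set`; the intermediate `roi_mask` is attached as
#'   attribute `"roi"`.
#' @export
segment_bscan <- function(bscan, params = segmentation_params()) {
  filt <- median_filter(bscan, params$median_kernel)
  src <- if (params$otsu_on_filtered) filt else bscan
  if (length(unique(as.vector(round(src)))) < 2L) {
    roi <- structure(list(mask = matrix(FALSE, nrow(bscan), ncol(bscan)),
                          surface = rep(NA_integer_, ncol(bscan))),
                     class = "roi_mask")
  } else {
    edges <- detect_edges(filt, params$canny_low, params$canny_high,
                          params$canny_sigma)
    fg <- otsu_threshold(src)$mask
    roi <- build_roi(edges, fg)
  }
  ts <- tile_bscan(bscan, roi, params$tile, params$min_overlap,
                   params$top_tile_rows_removed)
  attr(ts, "roi") <- roi
  ts
}

#' Segment every B-scan of a volume
#'
#' @param volume an `oct_volume`.
#' @param params a [segmentation_params()] list.
#' @return list of `tile_set`, one per B-scan in order, each with its
#'   `bscan_index` set; B-scans with zero kept tiles are flagged in the
#'   attribute `"empty_bscans"` (integer indices).
#' @export
segment_volume <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "oct_volume"))
  out <- vector("list", n_bscans(volume))
  for (i in seq_along(out)) {
    ts <- segment_bscan(volume$bscans[[i]], params)
    ts$bscan_index <- i
    out[[i]] <- ts
  }
  empty <- which(vapply(out, function(t) t$n_kept == 0L, logical(1)))
  attr(out, "empty_bscans") <- empty
  out
}
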