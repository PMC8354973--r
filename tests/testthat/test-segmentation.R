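# Median filter, Canny, Otsu, ROI fusion and tiling

test_that("median filter matches the sorted-window oracle and handles edges", {
  img <- octex:::.with_seed(1, matrix(sample(0:255, 16 * 16, TRUE), 16, 16))
  for (k in c(3L, 5L))
    expect_equal(median_filter(img, k), oracle_median(img, k))
  const <- matrix(7, 10, 10)
  expect_equal(median_filter(const, 3), const)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 100
  expect_equal(median_filter(imp, 3), matrix(0, 9, 9))
  expect_error(median_filter(img, 4), "odd")
})

test_that("Canny finds a horizontal step edge within one row in every column", {
  img <- matrix(0, 64, 64); img[33:64, ] <- 200
  edges <- detect_edges(img)
  hits <- apply(edges, 2, function(x) any(which(x) %in% 31:34))
  expect_true(all(hits))
  stray <- which(edges, arr.ind = TRUE)
  expect_true(all(stray[, 1] %in% 31:34))
  expect_false(any(detect_edges(matrix(5, 32, 32))))
  expect_error(detect_edges(img, 0.3, 0.2), "smaller")
  expect_error(detect_edges(img, -0.1, 0.2), "\\(0, 1\\)")
})

test_that("Otsu threshold maximizes between-class variance", {
  two <- matrix(c(10L, 200L), 16, 16)
  res <- otsu_threshold(two)
  expect_gt(res$threshold, 10); expect_lt(res$threshold, 200)
  expect_equal(res$mask, two == 200L)
  expect_error(otsu_threshold(matrix(3L, 8, 8)), "constant")
  # 256-level bimodal mixture vs exhaustive search
  img <- octex:::.with_seed(2, matrix(c(
    pmin(pmax(round(rnorm(300, 60, 25)), 0), 255),
    pmin(pmax(round(rnorm(212, 190, 20)), 0), 255)), 16, 32))
  expect_equal(otsu_threshold(img)$threshold, oracle_otsu(img))
})

test_that("ROI fusion recovers a planted band and bridges surface gaps", {
  img <- band_phantom(1024, 1024, 100, 600)
  roi <- build_roi(detect_edges(img), otsu_threshold(img)$mask)
  expect_true(all(abs(roi$surface - 100) <= 2))
  first <- apply(roi$mask, 2, function(x) which(x)[1])
  last <- apply(roi$mask, 2, function(x) rev(which(x))[1])
  expect_true(all(abs(first - 100) <= 2))
  expect_true(all(abs(last - 600) <= 2))
  # a 40-column hole in the edge map is bridged by interpolation
  edges <- detect_edges(img)
  edges[, 300:339] <- FALSE
  roi2 <- build_roi(edges, otsu_threshold(img)$mask)
  expect_true(all(colSums(roi2$mask[, 300:339]) > 0))
  expect_true(all(abs(roi2$surface[300:339] - 100) <= 2))
})

test_that("blank B-scans yield an empty ROI with sentinel surfaces", {
  blank <- matrix(FALSE, 32, 32)
  roi <- build_roi(blank, blank)
  expect_false(any(roi$mask))
  expect_true(all(is.na(roi$surface)))
})

test_that("ROI mask invariants hold on phantoms", {
  spec <- phantom_spec("vital_tumor", image_size = c(256, 256), seed = 9)
  b <- generate_bscan(spec)
  filt <- median_filter(b)
  fg <- otsu_threshold(filt)$mask
  roi <- build_roi(detect_edges(filt), fg)
  expect_true(all(fg[roi$mask]))             # subset of foreground
  above <- outer(seq_len(nrow(b)), roi$surface, "<")
  expect_false(any(roi$mask & above))        # nothing above the surface
})

test_that("tiling arithmetic, overlap rule and top-row removal are exact", {
  full <- roi_from_mask(matrix(TRUE, 1024, 1024))
  b <- matrix(0L, 1024, 1024)
  ts <- tile_bscan(b, full)
  expect_equal(ts$n_kept, (1024 / 32 - 3) * (1024 / 32))   # 928
  expect_equal(ts$n_candidate_tiles, 32 * 32)
  expect_true(all(vapply(ts$tiles, function(t) t$row_origin, 0) > 96))
  expect_true(all(vapply(ts$tiles, function(t)
    (t$row_origin - 1) %% 32 == 0 && (t$col_origin - 1) %% 32 == 0,
    logical(1))))

  empty <- roi_from_mask(matrix(FALSE, 1024, 1024))
  expect_equal(tile_bscan(b, empty)$n_kept, 0L)

  # coverage just below 90% excluded, just above included (tile rows 129..160)
  m89 <- matrix(FALSE, 256, 256)
  m89[129:160, 1:32][seq_len(911)] <- TRUE        # 911/1024 = 89.0%
  expect_equal(tile_bscan(matrix(0L, 256, 256), roi_from_mask(m89))$n_kept, 0L)
  m89b <- matrix(FALSE, 256, 256)
  m89b[129:160, 1:32][seq_len(921)] <- TRUE       # 89.9%, still below
  expect_equal(tile_bscan(matrix(0L, 256, 256), roi_from_mask(m89b))$n_kept, 0L)
  m90 <- matrix(FALSE, 256, 256)
  m90[129:160, 1:32][seq_len(922)] <- TRUE        # 90.04%
  ts90 <- tile_bscan(matrix(0L, 256, 256), roi_from_mask(m90))
  expect_equal(ts90$n_kept, 1L)
  expect_equal(ts90$tiles[[1]]$row_origin, 129L)

  expect_error(tile_bscan(matrix(0L, 16, 16), roi_from_mask(matrix(TRUE, 16, 16))),
               "tile size")
})

test_that("kept tiles are exact sub-arrays and grow monotonically with the ROI", {
  b <- octex:::.with_seed(3, matrix(sample(0:255, 256 * 256, TRUE), 256, 256))
  small <- octex:::.with_seed(4, matrix(runif(256 * 256) < 0.6, 256, 256))
  big <- small | octex:::.with_seed(5, matrix(runif(256 * 256) < 0.5, 256, 256))
  ts_small <- tile_bscan(b, roi_from_mask(small))
  ts_big <- tile_bscan(b, roi_from_mask(big))
  expect_gte(ts_big$n_kept, ts_small$n_kept)
  for (t in ts_small$tiles)
    expect_identical(t$block,
                     b[t$row_origin:(t$row_origin + 31),
                       t$col_origin:(t$col_origin + 31)])
})

test_that("segment_volume returns one tile set per B-scan and flags empties", {
  spec <- phantom_spec("healthy", image_size = c(256, 256), seed = 12)
  vol <- generate_volume(spec, n_bscans = 3)
  tilesets <- segment_volume(vol)
  expect_length(tilesets, 3L)
  expect_equal(vapply(tilesets, function(t) t$bscan_index, 0L), 1:3)
  expect_true(all(vapply(tilesets, function(t) t$n_kept, 0L) > 0))
  expect_length(attr(tilesets, "empty_bscans"), 0L)
  # all tiles lie below the per-column detected surface
  for (ts in tilesets) {
    roi <- attr(ts, "roi")
    for (t in ts$tiles)
      expect_gte(t$row_origin, min(roi$surface))
  }
  # deterministic given fixed parameters
  tilesets2 <- segment_volume(vol)
  expect_identical(lapply(tilesets, unclass), lapply(tilesets2, unclass))

  blankvol <- oct_volume(replicate(3, matrix(0L, 128, 128), simplify = FALSE))
  bts <- segment_volume(blankvol)
  expect_equal(attr(bts, "empty_bscans"), 1:3)
  expect_true(all(vapply(bts, function(t) t$n_kept, 0L) == 0L))
})
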