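#' @useDynLib octex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Default acquisition geometry: a 3.5 x 3.5 mm^2 field scanned at
# 1024 x 1024 lateral positions with 2 mm imaging depth over 1024 pixels.
.PITCH_LATERAL_UM <- 3500 / 1024
.PITCH_AXIAL_UM   <- 2000 / 1024

#' Construct an OCT volume
#'
#' An `oct_volume` is an ordered stack of B-scans (2-D grayscale images,
#' rows = depth with row 1 the shallowest/air side, columns = lateral
#' position) together with the physical pixel pitch and a sample identifier.
#'
#' @param bscans list of integer matrices, all of identical dimensions.
#' @param sample_id opaque sample identifier.
#' @param pixel_pitch_axial,pixel_pitch_lateral micrometers per pixel.
#'   Defaults correspond to a 3.5 mm lateral field and 2 mm depth sampled at
#'   1024 pixels each.
#' @param bit_depth stored bit depth, 8 or 16.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, sample_id = "sample",
                       pixel_pitch_axial = .PITCH_AXIAL_UM,
                       pixel_pitch_lateral = .PITCH_LATERAL_UM,
                       bit_depth = 8L) {
  if (!is.list(bscans) || length(bscans) < 1L)
    stop("`bscans` must be a non-empty list of matrices")
  if (!bit_depth %in% c(8L, 16L))
    stop("unsupported bit depth: ", bit_depth, " (must be 8 or 16)")
  d1 <- dim(bscans[[1L]])
  for (i in seq_along(bscans)) {
    b <- bscans[[i]]
    if (!is.matrix(b))
      stop("B-scan ", i, " is not a matrix")
    if (!identical(dim(b), d1))
      stop("B-scan ", i, " has dimensions ", paste(dim(b), collapse = "x"),
           ", expected ", paste(d1, collapse = "x"))
    if (anyNA(b) || min(b) < 0 || max(b) > 2^bit_depth - 1)
      stop("B-scan ", i, " has intensities outside [0, ", 2^bit_depth - 1, "]")
  }
  structure(
    list(bscans = lapply(bscans, function(b) {
           storage.mode(b) <- "integer"; b
         }),
         sample_id = as.character(sample_id),
         pixel_pitch_axial = pixel_pitch_axial,
         pixel_pitch_lateral = pixel_pitch_lateral,
         bit_depth = as.integer(bit_depth)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1L]])
  cat(sprintf("oct_volume '%s': %d B-scans of %d x %d (%d-bit)\n",
              x$sample_id, length(x$bscans), d[1L], d[2L], x$bit_depth))
  cat(sprintf("  pixel pitch: %.2f um axial, %.2f um lateral\n",
              x$pixel_pitch_axial, x$pixel_pitch_lateral))
  invisible(x)
}

#' Number of B-scans in a volume
#' @param volume an `oct_volume`.
#' @return integer count.
#' @export
n_bscans <- function(volume) length(volume$bscans)

#' Load an OCT volume from disk
#'
#' Reads either a multi-page TIFF (one page per B-scan, acquisition order)
#' or a directory of single-image files taken in lexical order.
#'
#' @param path multi-page TIFF file or directory of TIFF/PNG B-scans.
#' @param sample_id identifier attached to the volume; defaults to the
#'   file/directory base name.
#' @param ... passed on to [oct_volume()] (e.g. pixel pitches).
#' @return an `oct_volume` with bit depth preserved.
#' @export
load_volume <- function(path, sample_id = NULL, ...) {
  if (!file.exists(path))
    stop("volume path does not exist: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("directory contains no TIFF/PNG images: ", path)
    pages <- lapply(files, .read_image_page)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
  }
  d1 <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) > 2L)
      stop("page ", i, " of ", path, " is not single-channel grayscale")
    if (!identical(dim(pages[[i]]), d1))
      stop("page ", i, " of ", path, " has dimensions ",
           paste(dim(pages[[i]]), collapse = "x"), ", expected ",
           paste(d1, collapse = "x"))
  }
  mx <- max(vapply(pages, max, numeric(1)))
  bit_depth <- if (mx > 255) 16L else 8L
  if (mx > 65535)
    stop("unsupported bit depth in ", path, ": max intensity ", mx)
  oct_volume(pages, sample_id = sample_id, bit_depth = bit_depth, ...)
}

.read_image_page <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG B-scans requires the 'png' package")
    x <- png::readPNG(f)
    if (length(dim(x)) > 2L) x <- x[, , 1L]
    m <- round(x * 255)
    storage.mode(m) <- "integer"
    m
  } else {
    x <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(x)) > 2L)
      stop("image ", f, " is not single-channel grayscale")
    x
  }
}

#' Save an OCT volume as a multi-page TIFF
#'
#' The round trip through [load_volume()] is bit-exact for 8- and 16-bit
#' volumes.
#'
#' @param volume an `oct_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  scale <- 2^volume$bit_depth - 1
  pages <- lapply(volume$bscans, function(b) b / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth)
  invisible(path)
}

# ---- sample manifest ---------------------------------------------------

.MANIFEST_COLS <- c("sample_id", "primary_tumor", "tumor_histology",
                    "pct_vital_tumor", "pct_necrosis", "pct_healthy")

#' Load a sample manifest
#'
#' The manifest is a CSV with one row per tissue sample giving the
#' histopathological composition: columns `sample_id`, `primary_tumor`,
#' `tumor_histology`, `pct_vital_tumor`, `pct_necrosis`, `pct_healthy`.
#' The three percentages of each row must sum to 100 (tolerance +/- 0.5 to
#' absorb rounding in hand-entered tables). Class labels are not read from
#' the file; they are assigned by [apply_inclusion_filter()].
#'
#' @param path CSV file path.
#' @return data.frame of sample records with a `label` column set to `NA`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest path does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  df <- df[, .MANIFEST_COLS]
  tot <- df$pct_vital_tumor + df$pct_necrosis + df$pct_healthy
  bad <- which(abs(tot - 100) > 0.5)
  if (length(bad))
    stop("manifest percentages do not sum to 100 in row(s) ",
         paste(bad, collapse = ", "), " (sample ",
         paste(df$sample_id[bad], collapse = ", "), ")")
  df$label <- NA_character_
  df
}

#' Write a sample manifest
#' @param manifest data.frame as returned by [load_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, .MANIFEST_COLS], path, row.names = FALSE)
  invisible(path)
}

# ---- feature tables ----------------------------------------------------

#' Feature column schema
#'
#' Names and widths of the four feature blocks: 256 local-binary-pattern
#' bins, 7 run-length statistics, 5 Haralick features and 8 Laws texture
#' energies (276 columns in total). Column order is fixed.
#'
#' @return named list of character vectors (`lbp`, `rl`, `h`, `l`).
#' @export
feature_schema <- function() {
  list(
    lbp = sprintf("lbp_%03d", 0:255),
    rl  = paste0("rl_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre")),
    h   = paste0("h_", c("energy", "contrast", "correlation",
                         "homogeneity", "entropy")),
    l   = paste0("l_", c("e5l5", "s5l5", "r5l5", "w5l5",
                         "e5e5", "s5s5", "r5r5", "s5e5"))
  )
}

.ID_COLS <- c("sample_id", "bscan_index", "label")

#' Validate a feature table
#'
#' A feature table has one row per B-scan: identifier columns `sample_id`,
#' `bscan_index`, `label` followed by the 276 feature columns of
#' [feature_schema()] in schema order. No missing values are allowed
#' (B-scans without valid tiles are excluded upstream, never stored blank).
#'
#' @param table data.frame to validate.
#' @return the table, with feature columns reordered to the schema.
#' @export
validate_feature_table <- function(table) {
  sch <- unlist(feature_schema(), use.names = FALSE)
  missing <- setdiff(c(.ID_COLS, sch), names(table))
  extra <- setdiff(names(table), c(.ID_COLS, sch))
  if (length(missing) || length(extra))
    stop("feature table schema mismatch;",
         if (length(missing)) paste0(" missing: ",
           paste(utils::head(missing, 8), collapse = ", "),
           if (length(missing) > 8) sprintf(" (+%d more)", length(missing) - 8)),
         if (length(extra)) paste0(" extra: ",
           paste(utils::head(extra, 8), collapse = ", "),
           if (length(extra) > 8) sprintf(" (+%d more)", length(extra) - 8)))
  table <- table[, c(.ID_COLS, sch)]
  if (anyNA(table[, sch]))
    stop("feature table contains missing values")
  table
}

#' Save / load a feature table
#'
#' Plain CSV with a header row; numeric values are written with full
#' precision so that a round trip is lossless to at least 12 significant
#' digits.
#'
#' @param table a valid feature table.
#' @param path CSV path.
#' @return `save_feature_table`: `path`, invisibly. `load_feature_table`:
#'   the validated feature table.
#' @export
save_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  utils::write.csv(format(table, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path) {
  if (!file.exists(path))
    stop("feature table path does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_feature_table(df)
  df$bscan_index <- as.integer(df$bscan_index)
  df
}

#' Feature-matrix view of a feature table
#'
#' @param table a feature table.
#' @param families subset of `c("lbp", "rl", "h", "l")`; default all four.
#' @return numeric matrix of the selected feature blocks, rows aligned with
#'   the table.
#' @export
feature_matrix <- function(table, families = c("lbp", "rl", "h", "l")) {
  sch <- feature_schema()
  families <- match.arg(families, names(sch), several.ok = TRUE)
  cols <- unlist(sch[names(sch) %in% families], use.names = FALSE)
  as.matrix(table[, cols, drop = FALSE])
}
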