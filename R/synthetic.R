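# Synthetic OCT phantoms: B-scans with an air/tissue interface, class-
# specific texture below the surface, multiplicative gamma speckle and
# exponential depth attenuation. These provide ground truth for the
# segmentation and classification chain without clinical scans.

.PHANTOM_CLASSES <- c("healthy", "vital_tumor", "necrosis")

# displayed dynamic range of the log-compressed phantom B-scans (dB)
.PHANTOM_DR_DB <- 40

# deterministic per-B-scan seed derived from (master seed, index);
# exact in double arithmetic and always < 2^31
.hash_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483629 * 69069 + k * 40503 + 1) %%
               2147483629)
}

.default_texture_params <- function(tissue_class, rows) {
  switch(tissue_class,
    healthy = list(layer_period = rows / 12, layer_amp = 0.35),
    vital_tumor = list(blob_scale = 3, blob_amp = 0.6),
    necrosis = list(blob_scale = 5, blob_amp = 0.6,
                    void_density = 25 / (256 * 256),  # voids per pixel
                    void_radius_range = c(4, 14)))
}

#' Phantom B-scan specification
#'
#' Describes one synthetic tissue class: geometry, air/tissue surface
#' position, depth attenuation, speckle statistics and the class-specific
#' texture. Class texture emulates the qualitative appearance of the three
#' tissue types: smooth horizontal layering for healthy cortex,
#' mid-frequency correlated heterogeneity for vital tumor, and
#' heterogeneity pocked with dark elliptical voids for necrosis.
#'
#' @param tissue_class `"healthy"`, `"vital_tumor"` or `"necrosis"`.
#' @param image_size `(rows, cols)`; default `c(1024, 1024)`, the
#'   acquisition geometry of a 3.5 x 3.5 mm / 2 mm-depth volume.
#' @param surface_row_range interval the surface line stays within;
#'   default rows 80..200 at 1024-pixel depth, scaled proportionally for
#'   other sizes.
#' @param attenuation_coefficient exponential intensity decay per pixel of
#'   depth below the surface; default `3.3 / rows` (1/e depth of ~0.6 mm
#'   at the default geometry, within the ~2 mm penetration of brain
#'   tissue).
#' @param speckle_shape gamma shape parameter of the multiplicative
#'   speckle (mean 1, variance `1/shape`); default 2.
#' @param texture_params class-specific list; see Details. `NULL` uses the
#'   class defaults.
#' @param texture_contrast scales the class-texture amplitude; 0 removes
#'   all class-specific structure (classes become indistinguishable), 1 is
#'   the default study condition.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#'
#' @details `texture_params` fields: healthy — `layer_period` (pixels),
#' `layer_amp`; vital tumor — `blob_scale` (pixels), `blob_amp`; necrosis —
#' additionally `void_density` (voids per pixel of tissue) and
#' `void_radius_range` (pixels).
#'
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(tissue_class = c("healthy", "vital_tumor",
                                          "necrosis"),
                         image_size = c(1024L, 1024L),
                         surface_row_range = NULL,
                         attenuation_coefficient = NULL,
                         speckle_shape = 2,
                         texture_params = NULL,
                         texture_contrast = 1,
                         bit_depth = 8L, seed = 1L) {
  tissue_class <- match.arg(tissue_class)
  rows <- as.integer(image_size[1L]); cols <- as.integer(image_size[2L])
  if (rows < 64L || cols < 64L)
    stop("phantom images must be at least 64 x 64")
  if (is.null(surface_row_range))
    surface_row_range <- round(c(80, 200) / 1024 * rows)
  if (surface_row_range[1L] < 1 || surface_row_range[2L] > rows ||
      surface_row_range[1L] > surface_row_range[2L])
    stop("`surface_row_range` must be an interval within the image rows")
  if (is.null(attenuation_coefficient))
    attenuation_coefficient <- 3.3 / rows
  if (speckle_shape <= 0) stop("`speckle_shape` must be positive")
  if (texture_contrast < 0) stop("`texture_contrast` must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  tp <- .default_texture_params(tissue_class, rows)
  if (!is.null(texture_params)) tp[names(texture_params)] <- texture_params
  if (!is.null(tp$void_density) &&
      (tp$void_density < 0 || tp$void_density > 1))
    stop("`void_density` must lie in [0, 1]")
  structure(list(tissue_class = tissue_class,
                 image_size = c(rows, cols),
                 surface_row_range = surface_row_range,
                 attenuation_coefficient = attenuation_coefficient,
                 speckle_shape = speckle_shape,
                 texture_params = tp,
                 texture_contrast = texture_contrast,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth unit-variance random field: white noise blurred with a Gaussian
.smooth_field <- function(nr, nc, sigma) {
  g <- .gaussian_kernel(sigma)
  f <- .sepfilter(matrix(stats::rnorm(nr * nc), nr, nc), g, g)
  f / stats::sd(f)
}

# volume-level structure shared by all B-scans of one stack: surface
# baseline/wiggle and two heterogeneity basis fields to interpolate along
# the stack
.draw_shared <- function(spec) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  rng <- spec$surface_row_range
  amp <- min(0.02 * nr, diff(rng) / 4)
  shared <- list(
    s0 = stats::runif(1, rng[1L] + amp, rng[2L] - amp),
    surf_freq = stats::runif(1, 1, 2.5),
    surf_phase = stats::runif(1, 0, 2 * pi),
    surf_amp = amp,
    layer_phase = stats::runif(1, 0, 2 * pi))
  if (spec$tissue_class != "healthy") {
    sg <- spec$texture_params$blob_scale
    shared$F1 <- .smooth_field(nr, nc, sg)
    shared$F2 <- .smooth_field(nr, nc, sg)
  }
  shared
}

# one B-scan given shared volume structure; `frac` in [0,1] is the
# position along the stack (0 for a standalone B-scan)
.gen_bscan_core <- function(spec, shared, frac = 0) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  tp <- spec$texture_params
  contrast <- spec$texture_contrast
  maxval <- 2^spec$bit_depth - 1

  # smooth surface curve, drifting slowly along the stack
  xs <- seq_len(nc) / nc
  surf <- shared$s0 +
    shared$surf_amp * sin(2 * pi * shared$surf_freq * xs +
                          shared$surf_phase + 1.5 * frac) +
    0.3 * shared$surf_amp * sin(2 * pi * frac)
  surf <- pmin(pmax(round(surf), spec$surface_row_range[1L]),
               spec$surface_row_range[2L])
  surf <- as.integer(surf)

  depth <- outer(seq_len(nr), surf, "-")   # rows below surface are > 0

  # class texture field, mean ~1
  if (spec$tissue_class == "healthy") {
    tex <- 1 + contrast * tp$layer_amp *
      sin(2 * pi * depth / tp$layer_period + shared$layer_phase + 0.8 * frac)
  } else {
    th <- pi / 2 * frac
    G <- cos(th) * shared$F1 + sin(th) * shared$F2
    tex <- 1 + contrast * tp$blob_amp * G
    if (spec$tissue_class == "necrosis") {
      n_void <- stats::rpois(1, tp$void_density * nr * nc)
      if (n_void > 0) {
        rr <- seq_len(nr)
        for (v in seq_len(n_void)) {
          cy <- stats::runif(1, min(surf) + 0.05 * nr, nr)
          cx <- stats::runif(1, 1, nc)
          ra <- stats::runif(1, tp$void_radius_range[1L],
                             tp$void_radius_range[2L])
          rb <- ra * stats::runif(1, 0.5, 1)
          cset <- max(1, floor(cx - ra)):min(nc, ceiling(cx + ra))
          rset <- max(1, floor(cy - rb)):min(nr, ceiling(cy + rb))
          ell <- outer((rset - cy)^2 / rb^2, (cset - cx)^2 / ra^2, "+") <= 1
          # voids darken toward zero reflectivity, scaled by contrast
          tex[rset, cset][ell] <- tex[rset, cset][ell] * (1 - 0.85 * contrast)
        }
      }
    }
  }
  tex[tex < 0.05] <- 0.05

  speckle <- matrix(stats::rgamma(nr * nc, shape = spec$speckle_shape,
                                  rate = spec$speckle_shape), nr, nc)
  att <- exp(-spec$attenuation_coefficient * pmax(depth, 0))
  lin <- 0.5 * tex * att * speckle
  # bright specular line at the air/tissue interface
  line <- depth >= 0 & depth <= max(2L, round(nr / 256))
  lin[line] <- 0.9 * speckle[line]
  # near-noise-floor reflectivity above the surface
  above <- depth < 0
  lin[above] <- 2e-4 * abs(stats::rnorm(sum(above)))
  # log compression into a fixed 40 dB display range, as in processed
  # OCT B-scans
  db <- 10 * log10(pmax(lin, 1e-6))
  img <- (pmax(db, -.PHANTOM_DR_DB) + .PHANTOM_DR_DB) / .PHANTOM_DR_DB * maxval

  img <- matrix(as.integer(pmin(pmax(round(img), 0), maxval)), nr, nc)
  attr(img, "surface") <- surf
  img
}

#' Generate one phantom B-scan
#'
#' Deterministic given the spec (including its seed). The planted surface
#' row per column is attached as attribute `"surface"`.
#'
#' @param spec a [phantom_spec()].
#' @return integer matrix of the configured size and bit depth.
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    shared <- .draw_shared(spec)
    .gen_bscan_core(spec, shared, frac = 0)
  })
}

#' Generate a phantom OCT volume
#'
#' B-scans share the volume-level surface geometry and texture structure;
#' the heterogeneity field is interpolated smoothly along the stack and
#' speckle is redrawn per B-scan (per-B-scan seeds are derived from the
#' spec's master seed, so any B-scan can be regenerated independently).
#' Adjacent B-scans are therefore more strongly correlated than distant
#' ones, as in a real volumetric acquisition.
#'
#' @param spec a [phantom_spec()].
#' @param n_bscans number of B-scans (>= 1).
#' @param sample_id identifier for the resulting volume.
#' @return an `oct_volume`; planted surfaces are attached as attribute
#'   `"surfaces"` (list of integer vectors).
#' @export
generate_volume <- function(spec, n_bscans = 16L, sample_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_bscans >= 1L)
  if (is.null(sample_id))
    sample_id <- paste0(spec$tissue_class, "_s", spec$seed)
  shared <- .with_seed(spec$seed, .draw_shared(spec))
  bscans <- vector("list", n_bscans)
  for (k in seq_len(n_bscans)) {
    frac <- if (n_bscans > 1L) (k - 1) / (n_bscans - 1) else 0
    bscans[[k]] <- .with_seed(.hash_seed(spec$seed, k),
                              .gen_bscan_core(spec, shared, frac))
  }
  surfaces <- lapply(bscans, attr, "surface")
  bscans <- lapply(bscans, function(b) { attr(b, "surface") <- NULL; b })
  vol <- oct_volume(bscans, sample_id = sample_id,
                    bit_depth = spec$bit_depth)
  attr(vol, "surfaces") <- surfaces
  vol
}

#' Generate a phantom study collective
#'
#' Produces labeled phantom volumes for each tissue class with mild
#' within-class parameter jitter, plus a manifest whose percentage columns
#' are consistent with the class (so the inclusion filter retains every
#' sample).
#'
#' @param n_per_class named or positional counts for
#'   `(necrosis, vital_tumor, healthy)`; default `c(6, 4, 4)`, the size of
#'   a small surgical study collective.
#' @param image_size,n_bscans geometry per volume.
#' @param texture_contrast passed to every [phantom_spec()].
#' @param master_seed seed from which every per-volume seed is derived.
#' @return list with `volumes` (named list of `oct_volume`) and `manifest`
#'   (data.frame accepted by [apply_inclusion_filter()]).
#' @export
generate_study <- function(n_per_class = c(necrosis = 6L, vital_tumor = 4L,
                                           healthy = 4L),
                           image_size = c(256L, 256L), n_bscans = 16L,
                           texture_contrast = 1, master_seed = 1L) {
  if (is.null(names(n_per_class)))
    names(n_per_class) <- c("necrosis", "vital_tumor", "healthy")
  stopifnot(all(names(n_per_class) %in% .PHANTOM_CLASSES),
            all(n_per_class >= 1L))
  volumes <- list()
  man <- list()
  idx <- 0L
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      idx <- idx + 1L
      vseed <- .hash_seed(master_seed, idx)
      jit <- .with_seed(.hash_seed(vseed, 999L), list(
        contrast = stats::runif(1, 0.9, 1.1),
        speckle = stats::runif(1, 1.7, 2.3),
        pct = stats::runif(3)))
      spec <- phantom_spec(cls, image_size = image_size,
                           speckle_shape = jit$speckle,
                           texture_contrast = texture_contrast * jit$contrast,
                           seed = vseed)
      sid <- sprintf("%s_%02d", cls, i)
      volumes[[sid]] <- generate_volume(spec, n_bscans, sample_id = sid)
      pct <- switch(cls,
        necrosis = {
          nec <- round(85 + 15 * jit$pct[1L])
          vit <- round(min(100 - nec, 10 * jit$pct[2L]))
          c(vit, nec, 100 - nec - vit)
        },
        vital_tumor = {
          vit <- round(70 + 25 * jit$pct[1L])
          nec <- round(min(100 - vit, 10 * jit$pct[2L]))
          c(vit, nec, 100 - vit - nec)
        },
        healthy = {
          hea <- round(92 + 8 * jit$pct[1L])
          vit <- round(min(100 - hea, 5 * jit$pct[2L]))
          c(vit, 100 - hea - vit, hea)
        })
      man[[idx]] <- data.frame(sample_id = sid,
                               primary_tumor = "synthetic",
                               tumor_histology = "synthetic",
                               pct_vital_tumor = pct[1L],
                               pct_necrosis = pct[2L],
                               pct_healthy = pct[3L],
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  manifest$label <- NA_character_
  list(volumes = volumes, manifest = manifest)
}
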