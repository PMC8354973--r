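# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive per-pixel loops, distinct
# from the vectorized implementations they check.

random_tile <- function(seed, lo = 0L, hi = 255L) {
  octex:::.with_seed(seed, matrix(sample(lo:hi, 32 * 32, replace = TRUE),
                                  32, 32))
}

table1_path <- function() {
  system.file("extdata", "table1_manifest.csv", package = "octex")
}

# sliding-window median with replicated edges, one sort per pixel
oracle_median <- function(img, k) {
  h <- k %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - h):(i + h), 1L), nr)
      cj <- pmin(pmax((j - h):(j + h), 1L), nc)
      out[i, j] <- sort(as.vector(img[ri, cj]))[(k * k + 1) / 2]
    }
  }
  out
}

# exhaustive Otsu: between-class variance evaluated for every candidate
# split at an occupied level, foreground = pixels > t; threshold reported
# as the midpoint to the next occupied level
oracle_otsu <- function(img) {
  v <- as.integer(round(img))
  u <- sort(unique(v))
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(length(u) - 1)) {
    bg <- v[v <= u[i]]; fg <- v[v > u[i]]
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best + 1e-9) { best <- bcv; best_i <- i }
  }
  floor((u[best_i] + u[best_i + 1]) / 2)
}

# per-pixel LBP pattern enumeration (clockwise from top-left, MSB first)
oracle_lbp <- function(tile) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  h <- numeric(256)
  for (i in 2:31) {
    for (j in 2:31) {
      code <- 0
      for (k in 1:8) {
        nb <- tile[i + offs[[k]][1], j + offs[[k]][2]]
        code <- code * 2 + (nb >= tile[i, j])
      }
      h[code + 1] <- h[code + 1] + 1
    }
  }
  h / sum(h)
}

# explicit per-row run scanning for the run-length matrix
oracle_glrlm <- function(q, n_levels, max_len, direction) {
  if (direction == 90) q <- t(q)
  M <- matrix(0, n_levels, max_len)
  for (i in seq_len(nrow(q))) {
    row <- q[i, ]
    j <- 1
    while (j <= length(row)) {
      len <- 1
      while (j + len <= length(row) && row[j + len] == row[j]) len <- len + 1
      M[row[j], len] <- M[row[j], len] + 1
      j <- j + len
    }
  }
  M
}

oracle_runlength <- function(tile, gray_levels = 16, directions = c(0, 90)) {
  q <- quantize_tile(tile, gray_levels)
  L <- attr(q, "n_levels")
  mats <- lapply(directions, function(d) oracle_glrlm(q, L, 32, d))
  M <- Reduce(`+`, mats) / length(mats)
  nr_runs <- sum(M)
  sre <- 0; lre <- 0; lgre <- 0; hgre <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(32)) {
      sre <- sre + M[i, j] / j^2; lre <- lre + M[i, j] * j^2
      lgre <- lgre + M[i, j] / i^2; hgre <- hgre + M[i, j] * i^2
    }
  }
  c(sre / nr_runs, lre / nr_runs,
    sum(rowSums(M)^2) / nr_runs, sum(colSums(M)^2) / nr_runs,
    nr_runs / length(q), lgre / nr_runs, hgre / nr_runs)
}

# pairwise co-occurrence enumeration (symmetric, offsets averaged)
oracle_haralick <- function(tile, gray_levels = 16,
                            offsets = list(c(0, 1), c(1, 0))) {
  q <- quantize_tile(tile, gray_levels)
  L <- attr(q, "n_levels")
  Ps <- lapply(offsets, function(off) {
    P <- matrix(0, L, L)
    for (i in seq_len(32)) {
      for (j in seq_len(32)) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 >= 1 && i2 <= 32 && j2 >= 1 && j2 <= 32) {
          P[q[i, j], q[i2, j2]] <- P[q[i, j], q[i2, j2]] + 1
          P[q[i2, j2], q[i, j]] <- P[q[i2, j2], q[i, j]] + 1
        }
      }
    }
    P / sum(P)
  })
  P <- Reduce(`+`, Ps) / length(Ps)
  energy <- sum(P^2)
  contrast <- 0; hom <- 0; ent <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    contrast <- contrast + P[i, j] * (i - j)^2
    hom <- hom + P[i, j] / (1 + (i - j)^2)
    if (P[i, j] > 0) ent <- ent - P[i, j] * log(P[i, j])
  }
  pm <- rowSums(P)
  mu <- sum(seq_len(L) * pm)
  va <- sum((seq_len(L) - mu)^2 * pm)
  corr <- 0
  if (va > 0)
    for (i in seq_len(L)) for (j in seq_len(L))
      corr <- corr + (i - mu) * (j - mu) * P[i, j] / va
  c(energy, contrast, corr, hom, ent)
}

# direct (non-separable) valid 2-D correlation with the full 5x5 mask
oracle_laws <- function(tile) {
  vecs <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
               S5 = c(-1, 0, 2, 0, -1), R5 = c(1, -4, 6, -4, 1),
               W5 = c(-1, 2, 0, -2, 1))
  masks <- list(c("E5", "L5"), c("S5", "L5"), c("R5", "L5"), c("W5", "L5"),
                c("E5", "E5"), c("S5", "S5"), c("R5", "R5"), c("S5", "E5"))
  x <- tile - mean(tile)
  vapply(masks, function(mk) {
    m <- outer(vecs[[mk[1]]], vecs[[mk[2]]])
    acc <- 0
    for (i in 1:28) {
      for (j in 1:28) {
        acc <- acc + abs(sum(m * x[i:(i + 4), j:(j + 4)]))
      }
    }
    acc / (28 * 28)
  }, numeric(1))
}

# noise-free phantom with a flat bright band: surface at `top`, signal
# down to `bottom`
band_phantom <- function(nr, nc, top, bottom, lo = 5L, hi = 200L) {
  img <- matrix(lo, nr, nc)
  img[top:bottom, ] <- hi
  img
}

roi_from_mask <- function(mask) {
  surf <- apply(mask, 2, function(x) if (any(x)) which(x)[1] else NA_integer_)
  structure(list(mask = mask, surface = as.integer(surf)),
            class = "roi_mask")
}

# feature table with random values, for I/O and classification tests
random_feature_table <- function(n, seed = 1, labels = NULL) {
  sch <- unlist(feature_schema(), use.names = FALSE)
  octex:::.with_seed(seed, {
    m <- matrix(rnorm(n * length(sch)), n)
    colnames(m) <- sch
    df <- data.frame(sample_id = sprintf("s%02d", rep(seq_len(max(1, n %/% 4)),
                                                      length.out = n)),
                     bscan_index = as.integer(seq_len(n)),
                     label = if (is.null(labels))
                       rep(c("healthy", "necrosis"), length.out = n)
                     else labels,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(m))
  })
}
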