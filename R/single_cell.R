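# Per-cell 64 x 64 frame extraction and the fixed-length reference feature
# extractor (a deterministic, documented stand-in honoring the 128-feature
# contract of the learned embedding).

FRAME_SIDE <- 64L
N_FEATURES <- 128L

#' Extract fixed-size cell frames from an image
#'
#' One 64 x 64 frame per labelled object, centered on the object centroid
#' rounded to the nearest pixel; the frame spans `[centroid - 32,
#' centroid + 32)` on each axis and is zero-padded where it overlaps the
#' image edge.
#'
#' @param image Numeric matrix, or a `normalized_image`.
#' @param labels A `cell_label_map` or integer label matrix.
#' @return Object of class `cell_frames`: list with `frames` (list of
#'   64 x 64 matrices) and `info` (data frame cell_id, row, col of the
#'   source centroid).
#' @export
extract_frames <- function(image, labels) {
  img <- if (inherits(image, "normalized_image")) image$values else image
  lab <- if (inherits(labels, "cell_label_map")) labels$labels else labels
  stopifnot_matrix(img)
  if (!identical(dim(img), dim(lab)))
    stop("image and label map differ in shape")
  n <- max(lab)
  frames <- vector("list", n)
  info <- data.frame(cell_id = integer(), row = numeric(),
                     col = numeric())
  if (n == 0L)
    return(structure(list(frames = list(), info = info),
                     class = "cell_frames"))
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  crow <- vapply(split(rows, l), mean, numeric(1))
  ccol <- vapply(split(cols, l), mean, numeric(1))
  ord <- as.integer(names(crow))
  half <- FRAME_SIDE %/% 2L
  for (k in seq_along(ord)) {
    r0 <- floor(crow[k] + 0.5); c0 <- floor(ccol[k] + 0.5)
    fr <- matrix(0, FRAME_SIDE, FRAME_SIDE)
    rs <- (r0 - half):(r0 + half - 1L)
    cs <- (c0 - half):(c0 + half - 1L)
    rok <- rs >= 1L & rs <= nrow(img)
    cok <- cs >= 1L & cs <= ncol(img)
    fr[which(rok), which(cok)] <- img[rs[rok], cs[cok]]
    frames[[ord[k]]] <- fr
  }
  info <- data.frame(cell_id = ord[order(ord)], row = crow[order(ord)],
                     col = ccol[order(ord)])
  frames <- frames[order(ord)]
  structure(list(frames = frames, info = info), class = "cell_frames")
}

#' Mean raw intensity of one cell frame
#'
#' Arithmetic mean over all 64 x 64 pixels of the raw frame (including
#' non-cell pixels, matching the abundance-score convention); set
#' `masked = TRUE` to average only pixels above zero instead.
#'
#' @param frame 64 x 64 numeric matrix.
#' @param masked Optional masked-mean mode (off by default).
#' @return Scalar mean intensity.
#' @export
per_cell_mean_intensity <- function(frame, masked = FALSE) {
  if (masked) {
    nz <- frame[frame > 0]
    if (!length(nz)) return(0)
    return(mean(nz))
  }
  mean(frame)
}

# Static geometry for 64 x 64 frames: radial ring and angular sector index
# of every pixel, cached at first use.
frame_geometry <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- FRAME_SIDE
    ctr <- (s + 1) / 2
    dy <- rep(seq_len(s), times = s) - ctr
    dx <- rep(seq_len(s), each = s) - ctr
    r <- sqrt(dx^2 + dy^2)
    rmax <- max(r)
    ring <- pmin(floor(r / (rmax / 16)) + 1L, 16L)
    sector <- pmin(floor((atan2(dy, dx) + pi) / (2 * pi) * 16) + 1L, 16L)
    cache <<- list(ring = as.integer(ring), sector = as.integer(sector),
                   n_ring = tabulate(ring, 16L),
                   n_sector = tabulate(sector, 16L))
    cache
  }
})

group_means <- function(values, index, counts) {
  s <- vapply(seq_along(counts), function(g) 0, numeric(1))
  t <- tapply(values, index, sum)
  s[as.integer(names(t))] <- t
  s / counts
}

moment_stats <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(((v - m) / s)^3)
    kurt <- mean(((v - m) / s)^4) - 3
  }
  c(m, s, skew, kurt)
}

features_one_frame <- function(P, geom) {
  v <- as.numeric(P)
  if (any(!is.finite(v))) stop("non-finite pixels in frame")
  ms <- moment_stats(v)
  q <- quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  stats8 <- c(ms, min(v), max(v), q[2], q[3] - q[1])
  q16 <- quantile(v, probs = (1:16) / 17, names = FALSE, type = 7)
  radial <- group_means(v, geom$ring, geom$n_ring)
  radialc <- radial - ms[1]
  angular <- group_means(v, geom$sector, geom$n_sector)
  # gradient magnitude from central differences (replicated edges)
  s <- FRAME_SIDE
  gy <- P[c(2:s, s), ] - P[c(1, 1:(s - 1)), ]
  gx <- P[, c(2:s, s)] - P[, c(1, 1:(s - 1))]
  g <- sqrt(as.numeric(gx)^2 + as.numeric(gy)^2)
  grad16 <- c(mean(g), sqrt(mean((g - mean(g))^2)), max(g), median(g),
              quantile(g, probs = (1:12) / 13, names = FALSE, type = 7))
  # local 3x3 standard deviation map via box sums
  box <- function(M) {
    Mp <- matrix(0, s + 2L, s + 2L); Mp[2:(s + 1L), 2:(s + 1L)] <- M
    Mp[1:s, 1:s] + Mp[1:s, 2:(s + 1L)] + Mp[1:s, 3:(s + 2L)] +
      Mp[2:(s + 1L), 1:s] + Mp[2:(s + 1L), 2:(s + 1L)] +
      Mp[2:(s + 1L), 3:(s + 2L)] + Mp[3:(s + 2L), 1:s] +
      Mp[3:(s + 2L), 2:(s + 1L)] + Mp[3:(s + 2L), 3:(s + 2L)]
  }
  cnt <- box(matrix(1, s, s))
  mu <- box(P) / cnt
  varl <- pmax(box(P * P) / cnt - mu^2, 0)
  sl <- sqrt(as.numeric(varl))
  acor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  tex16 <- c(mean(sl), sqrt(mean((sl - mean(sl))^2)), max(sl), median(sl),
             quantile(sl, probs = (1:8) / 9, names = FALSE, type = 7),
             acor(as.numeric(P[1:(s - 1), ]), as.numeric(P[2:s, ])),
             acor(as.numeric(P[, 1:(s - 1)]), as.numeric(P[, 2:s])),
             acor(as.numeric(P[1:(s - 2), ]), as.numeric(P[3:s, ])),
             acor(as.numeric(P[, 1:(s - 2)]), as.numeric(P[, 3:s])))
  # binarized-shape block: threshold at the frame mean
  mask <- v >= ms[1]
  area <- sum(mask)
  if (area == 0 || area == length(v)) {
    shape8 <- c(area / length(v), 0, 0, 0, 0, 0, 0, 0)
    occ <- if (area == 0) numeric(16) else rep(1, 16)
  } else {
    ctr <- (s + 1) / 2
    dy <- rep(seq_len(s), times = s) - ctr
    dx <- rep(seq_len(s), each = s) - ctr
    mdy <- dy[mask]; mdx <- dx[mask]
    cy <- mean(mdy); cx <- mean(mdx)
    mu20 <- mean((mdy - cy)^2) / (s / 2)^2
    mu02 <- mean((mdx - cx)^2) / (s / 2)^2
    mu11 <- mean((mdy - cy) * (mdx - cx)) / (s / 2)^2
    tr <- mu20 + mu02
    det <- mu20 * mu02 - mu11^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
    l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
    ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    M <- matrix(mask, s, s)
    edge <- M & !(M[c(1, 1:(s - 1)), ] & M[c(2:s, s), ] &
                    M[, c(1, 1:(s - 1))] & M[, c(2:s, s)])
    shape8 <- c(area / length(v), cy / (s / 2), cx / (s / 2), mu20, mu02,
                mu11, ecc, sum(edge) / area)
    occ <- group_means(as.numeric(mask), geom$ring, geom$n_ring)
  }
  out <- c(stats8, q16, radial, radialc, angular, grad16, tex16, shape8,
           occ)
  stopifnot(length(out) == N_FEATURES)
  out
}

#' Reference per-cell feature extractor
#'
#' Deterministic 128-feature descriptor of a 64 x 64 frame, honoring the
#' fixed-length embedding contract of the screen. The vector is laid out in
#' versioned blocks: intensity moments and order statistics (1-8),
#' intensity quantiles (9-24), radial concentric-annulus means (25-40),
#' the same radial profile after per-frame mean centering (41-56), angular
#' sector means (57-72), gradient-magnitude statistics (73-88), local
#' 3 x 3 texture and lag autocorrelations (89-104), and binarized-shape
#' moments plus radial mask occupancy (105-128).
#'
#' @param frames A `cell_frames` object, a single 64 x 64 matrix, or a list
#'   of such matrices.
#' @return Matrix with one row per frame and 128 columns `f000` ... `f127`;
#'   attribute `extractor_id` identifies the block layout version.
#' @export
reference_features <- function(frames) {
  fr <- if (inherits(frames, "cell_frames")) frames$frames
        else if (is.matrix(frames)) list(frames) else frames
  geom <- frame_geometry()
  out <- matrix(NA_real_, length(fr), N_FEATURES,
                dimnames = list(NULL, sprintf("f%03d", 0:(N_FEATURES - 1))))
  for (i in seq_along(fr)) {
    if (!all(dim(fr[[i]]) == FRAME_SIDE))
      stop("frames must be exactly 64 x 64")
    out[i, ] <- features_one_frame(fr[[i]], geom)
  }
  attr(out, "extractor_id") <- "paraloc-reference-features-1"
  out
}
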