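# Background-reference estimation, log-standardization, and replicate-level
# quality filtering.

#' Estimate the per-pixel median background reference
#'
#' The reference image holds, at each coordinate, the median pixel value at
#' that coordinate across the whole dataset. Subtracting it corrects uneven
#' illumination and fixed read-out noise. With an even number of images the
#' median is the mean of the two central values.
#'
#' @param images List of numeric matrices with identical shape.
#' @return Object of class `background_reference` with fields `reference`
#'   and `n_images`.
#' @export
estimate_background_reference <- function(images) {
  if (length(images) < 1) stop("need at least one image")
  shp <- dim(images[[1]])
  for (im in images) {
    stopifnot_matrix(im, "images")
    if (!identical(dim(im), shp)) stop("images differ in shape")
  }
  n <- length(images)
  npx <- prod(shp)
  med <- numeric(npx)
  # chunked row-wise sort (order by (row, value)) keeps peak memory modest
  # for large stacks
  chunk <- max(1L, min(npx, 2L^22L %/% n))
  for (start in seq.int(1L, npx, by = chunk)) {
    ix <- start:min(start + chunk - 1L, npx)
    m <- vapply(images, `[`, numeric(length(ix)), ix)
    if (length(ix) == 1L) m <- matrix(m, nrow = 1L)
    sm <- matrix(m[order(row(m), m)], nrow = length(ix), byrow = TRUE)
    med[ix] <- if (n %% 2L == 1L) sm[, (n + 1L) %/% 2L]
               else (sm[, n %/% 2L] + sm[, n %/% 2L + 1L]) / 2
  }
  structure(list(reference = matrix(med, shp[1], shp[2]), n_images = n),
            class = "background_reference")
}

#' Subtract a background reference from an image
#'
#' Elementwise difference, clipped at zero: residuals below the median
#' background carry no abundance information.
#'
#' @param image Numeric matrix.
#' @param ref A `background_reference` (or a bare matrix).
#' @return Matrix of background-subtracted intensities.
#' @export
subtract_background <- function(image, ref) {
  r <- if (inherits(ref, "background_reference")) ref$reference else ref
  stopifnot_matrix(image)
  if (!identical(dim(image), dim(r)))
    stop("image and reference differ in shape")
  pmax(image - r, 0)
}

#' Log-transform and standardize an image
#'
#' Applies `x' = ln(x + 1)` per pixel, then standardizes the whole image to
#' mean 0 and standard deviation 1 (`x'' = (x' - mu) / sigma`, population
#' sigma). This compresses the wide dynamic range across proteins so one
#' segmentation model generalizes over strains.
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @return Object of class `normalized_image` with fields `values`, `mu`,
#'   `sigma`.
#' @export
log_standardize <- function(image) {
  stopifnot_matrix(image)
  if (any(image < 0)) stop("intensities must be nonnegative")
  lx <- log(image + 1)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma == 0)
    stop("degenerate input: constant image has zero standard deviation")
  structure(list(values = (lx - mu) / sigma, mu = mu, sigma = sigma),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat(sprintf("normalized_image: %d x %d (mu = %.4g, sigma = %.4g)\n",
              nrow(x$values), ncol(x$values), x$mu, x$sigma))
  invisible(x)
}

#' Filter replicates by cell count and exclusion list
#'
#' Drops replicates with very low cell numbers and any gene or image on a
#' user-supplied exclusion list (the screen excluded genes with mismatched
#' localization and images with artifacts by inspection). Every removal is
#' logged with its reason.
#'
#' @param samples Data frame with at least columns `id` (sample/replicate
#'   identifier), `gene`, and `n_cells`.
#' @param min_cells Minimum cells per replicate (default 50).
#' @param exclusions Optional data frame with columns `id` (gene or sample
#'   identifier) and `reason`.
#' @return List with `retained` (the surviving rows, unchanged) and `log`
#'   (data frame id, action, reason).
#' @export
filter_replicates <- function(samples, min_cells = 50, exclusions = NULL) {
  stopifnot(all(c("id", "gene", "n_cells") %in% names(samples)))
  log <- data.frame(id = character(), action = character(),
                    reason = character())
  drop <- rep(FALSE, nrow(samples))
  if (!is.null(exclusions) && nrow(exclusions)) {
    hit <- samples$gene %in% exclusions$id | samples$id %in% exclusions$id
    for (i in which(hit)) {
      key <- if (samples$gene[i] %in% exclusions$id) samples$gene[i]
             else samples$id[i]
      log <- rbind(log, data.frame(
        id = samples$id[i], action = "excluded",
        reason = exclusions$reason[match(key, exclusions$id)]))
    }
    drop <- drop | hit
  }
  low <- !drop & samples$n_cells < min_cells
  if (any(low))
    log <- rbind(log, data.frame(
      id = samples$id[low], action = "removed",
      reason = sprintf("low cell count (%d < %d)", samples$n_cells[low],
                       as.integer(min_cells))))
  drop <- drop | low
  if (all(drop)) warning("all replicates removed by filtering")
  list(retained = samples[!drop, , drop = FALSE], log = log)
}
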