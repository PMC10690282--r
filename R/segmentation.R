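# Distance-transform training targets, probability-map backends, and
# seeded-watershed post-processing into single-cell label maps.

#' Erode ground-truth stencils with the minimal cross
#'
#' Each labelled stencil is eroded independently with the 4-neighbor cross:
#' a pixel becomes background if any of its four neighbors (out-of-image
#' neighbors count as background) lies outside its own stencil. Because
#' erosion is per label, touching cells separate with a background gap.
#'
#' @param truth_labels Integer label matrix, 0 = background.
#' @return Logical matrix of the eroded foreground.
#' @export
erode_stencils <- function(truth_labels) {
  l <- truth_labels
  nr <- nrow(l); nc <- ncol(l)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- l
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  keep <- core > 0L &
    pad[1:nr, 2:(nc + 1L)] == core & pad[3:(nr + 2L), 2:(nc + 1L)] == core &
    pad[2:(nr + 1L), 1:nc] == core & pad[2:(nr + 1L), 3:(nc + 2L)] == core
  keep
}

#' Build the distance-transform training target
#'
#' Constructs the regression target used to train (or stand in for) the
#' segmentation model: the eroded binary stencils `B` are Euclidean
#' distance-transformed (distance of each foreground pixel to the nearest
#' background pixel), the distances are clipped at `clip_dist` pixels and
#' scaled to `[0, 1]` (`D'`), and the target is the weighted combination
#' `T = w B + (1 - w) D'`. With the defaults, border pixels of eroded
#' stencils obtain 0.81 (0.8 at one decimal) and values rise to 1 at
#' interior pixels at least `clip_dist` from background, focusing a learner
#' on object centers so touching cells separate.
#'
#' @param truth_labels Integer label matrix.
#' @param w Weight of the binary component (default 0.8).
#' @param clip_dist Clipping distance in pixels (default 20).
#' @return Object of class `target_map` with fields `values`, `w`,
#'   `clip_dist`.
#' @export
make_target_map <- function(truth_labels, w = 0.8, clip_dist = 20) {
  B <- erode_stencils(truth_labels)
  if (!any(B)) {
    values <- matrix(0, nrow(B), ncol(B))
  } else {
    D <- EBImage::distmap(matrix(as.numeric(B), nrow(B), ncol(B)),
                          metric = "euclidean")
    D <- pmin(as.numeric(D), clip_dist) / clip_dist
    values <- w * B + (1 - w) * matrix(D, nrow(B), ncol(B))
  }
  structure(list(values = values, w = w, clip_dist = clip_dist),
            class = "target_map")
}

#' Produce a per-pixel object-probability map
#'
#' Pluggable stand-in for a trained segmentation model, satisfying the same
#' contract (image in, probabilities in `[0, 1]` out). Two backends:
#' `"oracle"` returns the distance-transform target computed from
#' ground-truth labels (exact on synthetic data); `"intensity"` thresholds
#' the image with Otsu's method and returns the normalized in-mask distance
#' transform, requiring no ground truth.
#'
#' @param x A `paraloc_scene` (oracle mode needs its `labels`), a
#'   `normalized_image`, or a bare matrix.
#' @param backend `"oracle"` or `"intensity"`.
#' @param w,clip_dist Target-map parameters for oracle mode.
#' @return Object of class `probability_map` with fields `values`,
#'   `source`.
#' @export
reference_probability_map <- function(x, backend = c("oracle", "intensity"),
                                      w = 0.8, clip_dist = 20) {
  backend <- match.arg(backend)
  if (backend == "oracle") {
    if (!inherits(x, "paraloc_scene") || is.null(x$labels))
      stop("oracle mode needs a scene with ground-truth labels")
    tm <- make_target_map(x$labels, w = w, clip_dist = clip_dist)
    return(structure(list(values = tm$values, source = "oracle"),
                     class = "probability_map"))
  }
  img <- if (inherits(x, "paraloc_scene")) x$image
         else if (inherits(x, "normalized_image")) x$values
         else x
  stopifnot_matrix(img)
  rng <- range(img)
  if (diff(rng) == 0)
    return(structure(list(values = matrix(0, nrow(img), ncol(img)),
                          source = "intensity"),
                     class = "probability_map"))
  scaled <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- scaled > thr
  if (!any(fg)) {
    vals <- matrix(0, nrow(img), ncol(img))
  } else {
    D <- as.numeric(EBImage::distmap(matrix(as.numeric(fg), nrow(fg),
                                            ncol(fg)),
                                     metric = "euclidean"))
    D <- pmin(D, clip_dist) / clip_dist
    vals <- 0.8 * fg + 0.2 * matrix(D, nrow(fg), ncol(fg))
  }
  structure(list(values = vals, source = "intensity"),
            class = "probability_map")
}

#' Seeded-watershed post-processing of a probability map
#'
#' Connected components (4-connectivity) of pixels with probability at or
#' above `seed_thresh` become seeds; a seeded region-growing watershed on
#' the negated probability map, restricted to the support at or above
#' `boundary_thresh`, assigns every supported pixel to a seed. Objects
#' strictly smaller than `min_area` or strictly larger than `max_area`
#' pixels are then removed and the survivors relabelled consecutively.
#'
#' @param prob A `probability_map` or matrix of values in `[0, 1]`.
#' @param seed_thresh Seed threshold (default 0.8, inclusive).
#' @param boundary_thresh Boundary threshold (default 0.5, inclusive).
#' @param min_area,max_area Retained area bounds in pixels (defaults 256
#'   and 8192; the filter removes objects smaller than `min_area` and
#'   larger than `max_area`, keeping the bounds themselves).
#' @return Object of class `cell_label_map` with fields `labels` and
#'   `areas` (named per-label pixel counts).
#' @export
watershed_postprocess <- function(prob, seed_thresh = 0.8,
                                  boundary_thresh = 0.5, min_area = 256,
                                  max_area = 8192) {
  v <- if (inherits(prob, "probability_map")) prob$values else prob
  stopifnot_matrix(v)
  if (min(v) < 0 || max(v) > 1)
    stop("probability values must lie in [0, 1]")
  seeds <- .cc_label4(v >= seed_thresh)
  support <- v >= boundary_thresh
  lab <- .watershed_flood(v, seeds, support)
  filter_labels_by_area(lab, min_area = min_area, max_area = max_area)
}

#' Apply the area filter and relabel consecutively
#'
#' @param labels Integer label matrix.
#' @param min_area,max_area Inclusive bounds on retained object area.
#' @return A `cell_label_map`.
#' @export
filter_labels_by_area <- function(labels, min_area = 256, max_area = 8192) {
  tab <- tabulate(labels[labels > 0L])
  keep <- which(tab >= min_area & tab <= max_area)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  areas <- tab[keep]
  names(areas) <- as.character(seq_along(keep))
  structure(list(labels = out, areas = areas), class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d objects, areas %s px\n",
              length(x$areas),
              if (length(x$areas)) paste0("[", min(x$areas), ", ",
                                          max(x$areas), "]") else "-"))
  invisible(x)
}

#' Match segmented objects to ground truth by intersection-over-union
#'
#' Greedy one-to-one matching: each truth cell is paired with the predicted
#' object of maximal overlap, and counted recovered when their
#' intersection-over-union reaches `min_iou`.
#'
#' @param pred A `cell_label_map` or integer label matrix.
#' @param truth Ground-truth integer label matrix.
#' @param min_iou Recovery threshold (default 0.7).
#' @return List with `recovered` (count), `n_truth`, `recall`, and a
#'   per-truth-cell data frame `matches`.
#' @export
match_objects <- function(pred, truth, min_iou = 0.7) {
  p <- if (inherits(pred, "cell_label_map")) pred$labels else pred
  n_truth <- max(truth)
  if (n_truth == 0L)
    return(list(recovered = 0L, n_truth = 0L, recall = NA_real_,
                matches = data.frame()))
  p_area <- tabulate(p[p > 0L])
  t_area <- tabulate(truth[truth > 0L], nbins = n_truth)
  both <- truth > 0L & p > 0L
  inter <- table(truth = truth[both], pred = p[both])
  matches <- data.frame(truth = seq_len(n_truth), pred = NA_integer_,
                        iou = 0)
  if (length(inter)) {
    ti <- as.integer(rownames(inter))
    for (i in seq_along(ti)) {
      ov <- inter[i, ]
      j <- which.max(ov)
      pj <- as.integer(colnames(inter)[j])
      iou <- as.numeric(ov[j]) / (t_area[ti[i]] + p_area[pj] -
                                    as.numeric(ov[j]))
      matches$pred[ti[i]] <- pj
      matches$iou[ti[i]] <- iou
    }
  }
  rec <- sum(matches$iou >= min_iou)
  list(recovered = rec, n_truth = n_truth, recall = rec / n_truth,
       matches = matches)
}
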