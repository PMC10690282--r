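# Two-channel per-cell ER vs cytoplasm quantification: edge-cell removal,
# background QC, quantile-based pixel assignment from the reporter channel,
# and background-normalized median abundances.

#' Remove cells near the image edge
#'
#' The margin is the median major-axis length of the cells in the image;
#' cells whose centroid lies within that margin of any border are removed.
#'
#' @param cells Data frame with columns `cell_id`, `row`, `col`,
#'   `major_axis`.
#' @param shape Image dimensions `c(rows, cols)`.
#' @return List with `retained` (subset of `cells`) and `margin`.
#' @export
remove_edge_cells <- function(cells, shape) {
  if (nrow(cells) < 1) stop("need at least one cell")
  margin <- median(cells$major_axis)
  d <- pmin(cells$row, shape[1] + 1 - cells$row,
            cells$col, shape[2] + 1 - cells$col)
  list(retained = cells[d >= margin, , drop = FALSE], margin = margin)
}

#' Quality-control images by background intensity
#'
#' Within each replicate, images whose background intensity falls outside
#' `[mean - sd, mean + sd]` (population sd, inclusive bounds) are
#' discarded as extreme.
#'
#' @param backgrounds Numeric vector of per-image background intensities.
#' @param replicate Grouping vector aligned with `backgrounds` (default:
#'   one group).
#' @return Logical vector: `TRUE` for retained images.
#' @export
qc_background_images <- function(backgrounds,
                                 replicate = rep(1L, length(backgrounds))) {
  keep <- rep(TRUE, length(backgrounds))
  for (g in unique(replicate)) {
    ix <- which(replicate == g)
    if (length(ix) < 2L) {
      warning("replicate ", g, " has a single image; retained unchecked")
      next
    }
    b <- backgrounds[ix]
    m <- mean(b)
    s <- sqrt(mean((b - m)^2))
    keep[ix] <- b >= m - s & b <= m + s
  }
  keep
}

#' Assign within-cell pixels to ER and cytoplasm by reporter quantiles
#'
#' Within one cell mask, reporter-channel pixels with intensity at or above
#' the 0.975 quantile are marked ER; pixels strictly below the 0.973
#' quantile are marked cytoplasmic. The thin band between the two
#' quantiles stays unassigned (the rule is applied exactly as stated, with
#' linearly interpolated quantiles). Constant-intensity cells are flagged
#' degenerate.
#'
#' @param reporter_pixels Reporter intensities of the cell's pixels.
#' @param er_quantile ER cut (default 0.975, inclusive).
#' @param cyto_quantile Cytoplasm cut (default 0.973, strict).
#' @return List with `er` and `cyto` (logical vectors over the input),
#'   `n_er`, `degenerate`.
#' @export
assign_er_cytoplasm <- function(reporter_pixels, er_quantile = 0.975,
                                cyto_quantile = 0.973) {
  v <- reporter_pixels
  if (length(v) < 1) stop("empty pixel set")
  if (diff(range(v)) == 0)
    return(list(er = rep(FALSE, length(v)), cyto = rep(FALSE, length(v)),
                n_er = 0L, degenerate = TRUE))
  q_er <- quantile(v, er_quantile, names = FALSE, type = 7)
  q_cy <- quantile(v, cyto_quantile, names = FALSE, type = 7)
  er <- v >= q_er
  cyto <- v < q_cy
  list(er = er, cyto = cyto, n_er = sum(er), degenerate = FALSE)
}

#' Background-normalized compartment abundances of one cell
#'
#' Abundance in each compartment is the median GFP intensity over the
#' compartment's pixels divided by the image background intensity; the
#' whole-cell abundance uses the full mask. Cells with fewer than
#' `min_er_pixels` ER pixels are flagged for discard.
#'
#' @param gfp_pixels GFP intensities of the cell's pixels.
#' @param partition Result of [assign_er_cytoplasm()] on the same pixels.
#' @param background_intensity Positive background intensity of the image
#'   (median over non-cell pixels by convention).
#' @param cell_id Identifier carried through.
#' @param min_er_pixels Minimum ER pixel count (default 100).
#' @return Object of class `compartment_profile`: list with `cell_id`,
#'   `n_er_pixels`, `abundance_er`, `abundance_cyto`, `abundance_cell`,
#'   `qc_flags` (character vector), `retained`.
#' @export
compartment_abundance <- function(gfp_pixels, partition,
                                  background_intensity,
                                  cell_id = NA_integer_,
                                  min_er_pixels = 100L) {
  if (background_intensity <= 0)
    stop("background intensity must be positive")
  stopifnot(length(gfp_pixels) == length(partition$er))
  flags <- character()
  if (isTRUE(partition$degenerate)) flags <- c(flags, "degenerate")
  if (partition$n_er < min_er_pixels) flags <- c(flags, "few_er_pixels")
  med_or_na <- function(sel)
    if (any(sel)) median(gfp_pixels[sel]) / background_intensity
    else NA_real_
  if (!any(partition$er)) flags <- c(flags, "empty_er")
  if (!any(partition$cyto)) flags <- c(flags, "empty_cyto")
  structure(list(cell_id = cell_id, n_er_pixels = partition$n_er,
                 abundance_er = med_or_na(partition$er),
                 abundance_cyto = med_or_na(partition$cyto),
                 abundance_cell = median(gfp_pixels) /
                   background_intensity,
                 qc_flags = flags, retained = !length(flags)),
            class = "compartment_profile")
}

#' Quantify ER and cytoplasm abundance for every cell of a two-channel scene
#'
#' Applies the full validation-style analysis to one scene: edge-cell
#' removal (margin from the median major-axis length), per-cell
#' reporter-quantile pixel assignment, the minimum-ER-pixel filter, and
#' background-normalized median abundances. The background intensity is
#' the median of non-cell pixels in the GFP channel.
#'
#' @param gfp GFP-channel matrix.
#' @param reporter Reporter-channel matrix (ER marker), same shape.
#' @param labels Cell label matrix or `cell_label_map`.
#' @param er_quantile,cyto_quantile Quantile cuts (defaults 0.975, 0.973).
#' @param min_er_pixels Minimum ER pixels per retained cell (default 100).
#' @param drop_edge_cells Apply edge-cell removal (default TRUE).
#' @return Data frame: cell_id, n_er_pixels, abundance_er, abundance_cyto,
#'   abundance_cell, qc_flags (semicolon-separated), retained; attribute
#'   `background_intensity`.
#' @export
quantify_compartments <- function(gfp, reporter, labels,
                                  er_quantile = 0.975,
                                  cyto_quantile = 0.973,
                                  min_er_pixels = 100L,
                                  drop_edge_cells = TRUE) {
  lab <- if (inherits(labels, "cell_label_map")) labels$labels else labels
  stopifnot_matrix(gfp); stopifnot_matrix(reporter)
  if (!identical(dim(gfp), dim(lab)) || !identical(dim(reporter), dim(lab)))
    stop("channel and label shapes differ")
  bg <- median(gfp[lab == 0L])
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids))
    return(structure(data.frame(), background_intensity = bg))
  props <- lapply(ids, function(k) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    # major axis length from second moments of the mask (2 * 2sd of the
    # principal axis approximates the full axis of an ellipse)
    cv <- stats::cov(cbind(rows, cols))
    l1 <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
    list(cell_id = k, row = mean(rows), col = mean(cols),
         major_axis = 4 * sqrt(l1), idx = idx)
  })
  cells <- do.call(rbind, lapply(props, function(p)
    data.frame(cell_id = p$cell_id, row = p$row, col = p$col,
               major_axis = p$major_axis)))
  keep_ids <- cells$cell_id
  if (drop_edge_cells && nrow(cells))
    keep_ids <- remove_edge_cells(cells, dim(lab))$retained$cell_id
  out <- lapply(props, function(p) {
    if (!p$cell_id %in% keep_ids) return(NULL)
    part <- assign_er_cytoplasm(reporter[p$idx], er_quantile, cyto_quantile)
    pr <- compartment_abundance(gfp[p$idx], part, bg, cell_id = p$cell_id,
                                min_er_pixels = min_er_pixels)
    data.frame(cell_id = pr$cell_id, n_er_pixels = pr$n_er_pixels,
               abundance_er = pr$abundance_er,
               abundance_cyto = pr$abundance_cyto,
               abundance_cell = pr$abundance_cell,
               qc_flags = paste(pr$qc_flags, collapse = ";"),
               retained = pr$retained)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  structure(res, background_intensity = bg)
}
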