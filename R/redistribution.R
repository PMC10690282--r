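# Redistribution scores: centroid aggregation of single-cell features,
# Euclidean centroid distance, ROC-based threshold selection, and pair-level
# classification.

#' Aggregate single-cell features into a strain centroid
#'
#' Cells are pooled across replicates and the coordinate-wise arithmetic
#' mean of their feature vectors is the strain's centroid, representing its
#' subcellular protein distribution.
#'
#' @param features Numeric matrix, one row per cell (e.g. from
#'   [reference_features()]).
#' @param gene Gene identifier (optional bookkeeping).
#' @param background `"wild-type"` or `"deletion"`.
#' @return Object of class `strain_centroid` with fields `gene`,
#'   `background`, `centroid`, `n_cells`.
#' @export
strain_centroid <- function(features, gene = NA_character_,
                            background = c("wild-type", "deletion")) {
  background <- match.arg(background)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (nrow(features) < 1) stop("need at least one feature vector")
  structure(list(gene = gene, background = background,
                 centroid = colMeans(features), n_cells = nrow(features)),
            class = "strain_centroid")
}

#' Redistribution score of one protein
#'
#' Euclidean distance between the wild-type and deletion-background strain
#' centroids; a collective measure of localization and abundance change.
#'
#' @param wt,del `strain_centroid` objects (or bare numeric vectors) for
#'   the two backgrounds.
#' @return Nonnegative scalar score.
#' @export
redistribution_score <- function(wt, del) {
  a <- if (inherits(wt, "strain_centroid")) wt$centroid else wt
  b <- if (inherits(del, "strain_centroid")) del$centroid else del
  if (length(a) != length(b)) stop("centroid dimensions differ")
  sqrt(sum((a - b)^2))
}

#' Select the redistribution threshold by ROC analysis
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores, plus sentinels below the minimum and above the maximum. With the
#' strictly-greater classification rule, the threshold with minimal false
#' positive rate is chosen; ties are broken by maximal true positive rate,
#' then by the smallest threshold.
#'
#' @param pos_scores Scores of the labelled true cases (visually confirmed
#'   responders).
#' @param neg_scores Scores of the negative controls (randomly paired
#'   genes).
#' @return List with `threshold`, `tpr`, `fpr`, and the full `roc` table
#'   (threshold, tpr, fpr) for audit.
#' @export
select_threshold <- function(pos_scores, neg_scores) {
  if (length(pos_scores) < 1 || length(neg_scores) < 1)
    stop("need at least one positive and one negative score")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  roc <- data.frame(
    threshold = cand,
    tpr = vapply(cand, function(t) mean(pos_scores > t), numeric(1)),
    fpr = vapply(cand, function(t) mean(neg_scores > t), numeric(1)))
  ord <- order(roc$fpr, -roc$tpr, roc$threshold)
  best <- roc[ord[1], ]
  list(threshold = best$threshold, tpr = best$tpr, fpr = best$fpr,
       roc = roc)
}

#' Classify a score as redistributed
#'
#' Strictly-greater comparison against the selected threshold.
#'
#' @param score Redistribution score(s).
#' @param threshold Classification threshold.
#' @return Logical vector.
#' @export
classify_redistributed <- function(score, threshold) {
  score > threshold
}

#' Two-dimensional embedding of one gene's cells for visualization
#'
#' Pools the cells of both backgrounds, z-scores each feature over the
#' pooled set (dropping constant features with a warning), and projects
#' onto the top two principal components with a deterministic sign
#' convention (the largest-magnitude loading of each component is
#' positive). Used only for visualization; raw features feed the score.
#'
#' @param features Pooled feature matrix (both backgrounds).
#' @param background Character vector aligned with rows of `features`.
#' @return List with `embedding` (n x 2), `var_explained` (fractions for
#'   PC1, PC2), `centroids` (2 x 2 matrix of per-background centroid
#'   coordinates, the redistribution arrow), `background`.
#' @export
pca_view <- function(features, background) {
  if (nrow(features) < 3) stop("need at least three cells")
  sds <- apply(features, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped before PCA")
    features <- features[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (!ncol(features)) stop("all features constant")
  z <- scale(features, center = TRUE, scale = sds)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  emb <- z %*% rot
  if (k < 2L) emb <- cbind(emb, 0)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cen <- vapply(unique(background), function(b)
    colMeans(emb[background == b, , drop = FALSE]), numeric(2))
  list(embedding = emb, var_explained = ve[seq_len(min(2L, length(ve)))],
       centroids = t(cen), background = background)
}

#' Summarize pair-level redistribution responses
#'
#' Categorizes each paralog pair by how many of its members were classified
#' as redistributed: `"both"`, `"one"`, or `"none"`; pairs with a missing
#' member are flagged incomplete.
#'
#' @param results Data frame with columns `gene`, `paralog`,
#'   `redistributed` (one row per scored protein).
#' @return Data frame with one row per pair: `gene1`, `gene2`, `category`,
#'   `complete`.
#' @export
pair_response_summary <- function(results) {
  key <- t(apply(results[, c("gene", "paralog")], 1, sort))
  pid <- paste(key[, 1], key[, 2], sep = "|")
  out <- lapply(split(seq_len(nrow(results)), pid), function(ix) {
    g <- sort(unique(c(results$gene[ix], results$paralog[ix])))
    complete <- length(unique(results$gene[ix])) == 2L
    n_re <- sum(results$redistributed[ix])
    data.frame(gene1 = g[1], gene2 = g[2],
               category = if (!complete) NA_character_
               else c("none", "one", "both")[n_re + 1L],
               complete = complete)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!res$complete))
    warning(sum(!res$complete), " pair(s) incomplete: missing member")
  res
}
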