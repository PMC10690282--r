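# End-to-end orchestration: preprocessing, segmentation, feature
# extraction, replicate filtering, redistribution scoring, abundance
# testing, and report generation, driven by one configuration object.

#' Screen run configuration
#'
#' All thresholds default to the screen's published operating points:
#' watershed seeds at 0.8 and boundaries at 0.5 on the probability map,
#' retained areas in `[256, 8192]` px, abundance calls at `|lfc| >= 0.2`
#' and `q < 0.05`, colocalization at Jaccard >= 50, and ER/cytoplasm
#' reporter quantiles 0.975/0.973. The configuration round-trips
#' losslessly through YAML.
#'
#' @param ... Overrides of the defaults.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(seed_thresh = 0.8, boundary_thresh = 0.5, min_area = 256,
              max_area = 8192, target_w = 0.8, target_clip = 20,
              lfc_thresh = 0.2, q_thresh = 0.05, jaccard_thresh = 50,
              er_quantile = 0.975, cyto_quantile = 0.973,
              min_er_pixels = 100, min_cells = 50,
              segmentation_backend = "oracle", threshold = NULL,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full redistribution screen on a strain panel
#'
#' Stages: (1) per-pixel median background reference over every image,
#' subtracted with clipping at zero; (2) log-standardization of each
#' subtracted image; (3) probability-map segmentation (oracle or
#' intensity backend) with seeded-watershed post-processing and the area
#' filter; (4) 64 x 64 frame extraction -- raw frames for abundance,
#' normalized frames for features; (5) replicate-level cell-count
#' filtering; (6) centroid redistribution scores per gene with ROC
#' threshold selection (negative-control pairs as false cases, programmed
#' or user-supplied responders as true cases); (7) abundance fold changes
#' with rank-sum tests and Benjamini-Hochberg correction; (8) pair-level
#' summaries.
#'
#' @param panel A `strain_panel` (from [generate_strain_panel()] or
#'   [read_panel()]).
#' @param config A [run_config()].
#' @param true_cases Optional character vector of genes to treat as
#'   labelled true responders for threshold selection; defaults to genes
#'   with a programmed effect when the panel carries its pair
#'   specifications.
#' @param exclusions Optional exclusion list passed to
#'   [filter_replicates()].
#' @return Object of class `screen_result`: list of result tables
#'   (`redistribution`, `abundance`, `pairs`, `cells`, `filter_log`),
#'   the selected `threshold` with its ROC table, and a `manifest` of
#'   parameters.
#' @export
run_screen <- function(panel, config = run_config(), true_cases = NULL,
                       exclusions = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  md <- panel$metadata
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ref <- stage("background", estimate_background_reference(
    lapply(panel$scenes, `[[`, "image")))
  cell_tabs <- vector("list", nrow(md))
  feats <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    sc <- panel$scenes[[md$scene[i]]]
    raw <- stage("background", subtract_background(sc$image, ref))
    norm <- stage("normalize", log_standardize(raw))
    prob <- stage("segment", reference_probability_map(
      if (config$segmentation_backend == "oracle") sc else norm,
      backend = config$segmentation_backend, w = config$target_w,
      clip_dist = config$target_clip))
    seg <- stage("segment", watershed_postprocess(
      prob, seed_thresh = config$seed_thresh,
      boundary_thresh = config$boundary_thresh,
      min_area = config$min_area, max_area = config$max_area))
    raw_frames <- stage("frames", extract_frames(raw, seg))
    norm_frames <- stage("frames", extract_frames(norm, seg))
    f <- stage("features", reference_features(norm_frames))
    means <- vapply(raw_frames$frames, per_cell_mean_intensity, numeric(1))
    n <- length(means)
    cell_tabs[[i]] <- data.frame(
      strain = rep(md$strain[i], n), gene = rep(md$gene[i], n),
      paralog = rep(md$paralog[i], n),
      background = rep(md$background[i], n),
      replicate = rep(md$replicate[i], n), field = rep(md$field[i], n),
      cell_id = seq_len(n), mean_intensity = means)
    feats[[i]] <- f
  }
  cells <- do.call(rbind, cell_tabs)
  features <- do.call(rbind, feats)
  # replicate filtering on (strain, replicate) cell counts
  repkey <- paste(cells$strain, cells$replicate, sep = "|")
  counts <- aggregate(list(n_cells = cells$cell_id),
                      by = list(id = repkey, gene = cells$gene),
                      FUN = length)
  flt <- stage("filter", filter_replicates(counts,
                                           min_cells = config$min_cells,
                                           exclusions = exclusions))
  keep <- repkey %in% flt$retained$id
  cells <- cells[keep, , drop = FALSE]
  features <- features[keep, , drop = FALSE]

  genes <- unique(cells$gene)
  redis <- do.call(rbind, lapply(genes, function(g) {
    iw <- cells$gene == g & cells$background == "wild-type"
    id <- cells$gene == g & cells$background == "deletion"
    if (!any(iw) || !any(id)) return(NULL)
    s <- redistribution_score(
      strain_centroid(features[iw, , drop = FALSE], g, "wild-type"),
      strain_centroid(features[id, , drop = FALSE], g, "deletion"))
    data.frame(gene = g, paralog = cells$paralog[which(id)[1]],
               score = s, n_wt = sum(iw), n_del = sum(id))
  }))
  # threshold: negatives from control pairs, positives from programmed
  # effects or the user's labelled true cases
  neg_genes <- pos_genes <- character()
  if (!is.null(panel$pairs)) {
    for (p in panel$pairs) {
      if (isTRUE(p$control)) {
        neg_genes <- c(neg_genes, p$gene1, p$gene2)
      } else {
        if (p$lfc1 != 0 || p$reloc1 > 0) pos_genes <- c(pos_genes, p$gene1)
        if (p$lfc2 != 0 || p$reloc2 > 0) pos_genes <- c(pos_genes, p$gene2)
      }
    }
  }
  if (!is.null(true_cases)) pos_genes <- true_cases
  thr <- config$threshold
  roc <- NULL
  if (is.null(thr)) {
    pos <- redis$score[redis$gene %in% pos_genes]
    neg <- redis$score[redis$gene %in% neg_genes]
    if (length(pos) && length(neg)) {
      sel <- stage("threshold", select_threshold(pos, neg))
      thr <- sel$threshold
      roc <- sel$roc
    } else {
      stop("stage 'threshold' failed: no labelled true/false cases and ",
           "no fixed threshold configured")
    }
  }
  redis$threshold <- thr
  redis$redistributed <- classify_redistributed(redis$score, thr)

  abun <- do.call(rbind, lapply(genes, function(g) {
    xw <- cells$mean_intensity[cells$gene == g &
                                 cells$background == "wild-type"]
    xd <- cells$mean_intensity[cells$gene == g &
                                 cells$background == "deletion"]
    if (!length(xw) || !length(xd)) return(NULL)
    abundance_compare(xw, xd, gene = g,
                      paralog = redis$paralog[redis$gene == g][1])
  }))
  abun$q <- bh_adjust(abun$p)
  abun$direction <- classify_abundance(abun$lfc, abun$q,
                                       lfc_thresh = config$lfc_thresh,
                                       q_thresh = config$q_thresh)
  pairs <- stage("pairs", suppressWarnings(pair_response_summary(redis)))
  structure(list(
    redistribution = redis, abundance = abun, pairs = pairs,
    cells = cells, features = features, filter_log = flt$log,
    threshold = list(value = thr, roc = roc),
    manifest = list(config = unclass(config), n_scenes = nrow(md),
                    panel_seed = panel$seed,
                    extractor = attr(features, "extractor_id"))),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0(
    "screen_result: %d proteins scored, threshold %.3f, ",
    "%d redistributed\n"),
    nrow(x$redistribution), x$threshold$value,
    sum(x$redistribution$redistributed)))
  invisible(x)
}

#' Summarize a screen run
#'
#' Counts of redistributed proteins, pair-level response categories, and
#' abundance direction breakdowns; every number is recomputed from the
#' result tables.
#'
#' @param bundle A `screen_result`.
#' @return List of summary tables (class `screen_report`).
#' @export
make_report <- function(bundle) {
  if (is.null(bundle$redistribution) || !nrow(bundle$redistribution)) {
    warning("empty result bundle")
    return(structure(list(n_proteins = 0L), class = "screen_report"))
  }
  re <- bundle$redistribution
  ab <- bundle$abundance
  structure(list(
    n_proteins = nrow(re),
    n_redistributed = sum(re$redistributed),
    threshold = bundle$threshold$value,
    pair_categories = table(bundle$pairs$category),
    abundance_directions = table(ab$direction),
    volcano = ab[, c("gene", "lfc", "q")]),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen report\n")
  cat(sprintf("  proteins scored:   %d\n", x$n_proteins))
  if (x$n_proteins == 0L) return(invisible(x))
  cat(sprintf("  redistributed:     %d (score > %.3f)\n",
              x$n_redistributed, x$threshold))
  cat("  pair categories:  ",
      paste(sprintf("%s=%d", names(x$pair_categories),
                    x$pair_categories), collapse = " "), "\n")
  cat("  abundance calls:  ",
      paste(sprintf("%s=%d", names(x$abundance_directions),
                    x$abundance_directions), collapse = " "), "\n")
  invisible(x)
}
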