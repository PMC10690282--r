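# Image and table input/output. Intensity images travel as 16-bit TIFF
# (scaled by a stored factor so arbitrary-unit intensities survive the
# round trip), label maps as 16-bit TIFF, tables as TSV, configs as YAML.

#' Write an intensity image as 16-bit TIFF
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @param path Output path.
#' @param scale Divisor mapping intensities into `[0, 1]` before encoding;
#'   default scales the image maximum to the top of the 16-bit range.
#' @return The scale used, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  stopifnot_matrix(image)
  if (is.null(scale)) scale <- max(image, 1e-12)
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(scale)
}

#' Read an intensity image written by [write_image_tiff()]
#' @param path TIFF path.
#' @param scale Scale factor used at write time (default 1).
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 1) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * scale
}

#' Write a label map as 16-bit TIFF
#' @param labels Integer matrix, 0 = background.
#' @param path Output path.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_labels_tiff()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_labels_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE)

#' Write a strain panel to disk
#'
#' Writes each scene's GFP image (and reporter, if present) as 16-bit TIFF,
#' its truth label map as 16-bit TIFF, and a metadata TSV with columns
#' strain, gene, paralog, background, replicate, field, path_gfp,
#' path_reporter, path_truth. A fixed intensity scale is applied across the
#' panel so relative intensities are preserved.
#'
#' @param panel A `strain_panel`.
#' @param dir Output directory (created if needed).
#' @param scale Intensity divisor for the 16-bit encoding; default covers
#'   the panel-wide maximum.
#' @return Path of the metadata TSV, invisibly.
#' @export
write_panel <- function(panel, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scale))
    scale <- max(vapply(panel$scenes, function(s)
      max(s$image, if (is.null(s$reporter)) 0 else max(s$reporter)),
      numeric(1)))
  md <- panel$metadata
  md$path_gfp <- md$path_reporter <- md$path_truth <- NA_character_
  for (i in seq_len(nrow(md))) {
    sc <- panel$scenes[[md$scene[i]]]
    stem <- sprintf("%s_r%d_f%d", md$strain[i], md$replicate[i],
                    md$field[i])
    md$path_gfp[i] <- file.path(dir, paste0(stem, "_gfp.tif"))
    write_image_tiff(sc$image, md$path_gfp[i], scale = scale)
    if (!is.null(sc$reporter)) {
      md$path_reporter[i] <- file.path(dir, paste0(stem, "_rep.tif"))
      write_image_tiff(sc$reporter, md$path_reporter[i], scale = scale)
    }
    md$path_truth[i] <- file.path(dir, paste0(stem, "_truth.tif"))
    write_labels_tiff(sc$labels, md$path_truth[i])
  }
  meta_path <- file.path(dir, "metadata.tsv")
  cols <- c("strain", "gene", "paralog", "background", "replicate",
            "field", "path_gfp", "path_reporter", "path_truth")
  write_tsv(md[, cols], meta_path)
  yaml::write_yaml(list(intensity_scale = scale, seed = panel$seed),
                   file.path(dir, "panel.yaml"))
  invisible(meta_path)
}

#' Read a strain panel written by [write_panel()]
#' @param dir Panel directory.
#' @return A `strain_panel` (without per-cell truth records; the label maps
#'   carry the ground truth).
#' @export
read_panel <- function(dir) {
  md <- read_tsv(file.path(dir, "metadata.tsv"))
  cfg <- yaml::read_yaml(file.path(dir, "panel.yaml"))
  scenes <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    lab <- read_labels_tiff(md$path_truth[i])
    scenes[[i]] <- structure(list(
      image = read_image_tiff(md$path_gfp[i], scale = cfg$intensity_scale),
      reporter = if (!is.na(md$path_reporter[i]))
        read_image_tiff(md$path_reporter[i],
                        scale = cfg$intensity_scale) else NULL,
      labels = lab, cells = NULL, shape = dim(lab), seed = NA_integer_,
      effect = effect_spec(md$gene[i], "wild-type")),
      class = "paraloc_scene")
  }
  md$scene <- seq_len(nrow(md))
  structure(list(scenes = scenes, metadata = md, pairs = NULL,
                 seed = cfg$seed),
            class = "strain_panel")
}
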