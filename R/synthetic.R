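#' Subcellular localization classes for the synthetic renderer
#'
#' Each class is a rule describing where fluorescence concentrates inside an
#' elliptical cell, parameterized by the normalized elliptical radius
#' `u` (0 at the cell center, 1 on the membrane) and polar angle. The rules
#' are coarse geometric idealizations of the classic yeast GFP localization
#' patterns: a nuclear disk, a vacuolar disk, a perinuclear ring plus
#' cortical rim for the ER, radial tubule-like spokes for mitochondria, and
#' small puncta for Golgi/punctate patterns. Cytoplasmic signal fills the
#' interior outside the vacuole.
#'
#' @return Character vector of supported class names.
#' @export
localization_classes <- function() {
  c("cytoplasm", "nucleus", "ER", "mitochondria", "vacuole", "Golgi",
    "punctate")
}

# Relative intensity weights for one cell. `u` is normalized elliptical
# radius, `ang` polar angle in [-pi, pi]; both restricted to interior pixels.
# Weight layouts that need randomness (mitochondria spokes, puncta) draw from
# the active RNG stream so they are reproducible per scene seed.
render_weights <- function(class, u, ang) {
  w <- numeric(length(u))
  if (class == "cytoplasm") {
    w[u > 0.5] <- 1
  } else if (class == "nucleus") {
    w[u <= 0.3] <- 1
  } else if (class == "vacuole") {
    w[u <= 0.5] <- 1
  } else if (class == "ER") {
    w[u >= 0.25 & u <= 0.55] <- 1  # perinuclear annulus
  } else if (class == "mitochondria") {
    phis <- runif(3, -pi, pi)
    hit <- rep(FALSE, length(u))
    for (p in phis) {
      d <- abs(atan2(sin(ang - p), cos(ang - p)))
      hit <- hit | (d < 0.35 & u > 0.25 & u < 0.95)
    }
    w[hit] <- 1
  } else if (class == "Golgi" || class == "punctate") {
    k <- if (class == "Golgi") 3L else 6L
    rad <- if (class == "Golgi") 0.18 else 0.12
    cu <- sqrt(runif(k)) * 0.7
    ca <- runif(k, -pi, pi)
    hit <- rep(FALSE, length(u))
    for (i in seq_len(k)) {
      # distance in normalized polar coordinates
      dx <- u * cos(ang) - cu[i] * cos(ca[i])
      dy <- u * sin(ang) - cu[i] * sin(ca[i])
      hit <- hit | (sqrt(dx * dx + dy * dy) < rad)
    }
    w[hit] <- 1
  } else {
    stop("unknown localization class: ", class)
  }
  # guarantee a positive weight sum: fall back to faint uniform interior if a
  # sparse pattern missed every pixel of a small cell
  if (sum(w) == 0) w[] <- 1
  w
}

#' Programmed deletion-background effect for one strain
#'
#' Encodes what the paralog-deletion background does to the GFP-tagged
#' protein in a synthetic strain: a log2 abundance fold change and/or a
#' fractional relocalization of signal into a target compartment.
#'
#' @param gene Gene identifier.
#' @param background `"wild-type"` or `"deletion"`.
#' @param abundance_lfc Programmed log2 fold change of mean foreground
#'   intensity relative to wild type. Must be 0 in the wild-type background.
#' @param reloc_fraction Fraction of foreground signal moved into
#'   `reloc_target`, in `[0, 1]`. Must be 0 in the wild-type background.
#' @param reloc_target Target localization class, or `NULL`.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(gene = "GENE", background = c("wild-type", "deletion"),
                        abundance_lfc = 0, reloc_fraction = 0,
                        reloc_target = NULL) {
  background <- match.arg(background)
  if (background == "wild-type" &&
      (abundance_lfc != 0 || reloc_fraction != 0))
    stop("wild-type background must have abundance_lfc = 0 and ",
         "reloc_fraction = 0")
  if (reloc_fraction < 0 || reloc_fraction > 1)
    stop("reloc_fraction must lie in [0, 1]")
  if (reloc_fraction > 0 && is.null(reloc_target))
    stop("reloc_fraction > 0 requires a reloc_target")
  if (!is.null(reloc_target))
    reloc_target <- match.arg(reloc_target, localization_classes())
  structure(list(gene = gene, background = background,
                 abundance_lfc = abundance_lfc,
                 reloc_fraction = reloc_fraction,
                 reloc_target = reloc_target),
            class = "effect_spec")
}

# Rasterize one ellipse; returns linear pixel indices plus normalized radius
# and angle for interior pixels.
ellipse_pixels <- function(cy, cx, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  ry <- rep(rows, times = length(cols)) - cy
  rx <- rep(cols, each = length(rows)) - cx
  xr <- rx * cos(theta) + ry * sin(theta)
  yr <- -rx * sin(theta) + ry * cos(theta)
  u2 <- (xr / a)^2 + (yr / b)^2
  keep <- u2 <= 1
  idx <- (rep(cols, each = length(rows)) - 1L) * nr +
    rep(rows, times = length(cols))
  list(idx = idx[keep], u = sqrt(u2[keep]),
       ang = atan2(yr[keep], xr[keep]))
}

#' Generate one synthetic micrograph with ground truth
#'
#' Renders a field of non-overlapping elliptical cells on a noisy
#' background, emulating a single-plane fluorescence micrograph of yeast.
#' Per-pixel intensities are background plus programmed foreground signal
#' plus noise; a ground-truth label map and per-cell records accompany the
#' image.
#'
#' @param n_cells Number of cells to place (may be 0).
#' @param class Localization class name, one value or one per cell.
#' @param effect An [effect_spec()]; in a deletion background its
#'   `abundance_lfc` scales foreground intensity by `2^lfc` and its
#'   `reloc_fraction` moves that fraction of signal into the render region
#'   of `reloc_target`.
#' @param shape Image dimensions `c(rows, cols)`, at least 64 x 64.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical scenes.
#' @param cell_area Range of cell areas in pixels.
#' @param aspect Range of ellipse aspect ratios.
#' @param base_intensity Mean foreground intensity per cell in the
#'   wild-type background (arbitrary units).
#' @param intensity_cv Coefficient of variation of per-cell mean intensity.
#' @param noise List with `bg_mean`, `bg_sd` (additive Gaussian background)
#'   and `shot` (multiplicative shot-noise factor; the per-pixel sd of the
#'   shot term is `shot * sqrt(signal)`). Set `bg_sd = 0, shot = 0` for a
#'   noise-free scene.
#' @param with_reporter If `TRUE`, render a second channel carrying an ER
#'   reporter pattern in every cell.
#' @param reporter_intensity Mean reporter foreground intensity.
#' @param max_tries Rejection-sampling attempts per cell before declaring
#'   the packing impossible.
#' @return A `paraloc_scene`: list with `image`, `reporter` (or `NULL`),
#'   `labels` (0 = background, cells consecutive from 1) and `cells`, a
#'   data frame of per-cell truth (centroid, area, class, programmed mean
#'   intensity).
#' @export
generate_scene <- function(n_cells, class = "cytoplasm",
                           effect = effect_spec(), shape = c(512L, 512L),
                           seed, cell_area = c(400, 1200),
                           aspect = c(1.2, 2.2), base_intensity = 300,
                           intensity_cv = 0.15,
                           noise = list(bg_mean = 100, bg_sd = 8,
                                        shot = 0.5),
                           with_reporter = FALSE, reporter_intensity = 300,
                           max_tries = 200L) {
  if (missing(seed)) stop("a seed is required")
  if (any(shape < 64)) stop("image dimensions must be at least 64 x 64")
  if (n_cells < 0) stop("n_cells must be nonnegative")
  classes <- rep_len(as.character(class), max(n_cells, 1L))
  bad <- setdiff(unique(classes), localization_classes())
  if (length(bad)) stop("unknown localization class: ",
                        paste(bad, collapse = ", "))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  with_seed(seed, {
    image <- matrix(0, nr, nc)
    labels <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    cells <- data.frame(cell = integer(), row = numeric(), col = numeric(),
                        area = integer(), class = character(),
                        intensity = numeric())
    reporter <- if (with_reporter) matrix(0, nr, nc) else NULL
    lfc <- if (effect$background == "deletion") effect$abundance_lfc else 0
    f <- if (effect$background == "deletion") effect$reloc_fraction else 0
    target <- if (f > 0) effect$reloc_target else NULL
    placed <- 0L
    while (placed < n_cells) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        A <- runif(1, cell_area[1], cell_area[2])
        q <- runif(1, aspect[1], aspect[2])
        a <- sqrt(A * q / pi); b <- sqrt(A / (pi * q))
        theta <- runif(1, 0, pi)
        cy <- runif(1, a + 2, nr - a - 1)
        cx <- runif(1, a + 2, nc - a - 1)
        # collision test on an ellipse grown by 1.5 px keeps a >= 1 px gap
        grown <- ellipse_pixels(cy, cx, a + 1.5, b + 1.5, theta, nr, nc)
        if (any(occupied[grown$idx])) next
        px <- ellipse_pixels(cy, cx, a, b, theta, nr, nc)
        if (length(px$idx) == 0) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "impossible packing: placed %d of %d cells in a %d x %d field",
          placed, n_cells, nr, nc))
      placed <- placed + 1L
      occupied[grown$idx] <- TRUE
      labels[px$idx] <- placed
      cls <- classes[placed]
      w <- render_weights(cls, px$u, px$ang)
      if (!is.null(target) && target != cls) {
        tw <- render_weights(target, px$u, px$ang)
        own <- w
        own[tw > 0] <- 0            # own-class signal excluded from target
        if (sum(own) == 0) own <- w # degenerate full overlap
        w <- (1 - f) * own / sum(own) + f * tw / sum(tw)
      } else {
        w <- w / sum(w)
      }
      intensity <- base_intensity * 2^lfc *
        exp(rnorm(1, 0, intensity_cv) - intensity_cv^2 / 2)
      image[px$idx] <- image[px$idx] + intensity * length(px$idx) * w
      if (with_reporter) {
        rw <- render_weights("ER", px$u, px$ang)
        reporter[px$idx] <- reporter[px$idx] +
          reporter_intensity * length(px$idx) * rw / sum(rw)
      }
      cells <- rbind(cells, data.frame(
        cell = placed, row = mean((px$idx - 1L) %% nr + 1L),
        col = mean((px$idx - 1L) %/% nr + 1L),
        area = length(px$idx), class = cls, intensity = intensity))
    }
    add_noise <- function(img) {
      out <- img + noise$bg_mean
      if (noise$bg_sd > 0) out <- out + rnorm(length(img), 0, noise$bg_sd)
      if (noise$shot > 0)
        out <- out + rnorm(length(img)) * noise$shot * sqrt(pmax(img, 0))
      matrix(pmax(out, 0), nrow(img), ncol(img))
    }
    image <- add_noise(image)
    if (with_reporter) reporter <- add_noise(reporter)
    structure(list(image = image, reporter = reporter, labels = labels,
                   cells = cells, shape = c(nr, nc), seed = seed,
                   effect = effect),
              class = "paraloc_scene")
  })
}

#' @export
print.paraloc_scene <- function(x, ...) {
  cat(sprintf("paraloc_scene: %d x %d px, %d cells%s, background %s\n",
              x$shape[1], x$shape[2], nrow(x$cells),
              if (is.null(x$reporter)) "" else ", two channels",
              x$effect$background))
  invisible(x)
}

#' Describe one paralog pair for panel generation
#'
#' A pair contributes four strains: each GFP-tagged gene imaged in the
#' wild-type and in the deletion background of its paralog. The programmed
#' deletion-background response of each gene (abundance change,
#' relocalization) is given per gene; wild-type strains always carry null
#' effects.
#'
#' @param gene1,gene2 Gene names.
#' @param class1,class2 Wild-type localization class of each gene.
#' @param lfc1,lfc2 Programmed abundance log2 fold change of each gene in
#'   the deletion background of its paralog.
#' @param reloc1,reloc2 Programmed relocalized fraction for each gene.
#' @param target1,target2 Relocalization target class (defaults to the
#'   paralog's wild-type class, the compensation scenario).
#' @param control Logical: a negative-control pair (all effects forced
#'   null), emulating randomly paired genes.
#' @return A `paralog_pair` list.
#' @export
paralog_pair <- function(gene1, gene2, class1 = "cytoplasm",
                         class2 = "nucleus", lfc1 = 0, lfc2 = 0,
                         reloc1 = 0, reloc2 = 0, target1 = class2,
                         target2 = class1, control = FALSE) {
  if (gene1 == gene2) stop("a pair needs two distinct genes")
  if (control) { lfc1 <- lfc2 <- reloc1 <- reloc2 <- 0 }
  structure(list(gene1 = gene1, gene2 = gene2, class1 = class1,
                 class2 = class2, lfc1 = lfc1, lfc2 = lfc2,
                 reloc1 = reloc1, reloc2 = reloc2, target1 = target1,
                 target2 = target2, control = control),
            class = "paralog_pair")
}

#' Generate a full synthetic strain panel
#'
#' Emulates the screen design: four strains per paralog pair (each gene in
#' wild-type and paralog-deletion background), each imaged in several
#' replicates with several fields per replicate.
#'
#' @param pairs List of [paralog_pair()] objects.
#' @param replicates Number of replicates per strain (default 3).
#' @param fields_per_replicate Fields imaged per replicate (default 4).
#' @param n_cells Range of cells per field (default 50 to 100, sampled
#'   uniformly per field).
#' @param seed Master integer seed; all per-scene seeds derive from it.
#' @param ... Further arguments passed to [generate_scene()] (`shape`,
#'   `cell_area`, `noise`, ...).
#' @return A `strain_panel`: list with `scenes` (list of scenes) and
#'   `metadata` (data frame with columns strain, gene, paralog, background,
#'   replicate, field, scene).
#' @export
generate_strain_panel <- function(pairs, replicates = 3L,
                                  fields_per_replicate = 4L,
                                  n_cells = c(50L, 100L), seed, ...) {
  if (missing(seed)) stop("a seed is required")
  if (replicates < 1) stop("need at least one replicate")
  if (inherits(pairs, "paralog_pair")) pairs <- list(pairs)
  strains <- list()
  for (p in pairs) {
    strains[[length(strains) + 1L]] <- list(
      strain = paste0(p$gene1, "-GFP_wt"), gene = p$gene1,
      paralog = p$gene2, background = "wild-type", class = p$class1,
      effect = effect_spec(p$gene1, "wild-type"))
    strains[[length(strains) + 1L]] <- list(
      strain = paste0(p$gene1, "-GFP_", tolower(p$gene2), "del"),
      gene = p$gene1, paralog = p$gene2, background = "deletion",
      class = p$class1,
      effect = effect_spec(p$gene1, "deletion", p$lfc1, p$reloc1,
                           if (p$reloc1 > 0) p$target1 else NULL))
    strains[[length(strains) + 1L]] <- list(
      strain = paste0(p$gene2, "-GFP_wt"), gene = p$gene2,
      paralog = p$gene1, background = "wild-type", class = p$class2,
      effect = effect_spec(p$gene2, "wild-type"))
    strains[[length(strains) + 1L]] <- list(
      strain = paste0(p$gene2, "-GFP_", tolower(p$gene1), "del"),
      gene = p$gene2, paralog = p$gene1, background = "deletion",
      class = p$class2,
      effect = effect_spec(p$gene2, "deletion", p$lfc2, p$reloc2,
                           if (p$reloc2 > 0) p$target2 else NULL))
  }
  ids <- vapply(strains, `[[`, "", "strain")
  if (anyDuplicated(ids))
    stop("duplicate strain identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scenes <- list()
  meta <- list()
  k <- 0L
  for (si in seq_along(strains)) {
    st <- strains[[si]]
    for (r in seq_len(replicates)) {
      for (fd in seq_len(fields_per_replicate)) {
        k <- k + 1L
        sseed <- derive_seed(seed, k)
        nc_field <- with_seed(derive_seed(sseed, 1L),
                              n_cells[1] + sample.int(n_cells[2] -
                                                        n_cells[1] + 1L,
                                                      1L) - 1L)
        scenes[[k]] <- generate_scene(nc_field, class = st$class,
                                      effect = st$effect, seed = sseed, ...)
        meta[[k]] <- data.frame(strain = st$strain, gene = st$gene,
                                paralog = st$paralog,
                                background = st$background, replicate = r,
                                field = fd, scene = k)
      }
    }
  }
  structure(list(scenes = scenes, metadata = do.call(rbind, meta),
                 pairs = pairs, seed = seed),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("strain_panel: %d scenes, %d strains, %d pairs (seed %d)\n",
              length(x$scenes), length(unique(x$metadata$strain)),
              length(x$pairs), x$seed))
  invisible(x)
}
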