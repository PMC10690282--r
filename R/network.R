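# Interaction-network features: typed edge sets (physical and genetic
# interactions), stringency filtering, shared-interactor and path-length
# binning, colocalization Jaccard, and private-interactor enrichment.

#' Build a cleaned interaction network from an edge table
#'
#' Edges are undirected; self-loops are removed and duplicate edges
#' collapsed keeping the strongest evidence (smallest p, then largest
#' `|epsilon|`). For physical interactions, optional column filters mirror
#' the screen's cleaning (keep physical experiment types from
#' high-throughput studies).
#'
#' @param edges Data frame with columns `geneA`, `geneB`, `type`
#'   (`"ppi"` or `"gi"`); genetic edges should carry `epsilon` and `p`;
#'   physical edges may carry `experiment_type` and `throughput`.
#' @param ppi_experiment_type If non-`NULL`, keep only ppi edges whose
#'   `experiment_type` matches (default `"physical"`).
#' @param ppi_throughput If non-`NULL`, keep only ppi edges whose
#'   `throughput` matches (default `"high"` when the column exists).
#' @return Object of class `interaction_network` wrapping the cleaned edge
#'   table and an igraph per interaction type.
#' @export
interaction_network <- function(edges, ppi_experiment_type = "physical",
                                ppi_throughput = "high") {
  stopifnot(all(c("geneA", "geneB", "type") %in% names(edges)))
  if (!"epsilon" %in% names(edges)) edges$epsilon <- NA_real_
  if (!"p" %in% names(edges)) edges$p <- NA_real_
  if ("experiment_type" %in% names(edges) &&
      !is.null(ppi_experiment_type))
    edges <- edges[edges$type != "ppi" |
                     edges$experiment_type == ppi_experiment_type, ,
                   drop = FALSE]
  if ("throughput" %in% names(edges) && !is.null(ppi_throughput))
    edges <- edges[edges$type != "ppi" |
                     edges$throughput == ppi_throughput, , drop = FALSE]
  edges <- edges[edges$geneA != edges$geneB, , drop = FALSE]
  a <- pmin(edges$geneA, edges$geneB)
  b <- pmax(edges$geneA, edges$geneB)
  edges$geneA <- a; edges$geneB <- b
  key <- paste(a, b, edges$type, sep = "|")
  ord <- order(key, edges$p, -abs(edges$epsilon), na.last = TRUE)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  graphs <- lapply(split(edges, edges$type), function(e)
    igraph::graph_from_data_frame(e[, c("geneA", "geneB")],
                                  directed = FALSE))
  structure(list(edges = edges, graphs = graphs),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  tt <- table(x$edges$type)
  cat("interaction_network:",
      paste(sprintf("%s: %d edges", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

net_edges <- function(network, type) {
  e <- network$edges
  e[e$type == type, , drop = FALSE]
}

#' Filter genetic interactions by stringency class
#'
#' Classes follow the published digenic-interaction thresholds:
#' lenient (`p < 0.05`), intermediate (`p < 0.05` and `|epsilon| > 0.08`),
#' stringent (`p < 0.05` and `epsilon > 0.16` or `epsilon < -0.12`),
#' stringent_neg (`p < 0.05` and `epsilon < -0.12`), and synthetic_lethal
#' (`p < 0.05` and `epsilon < -0.35`). Edges lacking `epsilon` or `p` are
#' skipped with a warning.
#'
#' @param network An `interaction_network` (or gi edge data frame).
#' @param class One of `"lenient"`, `"intermediate"`, `"stringent"`,
#'   `"stringent_neg"`, `"synthetic_lethal"`.
#' @return The passing subset of gi edges.
#' @export
filter_gi <- function(network, class = c("lenient", "intermediate",
                                         "stringent", "stringent_neg",
                                         "synthetic_lethal")) {
  class <- match.arg(class)
  e <- if (inherits(network, "interaction_network"))
    net_edges(network, "gi") else network
  bad <- is.na(e$epsilon) | is.na(e$p)
  if (any(bad)) {
    warning(sum(bad), " gi edge(s) missing epsilon or p skipped")
    e <- e[!bad, , drop = FALSE]
  }
  keep <- switch(class,
    lenient = e$p < 0.05,
    intermediate = e$p < 0.05 & abs(e$epsilon) > 0.08,
    stringent = e$p < 0.05 & (e$epsilon > 0.16 | e$epsilon < -0.12),
    stringent_neg = e$p < 0.05 & e$epsilon < -0.12,
    synthetic_lethal = e$p < 0.05 & e$epsilon < -0.35)
  e[keep, , drop = FALSE]
}

neighbors_of <- function(network, gene, type) {
  g <- network$graphs[[type]]
  if (is.null(g) || !gene %in% igraph::V(g)$name) return(character())
  setdiff(igraph::neighbors(g, gene)$name, gene)
}

#' Shared-interactor count and cohort bin of one pair
#'
#' Counts network neighbors common to both paralogs (the pair members
#' themselves excluded) and bins the pair against the cohort median:
#' strictly more than the median is `"high"`, otherwise `"low"` (counts
#' equal to the median fall in `"low"` and are logged via attribute).
#'
#' @param network An `interaction_network`.
#' @param gene,paralog The pair to score.
#' @param all_pairs Data frame with columns `gene`, `paralog` defining the
#'   cohort over which the median is taken.
#' @param type Interaction type (default `"ppi"`).
#' @return List with `count`, `bin`, `median`, and the cohort `counts`;
#'   `bin` is `NA` when the gene is absent from the network.
#' @export
shared_interactor_bin <- function(network, gene, paralog, all_pairs,
                                  type = "ppi") {
  count_pair <- function(g1, g2) {
    n1 <- neighbors_of(network, g1, type)
    n2 <- neighbors_of(network, g2, type)
    length(setdiff(intersect(n1, n2), c(g1, g2)))
  }
  g <- network$graphs[[type]]
  present <- function(x) !is.null(g) && x %in% igraph::V(g)$name
  cohort_ok <- vapply(seq_len(nrow(all_pairs)), function(i)
    present(all_pairs$gene[i]) && present(all_pairs$paralog[i]), logical(1))
  counts <- vapply(which(cohort_ok), function(i)
    count_pair(all_pairs$gene[i], all_pairs$paralog[i]), numeric(1))
  med <- median(counts)
  if (!present(gene) || !present(paralog))
    return(list(count = NA_integer_, bin = NA_character_, median = med,
                counts = counts))
  n <- count_pair(gene, paralog)
  list(count = n, bin = if (n > med) "high" else "low", median = med,
       counts = counts)
}

#' Shortest-path-length bin of one pair
#'
#' Unweighted shortest path between the paralogs: a direct edge gives bin
#' `"1"`; any longer path, or disconnection, gives `"1+"`.
#'
#' @param network An `interaction_network`.
#' @param gene,paralog The pair.
#' @param type Interaction type (default `"ppi"`).
#' @return List with `length` (Inf when disconnected or absent) and `bin`.
#' @export
path_length_bin <- function(network, gene, paralog, type = "ppi") {
  g <- network$graphs[[type]]
  if (is.null(g) || !all(c(gene, paralog) %in% igraph::V(g)$name))
    return(list(length = Inf, bin = "1+"))
  d <- igraph::distances(g, v = gene, to = paralog)[1, 1]
  list(length = d, bin = if (is.finite(d) && d == 1) "1" else "1+")
}

#' Colocalization Jaccard index of two annotation sets
#'
#' `100 * |A intersect B| / |A union B|`; the pair is colocalized when the
#' index reaches 50.
#'
#' @param locA,locB Non-empty character vectors of compartment labels.
#' @return List with `jaccard` (percentage) and `colocalized` (logical).
#' @export
coloc_jaccard <- function(locA, locB) {
  locA <- unique(locA); locB <- unique(locB)
  if (!length(locA) || !length(locB))
    stop("localization sets must be non-empty")
  j <- 100 * length(intersect(locA, locB)) / length(union(locA, locB))
  list(jaccard = j, colocalized = j >= 50)
}

#' Enrichment of private interactors in the paralog's compartment
#'
#' Tests, over a cohort of paralogs, whether redistributed proteins are
#' more likely to possess private interactors (neighbors not shared with
#' the sister) residing in the sister's subcellular compartment. The 2 x 2
#' table is redistributed-status against the private-interactor flag; the
#' odds ratio is the cross-product ratio (with a 0.5 Haldane correction if
#' any cell is zero, reported) and the p-value is the two-sided Fisher
#' exact test.
#'
#' @param redistributed Logical vector over the cohort.
#' @param has_private_in_paralog_compartment Logical vector, aligned.
#' @return List with `table`, `odds_ratio`, `haldane` (logical), `p`.
#' @export
private_interactor_enrichment <- function(redistributed,
                                 has_private_in_paralog_compartment) {
  f <- has_private_in_paralog_compartment
  stopifnot(length(redistributed) == length(f))
  tab <- matrix(c(sum(redistributed & f), sum(redistributed & !f),
                  sum(!redistributed & f), sum(!redistributed & !f)),
                2, 2, byrow = TRUE,
                dimnames = list(c("redistributed", "not"),
                                c("private_in_comp", "not")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate)
    return(list(table = tab, odds_ratio = NA_real_, haldane = FALSE,
                p = 1))
  haldane <- any(tab == 0)
  t2 <- tab + if (haldane) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, haldane = haldane, p = min(p, 1))
}

#' Compare redistribution scores between two bins
#'
#' Two-sided rank-sum comparison of scores across a binary grouping (e.g.
#' low vs high shared interactors), with box-and-whisker summary statistics
#' per bin: median, linearly interpolated quartiles, and whiskers at
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#'
#' @param scores Numeric scores.
#' @param bin_labels Vector with exactly two distinct values, aligned.
#' @return List with `p` and a data frame `summary` (bin, n, median, q1,
#'   q3, whisker_low, whisker_high).
#' @export
compare_score_bins <- function(scores, bin_labels) {
  bins <- sort(unique(as.character(bin_labels)))
  if (length(bins) != 2) stop("need exactly two non-empty bins")
  x <- scores[bin_labels == bins[1]]
  y <- scores[bin_labels == bins[2]]
  if (!length(x) || !length(y)) stop("one bin is empty")
  ht <- rank_sum_test(x, y)
  summ <- do.call(rbind, lapply(bins, function(b) {
    v <- scores[bin_labels == b]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(bin = b, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], whisker_low = q[1] - 1.5 * iqr,
               whisker_high = q[3] + 1.5 * iqr)
  }))
  list(p = ht$p, summary = summ)
}

#' Read a localization annotation table
#'
#' TSV with columns `gene` and `compartments` (semicolon-separated labels).
#'
#' @param path TSV path.
#' @return Named list mapping gene to character vector of compartments.
#' @export
read_localization_annotation <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "compartments") %in% names(df)))
  ann <- lapply(strsplit(df$compartments, ";", fixed = TRUE), trimws)
  names(ann) <- df$gene
  if (any(!lengths(ann)))
    stop("annotated genes must have non-empty compartment sets")
  ann
}
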