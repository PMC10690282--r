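# Protein abundance quantification: condition-level abundance scores, log2
# fold changes, rank-sum significance, FDR control, and the
# compensation/dependency call.

#' Abundance score of one strain condition
#'
#' Mean raw pixel intensity across all the pixels of all the cell frames in
#' the condition (a pixel-weighted grand mean, not a mean of frame means).
#'
#' @param frames A `cell_frames` object or list of frames.
#' @return Scalar abundance score.
#' @export
abundance_score <- function(frames) {
  fr <- if (inherits(frames, "cell_frames")) frames$frames else frames
  if (is.matrix(fr)) fr <- list(fr)
  if (!length(fr)) stop("need at least one frame")
  tot <- 0; n <- 0
  for (f in fr) { tot <- tot + sum(f); n <- n + length(f) }
  tot / n
}

#' Log2 fold change of abundance scores with a pseudocount
#'
#' `log2(score_del + 1) - log2(score_wt + 1)`: deletion minus wild type, so
#' a positive value marks an abundance increase upon paralog loss (the
#' compensation direction).
#'
#' @param score_wt,score_del Nonnegative abundance scores.
#' @return Log2 fold change.
#' @export
log2_fold_change <- function(score_wt, score_del) {
  if (any(c(score_wt, score_del) < 0)) stop("scores must be nonnegative")
  log2(score_del + 1) - log2(score_wt + 1)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Compares per-cell mean intensities between backgrounds. The p-value is
#' exact (by enumeration of the U distribution) for small tie-free samples
#' (`n_x + n_y <= 12`); otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Numeric samples (e.g. per-cell mean intensities in the two
#'   backgrounds).
#' @return List with `p` (two-sided p-value), `u` (the U statistic of
#'   `x`), `exact` (logical).
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(p = min(ht$p.value, 1), u = unname(ht$statistic), exact = exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Classify an abundance change
#'
#' `"increased"` if `lfc >= lfc_thresh` and `q < q_thresh`; `"decreased"`
#' if `lfc <= -lfc_thresh` and `q < q_thresh`; otherwise `"none"`.
#'
#' @param lfc Log2 fold change(s).
#' @param q FDR-adjusted p-value(s).
#' @param lfc_thresh Effect-size threshold (default 0.2, inclusive).
#' @param q_thresh Significance threshold (default 0.05, strict).
#' @return Character vector in `{"increased", "decreased", "none"}`.
#' @export
classify_abundance <- function(lfc, q, lfc_thresh = 0.2, q_thresh = 0.05) {
  out <- rep("none", length(lfc))
  out[lfc >= lfc_thresh & q < q_thresh] <- "increased"
  out[lfc <= -lfc_thresh & q < q_thresh] <- "decreased"
  out
}

#' Call compensation or dependency for one protein
#'
#' Compensation: increased abundance, or relocalization into the paralog's
#' wild-type compartment. Dependency: decreased abundance, or
#' relocalization to a compartment that is neither the protein's own nor
#' its paralog's wild-type compartment. When signals conflict (e.g.
#' decreased abundance but compensatory relocalization) both flags are
#' reported with a warning.
#'
#' @param direction `"increased"`, `"decreased"`, or `"none"` (from
#'   [classify_abundance()]).
#' @param relocalized_to Compartment the protein moved to, or `NA`/`NULL`
#'   for no relocalization.
#' @param own_wt_compartment The protein's own wild-type compartment.
#' @param paralog_wt_compartment The paralog's wild-type compartment.
#' @return List with `call` (`"compensation"`, `"dependency"`, `"none"`, or
#'   `"conflict"`), `compensation`, `dependency` (logical flags).
#' @export
call_comp_dep <- function(direction, relocalized_to = NULL,
                          own_wt_compartment = NA_character_,
                          paralog_wt_compartment = NA_character_) {
  reloc <- !is.null(relocalized_to) && !is.na(relocalized_to)
  comp <- direction == "increased" ||
    (reloc && identical(relocalized_to, paralog_wt_compartment))
  dep <- direction == "decreased" ||
    (reloc && !relocalized_to %in%
       c(own_wt_compartment, paralog_wt_compartment))
  call <- if (comp && dep) "conflict"
          else if (comp) "compensation"
          else if (dep) "dependency" else "none"
  if (call == "conflict")
    warning("conflicting compensation and dependency signals")
  list(call = call, compensation = comp, dependency = dep)
}

#' Abundance analysis of one protein across backgrounds
#'
#' Convenience wrapper combining the abundance score, fold change and
#' rank-sum test for one gene's wild-type and deletion conditions.
#'
#' @param cell_means_wt,cell_means_del Per-cell mean intensities in the two
#'   backgrounds.
#' @param gene,paralog Identifiers carried through.
#' @return One-row data frame: gene, paralog, score_wt, score_del, lfc, p.
#' @export
abundance_compare <- function(cell_means_wt, cell_means_del,
                              gene = NA_character_,
                              paralog = NA_character_) {
  ht <- rank_sum_test(cell_means_wt, cell_means_del)
  data.frame(gene = gene, paralog = paralog,
             score_wt = mean(cell_means_wt),
             score_del = mean(cell_means_del),
             lfc = log2_fold_change(mean(cell_means_wt),
                                    mean(cell_means_del)),
             p = ht$p)
}
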