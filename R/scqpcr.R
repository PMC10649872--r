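#' Single-cell qPCR Ct matrix
#'
#' Cells x genes matrix of raw Ct values (cycles) with a not-detected mask
#' encoded as `NA`, plus the limit of detection used for normalization
#' (24 cycles by default, the Fluidigm Singular default) and optional cell
#' metadata (e.g. sample origin: day-10 ganglion vs day-40 tumor).
#'
#' @param ct numeric cells x genes matrix; `NA` marks not-detected wells
#' @param lod limit of detection in cycles (> 0)
#' @param meta optional data.frame of per-cell metadata, `nrow(ct)` rows
#' @return an object of class `ct_matrix`
#' @export
ct_matrix <- function(ct, lod = 24, meta = NULL) {
  ct <- as.matrix(ct)
  if (!isTRUE(lod > 0)) stop("lod must be positive")
  detected <- !is.na(ct)
  if (any(ct[detected] <= 0))
    stop("detected Ct values must be positive")
  if (!is.null(meta) && nrow(meta) != nrow(ct))
    stop("meta must have one row per cell")
  structure(list(ct = ct, lod = lod, meta = meta), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d cells x %d genes, LOD %g cycles, %.1f%% detected\n",
              nrow(x$ct), ncol(x$ct), x$lod, 100 * mean(!is.na(x$ct))))
  invisible(x)
}

#' LOD-normalize Ct values to log2 expression
#'
#' Expression = LOD - Ct, floored at 0; not-detected wells are 0. One PCR
#' cycle corresponds to one doubling, so the result is on a log2 scale with
#' the limit of detection as its zero.
#'
#' @param x a [ct_matrix()]
#' @return numeric cells x genes matrix of log2 expression (all >= 0)
#' @export
normalize_ct <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  expr <- pmax(x$lod - x$ct, 0)
  expr[is.na(x$ct)] <- 0
  expr
}

#' Signature score: mean per-gene Z across all cells
#'
#' Each signature gene is Z-scored across all cells (or samples); a cell's
#' score is the mean Z over the signature genes present in the matrix.
#' The reference population is always the full matrix: scores are computed
#' before any cell filtering, so later exclusions do not move the scale.
#' Genes with zero variance carry no information and are dropped with a
#' warning; duplicated genes in the signature count once.
#'
#' @param expr cells-or-samples x genes numeric matrix (log2 expression)
#' @param genes character vector of signature gene symbols
#' @return numeric vector, one score per row of `expr`
#' @export
signature_score <- function(expr, genes) {
  expr <- as.matrix(expr)
  genes <- unique(genes)
  present <- intersect(genes, colnames(expr))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  sub <- expr[, present, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance signature gene(s): %s",
                    paste(present[sds == 0], collapse = ", ")))
    sub <- sub[, sds > 0, drop = FALSE]
    # a constant gene's Z is 0 everywhere, so an all-constant signature
    # scores 0 for every cell
    if (ncol(sub) == 0L)
      return(rep(0, nrow(expr)))
  }
  z <- scale(sub)
  rowMeans(z)
}

#' Rule-based cell-type classification from signature scores
#'
#' Applies the threshold rules, Schwannian first:
#' Schwannian score > `schwannian_cutoff` (default 0.75) -> Schwannian;
#' otherwise neuroblast score > 0 and > ganglion score -> neuroblast;
#' otherwise ganglion score > 0 and > neuroblast score -> ganglion;
#' all remaining cells (including exact neuroblast/ganglion ties) are
#' excluded. Inequalities are strict.
#'
#' @param neuroblast,ganglion,schwannian per-cell signature scores (equal
#'   length, no missing values)
#' @param schwannian_cutoff threshold for the Schwannian rule
#' @param n_detected optional per-cell count of detected signature genes;
#'   cells with 0 are excluded outright (with a warning), since their scores
#'   reflect only the not-detected convention
#' @return factor with levels `neuroblast`, `ganglion`, `schwannian`,
#'   `excluded`
#' @export
classify_cells <- function(neuroblast, ganglion, schwannian,
                           schwannian_cutoff = 0.75, n_detected = NULL) {
  n <- length(neuroblast)
  if (length(ganglion) != n || length(schwannian) != n)
    stop("the three score vectors must have equal length")
  if (anyNA(neuroblast) || anyNA(ganglion) || anyNA(schwannian))
    stop("missing score")
  lab <- rep("excluded", n)
  lab[ganglion > 0 & ganglion > neuroblast] <- "ganglion"
  lab[neuroblast > 0 & neuroblast > ganglion] <- "neuroblast"
  lab[schwannian > schwannian_cutoff] <- "schwannian"
  if (!is.null(n_detected)) {
    none <- n_detected == 0
    if (any(none)) {
      warning(sprintf("%d cell(s) with no detected signature gene excluded",
                      sum(none)))
      lab[none] <- "excluded"
    }
  }
  factor(lab, levels = c("neuroblast", "ganglion", "schwannian", "excluded"))
}

#' Two-group rank-sum comparison of a score
#'
#' Two-sided Wilcoxon rank-sum test on a per-cell (or per-tumor) score
#' between two groups, e.g. MGS score in neuroblasts vs ganglion cells. The
#' exact null distribution is used for combined n <= 20 (when no ties), the
#' tie-corrected normal approximation otherwise.
#'
#' @param score numeric vector
#' @param group vector with exactly two distinct values, same length
#' @return list with `statistic` (rank-sum W) and `p_value`
#' @export
compare_groups <- function(score, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L)
    stop("grouping must define exactly two non-empty groups")
  x <- score[group == levels(group)[1L]]
  y <- score[group == levels(group)[2L]]
  if (length(x) == 0L || length(y) == 0L) stop("a group is empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = (length(x) + length(y)) <= 20,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson correlation between a signature score and a marker gene
#'
#' Used for MGS-vs-marker comparisons in single cells (e.g. Phox2b, hMYCN)
#' and for signature-vs-signature correlations in bulk samples or tumors.
#'
#' @param score per-cell/sample signature score
#' @param marker per-cell/sample expression of the marker gene (or a second
#'   signature's scores)
#' @return list with `r` (Pearson correlation) and `p_value` (two-sided)
#' @export
marker_correlation <- function(score, marker) {
  ok <- is.finite(score) & is.finite(marker)
  if (sum(ok) < 3L) stop("need at least 3 cells with finite values")
  x <- score[ok]; y <- marker[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in score or marker")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
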