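#' Per-gene genotype-by-time divergence fit
#'
#' Fits, for every gene, an ordinary least-squares model
#' `expression ~ genotype + time + genotype:time` with genotype coded 0
#' (wild-type) / 1 (transgenic) and time numeric in weeks, and tests the
#' interaction term two-sided. Genes whose trajectories diverge between
#' genotypes over time carry a non-zero interaction slope (log2 units per
#' week). P-values are Benjamini-Hochberg adjusted across genes and genes
#' with q < `alpha` are selected.
#'
#' The fit is vectorized: one QR decomposition of the design is shared by
#' all genes.
#'
#' @param expr samples x genes numeric matrix of log2 expression
#' @param design data.frame with one row per sample: `genotype` (factor or
#'   character; the reference level is wild-type) and `age` (numeric weeks)
#' @param alpha selection level on the BH-adjusted q-values
#' @param wild_type label of the wild-type genotype (coded 0)
#' @return data.frame with one row per gene: `gene`, `beta_interaction`,
#'   `p`, `q`, `selected`
#' @export
fit_divergence <- function(expr, design, alpha = 0.05,
                           wild_type = "wild-type") {
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(design))
    stop("design must have one row per sample (row of expr)")
  g <- as.numeric(design$genotype != wild_type)
  t <- as.numeric(design$age)
  if (length(unique(t)) < 2L || length(unique(g)) < 2L)
    stop("need at least 2 timepoints and 2 genotypes")
  X <- stats::model.matrix(~ g * t)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more samples than model coefficients")

  qrX <- qr(X)
  coefs <- qr.coef(qrX, expr)                    # p x n_genes
  resid <- expr - X %*% coefs
  df_res <- n - p
  sigma2 <- colSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[p, p])             # interaction is last column
  beta <- coefs[p, ]
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df_res)
  # noiseless degenerate fits: residual variance at rounding-error level
  exact <- sigma2 <= .Machine$double.eps^1.5 * pmax(1, colMeans(expr^2))
  pval[exact & abs(beta) <= 1e-8] <- 1
  pval[exact & abs(beta) > 1e-8] <- 0
  qval <- stats::p.adjust(pval, method = "BH")
  data.frame(
    gene = colnames(expr) %||% paste0("gene", seq_along(beta)),
    beta_interaction = unname(beta), p = unname(pval), q = unname(qval),
    selected = unname(qval < alpha),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster selected genes into gene groups
#'
#' Standardizes each gene (Z across samples) and applies agglomerative
#' hierarchical clustering with the Ward criterion on unsquared Euclidean
#' distances (the ward.D2 convention: distances are squared inside the merge
#' criterion, not before), then cuts the tree at `k` groups.
#'
#' @param expr samples x genes matrix
#' @param genes genes to cluster (default: all columns)
#' @param k number of gene groups (default 3)
#' @return list with `groups` (named integer vector of group ids 1..k) and
#'   `hclust` (the dendrogram)
#' @export
cluster_gene_groups <- function(expr, genes = colnames(expr), k = 3) {
  expr <- as.matrix(expr)
  genes <- intersect(genes, colnames(expr))
  if (length(genes) < k) stop("k exceeds the number of genes")
  z <- scale(expr[, genes, drop = FALSE])
  z[, apply(expr[, genes, drop = FALSE], 2, stats::sd) == 0] <- 0
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(groups = stats::cutree(hc, k = k), hclust = hc)
}

#' Genotype-by-time trajectory of a gene-group signature
#'
#' Scores every sample as the mean per-gene Z over the signature genes
#' (see [signature_score()]) and aggregates by genotype and timepoint.
#'
#' @param expr samples x genes matrix
#' @param genes signature gene symbols
#' @param design data.frame with `genotype` and `age` per sample
#' @return data.frame with `genotype`, `age`, `mean_score`, `sd_score`, `n`
#' @export
group_signature_trajectory <- function(expr, genes, design) {
  score <- signature_score(expr, genes)
  agg <- stats::aggregate(
    score,
    by = list(genotype = design$genotype, age = design$age),
    FUN = function(s) c(mean = mean(s), sd = stats::sd(s), n = length(s))
  )
  out <- data.frame(genotype = agg$genotype, age = agg$age,
                    mean_score = agg$x[, "mean"], sd_score = agg$x[, "sd"],
                    n = agg$x[, "n"], stringsAsFactors = FALSE)
  out[order(out$genotype, out$age), , drop = FALSE]
}

#' Correlation between two signature scores
#'
#' Pearson correlation of two per-sample signature scores (e.g. MGS vs a
#' MYC-target signature). Shares its implementation with
#' [marker_correlation()].
#'
#' @param score_a,score_b per-sample signature scores
#' @return list with `r` and `p_value`
#' @export
signature_correlation <- function(score_a, score_b) {
  marker_correlation(score_a, score_b)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a query gene
#' group within a stated universe, with Benjamini-Hochberg adjustment across
#' sets. Sets are flat gene lists (e.g. read from GMT); genes outside the
#' universe are ignored.
#'
#' @param group_genes query genes (must lie within `universe`)
#' @param gene_sets named list of character vectors
#' @param universe character vector of all assayed genes
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `q`
#' @export
ora_hypergeometric <- function(group_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  group_genes <- unique(group_genes)
  if (!all(group_genes %in% universe))
    stop("group genes must be contained in the universe")
  if (any(lengths(gene_sets) == 0L)) stop("gene sets must be non-empty")
  n_univ <- length(universe)
  n_grp <- length(group_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, group_genes))
    m <- length(set)
    p <- stats::phyper(k - 1, m, n_univ - m, n_grp, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
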