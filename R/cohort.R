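#' Stratify tumors by the divergence gene panel
#'
#' Z-scores every panel gene across tumors, clusters tumors with Ward
#' (ward.D2 convention) hierarchical clustering on Euclidean distances, cuts
#' the tree at `k = 3`, and names the classes `MGS.High`, `MGS.Int`,
#' `MGS.Low` by descending mean MGS score, so the names track the score
#' ordering whatever raw cluster ids the cut produces.
#'
#' @param expr tumors x genes matrix (log2 expression)
#' @param panel_genes genes used for clustering (the divergence panel)
#' @param mgs_genes genes of the mitotic gene signature used to name the
#'   classes (default [mgs_signature()])
#' @param k number of classes (default 3)
#' @return list with `classes` (factor `MGS.High`/`MGS.Int`/`MGS.Low`, one
#'   per tumor), `mgs_score` (per-tumor mean Z over `mgs_genes`), and
#'   `hclust`
#' @export
cluster_tumors <- function(expr, panel_genes = colnames(expr),
                           mgs_genes = mgs_signature(), k = 3) {
  expr <- as.matrix(expr)
  panel_genes <- intersect(panel_genes, colnames(expr))
  if (length(panel_genes) == 0L) stop("no panel gene present")
  if (nrow(expr) < k) stop("k exceeds the number of tumors")
  z <- scale(expr[, panel_genes, drop = FALSE])
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  score <- signature_score(expr, mgs_genes)
  cluster_means <- tapply(score, raw, mean)
  ord <- order(cluster_means, decreasing = TRUE)   # raw ids by descending MGS
  level_names <- if (k == 3) c("MGS.High", "MGS.Int", "MGS.Low")
                 else paste0("MGS.", seq_len(k))
  relabel <- stats::setNames(level_names, names(cluster_means)[ord])
  classes <- factor(relabel[as.character(raw)], levels = level_names)
  list(classes = classes, mgs_score = score, hclust = hc)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function with right censoring,
#' via the survival package. The estimate is 1 before the first event.
#'
#' @param time non-negative follow-up times (consistent units)
#' @param event 1 = event observed, 0 = censored
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` at each distinct observed time
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty cohort")
  if (any(time < 0) || !all(event %in% c(0, 1)))
    stop("times must be >= 0 and events 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' K-group log-rank test
#'
#' Standard log-rank statistic over k groups with the aggregated-risk-set
#' handling of tied event times; df = k - 1 and the p-value is the
#' chi-squared upper tail.
#'
#' @param time,event as in [km_estimate()]
#' @param group group membership, >= 2 non-empty groups
#' @return list with `chi2`, `df`, `p_value`
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Clinical covariate splits of the MGS score
#'
#' Rank-sum comparisons of the per-tumor MGS score between the standard
#' clinical strata: MYCN amplified vs non-amplified (tumors with unknown
#' status are dropped from this split only), INSS stage 4 vs other stages,
#' and age > 18 months vs <= 18 months.
#'
#' @param mgs_score per-tumor MGS score
#' @param clinical data.frame with columns `mycn_status`
#'   (`"amplified"`/`"non-amplified"`/`"unknown"`), `stage` (categorical;
#'   `"4"` marks stage 4), `age_group` (`">18m"`/`"<=18m"`)
#' @return data.frame with `split`, `n1`, `n2`, `statistic`, `p_value`
#' @export
clinical_splits <- function(mgs_score, clinical) {
  needed <- c("mycn_status", "stage", "age_group")
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols) > 0)
    stop(sprintf("missing covariate column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  one_split <- function(name, keep, strata) {
    s <- mgs_score[keep]; g <- strata[keep]
    res <- compare_groups(s, g)
    data.frame(split = name, n1 = sum(g == levels(as.factor(g))[1]),
               n2 = sum(g == levels(as.factor(g))[2]),
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }
  known <- clinical$mycn_status != "unknown"
  rbind(
    one_split("MYCN status", known, clinical$mycn_status),
    one_split("Stage 4 vs other", rep(TRUE, nrow(clinical)),
              ifelse(clinical$stage == "4", "stage4", "other")),
    one_split("Age > 18m vs <= 18m", rep(TRUE, nrow(clinical)),
              clinical$age_group)
  )
}
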