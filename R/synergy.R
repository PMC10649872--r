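#' Bliss independence prediction
#'
#' Expected combined fraction-affected of two independently acting agents:
#' `fa + fb - fa * fb`. Both inputs are probabilities in \[0, 1\].
#'
#' @param fa,fb fractions affected (1 - viability) of the single agents;
#'   vectors are combined elementwise
#' @return predicted combined fraction affected, in \[0, 1\]
#' @export
bliss_predicted_effect <- function(fa, fb) {
  if (any(!is.finite(fa)) || any(!is.finite(fb)) ||
      any(fa < 0 | fa > 1) || any(fb < 0 | fb > 1))
    stop("fractions affected must lie in [0, 1]")
  fa + fb - fa * fb
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Theoretical Bliss-additivity curve for a constant-ratio combination
#'
#' At each ladder position i the single agents' fractions affected are taken
#' as 1 minus their mean viabilities (clamped into \[0, 1\], since Bliss is
#' defined on probabilities), combined under Bliss independence, and
#' converted back to a viability. The additive series is indexed on agent A's
#' dose ladder, like the measured combination it is compared with.
#'
#' @param single_a,single_b single-agent [dose_response_series()] whose
#'   ladders correspond to the constant-ratio pairs actually tested
#' @param ratio dose ratio: agent B's dose at position i is
#'   `ratio * single_a$doses[i]` (relative tolerance 1e-6)
#' @return a one-replicate [dose_response_series()] holding the inferred
#'   additive viabilities
#' @export
additivity_curve <- function(single_a, single_b, ratio) {
  stopifnot(inherits(single_a, "dose_response_series"),
            inherits(single_b, "dose_response_series"))
  if (length(single_a$doses) != length(single_b$doses))
    stop("single-agent ladders must have equal length")
  if (!isTRUE(ratio > 0)) stop("ratio must be a positive scalar")
  expected_b <- ratio * single_a$doses
  if (any(abs(single_b$doses - expected_b) > 1e-6 * expected_b))
    stop("agent B doses do not match ratio * agent A doses (tolerance 1e-6)")
  fa <- clamp01(1 - colMeans(single_a$viability))
  fb <- clamp01(1 - colMeans(single_b$viability))
  add_viab <- 1 - bliss_predicted_effect(fa, fb)
  dose_response_series(
    agent = paste0(single_a$agent, "+", single_b$agent, " (additive)"),
    condition = single_a$condition,
    doses = single_a$doses,
    viability = matrix(add_viab, nrow = 1L),
    ratio_partner = list(agent = single_b$agent, ratio = ratio)
  )
}

#' Score a drug combination for synergy and potency
#'
#' Builds the Bliss additivity curve from the single agents, normalizes all
#' AUCs within one comparison set (the measured series plus the additive
#' series; by default the two singles and the combination, and any extra
#' series supplied, e.g. the same experiment under the other MYCN state so
#' that normalization is anchored on the least potent condition across both).
#' Synergy is the additive normalized AUC minus the combination normalized
#' AUC (positive = super-additive killing); potency is 1 minus the
#' combination normalized AUC.
#'
#' @param combo measured combination series (constant ratio, indexed on
#'   agent A's dose)
#' @param single_a,single_b the matching single-agent series
#' @param ratio dose ratio of B to A; defaults to `combo$ratio_partner$ratio`
#' @param extra_comparison optional list of further [dose_response_series()]
#'   to include in the normalization set
#' @return an object of class `synergy_result`: a list with
#'   `combination_label`, `condition`, `auc_combo`, `auc_additive`,
#'   `synergy`, `potency`, and `per_dose_excess` (combination fraction
#'   affected minus the Bliss prediction at each ladder position)
#' @export
score_combination <- function(combo, single_a, single_b, ratio = NULL,
                              extra_comparison = list()) {
  stopifnot(inherits(combo, "dose_response_series"))
  if (is.null(ratio)) ratio <- combo$ratio_partner$ratio
  if (is.null(ratio)) stop("ratio not given and combo carries no ratio_partner")
  additive <- additivity_curve(single_a, single_b, ratio)
  if (length(combo$doses) != length(additive$doses))
    stop("combination ladder does not match the single-agent ladders")

  members <- c(list(single_a, single_b, combo), extra_comparison,
               list(additive))
  labels <- vapply(members, function(s) paste(s$agent, s$condition, sep = " | "),
                   character(1))
  labels <- make.unique(labels)
  raw <- vapply(members, auc_log_dose, numeric(1))
  names(raw) <- labels
  norm <- normalize_auc(raw)
  combo_lab <- labels[[3L]]
  add_lab <- labels[[length(labels)]]
  auc_combo <- norm$normalized_auc[norm$label == combo_lab]
  auc_additive <- norm$normalized_auc[norm$label == add_lab]

  fa_combo <- clamp01(1 - colMeans(combo$viability))
  fa_pred <- 1 - colMeans(additive$viability)

  structure(
    list(
      combination_label = combo$agent,
      condition = combo$condition,
      auc_combo = auc_combo,
      auc_additive = auc_additive,
      synergy = auc_additive - auc_combo,
      potency = 1 - auc_combo,
      per_dose_excess = fa_combo - fa_pred
    ),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> %s [%s]: synergy %.4f, potency %.4f\n",
              x$combination_label, x$condition, x$synergy, x$potency))
  invisible(x)
}

#' MYCN-selectivity table across combinations
#'
#' For each combination scored under both MYCN conditions, reports the
#' between-condition differences in synergy and potency and ranks the
#' combinations lexicographically: largest delta-synergy first, ties broken
#' by delta-potency, then by combination label (stable).
#'
#' @param results list of `synergy_result` objects covering every
#'   combination under both conditions
#' @param condition_pos,condition_neg the condition labels to difference
#'   (positive minus negative)
#' @return data.frame with one row per combination: synergy and potency in
#'   each condition, `d_synergy`, `d_potency`, and `rank` (1 = most
#'   MYCN-selective)
#' @export
myc_selectivity_table <- function(results, condition_pos = "MYCN+",
                                  condition_neg = "MYCN-") {
  stopifnot(length(results) > 0)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(combination = r$combination_label, condition = r$condition,
               synergy = r$synergy, potency = r$potency,
               stringsAsFactors = FALSE)
  }))
  combos <- sort(unique(df$combination))
  rows <- lapply(combos, function(cb) {
    pos <- df[df$combination == cb & df$condition == condition_pos, ]
    neg <- df[df$combination == cb & df$condition == condition_neg, ]
    if (nrow(pos) != 1L || nrow(neg) != 1L)
      stop(sprintf("combination '%s' lacks a matched condition pair", cb))
    data.frame(
      combination = cb,
      synergy_pos = pos$synergy, synergy_neg = neg$synergy,
      d_synergy = pos$synergy - neg$synergy,
      potency_pos = pos$potency, potency_neg = neg$potency,
      d_potency = pos$potency - neg$potency,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$d_synergy, -out$d_potency, out$combination)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}
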