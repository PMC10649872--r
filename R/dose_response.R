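#' Dose-response series
#'
#' Container for one agent (or one fixed-ratio combination) measured over an
#' increasing dose ladder with replicate viabilities under a named condition
#' (e.g. `"MYCN+"` / `"MYCN-"`). Viability is the fraction of untreated
#' control; values above 1 are retained (plate readers can report more signal
#' than control wells).
#'
#' @param agent agent label (for a combination, e.g. `"barasertib+S63845"`)
#' @param condition condition label, e.g. MYCN induction state
#' @param doses strictly increasing positive doses (molar)
#' @param viability replicate x dose matrix (or a vector for one replicate)
#'   of non-negative viabilities, fraction of untreated control
#' @param ratio_partner optional list `(agent, ratio)` recording that this
#'   series is a constant-ratio combination: the partner agent's dose at
#'   ladder position i is `ratio * doses[i]`
#' @return an object of class `dose_response_series`
#' @export
dose_response_series <- function(agent, condition, doses, viability,
                                 ratio_partner = NULL) {
  doses <- as.numeric(doses)
  if (length(doses) < 2L)
    stop("a dose-response series needs at least 2 doses")
  if (any(doses <= 0) || any(diff(doses) <= 0))
    stop("doses must be strictly increasing and positive")
  if (is.null(dim(viability)))
    viability <- matrix(viability, nrow = 1L)
  viability <- as.matrix(viability)
  if (ncol(viability) != length(doses))
    stop("viability must have one column per dose")
  if (any(!is.finite(viability)) || any(viability < 0))
    stop("viabilities must be finite and non-negative")
  structure(
    list(agent = as.character(agent), condition = as.character(condition),
         doses = doses, viability = viability, ratio_partner = ratio_partner),
    class = "dose_response_series"
  )
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("<dose_response_series> %s [%s]: %d doses x %d replicates\n",
              x$agent, x$condition, length(x$doses), nrow(x$viability)))
  invisible(x)
}

#' Normalize raw plate signal to viability
#'
#' Divides every well by the mean control signal of its replicate row, so
#' untreated controls map to 1 on average. No clipping is applied.
#'
#' @param raw_signal replicate x well matrix of raw fluorescence/absorbance
#' @param control_wells column indices of the untreated control wells
#' @return replicate x well matrix of viabilities (control columns retained)
#' @export
normalize_viability <- function(raw_signal, control_wells) {
  raw_signal <- as.matrix(raw_signal)
  if (length(control_wells) < 1L)
    stop("at least one control well is required")
  ctrl <- rowMeans(raw_signal[, control_wells, drop = FALSE])
  if (any(ctrl <= 0))
    stop("control mean must be positive in every replicate")
  sweep(raw_signal, 1L, ctrl, "/")
}

#' Area under the dose-response curve on a log10 dose axis
#'
#' Trapezoidal integral of mean viability over log10(dose), from the lowest
#' to the highest dose. No curve fitting or interpolation is performed: the
#' observed mean curve is integrated as plotted. Units are
#' viability x log10-dose.
#'
#' @param series a [dose_response_series()]
#' @return raw AUC (scalar)
#' @export
auc_log_dose <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  pracma::trapz(log10(series$doses), colMeans(series$viability))
}

#' Per-replicate AUCs of a series
#'
#' @param series a [dose_response_series()]
#' @return numeric vector, one log10-dose trapezoidal AUC per replicate
#' @export
replicate_aucs <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  lx <- log10(series$doses)
  apply(series$viability, 1L, function(v) pracma::trapz(lx, v))
}

#' Normalize raw AUCs within a comparison set
#'
#' Each raw AUC is expressed as a fraction of the maximum raw AUC in the set,
#' i.e. relative to the least potent condition, which is anchored at 1. The
#' comparison set conventionally holds all series of one combination
#' experiment across both MYCN conditions.
#'
#' @param aucs named numeric vector of raw AUCs (names are series labels)
#' @return data.frame with columns `label`, `raw_auc`, `normalized_auc`,
#'   `reference_label`
#' @export
normalize_auc <- function(aucs) {
  if (length(aucs) < 1L) stop("comparison set must be non-empty")
  if (is.null(names(aucs)) || anyNA(names(aucs)) || any(names(aucs) == ""))
    stop("raw AUCs must be labelled")
  ref <- which.max(aucs)
  if (aucs[ref] <= 0)
    stop("maximum raw AUC must be positive to define the reference")
  data.frame(
    label = names(aucs),
    raw_auc = as.numeric(aucs),
    normalized_auc = as.numeric(aucs) / aucs[[ref]],
    reference_label = names(aucs)[ref],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare the AUCs of two series at replicate level
#'
#' Computes one log10-dose AUC per replicate in each series and applies a
#' two-sided two-sample (Welch) t-test. Degenerate zero-variance cases are
#' handled explicitly: identical replicate AUCs in both groups give p = 1
#' (no evidence), and zero-variance groups offset by a constant give a
#' machine-floor p.
#'
#' @param series_a,series_b [dose_response_series()] objects with >= 2
#'   replicates each
#' @return list with `difference` (mean AUC of a minus mean AUC of b) and
#'   `p_value`
#' @export
compare_auc <- function(series_a, series_b) {
  a <- replicate_aucs(series_a)
  b <- replicate_aucs(series_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both series need at least 2 replicates")
  diff_ab <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (diff_ab == 0) 1 else .Machine$double.xmin
  } else {
    p <- stats::t.test(a, b)$p.value
  }
  list(difference = diff_ab, p_value = p)
}
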