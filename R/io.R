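#' Read and write the pipeline's file formats
#'
#' All tabular formats are UTF-8, comma-separated with a header row. GMT is
#' the usual tab-separated `name, description, gene, gene, ...` layout.
#' Identifiers are case-sensitive exact strings; duplicate ids are an error.
#'
#' @name mgskit-io
NULL

stop_if_empty <- function(df, path) {
  if (nrow(df) == 0L) stop(sprintf("%s: empty file", path))
  df
}

check_numeric_cells <- function(df, cols, path, offset = 1L) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value in column '%s' at line(s) %s",
                   path, cl, paste(bad + offset, collapse = ", ")))
    df[[cl]] <- v
  }
  df
}

#' Read an expression matrix CSV
#'
#' First column = sample/cell/tumor id, remaining columns = genes.
#'
#' @param path CSV file path
#' @return numeric samples x genes matrix with dimnames
#' @export
read_expression_csv <- function(path) {
  df <- stop_if_empty(utils::read.csv(path, check.names = FALSE,
                                      colClasses = "character"), path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicate sample ids", path))
  if (anyDuplicated(names(df)[-1L])) stop(sprintf("%s: duplicate gene ids", path))
  df <- check_numeric_cells(df, names(df)[-1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (any(!is.finite(m))) stop(sprintf("%s: missing or non-finite values", path))
  m
}

#' @rdname read_expression_csv
#' @param expr samples x genes matrix
#' @param id_col name of the identifier column
#' @export
write_expression_csv <- function(expr, path, id_col = "sample") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-cell Ct matrix CSV
#'
#' Cells as rows, genes as columns; the sentinel `"ND"` or a blank cell
#' marks a not-detected well.
#'
#' @param path CSV path
#' @param lod limit of detection in cycles
#' @param meta optional per-cell metadata data.frame
#' @return a [ct_matrix()]
#' @export
read_ct_csv <- function(path, lod = 24, meta = NULL) {
  df <- stop_if_empty(utils::read.csv(path, check.names = FALSE,
                                      colClasses = "character"), path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicate cell ids", path))
  if (anyDuplicated(names(df)[-1L])) stop(sprintf("%s: duplicate gene ids", path))
  body <- df[, -1L, drop = FALSE]
  body[body == "ND" | body == ""] <- NA
  body <- check_numeric_cells(body, names(body), path)
  m <- as.matrix(body)
  rownames(m) <- ids
  ct_matrix(m, lod = lod, meta = meta)
}

#' @rdname read_ct_csv
#' @param x a [ct_matrix()]
#' @export
write_ct_csv <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  m <- matrix(ifelse(is.na(x$ct), "ND", format(x$ct, trim = TRUE,
                                               digits = 15)),
              nrow = nrow(x$ct), dimnames = dimnames(x$ct))
  df <- data.frame(cell = rownames(m) %||% sprintf("cell%04d", seq_len(nrow(m))),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path: tab-separated `name`, `description`, then genes
#' @return named list of character gene vectors; descriptions kept in the
#'   `"description"` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0)
    stop(sprintf("%s: malformed GMT line(s) %s (need name, description, >=1 gene)",
                 path, paste(short, collapse = ", ")))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop(sprintf("%s: duplicate set names", path))
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @param descriptions optional character vector of set descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "description") %||% rep("", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read dose-response plates from a long-format CSV
#'
#' Expected columns: `agent`, `condition`, `dose`, `replicate`, `value`,
#' `is_control`. If control rows are present for an (agent, condition)
#' block, every value is normalized by its replicate's mean control signal
#' (see [normalize_viability()]); otherwise values are taken as viabilities.
#'
#' @param path CSV path
#' @return list of [dose_response_series()], one per (agent, condition)
#' @export
read_plates_csv <- function(path) {
  df <- stop_if_empty(utils::read.csv(path, check.names = FALSE,
                                      colClasses = "character"), path)
  needed <- c("agent", "condition", "dose", "replicate", "value", "is_control")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df <- check_numeric_cells(df, c("dose", "value"), path)
  df$is_control <- df$is_control %in% c("TRUE", "true", "1")
  keys <- unique(df[, c("agent", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    blk <- df[df$agent == keys$agent[i] & df$condition == keys$condition[i], ]
    reps <- sort(unique(blk$replicate))
    doses <- sort(unique(blk$dose[!blk$is_control]))
    viab <- matrix(NA_real_, nrow = length(reps), ncol = length(doses))
    for (r in seq_along(reps)) {
      rb <- blk[blk$replicate == reps[r], ]
      ctrl <- rb$value[rb$is_control]
      vals <- rb$value[!rb$is_control][order(rb$dose[!rb$is_control])]
      if (length(vals) != length(doses))
        stop(sprintf("%s: agent %s replicate %s does not cover the dose ladder",
                     path, keys$agent[i], reps[r]))
      viab[r, ] <- if (length(ctrl) > 0) vals / mean(ctrl) else vals
    }
    dose_response_series(keys$agent[i], keys$condition[i], doses, viab)
  })
  out
}

#' @rdname read_plates_csv
#' @param series_list list of [dose_response_series()]
#' @export
write_plates_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    expand <- expand.grid(replicate = seq_len(nrow(s$viability)),
                          dose_idx = seq_along(s$doses))
    data.frame(agent = s$agent, condition = s$condition,
               dose = s$doses[expand$dose_idx], replicate = expand$replicate,
               value = s$viability[cbind(expand$replicate, expand$dose_idx)],
               is_control = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Required columns: `time` (>= 0) and `event` (0/1); the standard clinical
#' covariates `mycn_status`, `stage`, `age_group` are kept when present.
#'
#' @param path CSV path
#' @return data.frame validated against the survival invariants
#' @export
read_clinical_csv <- function(path) {
  df <- stop_if_empty(utils::read.csv(path, check.names = FALSE,
                                      colClasses = "character"), path)
  miss <- setdiff(c("time", "event"), names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df <- check_numeric_cells(df, c("time", "event"), path)
  if (any(df$time < 0)) stop(sprintf("%s: negative survival time", path))
  if (!all(df$event %in% c(0, 1))) stop(sprintf("%s: event must be 0/1", path))
  df
}

#' @rdname read_clinical_csv
#' @param clinical data.frame
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured run configuration
#'
#' A flat YAML-serialized configuration recording the seed and analysis
#' parameters, round-tripping losslessly so any run can be reproduced
#' byte-identically from its recorded config.
#'
#' @param seed integer seed
#' @param alpha selection level for divergence
#' @param lod single-cell limit of detection (cycles)
#' @param k_clusters number of gene/tumor clusters
#' @param normalization_reference AUC normalization policy
#' @param paths named list of file paths
#' @return an object of class `run_config` (a named list)
#' @export
run_config <- function(seed = 1, alpha = 0.05, lod = 24, k_clusters = 3,
                       normalization_reference = "max-auc-in-comparison-set",
                       paths = list()) {
  structure(list(seed = as.integer(seed), alpha = alpha, lod = lod,
                 k_clusters = as.integer(k_clusters),
                 normalization_reference = normalization_reference,
                 paths = paths),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, c(x[setdiff(names(x), "paths")],
                        list(paths = x$paths %||% list())))
}
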