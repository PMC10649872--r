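#' Gene signatures used throughout the pipeline
#'
#' `mgs_signature()` returns the 9-gene mitotic gene signature (MGS) scored
#' across bulk samples, single cells and tumors. `celltype_signatures()`
#' returns the three 3-gene marker panels used to type cells dissociated from
#' sympathetic ganglia and tumors: immature neuroblasts, mature ganglion
#' cells, and Schwannian stroma.
#'
#' Gene identifiers are case-sensitive exact strings; no human/mouse symbol
#' aliasing is applied (mouse-cased symbols are used for the murine panels,
#' and `hMYCN` denotes the human transgene probe).
#'
#' @return `mgs_signature()`: a character vector of 9 gene symbols.
#'   `celltype_signatures()`: a named list of three character vectors
#'   (`neuroblast`, `ganglion`, `schwannian`).
#' @export
mgs_signature <- function() {
  c("Bub1b", "Kif23", "Bub1", "Kifc1", "Aspm", "Plk4", "Depdc1a", "Ccnb2",
    "Prr11")
}

#' @rdname mgs_signature
#' @export
celltype_signatures <- function() {
  list(
    neuroblast = c("Phox2b", "hMYCN", "Dlk1"),
    ganglion   = c("Gap43", "Dbh", "Tubb3"),
    schwannian = c("Sox10", "Col1a2", "S100a1")
  )
}

#' Full targeted single-cell qPCR panel
#'
#' The 18-gene panel assayed per cell: the three cell-type marker triplets
#' plus the 9 MGS genes.
#'
#' @return character vector of 18 gene symbols
#' @export
scqpcr_panel <- function() {
  c(unlist(celltype_signatures(), use.names = FALSE), mgs_signature())
}
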