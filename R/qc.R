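#' Barcode- and gene-level QC thresholds
#'
#' The defaults are the study's exact published cutoffs for human temporal
#' cortex snRNA-seq: keep barcodes with at least 200 UMIs at the pre-call
#' stage, then remove barcodes with fewer than 400 or more than 8000
#' detected genes, fewer than 500 or more than 46425 mapped UMIs, or more
#' than 10% of UMIs mapped to the mitochondrial genome; finally remove
#' genes detected in fewer than 5 cells. Removal conditions are strict
#' inequalities, so boundary values are retained.
#'
#' @param min_umi_precall Minimum UMI count at the pre-call stage.
#' @param min_genes,max_genes Detected-gene bounds (remove if `< min` or
#'   `> max`).
#' @param min_umi,max_umi Mapped-UMI bounds (remove if `< min` or `> max`).
#' @param max_mito_frac Maximum mitochondrial UMI fraction (remove if
#'   greater), computed on the raw counts of the barcode.
#' @param min_cells_per_gene Minimum number of cells a gene must be
#'   detected in (UMI >= 1) to be retained.
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi_precall = 200,
                          min_genes = 400, max_genes = 8000,
                          min_umi = 500, max_umi = 46425,
                          max_mito_frac = 0.10,
                          min_cells_per_gene = 5) {
  th <- list(min_umi_precall = min_umi_precall,
             min_genes = min_genes, max_genes = max_genes,
             min_umi = min_umi, max_umi = max_umi,
             max_mito_frac = max_mito_frac,
             min_cells_per_gene = min_cells_per_gene)
  if (th$min_genes >= th$max_genes || th$min_umi >= th$max_umi) {
    stop("paired bounds must satisfy min < max")
  }
  if (th$max_mito_frac < 0 || th$max_mito_frac > 1) {
    stop("`max_mito_frac` must lie in [0, 1]")
  }
  structure(th, class = "qc_thresholds")
}

new_qc_report <- function(axis, n_input, n_retained, removed_by_rule) {
  structure(list(
    axis = axis, n_input = n_input, n_retained = n_retained,
    n_removed = n_input - n_retained,
    rules = tibble::tibble(rule = names(removed_by_rule),
                           n_removed = lengths(removed_by_rule)),
    removed_by_rule = removed_by_rule,
    notes = character(0)), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %d -> %d (removed %d)\n",
              x$axis, x$n_input, x$n_retained, x$n_removed))
  print(x$rules)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Filter barcodes by UMI, detected-gene and mitochondrial-fraction rules
#'
#' A barcode is retained iff it satisfies all of: UMI >= `min_umi_precall`;
#' `min_genes` <= detected genes <= `max_genes`; `min_umi` <= UMI <=
#' `max_umi`; mitochondrial fraction <= `max_mito_frac`. The rules are a
#' conjunction, so their order is irrelevant; the mitochondrial fraction is
#' computed on the raw (pre-filter) counts of each barcode. The order of
#' surviving barcodes is preserved.
#'
#' @param cm A [count_matrix()] whose gene metadata carries a logical
#'   `mito` column.
#' @param thresholds A [qc_thresholds()].
#' @return A list with elements `counts` (the filtered [count_matrix()])
#'   and `report` (a `qc_report` with per-rule removed-barcode lists).
#' @export
filter_barcodes <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"),
            inherits(thresholds, "qc_thresholds"))
  if (!"mito" %in% names(cm$genes)) {
    stop("gene metadata must carry a logical `mito` flag")
  }
  th <- thresholds
  umi <- Matrix::colSums(cm$counts)
  n_genes <- Matrix::colSums(cm$counts > 0)
  mito_umi <- Matrix::colSums(cm$counts[cm$genes$mito, , drop = FALSE])
  mito_frac <- ifelse(umi > 0, mito_umi / umi, 0)
  bc <- cm$cells$barcode

  removed <- list(
    precall_umi = bc[umi < th$min_umi_precall],
    detected_genes = bc[n_genes < th$min_genes | n_genes > th$max_genes],
    mapped_umi = bc[umi < th$min_umi | umi > th$max_umi],
    mito_fraction = bc[mito_frac > th$max_mito_frac])
  keep <- umi >= th$min_umi_precall &
    n_genes >= th$min_genes & n_genes <= th$max_genes &
    umi >= th$min_umi & umi <= th$max_umi &
    mito_frac <= th$max_mito_frac
  if (!any(keep)) stop("no barcodes survive QC filtering")
  list(counts = subset_count_matrix(cm, cells = which(keep)),
       report = new_qc_report("barcodes", length(bc), sum(keep), removed))
}

#' Filter genes by minimum detection across cells
#'
#' Retains genes detected (UMI >= 1) in at least `min_cells_per_gene`
#' cells; applied after barcode filtering (the order is part of the
#' contract). If `protein_coding_only = TRUE` and the gene metadata has a
#' `protein_coding` flag, non-coding genes are also removed.
#'
#' @param cm A [count_matrix()], typically the output of
#'   [filter_barcodes()].
#' @param thresholds A [qc_thresholds()].
#' @param protein_coding_only Restrict to protein-coding genes when the
#'   metadata flag is present.
#' @return A list with elements `counts` and `report`, as in
#'   [filter_barcodes()] but on the gene axis.
#' @export
filter_genes <- function(cm, thresholds = qc_thresholds(),
                         protein_coding_only = FALSE) {
  stopifnot(inherits(cm, "count_matrix"),
            inherits(thresholds, "qc_thresholds"))
  det <- Matrix::rowSums(cm$counts > 0)
  keep <- det >= thresholds$min_cells_per_gene
  removed <- list(low_detection = cm$genes$gene[!keep])
  if (protein_coding_only && "protein_coding" %in% names(cm$genes)) {
    removed$non_coding <- cm$genes$gene[!cm$genes$protein_coding]
    keep <- keep & cm$genes$protein_coding
  }
  if (!any(keep)) stop("no genes survive QC filtering")
  list(counts = subset_count_matrix(cm, genes = which(keep)),
       report = new_qc_report("genes", nrow(cm$genes), sum(keep), removed))
}

#' Remove externally labelled doublet barcodes
#'
#' Doublet detection itself is out of scope: labels (e.g. from Scrublet)
#' are consumed, not computed. Labels that reference absent barcodes are
#' logged with a warning, not fatal.
#'
#' @param cm A [count_matrix()].
#' @param doublet_barcodes Character vector of barcodes to remove.
#' @return A list with elements `counts` and `report`.
#' @export
apply_doublet_labels <- function(cm, doublet_barcodes) {
  stopifnot(inherits(cm, "count_matrix"))
  doublet_barcodes <- unique(doublet_barcodes)
  unknown <- setdiff(doublet_barcodes, cm$cells$barcode)
  present <- intersect(doublet_barcodes, cm$cells$barcode)
  keep <- !(cm$cells$barcode %in% present)
  rep <- new_qc_report("barcodes", length(keep), sum(keep),
                       list(doublet = present))
  if (length(unknown)) {
    rep$notes <- sprintf("%d doublet label(s) reference absent barcodes",
                         length(unknown))
    warning(rep$notes)
  }
  if (!any(keep)) stop("no barcodes survive doublet removal")
  list(counts = subset_count_matrix(cm, cells = which(keep)), report = rep)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(axis = report$axis, n_input = report$n_input,
         n_retained = report$n_retained, n_removed = report$n_removed,
         removed_by_rule = report$removed_by_rule, notes = report$notes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
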