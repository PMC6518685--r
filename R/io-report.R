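#' Columns of the per-gene family report
#' @keywords internal
family_report_columns <- function() {
  c("gene_id", "type", "ecm_spacing", "protein_length_aa", "cds_length_bp",
    "mw_kda", "pi", "intron_count", "chrom", "start", "end")
}

#' Write the per-gene family report
#'
#' One row per classified gene, the analog of a supplementary "features of
#' the deduced proteins" table: identifier, assigned type, ECM spacing
#' string, protein length (aa), CDS length (bp), molecular weight (kDa),
#' isoelectric point, intron count and genomic position.
#'
#' @param rows data.frame containing at least the columns of
#'   [family_report_columns()].
#' @param path Output TSV path.
#' @return The sorted data.frame, invisibly.
#' @details Rows are written in a stable order: by type, then gene id.
#'   Missing mandatory columns raise a schema error.
#' @export
write_family_report <- function(rows, path) {
  cols <- family_report_columns()
  if (!is.data.frame(rows)) stop("rows must be a data.frame")
  missing <- setdiff(cols, names(rows))
  if (length(missing)) {
    stop("family report schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- rows[, cols, drop = FALSE]
  if (nrow(rows)) rows <- rows[order(rows$type, rows$gene_id), , drop = FALSE]
  rownames(rows) <- NULL
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(rows)
}

#' Write a generic TSV report with a header row
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
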