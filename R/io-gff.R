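#' Read gene loci and gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `exon` features. Coordinates are GFF3
#' conventions throughout the package: 1-based, inclusive. Each gene is
#' assigned a per-chromosome ordinal `rank` by ascending start, ties broken
#' by ascending end then lexicographic gene id; the tandem-duplication rule
#' counts intervening genes on these ranks.
#'
#' @param path Path to a GFF3 file.
#' @return A list with
#'   * `loci`: data.frame `gene_id`, `chrom`, `strand`, `start`, `end`,
#'     `rank`;
#'   * `models`: named list (by gene id) of gene models, each a list with
#'     `gene_id`, `mrna_id` and an `exons` two-column matrix
#'     (`start`, `end`), sorted, non-overlapping. When a gene carries
#'     several mRNAs the first in file order is taken as representative and
#'     the choice is recorded in `mrna_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) vapply(p, function(x) as.character(x)[1] %||% NA_character_, character(1))

  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  loci <- data.frame(
    gene_id = as.character(genes$ID),
    chrom = genes$seqnames,
    strand = genes$strand,
    start = genes$start,
    end = genes$end,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene id in GFF3")
  if (any(!loci$strand %in% c("+", "-"))) {
    stop("gene feature without +/- strand: ",
         loci$gene_id[!loci$strand %in% c("+", "-")][1])
  }
  loci <- loci[order(loci$chrom, loci$start, loci$end, loci$gene_id), ]
  loci$rank <- stats::ave(seq_len(nrow(loci)), loci$chrom, FUN = seq_along)
  rownames(loci) <- NULL

  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(mrnas) > 0) mrnas$parent <- first_parent(mrnas$Parent)
  if (nrow(exons) > 0) exons$parent <- first_parent(exons$Parent)

  models <- list()
  for (i in seq_len(nrow(loci))) {
    gid <- loci$gene_id[i]
    gm <- mrnas[!is.na(mrnas$parent) & mrnas$parent == gid, , drop = FALSE]
    if (nrow(gm) == 0) next
    mid <- as.character(gm$ID)[1]
    ge <- exons[!is.na(exons$parent) & exons$parent == mid, , drop = FALSE]
    if (nrow(ge) == 0) next
    ex <- cbind(start = ge$start, end = ge$end)
    ex <- ex[order(ex[, 1], ex[, 2]), , drop = FALSE]
    if (any(ex[, 1] < loci$start[i]) || any(ex[, 2] > loci$end[i])) {
      stop("exon outside parent gene span for gene '", gid, "'")
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      stop("overlapping exons in gene '", gid, "'")
    }
    models[[gid]] <- list(gene_id = gid, mrna_id = mid, exons = ex)
  }
  list(loci = loci, models = models)
}

#' Number of introns of a gene model
#'
#' @param model A gene model as returned in `read_gff3()$models`.
#' @return Integer: number of exons minus one.
#' @export
count_introns <- function(model) {
  stopifnot(is.list(model), is.matrix(model$exons), nrow(model$exons) >= 1)
  nrow(model$exons) - 1L
}
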