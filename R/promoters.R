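#' Bundled cis-element functional categories
#'
#' Element-name to category mapping for the family survey's three
#' functional groups: A = phytohormone response, B = biotic/abiotic
#' stress, C = growth and development. Motif sequences are user input
#' (the upstream motif database's content is not redistributable);
#' endosperm-development elements are deliberately absent.
#'
#' @return data.frame `element`, `category`.
#' @export
default_element_categories <- function() {
  if (is.null(.ltp_cache$elements)) {
    .ltp_cache$elements <- utils::read.delim(
      ltp_extdata("cis_element_categories.tsv"), stringsAsFactors = FALSE)
  }
  .ltp_cache$elements
}

#' Read a cis-element motif table
#'
#' @param path TSV with columns `element`, `pattern` (IUPAC nucleotide
#'   codes), `category` (A/B/C).
#' @return Validated data.frame.
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "pattern", "category")
  if (!all(need %in% names(df))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(df$pattern))) stop("empty motif pattern")
  bad <- grepl("[^ACGTURYSWKMBDHVN]", toupper(df$pattern))
  if (any(bad)) stop("non-IUPAC character in pattern for ", df$element[bad][1])
  df$pattern <- toupper(df$pattern)
  df
}

#' Extract promoter windows upstream of gene starts
#'
#' For a `+`-strand gene the window is the `length` bp immediately 5' of
#' the gene start; for a `-`-strand gene, the reverse complement of the
#' `length` bp immediately downstream of the gene end. The transcription
#' start site is approximated by the gene-feature boundary. Windows are
#' truncated at chromosome edges and flagged.
#'
#' @param loci Gene loci data.frame (from [read_gff3()]).
#' @param genome Named character vector of chromosome sequences.
#' @param length Window length in bp (default 1500).
#' @return List `seqs` (named character vector, one promoter per gene) and
#'   `truncated` (named logical vector).
#' @export
extract_promoters <- function(loci, genome, length = 1500L) {
  miss <- setdiff(unique(loci$chrom), names(genome))
  if (base::length(miss)) stop("chromosome(s) missing from genome: ",
                               paste(miss, collapse = ", "))
  seqs <- character(nrow(loci)); trunc <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    chrom <- genome[[loci$chrom[i]]]
    clen <- nchar(chrom)
    if (loci$strand[i] == "+") {
      to <- loci$start[i] - 1L
      from <- max(1L, loci$start[i] - length)
      s <- if (to >= from) substr(chrom, from, to) else ""
    } else {
      from <- loci$end[i] + 1L
      to <- min(clen, loci$end[i] + length)
      s <- if (to >= from) substr(chrom, from, to) else ""
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    seqs[i] <- s
    trunc[i] <- nchar(s) < length
  }
  names(seqs) <- names(trunc) <- loci$gene_id
  list(seqs = seqs, truncated = trunc)
}

#' Scan promoters for cis-element motifs
#'
#' Exact IUPAC matching, case-insensitive, on both strands by default;
#' overlapping matches are all reported. Minus-strand hits are reported at
#' the forward-strand start of the matched window.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param motifs Motif table as from [read_motifs()].
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return List `hits` (data.frame `gene_id`, `element`, `category`,
#'   `strand`, `start`) and `counts` (data.frame `gene_id`, `A`, `B`, `C`,
#'   `total`).
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  stopifnot(!is.null(names(promoters)))
  rows <- list()
  for (g in names(promoters)) {
    subj <- Biostrings::DNAString(toupper(promoters[[g]]))
    if (length(subj) == 0) next
    for (k in seq_len(nrow(motifs))) {
      pat <- Biostrings::DNAString(motifs$pattern[k])
      if (length(pat) > length(subj)) next
      fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
      for (st in Biostrings::start(fwd)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = g, element = motifs$element[k],
          category = motifs$category[k], strand = "+", start = st,
          stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                        subj, fixed = FALSE)
        for (st in Biostrings::start(rev)) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, element = motifs$element[k],
            category = motifs$category[k], strand = "-", start = st,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), element = character(0),
               category = character(0), strand = character(0),
               start = integer(0), stringsAsFactors = FALSE)
  counts <- data.frame(gene_id = names(promoters), stringsAsFactors = FALSE)
  for (cat in c("A", "B", "C")) {
    counts[[cat]] <- vapply(counts$gene_id, function(g) {
      sum(hits$gene_id == g & hits$category == cat)
    }, integer(1))
  }
  counts$total <- counts$A + counts$B + counts$C
  rownames(counts) <- NULL
  list(hits = hits, counts = counts)
}
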