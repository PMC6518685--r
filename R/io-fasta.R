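#' Read a FASTA file into a named character vector
#'
#' Sequences are represented throughout the package as named character
#' vectors: names are record identifiers (the first whitespace-delimited
#' token of each header), values are upper-cased sequences.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (20 standard residues plus `X`) or
#'   `"nucleotide"` (`ACGTN`).
#' @return Named character vector of upper-cased sequences.
#' @details Duplicate identifiers, empty sequences, empty identifiers and
#'   characters outside the declared alphabet are rejected with an error
#'   naming the offending record.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MCK"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(stats::setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at record ",
         which(is.na(ids) | !nzchar(ids))[1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for record '", ids[empty][1], "'")
  allowed <- if (alphabet == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    stop("record '", ids[bad][1], "' contains characters outside the ",
         alphabet, " alphabet")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
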