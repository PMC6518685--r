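blosum62 <- function() {
  if (is.null(.ltp_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ltp_cache$blosum62 <- e$BLOSUM62
  }
  .ltp_cache$blosum62
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Gotoh three-state dynamic programming. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (the opening residue carries the open
#' penalty). Tie-breaking is deterministic: diagonal (substitution) is
#' preferred over a gap in `b` ("up", consuming `a`), which is preferred
#' over a gap in `a` ("left").
#'
#' @param a,b Non-empty protein sequences.
#' @param submat Substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults 10
#'   and 0.5).
#' @return List `aligned_a`, `aligned_b` (equal-length gapped strings, no
#'   dual-gap column), `score`.
#' @export
align_proteins_global <- function(a, b, submat = blosum62(),
                                  gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (any(!av %in% rownames(submat))) stop("residue absent from matrix in a")
  if (any(!bv %in% colnames(submat))) stop("residue absent from matrix in b")
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # state 1 = M (diagonal), 2 = X (up, gap in b), 3 = Y (left, gap in a)
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- matrix(0L, n + 1, m + 1)
  ptrY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -(gap_open + (i - 2) * gap_extend)
    ptrX[i, 1] <- if (i == 2) 1L else 2L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -(gap_open + (j - 2) * gap_extend)
    ptrY[1, j] <- if (j == 2) 1L else 3L
  }
  pick <- function(cands) which.max(cands)  # first max: M > X > Y priority
  for (i in 2:(n + 1)) {
    si <- submat[av[i - 1], ]
    for (j in 2:(m + 1)) {
      s <- si[bv[j - 1]]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- pick(cand)
      M[i, j] <- cand[k] + s
      ptrM[i, j] <- k
      cand <- c(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend,
                Y[i - 1, j] - gap_open)
      k <- pick(cand)
      X[i, j] <- cand[k]
      ptrX[i, j] <- k
      cand <- c(M[i, j - 1] - gap_open, X[i, j - 1] - gap_open,
                Y[i, j - 1] - gap_extend)
      k <- pick(cand)
      Y[i, j] <- cand[k]
      ptrY[i, j] <- k
    }
  }
  state <- pick(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  score <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])[state]
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      prev <- ptrM[i, j]
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- ptrX[i, j]
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      i <- i - 1
    } else {
      prev <- ptrY[i, j]
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      j <- j - 1
    }
    state <- prev
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""), score = unname(score))
}

#' Translate a coding sequence
#'
#' Standard genetic code; a terminal stop codon is stripped first; codons
#' containing `N` translate to `X`.
#'
#' @param cds Nucleotide string (`ACGTN`), length divisible by 3 after
#'   terminal-stop removal.
#' @return Amino-acid string without the terminal stop.
#' @export
translate_cds <- function(cds) {
  cds <- strip_terminal_stop(toupper(cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X", unname(gc[codons]))
  if (any(is.na(aa))) stop("untranslatable codon: ", codons[is.na(aa)][1])
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

#' Strip a terminal stop codon if present
#' @param cds Upper-case nucleotide string.
#' @return The CDS without its final codon when that codon is a stop.
#' @export
strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3 && n %% 3 == 0 &&
      substr(cds, n - 2, n) %in% c("TAA", "TAG", "TGA")) {
    return(substr(cds, 1, n - 3))
  }
  cds
}

#' Check that a CDS translates to its paired protein
#'
#' Fails loudly on mismatch rather than repairing silently: downstream
#' Ka/Ks validity depends on correct pairing. `X` in the protein is
#' tolerated opposite an `N`-containing codon.
#'
#' @param cds Coding sequence.
#' @param protein Protein sequence.
#' @param id Identifier used in error messages.
#' @return `TRUE` invisibly.
#' @export
check_cds_matches_protein <- function(cds, protein, id = "?") {
  tr <- translate_cds(cds)
  p <- toupper(protein)
  if (nchar(tr) != nchar(p)) {
    stop("CDS/protein length mismatch for '", id, "': ", nchar(tr),
         " aa vs ", nchar(p), " aa")
  }
  tv <- strsplit(tr, "")[[1]]; pv <- strsplit(p, "")[[1]]
  bad <- which(tv != pv & tv != "X" & pv != "X")
  if (length(bad)) {
    stop("CDS translation mismatch for '", id, "' at residue ", bad[1])
  }
  invisible(TRUE)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue becomes its source codon; each protein gap becomes
#' a whole-codon gap `---`, so reading frames are preserved.
#'
#' @param aln Protein alignment from [align_proteins_global()].
#' @param cds_a,cds_b Coding sequences whose translations equal the
#'   de-gapped aligned proteins (terminal stops stripped; checked).
#' @return List `codon_a`, `codon_b`: equal-length gapped codon strings.
#' @export
backtranslate_alignment <- function(aln, cds_a, cds_b) {
  ga <- strsplit(aln$aligned_a, "")[[1]]
  gb <- strsplit(aln$aligned_b, "")[[1]]
  ca <- strip_terminal_stop(toupper(cds_a))
  cb <- strip_terminal_stop(toupper(cds_b))
  check_cds_matches_protein(ca, gsub("-", "", aln$aligned_a), "a")
  check_cds_matches_protein(cb, gsub("-", "", aln$aligned_b), "b")
  take <- function(gapped, cds) {
    out <- character(length(gapped)); k <- 0L
    for (i in seq_along(gapped)) {
      if (gapped[i] == "-") {
        out[i] <- "---"
      } else {
        out[i] <- substr(cds, 3 * k + 1, 3 * k + 3)
        k <- k + 1L
      }
    }
    paste(out, collapse = "")
  }
  list(codon_a = take(ga, ca), codon_b = take(gb, cb))
}
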