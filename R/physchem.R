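aa_mass_table <- function() {
  if (is.null(.ltp_cache$masses)) {
    df <- utils::read.delim(ltp_extdata("aa_masses.tsv"),
                            stringsAsFactors = FALSE)
    .ltp_cache$masses <- stats::setNames(df$mass, df$residue)
  }
  .ltp_cache$masses
}

pka_table <- function(path = NULL) {
  if (!is.null(path)) {
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  if (is.null(.ltp_cache$pka)) {
    .ltp_cache$pka <- utils::read.delim(ltp_extdata("pka_bjellqvist.tsv"),
                                        stringsAsFactors = FALSE)
  }
  .ltp_cache$pka
}

#' Protein molecular weight
#'
#' Sum of average (not monoisotopic) residue masses plus one water,
#' reported in kDa — the convention of the proteome portals whose tables
#' this mirrors. The residue-mass table is bundled data
#' (`extdata/aa_masses.tsv`).
#'
#' @param seq Protein sequence over the 20 standard residues (`X` is not
#'   permitted: an ambiguous residue has no mass).
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  masses <- aa_mass_table()
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!ch %in% setdiff(names(masses), "water"))
  if (length(bad)) {
    stop("illegal residue '", ch[bad[1]], "' at position ", bad[1])
  }
  (sum(masses[ch]) + masses[["water"]]) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R): positive-group fractions
#' minus negative-group fractions. Monotonically non-increasing in pH.
#'
#' @param seq Protein sequence.
#' @param ph pH value(s).
#' @param pka pKa table (data.frame `group`, `pka`, `charge`); default the
#'   bundled Bjellqvist-style set.
#' @return Net charge, vectorized over `ph`.
#' @export
protein_charge <- function(seq, ph, pka = pka_table()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  counts <- c(nterm = 1, cterm = 1, table(ch)[intersect(unique(ch), pka$group)])
  vapply(ph, function(p) {
    z <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      n <- counts[g]
      if (is.na(n)) next
      if (pka$charge[i] == "positive") {
        z <- z + n / (1 + 10^(p - pka$pka[i]))
      } else {
        z <- z - n / (1 + 10^(pka$pka[i] - p))
      }
    }
    z
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which [protein_charge()] crosses zero, located by bisection on
#' \[0, 14\] to `|Z| < 1e-4` or an interval narrower than `1e-4`. Because
#' every sequence has a free N- and C-terminus, the charge curve always
#' crosses zero and a root exists.
#'
#' @inheritParams protein_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = pka_table()) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    z <- protein_charge(seq, mid, pka)
    if (abs(z) < 1e-4 || (hi - lo) < 1e-4) return(mid)
    if (z > 0) lo <- mid else hi <- mid
  }
}

#' All physicochemical descriptors for one protein
#'
#' @param seq Protein sequence.
#' @return List `length`, `mw` (kDa), `pi`.
#' @export
physchem <- function(seq) {
  list(length = nchar(seq), mw = molecular_weight(seq),
       pi = isoelectric_point(seq))
}
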