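codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[order(names(gc))]
}

sense_codons <- function() {
  gc <- codon_table()
  names(gc)[gc != "*"]
}

# Per-codon synonymous site fraction: over the 3 positions, the proportion
# of the 9 possible single-nucleotide changes that preserve the amino acid
# (changes producing a stop codon count as nonsynonymous), divided by 3 per
# position. Cached for the 61 sense codons.
syn_sites_codon <- function(codon) {
  if (is.null(.ltp_cache$syn_sites)) {
    gc <- codon_table()
    nts <- c("A", "C", "G", "T")
    tab <- vapply(sense_codons(), function(cd) {
      ch <- strsplit(cd, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        for (nt in setdiff(nts, ch[pos])) {
          alt <- ch; alt[pos] <- nt
          alt <- paste(alt, collapse = "")
          if (gc[alt] != "*" && gc[alt] == gc[cd]) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .ltp_cache$syn_sites <- tab
  }
  .ltp_cache$syn_sites[[codon]]
}

# Average synonymous/nonsynonymous difference counts between two codons:
# all orderings of the single-nucleotide steps, paths through stop codons
# excluded (if every path hits a stop, all paths are used).
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  gc <- codon_table()
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  perms <- if (length(pos) == 1) list(pos) else {
    pl <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { pl[[length(pl) + 1]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), pos)
    pl
  }
  eval_path <- function(ord) {
    cur <- v1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- v2[p]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      if (aa_nxt == "*") return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  vals <- lapply(perms, eval_path)
  ok <- !vapply(vals, is.null, logical(1))
  if (!any(ok)) {
    # degenerate: every ordering passes through a stop; fall back to
    # counting steps ignoring the stop exclusion
    vals <- lapply(perms, function(ord) {
      cur <- v1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- v2[p]
        if (gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")]) {
          sd <- sd + 1
        } else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(vals))
  }
  mat <- do.call(rbind, vals[ok])
  colMeans(mat)
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3 != 0) stop("frame violation: length not divisible by 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Nei-Gojobori (1986) site and difference counts
#'
#' For each compared codon pair: synonymous sites are the per-position
#' fractions of synonymous one-step changes (averaged between the two
#' codons); nonsynonymous sites are the complement to 3. Differences at
#' multi-position codon pairs are averaged over all orderings of the
#' single-nucleotide steps, excluding paths through stop codons. Codon
#' columns containing a gap, a stop codon or an ambiguity code are skipped
#' and counted in `codons_skipped`.
#'
#' @param codon_a,codon_b Equal-length gapped codon strings (gap unit =
#'   whole codon) from [backtranslate_alignment()], or plain equal-length
#'   CDS strings.
#' @return List `S`, `N` (fractional site counts), `Sd`, `Nd` (fractional
#'   difference counts), `codons_compared`, `codons_skipped`.
#' @export
ng86_counts <- function(codon_a, codon_b) {
  ca <- split_codons(toupper(codon_a))
  cb <- split_codons(toupper(codon_b))
  if (length(ca) != length(cb)) stop("codon alignments differ in length")
  sense <- sense_codons()
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; skipped <- 0L; compared <- 0L
  for (k in seq_along(ca)) {
    a <- ca[k]; b <- cb[k]
    if (!(a %in% sense) || !(b %in% sense)) { skipped <- skipped + 1L; next }
    compared <- compared + 1L
    s <- (syn_sites_codon(a) + syn_sites_codon(b)) / 2
    S <- S + s
    N <- N + 3 - s
    if (a != b) {
      d <- codon_path_diffs(a, b)
      Sd <- Sd + d[["sd"]]
      Nd <- Nd + d[["nd"]]
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       codons_compared = compared, codons_skipped = skipped)
}

#' Ka and Ks from NG86 counts with Jukes-Cantor correction
#'
#' `pN = Nd/N`, `pS = Sd/S`; each proportion is corrected by
#' `d = -(3/4) ln(1 - 4p/3)`. A proportion at or beyond the JC saturation
#' bound 3/4 yields `NA` and the `saturated` flag.
#'
#' @param counts Output of [ng86_counts()] (requires `S > 0`, `N > 0`).
#' @return List `ka`, `ks`, `ratio` (`NA` when `ks` is 0 or undefined),
#'   `saturated` (logical).
#' @export
kaks_estimate <- function(counts) {
  stopifnot(counts$S > 0, counts$N > 0)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pN <- counts$Nd / counts$N
  pS <- counts$Sd / counts$S
  ka <- jc(pN); ks <- jc(pS)
  saturated <- is.na(ka) || is.na(ks)
  ratio <- if (!saturated && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, saturated = saturated)
}

#' Full Ka/Ks analysis of one coding-sequence pair
#'
#' Translate both CDS, align the proteins globally, back-translate to a
#' codon alignment, apply NG86 counting with Jukes-Cantor correction, then
#' categorize selection and date the divergence from Ks.
#'
#' @param cds_a,cds_b Coding sequences (terminal stops tolerated).
#' @param r Neutral substitution rate for [divergence_time()].
#' @return List `ka`, `ks`, `ratio`, `selection`, `time_mya`, `saturated`,
#'   `codons_compared`, `codons_skipped`, `estimator = "NG86+JC"`.
#' @export
kaks_pair <- function(cds_a, cds_b, r = 2.6e-9) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- align_proteins_global(pa, pb)
  cod <- backtranslate_alignment(aln, cds_a, cds_b)
  counts <- ng86_counts(cod$codon_a, cod$codon_b)
  est <- kaks_estimate(counts)
  sel <- if (est$saturated) "undetermined" else categorize_selection(est$ka, est$ks)
  tm <- if (is.na(est$ks)) NA_real_ else divergence_time(est$ks, r)
  c(est, list(selection = sel, time_mya = tm,
              codons_compared = counts$codons_compared,
              codons_skipped = counts$codons_skipped,
              estimator = "NG86+JC"))
}
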