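#' Find eight-cysteine-motif (ECM) occurrences in a protein sequence
#'
#' The ECM skeleton is `C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C`: eight cysteines of
#' which the third and fourth are adjacent (`CC`) and the fifth and sixth
#' are separated by exactly one non-cysteine residue (`CXC`). The five
#' variable spacers are `s1 = c2-c1-1`, `s2 = c3-c2-1`, `s3 = c5-c4-1`,
#' `s4 = c7-c6-1`, `s5 = c8-c7-1` (positions 1-based).
#'
#' @param seq Amino-acid string (20-letter alphabet plus `X`).
#' @param min_spacer,max_spacer Global scan bounds applied to each of
#'   `s1..s5` before any template is consulted (defaults 3 and 40; wide
#'   enough for every bundled template value, 3..30, with margin).
#' @param allow_cys_in_spacers If `FALSE` (default) spacer residues must be
#'   cysteine-free, so the eight motif cysteines are consecutive cysteines
#'   of the sequence. The literal reading of "X = any amino acid" is kept
#'   available via `TRUE`, at the cost of combinatorial ambiguity.
#' @return List of matches ordered by `c1` then `c8`; each match is a list
#'   with `cys` (8 ascending 1-based positions), `spacers` (integer 5) and
#'   `ecm_seq` (substring from `c1` to `c8` inclusive). Empty list when the
#'   sequence carries no valid motif.
#' @examples
#' s <- paste0("M", "C", strrep("A", 9), "C", strrep("A", 12), "CC",
#'             strrep("A", 19), "CAC", strrep("A", 20), "C",
#'             strrep("A", 3), "C")
#' find_ecm_matches(s)[[1]]$spacers
#' @export
find_ecm_matches <- function(seq, min_spacer = 3L, max_spacer = 40L,
                             allow_cys_in_spacers = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  cp <- which(ch == "C")
  nc <- length(cp)
  if (nc < 8) return(list())
  # cumulative cysteine count for O(1) "any C strictly between a and b"
  ccum <- cumsum(ch == "C")
  c_between <- function(a, b) {
    if (b - a < 2) return(FALSE)
    (ccum[b - 1] - ccum[a]) > 0
  }
  ok_spacer <- function(a, b) {
    s <- b - a - 1L
    s >= min_spacer && s <= max_spacer &&
      (allow_cys_in_spacers || !c_between(a, b))
  }
  out <- list()
  for (i1 in seq_len(nc - 7)) {
    p1 <- cp[i1]
    for (i2 in (i1 + 1):(nc - 6)) {
      p2 <- cp[i2]
      if (p2 - p1 - 1 > max_spacer) break
      if (!ok_spacer(p1, p2)) next
      for (i3 in (i2 + 1):(nc - 5)) {
        p3 <- cp[i3]
        if (p3 - p2 - 1 > max_spacer) break
        if (!ok_spacer(p2, p3)) next
        p4 <- p3 + 1L
        if (p4 > n || ch[p4] != "C") next
        i4 <- i3 + 1L          # p4 is the next cysteine after p3
        if (i4 > nc - 4 || cp[i4] != p4) next
        for (i5 in (i4 + 1):(nc - 3)) {
          p5 <- cp[i5]
          if (p5 - p4 - 1 > max_spacer) break
          if (!ok_spacer(p4, p5)) next
          p6 <- p5 + 2L
          if (p6 > n || ch[p6] != "C" || ch[p5 + 1] == "C") next
          i6 <- match(p6, cp)
          if (is.na(i6) || i6 > nc - 2) next
          for (i7 in (i6 + 1):(nc - 1)) {
            p7 <- cp[i7]
            if (p7 - p6 - 1 > max_spacer) break
            if (!ok_spacer(p6, p7)) next
            for (i8 in (i7 + 1):nc) {
              p8 <- cp[i8]
              if (p8 - p7 - 1 > max_spacer) break
              if (!ok_spacer(p7, p8)) next
              pos <- c(p1, p2, p3, p4, p5, p6, p7, p8)
              out[[length(out) + 1]] <- list(
                cys = pos,
                spacers = c(p2 - p1, p3 - p2, p5 - p4, p7 - p6, p8 - p7) - 1L,
                ecm_seq = substr(seq, p1, p8)
              )
            }
          }
        }
      }
    }
  }
  if (length(out) > 1) {
    o <- order(vapply(out, function(m) m$cys[1], integer(1)),
               vapply(out, function(m) m$cys[8], integer(1)))
    out <- out[o]
  }
  out
}

#' Classify one ECM match by spacing templates
#'
#' @param match An ECM match from [find_ecm_matches()].
#' @param templates Template registry from [read_templates()].
#' @return Character vector of matching type names in registry order
#'   (possibly empty).
#' @export
classify_by_spacing <- function(match, templates = default_templates()) {
  s <- match$spacers
  hits <- vapply(templates, function(tp) {
    all(vapply(1:5, function(k) s[k] %in% tp$allowed[[k]], logical(1)))
  }, logical(1))
  names(templates)[hits]
}

#' Classify an ECM by similarity to reference ECM sequences
#'
#' Fallback used when an ECM matches no spacing template (the route by
#' which new types are erected). The query is globally aligned against each
#' reference; percent identity is identical columns over alignment columns
#' (the global aligner never emits dual-gap columns).
#'
#' @param ecm_seq Query ECM amino-acid string.
#' @param references data.frame with columns `type_name`, `id`, `seq`,
#'   ordered by type-registry order then reference id; the first reference
#'   achieving the maximum identity wins ties.
#' @return List `type_name`, `identity` (percent), `ref_id`.
#' @export
classify_by_similarity <- function(ecm_seq, references) {
  if (is.null(references) || nrow(references) == 0) {
    stop("classify_by_similarity requires at least one reference")
  }
  ident <- vapply(seq_len(nrow(references)), function(i) {
    aln <- align_proteins_global(ecm_seq, references$seq[i])
    a <- strsplit(aln$aligned_a, "")[[1]]
    b <- strsplit(aln$aligned_b, "")[[1]]
    100 * sum(a == b & a != "-") / length(a)
  }, numeric(1))
  best <- which.max(ident)
  list(type_name = references$type_name[best], identity = ident[best],
       ref_id = references$id[best])
}

#' Classify every protein of a proteome
#'
#' Per protein: scan for ECMs; proteins with none are `no_ecm`. Among the
#' motif candidates the best match is the one matching the fewest (but at
#' least one) spacing templates — the most specific — with ties broken by
#' the most N-terminal `c1`. If no candidate matches any template and a
#' similarity fallback is configured, the best (most N-terminal) ECM is
#' compared against the references; below the identity threshold (or with
#' no fallback) the protein is `unclassified`.
#'
#' @param records Named character vector of protein sequences.
#' @param templates Template registry.
#' @param references Optional reference data.frame for
#'   [classify_by_similarity()]; enables the fallback.
#' @param min_spacer,max_spacer,allow_cys_in_spacers Scan bounds, see
#'   [find_ecm_matches()].
#' @param similarity_threshold Minimum percent identity for a similarity
#'   assignment (default 50).
#' @return List with
#'   * `results`: data.frame `id`, `assigned_type`, `method`
#'     (`spacing`/`similarity`/`none`), `matched_types` (comma-joined),
#'     `spacers` (comma-joined, `NA` when no ECM), `c1`, `ecm_seq`;
#'   * `summary`: data.frame `type`, `count`, `percent` (of classified
#'     proteins), registry order, zero-count types omitted.
#' @export
classify_proteome <- function(records, templates = default_templates(),
                              references = NULL,
                              min_spacer = 3L, max_spacer = 40L,
                              allow_cys_in_spacers = FALSE,
                              similarity_threshold = 50) {
  n <- length(records)
  res <- data.frame(
    id = names(records) %||% character(0),
    assigned_type = character(n),
    method = character(n),
    matched_types = character(n),
    spacers = character(n),
    c1 = rep(NA_integer_, n),
    ecm_seq = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    matches <- find_ecm_matches(records[[i]], min_spacer, max_spacer,
                                allow_cys_in_spacers)
    if (length(matches) == 0) {
      res$assigned_type[i] <- "no_ecm"
      res$method[i] <- "none"
      next
    }
    types_per_match <- lapply(matches, classify_by_spacing, templates = templates)
    n_types <- lengths(types_per_match)
    if (any(n_types > 0)) {
      cand <- which(n_types > 0)
      best <- cand[which.min(n_types[cand])]  # matches sorted by c1: stable
      m <- matches[[best]]
      tps <- types_per_match[[best]]
      res$assigned_type[i] <- tps[1]
      res$method[i] <- "spacing"
      res$matched_types[i] <- paste(tps, collapse = ",")
    } else {
      m <- matches[[1]]
      if (!is.null(references) && nrow(references) > 0) {
        sim <- classify_by_similarity(m$ecm_seq, references)
        if (sim$identity >= similarity_threshold) {
          res$assigned_type[i] <- sim$type_name
          res$method[i] <- "similarity"
        } else {
          res$assigned_type[i] <- "unclassified"
          res$method[i] <- "none"
        }
      } else {
        res$assigned_type[i] <- "unclassified"
        res$method[i] <- "none"
      }
    }
    res$spacers[i] <- paste(m$spacers, collapse = ",")
    res$c1[i] <- m$cys[1]
    res$ecm_seq[i] <- m$ecm_seq
  }
  classified <- res[!res$assigned_type %in% c("no_ecm", "unclassified"), ,
                    drop = FALSE]
  type_order <- unique(c(names(templates), sort(unique(classified$assigned_type))))
  counts <- table(factor(classified$assigned_type, levels = type_order))
  counts <- counts[counts > 0]
  summary <- data.frame(
    type = names(counts),
    count = as.integer(counts),
    percent = if (nrow(classified)) round(100 * as.integer(counts) /
                                            nrow(classified), 2) else numeric(0),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(results = res, summary = summary)
}

#' Position-by-residue count matrix for a sequence logo
#'
#' @param seqs Character vector of aligned, equal-length sequences (gaps
#'   allowed and counted in a `-` row).
#' @return Integer matrix, rows = residues observed (plus `-` if present),
#'   columns = positions; every column sums to `length(seqs)`.
#' @export
consensus_logo_counts <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  residues <- sort(unique(as.vector(mat)))
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(factor(mat[, j], levels = residues), nbins = length(residues))
  }, integer(length(residues)))
  counts <- matrix(counts, nrow = length(residues),
                   dimnames = list(residues, NULL))
  counts
}
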