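# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive (enumeration / brute force) and share no code with the
# package implementation.

# every 8-subset of cysteine positions satisfying the ECM constraints
brute_force_ecm <- function(seq, min_spacer = 3, max_spacer = 40,
                            allow_cys_in_spacers = FALSE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  cp <- which(ch == "C")
  if (length(cp) < 8) return(list())
  out <- list()
  for (idx in seq_len(ncol(combn_safe(length(cp), 8)))) {
    p <- cp[combn_safe(length(cp), 8)[, idx]]
    s <- c(p[2] - p[1], p[3] - p[2], p[5] - p[4], p[7] - p[6], p[8] - p[7]) - 1
    if (p[4] != p[3] + 1) next
    if (p[6] != p[5] + 2) next
    if (ch[p[5] + 1] == "C") next
    if (any(s < min_spacer | s > max_spacer)) next
    if (!allow_cys_in_spacers) {
      gaps <- list(c(p[1], p[2]), c(p[2], p[3]), c(p[4], p[5]),
                   c(p[6], p[7]), c(p[7], p[8]))
      has_c <- any(vapply(gaps, function(g) {
        g[2] - g[1] >= 2 && any(ch[(g[1] + 1):(g[2] - 1)] == "C")
      }, logical(1)))
      if (has_c) next
    }
    out[[length(out) + 1]] <- list(cys = p, spacers = as.integer(s))
  }
  # order by c1 then c8, as the implementation promises
  if (length(out) > 1) {
    o <- order(vapply(out, function(m) m$cys[1], integer(1)),
               vapply(out, function(m) m$cys[8], integer(1)))
    out <- out[o]
  }
  out
}

# memoized combn to keep the 500-sequence oracle loop affordable
.combn_cache <- new.env(parent = emptyenv())
combn_safe <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.combn_cache[[key]])) .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

random_protein <- function(len, n_cys) {
  res <- sample(strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE)
  res[sample.int(len, min(n_cys, len))] <- "C"
  paste(res, collapse = "")
}

# NG86 oracle: explicit per-position site enumeration and full recursive
# path enumeration between two codons (standard code via Biostrings)
GC_TAB <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), v[pos])) {
    w <- v; w[pos] <- nt
    if (GC_TAB[paste(w, collapse = "")] == GC_TAB[codon]) syn <- syn + 1 / 3
  }
  syn
}

oracle_paths <- function(c1, c2, skip_stops = TRUE) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  if (!length(pos)) return(matrix(c(0, 0), 1, dimnames = list(NULL, c("sd", "nd"))))
  res <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      res[[length(res) + 1]] <<- c(sd = sd, nd = nd)
      return()
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- v2[p]
      if (skip_stops && GC_TAB[paste(nxt, collapse = "")] == "*") next
      same <- unname(GC_TAB[paste(cur, collapse = "")] ==
                       GC_TAB[paste(nxt, collapse = "")])
      recurse(nxt, setdiff(remaining, p), sd + same, nd + !same)
    }
  }
  recurse(v1, pos, 0, 0)
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

oracle_ng86 <- function(cds_a, cds_b) {
  n <- nchar(cds_a)
  ca <- substring(cds_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(cds_b, seq(1, n, 3), seq(3, n, 3))
  S <- 0; Sd <- 0; Nd <- 0; compared <- 0
  for (k in seq_along(ca)) {
    ok <- !grepl("[^ACGT]", ca[k]) && !grepl("[^ACGT]", cb[k]) &&
      GC_TAB[ca[k]] != "*" && GC_TAB[cb[k]] != "*"
    if (!ok) next
    compared <- compared + 1
    S <- S + (oracle_syn_sites(ca[k]) + oracle_syn_sites(cb[k])) / 2
    paths <- oracle_paths(ca[k], cb[k], skip_stops = TRUE)
    if (is.null(paths)) paths <- oracle_paths(ca[k], cb[k], skip_stops = FALSE)
    Sd <- Sd + mean(paths[, "sd"])
    Nd <- Nd + mean(paths[, "nd"])
  }
  list(S = S, N = 3 * compared - S, Sd = Sd, Nd = Nd)
}

random_sense_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (GC_TAB[cd] != "*") return(cd)
  }
}

# exhaustive global-alignment score for short sequences: enumerate every
# alignment recursively with affine gaps (open charged on the first gapped
# column of a run)
oracle_best_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return()
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, score + submat[av[i], bv[j]], "M")
    }
    if (i <= length(av)) {
      pen <- if (state == "X") gap_extend else gap_open
      recurse(i + 1, j, score - pen, "X")
    }
    if (j <= length(bv)) {
      pen <- if (state == "Y") gap_extend else gap_open
      recurse(i, j + 1, score - pen, "Y")
    }
  }
  recurse(1, 1, 0, "M")
  best
}

# brute-force tandem caller: all-pairs rule check + transitive closure by
# repeated set merging
oracle_tandem <- function(family_ids, loci, max_intervening = 5,
                          max_distance = 1e5) {
  fam <- loci[loci$gene_id %in% family_ids, ]
  sets <- lapply(fam$gene_id, function(g) g)
  qualifies <- function(a, b) {
    if (a$chrom != b$chrom) return(FALSE)
    lo <- if (a$rank < b$rank) a else b
    hi <- if (a$rank < b$rank) b else a
    (hi$rank - lo$rank - 1) <= max_intervening &&
      (hi$start - lo$start) <= max_distance
  }
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        link <- FALSE
        for (x in sets[[i]]) for (y in sets[[j]]) {
          if (qualifies(fam[fam$gene_id == x, ], fam[fam$gene_id == y, ])) {
            link <- TRUE
          }
        }
        if (link) {
          sets[[i]] <- c(sets[[i]], sets[[j]])
          sets <- sets[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  Filter(function(s) length(s) >= 2, lapply(sets, sort))
}

# sliding-window IUPAC scan (pattern is plain ACGT in the tests that use it)
oracle_scan <- function(promoter, pattern) {
  hits <- integer(0)
  L <- nchar(pattern)
  for (i in seq_len(nchar(promoter) - L + 1)) {
    if (substr(promoter, i, i + L - 1) == pattern) hits <- c(hits, i)
  }
  hits
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

table1_composition <- function() {
  c(I = 36, II = 6, IV = 10, V = 2, VII = 1, VIII = 12, XII = 7, XIII = 9)
}

# node-label -> bipartition map for a tree annotated by bootstrap_support
tree_bipartitions_for_test <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- list()
  labs <- tree$node.label
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out[[paste(side, collapse = "|")]] <- suppressWarnings(as.numeric(labs[k]))
  }
  out
}
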