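#' Pairwise p-distances from an alignment
#'
#' Proportion of differing sites per pair. Under pairwise deletion a site
#' contributes to a pair only when both sequences carry an unambiguous,
#' non-gap residue there; under complete deletion columns with any missing
#' state are removed first. Missing states: `-`, `.`, `?`, `X`, `N`.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return List `dist` (symmetric matrix, zero diagonal, entries in
#'   \[0,1\]) and `sites` (per-pair compared-site counts). A pair with
#'   zero comparable sites is an error.
#' @export
p_distance <- function(seqs, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1) stop("aligned sequences differ in length")
  missing_states <- c("-", ".", "?", "X", "N")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ok <- !matrix(mat %in% missing_states, nrow = n)
  if (deletion == "complete") {
    keep <- colSums(ok) == n
    mat <- mat[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  cmp <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    nsites <- sum(both)
    if (nsites == 0) {
      stop("no comparable sites between '", names(seqs)[i], "' and '",
           names(seqs)[j], "'")
    }
    mism <- sum(mat[i, both] != mat[j, both])
    d[i, j] <- d[j, i] <- mism / nsites
    cmp[i, j] <- cmp[j, i] <- nsites
  }
  list(dist = d, sites = cmp)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Tie-breaking is
#' deterministic: each active node is represented by the lexicographically
#' smallest leaf label it contains, and among equal-Q pairs the pair whose
#' sorted representative labels come first lexicographically is joined.
#' Negative branch-length estimates are clamped to zero and flagged in the
#' `"negative_branches"` attribute of the result.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa), or
#'   the list returned by [p_distance()].
#' @return Unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (is.list(dm) && !is.null(dm$dist)) dm <- dm$dist
  stopifnot(is.matrix(dm), nrow(dm) >= 3, !is.null(rownames(dm)))
  labels <- rownames(dm)
  d <- dm
  nwk <- labels            # newick fragment per active node
  rep_leaf <- labels       # smallest contained leaf label
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    q[lower.tri(q, diag = TRUE)] <- Inf
    cand <- which(q <= min(q) + 1e-12, arr.ind = TRUE)
    keys <- vapply(seq_len(nrow(cand)), function(k) {
      paste(sort(c(rep_leaf[cand[k, 1]], rep_leaf[cand[k, 2]])),
            collapse = "\r")
    }, character(1))
    pick <- order(keys)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    newdist <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    newnwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    newrep <- min(rep_leaf[i], rep_leaf[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(d, newdist)
    d <- cbind(d, c(newdist, 0))
    nwk <- c(nwk[keep], newnwk)
    rep_leaf <- c(rep_leaf[keep], newrep)
  }
  # closed-form resolution of the final three nodes around a central vertex
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb), ",",
                nwk[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branches") <- clamped
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa in two; a bipartition is canonicalized
#' as the sorted side not containing the alphabetically first taxon,
#' serialized as one string.
#'
#' @param tree `ape::phylo`.
#' @return Character vector of canonical bipartition keys.
#' @keywords internal
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' each replicate tree is rebuilt with [p_distance()] +
#' [neighbor_joining()], and each internal edge of the reference tree is
#' annotated with the percentage of replicates containing its bipartition.
#'
#' @param seqs Aligned sequences as for [p_distance()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed; recorded in the `"seed"` attribute of the result.
#' @param deletion Gap treatment, see [p_distance()].
#' @return The reference `ape::phylo` tree with supports (0..100, rounded
#'   to one decimal) as internal node labels; the root label is empty.
#'   Replicates whose resampled columns leave some pair with no comparable
#'   site are dropped and counted in attribute `"failed_replicates"`.
#' @export
bootstrap_support <- function(seqs, n_replicates = 1000L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  ref <- neighbor_joining(p_distance(seqs, deletion))
  ref_parts <- tree_bipartitions(ref)
  hit <- stats::setNames(numeric(length(ref_parts)), ref_parts)
  L <- unique(nchar(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  set.seed(seed)
  used <- 0L; failed <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rseqs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rseqs) <- names(seqs)
    rt <- tryCatch(neighbor_joining(p_distance(rseqs, deletion)),
                   error = function(e) NULL)
    if (is.null(rt)) { failed <- failed + 1L; next }
    used <- used + 1L
    bp <- tree_bipartitions(rt)
    present <- ref_parts %in% bp
    hit[present] <- hit[present] + 1
  }
  support <- if (used > 0) round(100 * hit / used, 1) else hit * NA
  # map supports onto internal node labels
  ntip <- length(ref$tip.label)
  labs <- character(ref$Nnode)
  parts <- ape::prop.part(ref)
  tips <- sort(ref$tip.label)
  for (k in seq_along(parts)) {
    side <- sort(ref$tip.label[parts[[k]]])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) labs[k] <- as.character(support[[key]])
  }
  ref$node.label <- labs
  attr(ref, "seed") <- seed
  attr(ref, "failed_replicates") <- failed
  ref
}

#' Anchor-based multiple alignment of ECM sequences
#'
#' ECMs share the eight-cysteine skeleton, so a progressive aligner is
#' unnecessary: the eight cysteines (and the single CXC spacer residue)
#' are pinned columnwise and each variable spacer is padded on the right
#' with gaps to the longest spacer observed at that slot.
#'
#' @param matches Named list of ECM matches (one per protein), as returned
#'   by [find_ecm_matches()]; names become taxon labels.
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_ecm_anchored <- function(matches) {
  stopifnot(length(matches) >= 1, !is.null(names(matches)))
  sp <- do.call(rbind, lapply(matches, `[[`, "spacers"))
  maxsp <- apply(sp, 2, max)
  out <- vapply(matches, function(m) {
    e <- m$ecm_seq
    cys <- m$cys - m$cys[1] + 1L   # positions within ecm_seq
    seg <- function(a, b) substr(e, a, b)
    pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
    paste0("C", pad(seg(cys[1] + 1, cys[2] - 1), maxsp[1]),
           "C", pad(seg(cys[2] + 1, cys[3] - 1), maxsp[2]),
           "CC", pad(seg(cys[4] + 1, cys[5] - 1), maxsp[3]),
           "C", seg(cys[5] + 1, cys[5] + 1), "C",
           pad(seg(cys[6] + 1, cys[7] - 1), maxsp[4]),
           "C", pad(seg(cys[7] + 1, cys[8] - 1), maxsp[5]), "C")
  }, character(1))
  out
}

#' Write a tree to a Newick file
#'
#' Bootstrap supports, when present, are emitted as internal node labels.
#'
#' @param tree `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
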