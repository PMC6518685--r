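#' Call tandem-duplication clusters among family genes
#'
#' Two family genes qualify as a tandem pair when they lie on the same
#' chromosome, are separated by no more than `max_intervening` other
#' annotated genes (of any family; difference of ordinal ranks minus one)
#' and are within `max_distance` base pairs. Clusters are the connected
#' components of the qualifying-pair graph (transitive closure: a chain
#' a-b-c is one cluster even if a-c alone fails), singletons discarded.
#'
#' @param family_ids Character vector of family gene ids.
#' @param loci Gene locus data.frame from [read_gff3()] (`gene_id`,
#'   `chrom`, `start`, `end`, `rank`).
#' @param max_intervening Maximum number of intervening genes (default 5).
#' @param max_distance Maximum genomic distance in bp (default 100000).
#' @param distance_mode `"start"` (default): start-to-start distance,
#'   monotone with rank order and unambiguous for nested annotations;
#'   `"gap"`: end of the upstream gene to start of the downstream gene.
#' @return List of clusters, each `list(chrom, members)` with members
#'   ordered by rank; ordered by chromosome then first member rank.
#' @export
find_tandem_clusters <- function(family_ids, loci, max_intervening = 5L,
                                 max_distance = 100000L,
                                 distance_mode = c("start", "gap")) {
  distance_mode <- match.arg(distance_mode)
  unknown <- setdiff(family_ids, loci$gene_id)
  if (length(unknown)) {
    stop("unknown family gene id(s): ", paste(unknown, collapse = ", "))
  }
  fam <- loci[loci$gene_id %in% family_ids, , drop = FALSE]
  fam <- fam[order(fam$chrom, fam$rank), , drop = FALSE]
  n <- nrow(fam)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (fam$chrom[i] != fam$chrom[j]) next
      lo <- which.min(c(fam$rank[i], fam$rank[j]))
      a <- if (lo == 1) i else j
      b <- if (lo == 1) j else i
      if (fam$rank[b] - fam$rank[a] - 1 > max_intervening) next
      d <- if (distance_mode == "start") fam$start[b] - fam$start[a]
           else fam$start[b] - fam$end[a]
      if (d > max_distance) next
      union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    if (length(idx) < 2) next
    idx <- idx[order(fam$rank[idx])]
    out[[length(out) + 1]] <- list(chrom = fam$chrom[idx[1]],
                                   members = fam$gene_id[idx])
  }
  out
}

#' Enumerate the qualifying tandem pairs inside called clusters
#'
#' @inheritParams find_tandem_clusters
#' @param clusters Output of [find_tandem_clusters()].
#' @return data.frame `gene_a`, `gene_b`, `mode = "tandem"`; the edges of
#'   the qualifying-pair graph restricted to cluster members.
#' @export
tandem_pairs <- function(clusters, loci, max_intervening = 5L,
                         max_distance = 100000L,
                         distance_mode = c("start", "gap")) {
  distance_mode <- match.arg(distance_mode)
  rows <- list()
  idx <- stats::setNames(seq_len(nrow(loci)), loci$gene_id)
  for (cl in clusters) {
    mem <- cl$members
    for (i in seq_along(mem)[-length(mem)]) for (j in (i + 1):length(mem)) {
      a <- loci[idx[mem[i]], ]; b <- loci[idx[mem[j]], ]
      if (b$rank - a$rank - 1 > max_intervening) next
      d <- if (distance_mode == "start") b$start - a$start else b$start - a$end
      if (d > max_distance) next
      rows[[length(rows) + 1]] <- data.frame(gene_a = a$gene_id,
                                             gene_b = b$gene_id,
                                             mode = "tandem",
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Load segmental-duplication anchor pairs
#'
#' Segmental-duplication discovery itself is out of scope; precomputed
#' anchor pairs (e.g. from a plant genome duplication database) are taken
#' as input: a two-column TSV `gene_a`, `gene_b` (header optional). Pairs
#' are deduplicated order-independently; pairs with a non-family member
#' are dropped with a message.
#'
#' @param path Anchors TSV path.
#' @param family_ids Family gene ids used as the filter.
#' @return data.frame `gene_a`, `gene_b`, `mode = "segmental"`.
#' @export
load_segmental_anchors <- function(path, family_ids) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(strsplit(lines[1], "\t")[[1]][1:2]),
                                 c("gene_a", "gene_b"))) {
    lines <- lines[-1]
  }
  out <- list(); seen <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t")[[1]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      stop("malformed anchor line ", k, ": '", lines[k], "'")
    }
    a <- f[1]; b <- f[2]
    if (!(a %in% family_ids) || !(b %in% family_ids)) {
      message("anchor pair dropped (non-family gene): ", a, " / ", b)
      next
    }
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- data.frame(gene_a = a, gene_b = b,
                                         mode = "segmental",
                                         stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Divergence time from synonymous divergence
#'
#' `t = Ks / (2 r)`, with the neutral substitution rate
#' `r = 2.6e-9` substitutions per site per year by default; reported in
#' million years.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param r Neutral substitution rate per site per year.
#' @return Divergence time in million years (unrounded; round at display).
#' @examples
#' round(divergence_time(4.92384), 2)  # 946.89
#' @export
divergence_time <- function(ks, r = 2.6e-9) {
  stopifnot(r > 0)
  if (any(ks < 0, na.rm = TRUE)) stop("negative ks")
  ks / (2 * r) / 1e6
}

#' Selection category from Ka and Ks
#'
#' Ka/Ks < 1 indicates purifying selection, > 1 positive selection, = 1
#' neutral evolution; with Ks = 0 the ratio is undefined.
#'
#' @param ka,ks Non-negative substitution rates.
#' @param eps Half-width of the neutrality band around ratio 1 (default
#'   1e-9, i.e. effectively strict comparison).
#' @return One of `"purifying"`, `"neutral"`, `"positive"`,
#'   `"undetermined"`.
#' @export
categorize_selection <- function(ka, ks, eps = 1e-9) {
  if (is.na(ka) || is.na(ks)) return("undetermined")
  stopifnot(ka >= 0, ks >= 0)
  if (ks == 0) return("undetermined")
  ratio <- ka / ks
  if (ratio < 1 - eps) "purifying"
  else if (ratio > 1 + eps) "positive"
  else "neutral"
}
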