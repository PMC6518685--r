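AA_NO_CYS <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]  # 19 residues

codons_for_aa <- function() {
  if (is.null(.ltp_cache$codons_by_aa)) {
    gc <- codon_table()
    .ltp_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .ltp_cache$codons_by_aa
}

sample1 <- function(v) v[sample.int(length(v), 1L)]

random_cds_for_protein <- function(protein, add_stop = TRUE) {
  byaa <- codons_for_aa()
  ch <- strsplit(protein, "")[[1]]
  codons <- vapply(ch, function(aa) sample1(byaa[[aa]]), character(1))
  if (add_stop) codons <- c(codons, sample1(c("TAA", "TAG", "TGA")))
  paste(codons, collapse = "")
}

build_ecm_protein <- function(spacers, mutate_cys = NA_integer_) {
  fill <- function(k) paste(sample(AA_NO_CYS, k, replace = TRUE), collapse = "")
  leader <- fill(sample(20:35, 1))
  tail <- fill(sample(0:20, 1))
  skeleton <- c("C", fill(spacers[1]), "C", fill(spacers[2]), "C", "C",
                fill(spacers[3]), "C", fill(1), "C", fill(spacers[4]),
                "C", fill(spacers[5]), "C")
  if (!is.na(mutate_cys)) {
    cys_slots <- which(skeleton == "C")
    skeleton[cys_slots[mutate_cys]] <- sample1(AA_NO_CYS)
  }
  paste0(leader, paste(skeleton, collapse = ""), tail)
}

#' Generate a synthetic proteome with planted nsLTP types and decoys
#'
#' Family proteins are built on the ECM skeleton with each spacer length
#' drawn uniformly from the named template's allowed set, spacers (and the
#' leader/tail flanks) filled with cysteine-free residues, so every family
#' protein carries exactly one valid ECM assignment. Decoys probe the
#' classifier's failure modes independently: `7cys` (one motif cysteine
#' mutated away), `spacer` (one spacer outside every bundled template's
#' allowed values, but inside the scan bounds), `nocys` (random
#' cysteine-free protein). Coding sequences are built by uniform random
#' codon choice per residue plus a random terminal stop.
#'
#' @param composition Named integer vector, type name -> member count
#'   (types must exist in `templates`); may be empty.
#' @param n_decoys Number of decoys, split round-robin over the three
#'   decoy classes.
#' @param seed RNG seed; all randomness derives from it.
#' @param templates Template registry.
#' @return List `proteins`, `cds` (named character vectors) and `truth`
#'   (data.frame `id`, `class`, `spacers`).
#' @export
generate_proteome <- function(composition, n_decoys = 0L, seed = 1L,
                              templates = default_templates()) {
  unknown <- setdiff(names(composition), names(templates))
  if (length(unknown)) stop("unknown type(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  proteins <- character(0); cds <- character(0)
  truth <- list()
  for (tp in names(composition)) {
    allowed <- templates[[tp]]$allowed
    for (k in seq_len(composition[[tp]])) {
      spacers <- vapply(allowed, sample1, integer(1))
      prot <- build_ecm_protein(spacers)
      id <- sprintf("LTP_%s_%02d", tp, k)
      proteins[[id]] <- prot
      cds[[id]] <- random_cds_for_protein(prot)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = tp, spacers = paste(spacers, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0) {
    classes <- rep(c("decoy_7cys", "decoy_spacer", "decoy_nocys"),
                   length.out = n_decoys)
    # spacer values outside every bundled allowed set (max template value
    # is 30) yet inside the default scan bounds [3, 40]
    out_of_range <- 31:40
    for (k in seq_len(n_decoys)) {
      tp <- sample1(names(templates))
      allowed <- templates[[tp]]$allowed
      id <- sprintf("DECOY_%03d", k)
      if (classes[k] == "decoy_7cys") {
        spacers <- vapply(allowed, sample1, integer(1))
        prot <- build_ecm_protein(spacers, mutate_cys = sample.int(8, 1))
      } else if (classes[k] == "decoy_spacer") {
        spacers <- vapply(allowed, sample1, integer(1))
        slot <- sample.int(5, 1)
        spacers[slot] <- sample1(out_of_range)
        prot <- build_ecm_protein(spacers)
      } else {
        spacers <- NA
        prot <- paste(sample(AA_NO_CYS, sample(100:200, 1), replace = TRUE),
                      collapse = "")
      }
      proteins[[id]] <- prot
      cds[[id]] <- random_cds_for_protein(prot)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, class = classes[k],
        spacers = if (all(is.na(spacers))) NA_character_ else
          paste(spacers, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), class = character(0),
               spacers = character(0), stringsAsFactors = FALSE)
  list(proteins = proteins, cds = cds, truth = truth, seed = seed)
}

#' Generate a synthetic chromosome gene map with planted tandem clusters
#'
#' Chromosomes are filled with background genes; family genes are planted
#' either as clusters obeying the tandem rule (consecutive members
#' separated by few background genes and short distances), as singletons,
#' or as decoy pairs violating exactly one rule condition each:
#' `decoy_intervening` pairs are close in bp but separated by
#' `max_intervening + 1` background genes; `decoy_distance` pairs are
#' adjacent in rank but farther apart than `max_distance`. Units are
#' isolated from each other by separator runs of background genes that
#' violate both conditions.
#'
#' @param cluster_sizes Integer vector: one planted cluster per entry
#'   (each >= 2).
#' @param n_singletons Number of isolated family genes.
#' @param n_decoy_intervening,n_decoy_distance Number of decoy pairs of
#'   each class.
#' @param n_chromosomes Number of chromosomes (units assigned round-robin).
#' @param max_intervening,max_distance The rule thresholds the planted
#'   layout is built against (defaults 5 genes / 100 kb).
#' @param intra_gap_genes Possible background-gene counts between
#'   consecutive cluster members (must respect `max_intervening`).
#' @param intra_gap_bp Range of start-to-start distances between
#'   consecutive cluster members (must respect `max_distance`).
#' @param seed RNG seed.
#' @param path Output GFF3 path (default: a tempfile).
#' @return List `gff` (path), `truth` (data.frame `gene_id`, `chrom`,
#'   `cluster`: cluster label, `"singleton"`, or decoy class),
#'   `family_ids`, `expected_clusters` (list of member-id vectors).
#' @export
generate_gene_map <- function(cluster_sizes = integer(0), n_singletons = 0L,
                              n_decoy_intervening = 0L, n_decoy_distance = 0L,
                              n_chromosomes = 3L,
                              max_intervening = 5L, max_distance = 100000L,
                              intra_gap_genes = 0:2,
                              intra_gap_bp = c(5000L, 15000L),
                              seed = 1L, path = tempfile(fileext = ".gff3")) {
  if (any(cluster_sizes < 2)) stop("cluster sizes must be >= 2")
  if (max(c(intra_gap_genes, 0)) > max_intervening) {
    stop("planted intra-cluster gene gap violates the declared rule")
  }
  if (intra_gap_bp[2] > max_distance) {
    stop("planted intra-cluster distance violates the declared rule")
  }
  set.seed(seed)
  units <- c(
    lapply(seq_along(cluster_sizes),
           function(i) list(kind = "cluster", size = cluster_sizes[i],
                            label = sprintf("C%02d", i))),
    rep(list(list(kind = "singleton")), n_singletons),
    rep(list(list(kind = "decoy_intervening")), n_decoy_intervening),
    rep(list(list(kind = "decoy_distance")), n_decoy_distance)
  )
  chrom_of <- rep_len(sprintf("chr%02d", seq_len(n_chromosomes)),
                      length(units) %||% 0)
  genes <- list()        # gene_id, chrom, start, end, strand
  truth <- list()
  fam_n <- 0L; bg_n <- 0L
  cursor <- stats::setNames(rep(10000L, n_chromosomes),
                            sprintf("chr%02d", seq_len(n_chromosomes)))
  add_gene <- function(chrom, start, family, label = NA_character_) {
    len <- sample(1000:2000, 1)
    if (family) {
      fam_n <<- fam_n + 1L
      gid <- sprintf("LTP%03d", fam_n)
      truth[[length(truth) + 1]] <<- data.frame(
        gene_id = gid, chrom = chrom, cluster = label,
        stringsAsFactors = FALSE)
    } else {
      bg_n <<- bg_n + 1L
      gid <- sprintf("BG%04d", bg_n)
    }
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = gid, chrom = chrom, start = start, end = start + len,
      strand = sample1(c("+", "-")), stringsAsFactors = FALSE)
    gid
  }
  separator <- function(chrom) {
    for (s in 1:7) {
      cursor[chrom] <<- cursor[chrom] + 30000L
      add_gene(chrom, cursor[chrom], family = FALSE)
    }
    cursor[chrom] <<- cursor[chrom] + 30000L
  }
  place_between <- function(chrom, from, to, n_bg) {
    if (n_bg == 0) return()
    at <- round(seq(from, to, length.out = n_bg + 2))[2:(n_bg + 1)]
    for (a in at) add_gene(chrom, as.integer(a), family = FALSE)
  }
  expected <- list()
  for (u in seq_along(units)) {
    unit <- units[[u]]; chrom <- chrom_of[u]
    if (unit$kind == "cluster") {
      members <- character(unit$size)
      members[1] <- add_gene(chrom, cursor[chrom], TRUE, unit$label)
      for (m in 2:unit$size) {
        gap_bp <- sample(intra_gap_bp[1]:intra_gap_bp[2], 1)
        n_bg <- sample1(intra_gap_genes)
        place_between(chrom, cursor[chrom] + 2100, cursor[chrom] + gap_bp - 100,
                      n_bg)
        cursor[chrom] <- cursor[chrom] + gap_bp
        members[m] <- add_gene(chrom, cursor[chrom], TRUE, unit$label)
      }
      expected[[unit$label]] <- members
    } else if (unit$kind == "singleton") {
      add_gene(chrom, cursor[chrom], TRUE, "singleton")
    } else if (unit$kind == "decoy_intervening") {
      # max_intervening + 1 background genes within max_distance: fails the
      # gene-count condition only
      span <- round(max_distance * 0.7)
      add_gene(chrom, cursor[chrom], TRUE, "decoy_intervening")
      place_between(chrom, cursor[chrom] + 2100,
                    cursor[chrom] + span - 100, max_intervening + 1L)
      cursor[chrom] <- cursor[chrom] + span
      add_gene(chrom, cursor[chrom], TRUE, "decoy_intervening")
    } else {
      # adjacent in rank but beyond max_distance: fails the distance only
      add_gene(chrom, cursor[chrom], TRUE, "decoy_distance")
      cursor[chrom] <- cursor[chrom] + as.integer(1.5 * max_distance)
      add_gene(chrom, cursor[chrom], TRUE, "decoy_distance")
    }
    cursor[chrom] <- cursor[chrom] + 5000L
    separator(chrom)
  }
  gdf <- do.call(rbind, genes)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), chrom = character(0),
               cluster = character(0), stringsAsFactors = FALSE)
  # emit GFF3: gene + mRNA + 1-3 exons per gene
  fmtc <- function(x) format(as.numeric(x), scientific = FALSE, trim = TRUE)
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gdf))) {
    g <- gdf[i, ]
    lines <- c(lines, paste(g$chrom, "ltpscan_sim", "gene", fmtc(g$start),
                            fmtc(g$end), ".", g$strand, ".",
                            paste0("ID=", g$gene_id), sep = "\t"))
    mid <- paste0(g$gene_id, ".1")
    lines <- c(lines, paste(g$chrom, "ltpscan_sim", "mRNA", fmtc(g$start),
                            fmtc(g$end), ".", g$strand, ".",
                            paste0("ID=", mid, ";Parent=", g$gene_id),
                            sep = "\t"))
    n_ex <- sample.int(3, 1)
    bounds <- round(seq(g$start, g$end, length.out = 2 * n_ex))
    for (e in seq_len(n_ex)) {
      lines <- c(lines, paste(g$chrom, "ltpscan_sim", "exon",
                              fmtc(bounds[2 * e - 1]), fmtc(bounds[2 * e]),
                              ".", g$strand, ".",
                              paste0("ID=", mid, ".exon", e, ";Parent=", mid),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  list(gff = path, truth = truth, family_ids = truth$gene_id,
       expected_clusters = expected, seed = seed)
}

#' Simulate a pair of coding sequences with known divergence
#'
#' A random stop-free ancestor CDS is generated, then each descendant
#' lineage receives Poisson-distributed numbers of synonymous and
#' nonsynonymous single-nucleotide substitutions with expectations
#' `target_ks/2 * S` and `target_ka/2 * N` (S, N: NG86 site counts of the
#' ancestor). A proposed change creating a stop codon is resampled.
#' Realized per-site divergences (event counts over ancestor site counts)
#' are recorded as the ground truth.
#'
#' @param n_codons Ancestor length in codons.
#' @param target_ks,target_ka Expected substitutions per synonymous /
#'   nonsynonymous site across the pair (both lineages combined). Values
#'   beyond 3 are refused as saturated.
#' @param seed RNG seed.
#' @return List `cds_a`, `cds_b`, `ancestor`, `truth` (list `ks`, `ka`,
#'   `syn_events`, `nonsyn_events`, `S`, `N`).
#' @export
simulate_codon_pair <- function(n_codons, target_ks, target_ka, seed = 1L) {
  stopifnot(n_codons >= 1, target_ks >= 0, target_ka >= 0)
  if (target_ks > 3 || target_ka > 3) stop("saturation request: target > 3")
  set.seed(seed)
  anc <- vapply(seq_len(n_codons), function(i) sample1(sense_codons()),
                character(1))
  S <- sum(vapply(anc, syn_sites_codon, numeric(1)))
  N <- 3 * n_codons - S
  gc <- codon_table()
  nts <- c("A", "C", "G", "T")
  mutate <- function(codons, synonymous) {
    repeat {
      ci <- sample.int(length(codons), 1)
      pos <- sample.int(3, 1)
      v <- strsplit(codons[ci], "")[[1]]
      alt <- v; alt[pos] <- sample1(setdiff(nts, v[pos]))
      altc <- paste(alt, collapse = "")
      if (gc[altc] == "*") next
      is_syn <- gc[altc] == gc[codons[ci]]
      if (is_syn == synonymous) {
        codons[ci] <- altc
        return(codons)
      }
    }
  }
  evolve <- function(codons, n_syn, n_nonsyn) {
    plan <- sample(c(rep(TRUE, n_syn), rep(FALSE, n_nonsyn)))
    for (syn in plan) codons <- mutate(codons, syn)
    codons
  }
  ns_a <- stats::rpois(1, target_ks / 2 * S)
  nn_a <- stats::rpois(1, target_ka / 2 * N)
  ns_b <- stats::rpois(1, target_ks / 2 * S)
  nn_b <- stats::rpois(1, target_ka / 2 * N)
  a <- evolve(anc, ns_a, nn_a)
  b <- evolve(anc, ns_b, nn_b)
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       ancestor = paste(anc, collapse = ""),
       truth = list(ks = (ns_a + ns_b) / S, ka = (nn_a + nn_b) / N,
                    syn_events = ns_a + ns_b, nonsyn_events = nn_a + nn_b,
                    S = S, N = N),
       seed = seed)
}
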