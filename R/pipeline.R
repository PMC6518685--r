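#' Build a pipeline run configuration
#'
#' @param proteome,cds,gff Input paths (protein FASTA, coding-sequence
#'   FASTA, GFF3). `proteome` is required for the `classify` stage; `cds`
#'   for `kaks`; `gff` for `duplication` and `promoters`.
#' @param genome Genome FASTA path (promoter stage only).
#' @param motifs Cis-element motif TSV path (promoter stage only).
#' @param anchors Optional segmental-anchor TSV path.
#' @param templates_path Template registry TSV (default: bundled).
#' @param references Optional similarity-fallback references (data.frame).
#' @param min_spacer,max_spacer ECM scan bounds.
#' @param max_intervening,max_distance Tandem-duplication thresholds.
#' @param r Neutral substitution rate (per site per year).
#' @param bootstrap Bootstrap replicates for the tree stage.
#' @param promoter_length Promoter window length in bp.
#' @param seed Seed used by every stochastic stage; recorded in outputs.
#' @param stages Character vector of enabled stages, subset of
#'   `c("classify", "report", "duplication", "kaks", "tree", "promoters")`.
#' @param out_dir Output directory for the report bundle.
#' @return Object of class `ltp_config`.
#' @export
ltp_config <- function(proteome = NULL, cds = NULL, gff = NULL,
                       genome = NULL, motifs = NULL, anchors = NULL,
                       templates_path = NULL, references = NULL,
                       min_spacer = 3L, max_spacer = 40L,
                       max_intervening = 5L, max_distance = 100000L,
                       r = 2.6e-9, bootstrap = 1000L,
                       promoter_length = 1500L, seed = 1L,
                       stages = c("classify", "report", "duplication",
                                  "kaks", "tree"),
                       out_dir = tempfile("ltpscan_run_")) {
  stopifnot(max_intervening >= 0, max_distance > 0, r > 0, bootstrap >= 0)
  cfg <- list(proteome = proteome, cds = cds, gff = gff, genome = genome,
              motifs = motifs, anchors = anchors,
              templates_path = templates_path, references = references,
              min_spacer = min_spacer, max_spacer = max_spacer,
              max_intervening = max_intervening, max_distance = max_distance,
              r = r, bootstrap = bootstrap,
              promoter_length = promoter_length, seed = seed,
              stages = stages, out_dir = out_dir)
  class(cfg) <- "ltp_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; keys mirror the
#' arguments of [ltp_config()]. Values given programmatically (the `...`)
#' override the file.
#'
#' @param path Config file path.
#' @param ... Overrides passed to [ltp_config()].
#' @return `ltp_config` object.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p) {
    c(trimws(p[1]), trimws(paste(p[-1], collapse = "=")))
  })
  args <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  numeric_keys <- c("min_spacer", "max_spacer", "max_intervening",
                    "max_distance", "r", "bootstrap", "promoter_length",
                    "seed")
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  if ("stages" %in% names(args)) {
    args$stages <- trimws(strsplit(args$stages[[1]], ",")[[1]])
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(ltp_config, args)
}

#' Collapse an integer set to the compact print syntax
#'
#' Consecutive runs become `a-b`; everything else is comma-separated
#' (e.g. `c(3, 13, 14)` -> `"3,13-14"`, `c(12:17)` -> `"12-17"`).
#'
#' @param v Integer vector.
#' @return Character scalar.
#' @export
compact_range <- function(v) {
  v <- sort(unique(as.integer(v)))
  if (!length(v)) return("")
  runs <- split(v, cumsum(c(1, diff(v) != 1)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = ",")
}

#' Summarize classified types in the family-table style
#'
#' Per type: member count, percentage of classified proteins, and the
#' realized spacing pattern in the compact syntax
#' `CX<s1>CX<s2>CCX<s3>CXCX<s4>CX<s5>C` built from the observed spacer
#' value sets.
#'
#' @param results Classification results data.frame from
#'   [classify_proteome()].
#' @return data.frame `type`, `count`, `percent`, `pattern`.
#' @export
summarize_types <- function(results) {
  cls <- results[!results$assigned_type %in% c("no_ecm", "unclassified") &
                   !is.na(results$spacers), , drop = FALSE]
  if (nrow(cls) == 0) {
    return(data.frame(type = character(0), count = integer(0),
                      percent = numeric(0), pattern = character(0),
                      stringsAsFactors = FALSE))
  }
  types <- unique(cls$assigned_type)
  rows <- lapply(types, function(tp) {
    sub <- cls[cls$assigned_type == tp, , drop = FALSE]
    sp <- do.call(rbind, lapply(strsplit(sub$spacers, ","), as.integer))
    sets <- lapply(1:5, function(k) compact_range(sp[, k]))
    data.frame(type = tp, count = nrow(sub),
               percent = round(100 * nrow(sub) / nrow(cls), 2),
               pattern = paste0("CX", sets[[1]], "CX", sets[[2]], "CCX",
                                sets[[3]], "CXCX", sets[[4]], "CX",
                                sets[[5]], "C"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$type), , drop = FALSE]
}

#' Drop genes with zero expression everywhere
#'
#' Rows (genes) whose expression is zero in every condition are excluded
#' before expression reporting; row order is otherwise preserved.
#'
#' @param mat Non-negative numeric matrix (genes x conditions).
#' @return The filtered matrix.
#' @export
filter_expressed <- function(mat) {
  stopifnot(is.matrix(mat) || is.data.frame(mat))
  m <- as.matrix(mat)
  if (nrow(m) == 0) return(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative expression value")
  m[rowSums(m != 0, na.rm = TRUE) > 0, , drop = FALSE]
}

#' Run the full family survey pipeline
#'
#' Orchestrates classify -> characterize -> duplication -> Ka/Ks -> tree ->
#' promoters. Stage inputs are validated before any stage runs. Outputs are
#' written to `config$out_dir`: `family_report.tsv`, `type_summary.tsv`,
#' `clusters.tsv`, `kaks.tsv`, `tree.nwk`, `promoter_hits.tsv` and
#' `run.log`, each applicable to its enabled stage.
#'
#' @param config `ltp_config` object.
#' @return The report bundle (named list), invisibly: `classification`,
#'   `summary`, `family_report`, `clusters`, `pairs`, `kaks`, `tree`,
#'   `promoters`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ltp_config"))
  st <- config$stages
  need <- function(stage, field) {
    if (stage %in% st && is.null(config[[field]])) {
      stop("stage '", stage, "' requires config field '", field, "'")
    }
  }
  need("classify", "proteome")
  need("report", "proteome")
  need("duplication", "gff")
  need("kaks", "cds")
  need("promoters", "gff"); need("promoters", "genome")
  need("promoters", "motifs")
  if (("report" %in% st || "duplication" %in% st || "kaks" %in% st ||
       "tree" %in% st) && !"classify" %in% st) {
    stop("downstream stages require the 'classify' stage")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logl <- c(sprintf("ltpscan run; seed=%d", as.integer(config$seed)))
  note <- function(...) logl <<- c(logl, sprintf(...))
  bundle <- list(config = config, log = logf)
  templates <- if (is.null(config$templates_path)) default_templates() else
    read_templates(config$templates_path)

  gffdat <- NULL
  if (!is.null(config$gff)) gffdat <- read_gff3(config$gff)

  if ("classify" %in% st) {
    prots <- read_fasta(config$proteome, "protein")
    cl <- classify_proteome(prots, templates, config$references,
                            config$min_spacer, config$max_spacer)
    n_noecm <- sum(cl$results$assigned_type == "no_ecm")
    n_uncl <- sum(cl$results$assigned_type == "unclassified")
    note("classify: %d proteins scanned; %d without ECM; %d unclassified; %d assigned",
         length(prots), n_noecm, n_uncl, length(prots) - n_noecm - n_uncl)
    bundle$classification <- cl$results
    bundle$summary <- summarize_types(cl$results)
    write_tsv(bundle$summary, file.path(config$out_dir, "type_summary.tsv"))
    family <- cl$results$id[!cl$results$assigned_type %in%
                              c("no_ecm", "unclassified")]
  }

  if ("report" %in% st) {
    cdss <- if (!is.null(config$cds)) read_fasta(config$cds, "nucleotide")
            else NULL
    rows <- lapply(family, function(id) {
      seq <- prots[[id]]
      pc <- tryCatch(physchem(seq),
                     error = function(e) list(length = nchar(seq),
                                              mw = NA_real_, pi = NA_real_))
      loc <- if (!is.null(gffdat) && id %in% gffdat$loci$gene_id) {
        gffdat$loci[gffdat$loci$gene_id == id, ]
      } else NULL
      model <- if (!is.null(gffdat)) gffdat$models[[id]] else NULL
      cds_len <- if (!is.null(cdss) && id %in% names(cdss)) {
        nchar(strip_terminal_stop(cdss[[id]]))
      } else NA_integer_
      data.frame(
        gene_id = id,
        type = bundle$classification$assigned_type[
          bundle$classification$id == id],
        ecm_spacing = bundle$classification$spacers[
          bundle$classification$id == id],
        protein_length_aa = pc$length,
        cds_length_bp = cds_len,
        mw_kda = round(pc$mw, 2), pi = round(pc$pi, 2),
        intron_count = if (is.null(model)) NA_integer_ else
          count_introns(model),
        chrom = if (is.null(loc)) NA_character_ else loc$chrom,
        start = if (is.null(loc)) NA_integer_ else loc$start,
        end = if (is.null(loc)) NA_integer_ else loc$end,
        stringsAsFactors = FALSE)
    })
    rows <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(
        data.frame(matrix(ncol = length(family_report_columns()), nrow = 0)),
        family_report_columns())
    bundle$family_report <- write_family_report(
      rows, file.path(config$out_dir, "family_report.tsv"))
    note("report: %d family rows written", nrow(rows))
  }

  pairs <- NULL
  if ("duplication" %in% st) {
    fam_in_gff <- intersect(family, gffdat$loci$gene_id)
    missing_gff <- setdiff(family, fam_in_gff)
    if (length(missing_gff)) {
      note("duplication: %d family gene(s) absent from GFF (unplaced), skipped",
           length(missing_gff))
    }
    clusters <- find_tandem_clusters(fam_in_gff, gffdat$loci,
                                     config$max_intervening,
                                     config$max_distance)
    bundle$clusters <- clusters
    pairs <- tandem_pairs(clusters, gffdat$loci, config$max_intervening,
                          config$max_distance)
    if (!is.null(config$anchors)) {
      seg <- load_segmental_anchors(config$anchors, family)
      pairs <- rbind(pairs, seg)
    }
    bundle$pairs <- pairs
    n_members <- length(unlist(lapply(clusters, `[[`, "members")))
    note("duplication: %d tandem cluster(s), %d member gene(s), %d pair(s) total",
         length(clusters), n_members, nrow(pairs))
    cl_rows <- if (length(clusters)) {
      do.call(rbind, lapply(seq_along(clusters), function(i) {
        data.frame(cluster = sprintf("C%02d", i),
                   chrom = clusters[[i]]$chrom,
                   members = paste(clusters[[i]]$members, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    } else data.frame(cluster = character(0), chrom = character(0),
                      members = character(0), stringsAsFactors = FALSE)
    write_tsv(cl_rows, file.path(config$out_dir, "clusters.tsv"))
  }

  if ("kaks" %in% st && !is.null(pairs) && nrow(pairs) > 0) {
    cdss <- read_fasta(config$cds, "nucleotide")
    krows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
      if (!a %in% names(cdss) || !b %in% names(cdss)) {
        note("kaks: pair %s/%s skipped (missing CDS)", a, b)
        return(NULL)
      }
      kk <- kaks_pair(cdss[[a]], cdss[[b]], r = config$r)
      data.frame(gene_a = a, gene_b = b, mode = pairs$mode[i],
                 ka = round(kk$ka, 5), ks = round(kk$ks, 5),
                 ratio = round(kk$ratio, 5), selection = kk$selection,
                 time_mya = round(kk$time_mya, 2),
                 estimator = kk$estimator, stringsAsFactors = FALSE)
    })
    krows <- do.call(rbind, krows[!vapply(krows, is.null, logical(1))])
    bundle$kaks <- krows
    if (!is.null(krows)) {
      write_tsv(krows, file.path(config$out_dir, "kaks.tsv"))
      note("kaks: %d pair(s) estimated (NG86+JC); %d purifying, %d positive",
           nrow(krows), sum(krows$selection == "purifying"),
           sum(krows$selection == "positive"))
    }
  }

  if ("tree" %in% st && length(family) >= 3) {
    prots_fam <- prots[family]
    matches <- lapply(prots_fam, function(s) {
      find_ecm_matches(s, config$min_spacer, config$max_spacer)[[1]]
    })
    aln <- align_ecm_anchored(matches)
    tree <- if (config$bootstrap > 0) {
      bootstrap_support(aln, n_replicates = config$bootstrap,
                        seed = config$seed)
    } else neighbor_joining(p_distance(aln))
    bundle$tree <- tree
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
    note("tree: NJ over %d taxa; %d bootstrap replicate(s); seed %d",
         length(aln), as.integer(config$bootstrap), as.integer(config$seed))
  }

  if ("promoters" %in% st) {
    genome <- read_fasta(config$genome, "nucleotide")
    motifs <- read_motifs(config$motifs)
    loci_fam <- gffdat$loci[gffdat$loci$gene_id %in% family, , drop = FALSE]
    prom <- extract_promoters(loci_fam, genome, config$promoter_length)
    if (any(prom$truncated)) {
      note("promoters: %d window(s) truncated at a chromosome edge",
           sum(prom$truncated))
    }
    scan <- scan_promoters(prom$seqs, motifs)
    bundle$promoters <- scan
    write_tsv(scan$hits, file.path(config$out_dir, "promoter_hits.tsv"))
    note("promoters: %d hit(s) in %d promoter(s)", nrow(scan$hits),
         length(prom$seqs))
  }

  writeLines(logl, logf)
  invisible(bundle)
}
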