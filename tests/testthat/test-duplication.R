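mk_loci <- function(starts, chrom = "chr1", ids = NULL, width = 1000) {
  n <- length(starts)
  ids <- ids %||% sprintf("g%02d", seq_len(n))
  df <- data.frame(gene_id = ids, chrom = chrom, strand = "+",
                   start = starts, end = starts + width,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  df$rank <- stats::ave(seq_len(n), df$chrom, FUN = seq_along)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("adjacent close family genes form one transitive cluster", {
  loci <- mk_loci(c(10000, 20000, 30000))
  cl <- find_tandem_clusters(loci$gene_id, loci)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, loci$gene_id)
})

test_that("the two rule conditions are enforced independently", {
  # 6 intervening genes, 50 kb apart: fails the gene-count condition
  starts <- seq(10000, by = 7000, length.out = 8)
  loci <- mk_loci(starts)
  fam <- c("g01", "g08")  # ranks 1 and 8: 6 intervening
  expect_identical(find_tandem_clusters(fam, loci), list())
  # exactly 5 intervening at the same distances: qualifies
  fam2 <- c("g01", "g07")
  expect_length(find_tandem_clusters(fam2, loci), 1)
  # adjacent ranks but 150 kb apart: fails the distance condition
  loci2 <- mk_loci(c(10000, 160000))
  expect_identical(find_tandem_clusters(loci2$gene_id, loci2), list())
  # boundary: exactly 100 kb start-to-start qualifies
  loci3 <- mk_loci(c(10000, 110000))
  expect_length(find_tandem_clusters(loci3$gene_id, loci3), 1)
  expect_error(find_tandem_clusters("nope", loci), "unknown")
})

test_that("chains cluster transitively even when end pairs fail", {
  loci <- mk_loci(c(10000, 90000, 170000))
  cl <- find_tandem_clusters(loci$gene_id, loci)
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 3)
})

test_that("random layouts match the brute-force union-find oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(6:14, 1)
    starts <- sort(sample(seq(1e4, 4e5, by = 1e3), n))
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    loci <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = chrom,
                       strand = "+", start = starts, end = starts + 500,
                       stringsAsFactors = FALSE)
    loci <- loci[order(loci$chrom, loci$start), ]
    loci$rank <- stats::ave(seq_len(n), loci$chrom, FUN = seq_along)
    fam <- sample(loci$gene_id, sample(3:n, 1))
    got <- find_tandem_clusters(fam, loci)
    got_sets <- lapply(got, function(cl) sort(cl$members))
    want <- oracle_tandem(fam, loci)
    key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))
    expect_identical(key(got_sets), key(want))
    # shuffle invariance
    got2 <- find_tandem_clusters(sample(fam), loci[sample(1:n), ])
    expect_identical(key(lapply(got2, function(cl) sort(cl$members))),
                     key(want))
  }
})

test_that("segmental anchors are filtered and deduplicated", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "a\tb", "b\ta", "a\tz"), tf)
  expect_message(out <- load_segmental_anchors(tf, c("a", "b")),
                 "non-family")
  expect_identical(nrow(out), 1L)
  expect_identical(out$mode, "segmental")
  writeLines(c("a\tb", "broken-line"), tf)
  expect_error(load_segmental_anchors(tf, c("a", "b")), "line 2")
  writeLines(character(0), tf)
  expect_identical(nrow(load_segmental_anchors(tf, "a")), 0L)
})

test_that("divergence_time implements t = Ks/2r", {
  expect_equal(round(divergence_time(4.92384), 2), 946.89)
  expect_equal(round(divergence_time(0.52), 2), 100)
  expect_identical(divergence_time(0), 0)
  # linear in ks, inverse in r
  expect_equal(divergence_time(1.2), 3 * divergence_time(0.4))
  expect_equal(divergence_time(0.5, r = 5.2e-9), divergence_time(0.5) / 2)
  expect_error(divergence_time(-0.1), "negative")
})

test_that("selection categories follow the Ka/Ks thresholds", {
  expect_identical(categorize_selection(0.2, 0.8), "purifying")
  expect_identical(categorize_selection(1.2, 0.6), "positive")
  expect_identical(categorize_selection(0.5, 0), "undetermined")
  expect_identical(categorize_selection(0.5, 0.5), "neutral")
})

test_that("planted maps are recovered with perfect precision and recall", {
  gm <- generate_gene_map(cluster_sizes = c(3, 2, 4), n_singletons = 5,
                          n_decoy_intervening = 2, n_decoy_distance = 2,
                          n_chromosomes = 3, seed = 19)
  g <- read_gff3(gm$gff)
  cl <- find_tandem_clusters(gm$family_ids, g$loci)
  called <- sort(unlist(lapply(cl, `[[`, "members")))
  truth <- gm$truth
  planted <- sort(truth$gene_id[grepl("^C", truth$cluster)])
  expect_identical(called, planted)   # precision = recall = 1
  # cluster-level identity
  key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))
  expect_identical(key(lapply(cl, function(x) sort(x$members))),
                   key(lapply(unname(gm$expected_clusters), sort)))
})
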