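test_that("p-distance handles gaps by pairwise deletion", {
  d <- p_distance(c(a = "ACCT", b = "ACCT"))$dist
  expect_equal(d["a", "b"], 0)
  d2 <- p_distance(c(a = "AC-T", b = "ACGT"))$dist
  expect_equal(d2["a", "b"], 0)          # gap site excluded: 0/3
  d3 <- p_distance(c(a = "ACGT", b = "ACGA"))$dist
  expect_equal(d3["a", "b"], 0.25)
  expect_error(p_distance(c(a = "AC", b = "ACG")), "length")
  expect_error(p_distance(c(a = "--A", b = "A--")), "comparable")
})

test_that("p-distance is symmetric with zero diagonal and [0,1] entries", {
  set.seed(41)
  for (k in 1:10) {
    n <- sample(3:8, 1); L <- sample(20:60, 1)
    seqs <- vapply(1:n, function(i) {
      s <- sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                  prob = c(rep(0.23, 4), 0.08))
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("t", 1:n)
    p <- tryCatch(p_distance(seqs), error = function(e) NULL)
    if (is.null(p)) next
    expect_true(all(abs(p$dist - t(p$dist)) < 1e-12))
    expect_true(all(diag(p$dist) == 0))
    expect_true(all(p$dist >= 0 & p$dist <= 1))
  }
})

test_that("NJ recovers a known 4-taxon additive tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  expect_equal(as.numeric(ape::dist.topo(nj, ape::unroot(tr))), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
})

test_that("3 taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_identical(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("ties resolve deterministically on equidistant matrices", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # lexicographically first pair (a, b) joined first
  expect_true(grepl("\\(a:[0-9.]+,b:", ape::write.tree(t1)) ||
              grepl("\\(b:[0-9.]+,a:", ape::write.tree(t1)))
})

test_that("NJ reproduces random additive trees (topology and lengths)", {
  set.seed(43)
  for (k in 1:30) {
    ntax <- sample(4:12, 1)
    tr <- ape::rtree(ntax, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(tr, nj)), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    expect_true(all(nj$edge.length >= 0))
  }
})

test_that("negative branch estimates are clamped and flagged", {
  # strongly non-additive matrix forces a negative NJ estimate
  D <- matrix(c(0, 1, 10, 10,
                1, 0, 1, 10,
                10, 1, 0, 1,
                10, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is seeded, bounded and certain when diagnostic", {
  # two clean 3-taxon clades separated by many invariant diagnostic columns
  blockA <- strrep("A", 100); blockC <- strrep("C", 100)
  seqs <- c(a1 = paste0(blockA, "GGGTT"), a2 = paste0(blockA, "GGTTT"),
            a3 = paste0(blockA, "GTTTT"),
            b1 = paste0(blockC, "GGGTT"), b2 = paste0(blockC, "GGTTT"),
            b3 = paste0(blockC, "GTTTT"))
  tr <- bootstrap_support(seqs, n_replicates = 50, seed = 99)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the central a|b split cannot be broken by any column resample
  parts <- tree_bipartitions_for_test(tr)
  central <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_true(central %in% names(parts))
  expect_equal(unname(parts[[central]]), 100)
  # determinism
  tr2 <- bootstrap_support(seqs, n_replicates = 50, seed = 99)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- bootstrap_support(seqs, n_replicates = 50, seed = 100)
  expect_identical(tr3$tip.label, tr$tip.label)
})

test_that("anchored ECM alignment pins cysteines and pads spacers", {
  sim <- generate_proteome(c(I = 3, II = 2), seed = 55)
  matches <- lapply(sim$proteins, function(s) find_ecm_matches(s)[[1]])
  aln <- align_ecm_anchored(matches)
  expect_length(unique(nchar(aln)), 1)
  # cysteine columns are invariant across all sequences
  mat <- do.call(rbind, strsplit(aln, ""))
  cys_cols <- which(apply(mat, 2, function(col) all(col == "C")))
  expect_gte(length(cys_cols), 8)
  expect_identical(gsub("-", "", aln[["LTP_I_01"]]),
                   matches[["LTP_I_01"]]$ecm_seq)
})
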