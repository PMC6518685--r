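test_that("global alignment handles identity and forced gaps", {
  a <- align_proteins_global("MKC", "MKC")
  expect_identical(a$aligned_a, "MKC")
  expect_identical(a$aligned_b, "MKC")
  a2 <- align_proteins_global("MKC", "MC")
  expect_identical(nchar(a2$aligned_a), 3L)
  expect_identical(sum(strsplit(a2$aligned_b, "")[[1]] == "-"), 1L)
  # de-gapping recovers the inputs; never a dual-gap column
  ga <- strsplit(a2$aligned_a, "")[[1]]
  gb <- strsplit(a2$aligned_b, "")[[1]]
  expect_identical(gsub("-", "", a2$aligned_a), "MKC")
  expect_identical(gsub("-", "", a2$aligned_b), "MC")
  expect_false(any(ga == "-" & gb == "-"))
})

test_that("alignment scores equal exhaustive enumeration for short inputs", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- e$BLOSUM62
  set.seed(21)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (k in 1:25) {
    a <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    got <- align_proteins_global(a, b)
    expect_equal(got$score, oracle_best_score(a, b, sub))
  }
})

test_that("backtranslation maps protein gaps to codon gaps", {
  aln <- align_proteins_global("MKC", "MC")
  cod <- backtranslate_alignment(aln, "ATGAAATGT", "ATGTGTTAA")
  expect_identical(nchar(cod$codon_a), 9L)
  expect_identical(gsub("-", "", cod$codon_a), "ATGAAATGT")
  expect_identical(gsub("-", "", cod$codon_b), "ATGTGT")
  expect_match(cod$codon_b, "---")
  # round-trip on a gapless pair: concatenated codons
  aln2 <- align_proteins_global("MK", "MK")
  cod2 <- backtranslate_alignment(aln2, "ATGAAA", "ATGAAG")
  expect_identical(cod2$codon_a, "ATGAAA")
  expect_identical(cod2$codon_b, "ATGAAG")
  expect_error(backtranslate_alignment(aln2, "ATGTGT", "ATGAAG"),
               "mismatch")
})

test_that("NG86 counting matches hand and oracle values", {
  z <- ng86_counts("TTT", "TTT")
  expect_equal(z$Sd + z$Nd, 0)
  z2 <- ng86_counts("TTT", "TTA")
  expect_equal(z2$Nd, 1)   # Phe -> Leu, nonsynonymous single step
  expect_equal(z2$Sd, 0)
  # gap and stop columns are skipped and counted
  z3 <- ng86_counts("TTT---TAA", "TTTAAATAA")
  expect_identical(z3$codons_compared, 1L)
  expect_identical(z3$codons_skipped, 2L)
})

test_that("NG86 equals the explicit path-enumeration oracle", {
  set.seed(31)
  for (k in 1:200) {
    a <- random_sense_codon(); b <- random_sense_codon()
    got <- ng86_counts(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S)
    expect_equal(got$N, want$N)
    expect_equal(got$Sd, want$Sd)
    expect_equal(got$Nd, want$Nd)
  }
})

test_that("site conservation and symmetry hold", {
  set.seed(32)
  mk_cds <- function(n) paste(replicate(n, random_sense_codon()),
                              collapse = "")
  for (k in 1:10) {
    n <- sample(5:30, 1)
    a <- mk_cds(n); b <- mk_cds(n)
    z <- ng86_counts(a, b)
    expect_equal(z$S + z$N, 3 * z$codons_compared)
    z2 <- ng86_counts(b, a)
    expect_equal(z$S, z2$S)
    expect_equal(z$Sd, z2$Sd)
    expect_equal(z$Nd, z2$Nd)
  }
})

test_that("Jukes-Cantor correction matches the closed form", {
  counts <- list(S = 100, N = 200, Sd = 30, Nd = 0)
  est <- kaks_estimate(counts)
  expect_equal(est$ks, -0.75 * log(1 - 4 * 0.3 / 3))
  expect_equal(est$ka, 0)
  expect_false(est$saturated)
  expect_equal(est$ratio, 0)  # ka = 0 over ks > 0

  sat <- kaks_estimate(list(S = 10, N = 10, Sd = 8, Nd = 0))
  expect_true(sat$saturated)
  expect_true(is.na(sat$ks))
})

test_that("mutations at 4-fold degenerate third positions give ka = 0", {
  # GGx = Gly for every x: change third positions only
  a <- strrep("GGA", 10)
  b <- paste(rep(c("GGC", "GGA"), 5), collapse = "")
  z <- ng86_counts(a, b)
  expect_equal(z$Nd, 0)
  est <- kaks_estimate(z)
  expect_equal(est$ka, 0)
  expect_gt(est$ks, 0)
})

test_that("kaks_pair runs the full route and is symmetric", {
  sim <- simulate_codon_pair(60, 0.3, 0.05, seed = 8)
  k1 <- kaks_pair(sim$cds_a, sim$cds_b)
  k2 <- kaks_pair(sim$cds_b, sim$cds_a)
  expect_equal(k1$ka, k2$ka)
  expect_equal(k1$ks, k2$ks)
  expect_identical(k1$estimator, "NG86+JC")
  expect_true(k1$ka >= 0 && k1$ks >= 0)
  expect_identical(k1$selection,
                   categorize_selection(k1$ka, k1$ks))
})
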