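type_I_protein <- function() {
  paste0("M", "C", strrep("A", 9), "C", strrep("A", 12), "CC",
         strrep("A", 19), "CAC", strrep("A", 20), "C", strrep("A", 3), "C")
}

test_that("find_ecm_matches detects a constructed type-I motif", {
  m <- find_ecm_matches(type_I_protein())
  expect_length(m, 1)
  expect_identical(m[[1]]$spacers, c(9L, 12L, 19L, 20L, 3L))
  expect_identical(substr(m[[1]]$ecm_seq, 1, 1), "C")
  # structural invariants
  cys <- m[[1]]$cys
  expect_identical(cys[4], cys[3] + 1L)
  expect_identical(cys[6], cys[5] + 2L)
})

test_that("sequences without cysteines yield no matches", {
  expect_identical(find_ecm_matches("MKLLVA"), list())
  expect_identical(find_ecm_matches(strrep("A", 200)), list())
})

test_that("find_ecm_matches equals brute-force subset enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    seq <- random_protein(sample(60:200, 1), sample(6:12, 1))
    got <- find_ecm_matches(seq)
    want <- brute_force_ecm(seq)
    expect_identical(length(got), length(want))
    if (length(got)) {
      expect_identical(lapply(got, `[[`, "cys"), lapply(want, `[[`, "cys"))
      expect_identical(lapply(got, `[[`, "spacers"),
                       lapply(want, `[[`, "spacers"))
    }
  }
})

test_that("allow_cys_in_spacers recovers the literal reading", {
  # 9 cysteines: an extra C inside spacer 2 of an otherwise valid motif
  seq <- paste0("C", strrep("A", 9), "C", strrep("A", 5), "C",
                strrep("A", 6), "CC", strrep("A", 19), "CAC",
                strrep("A", 20), "C", strrep("A", 3), "C")
  strict <- find_ecm_matches(seq)
  loose <- find_ecm_matches(seq, allow_cys_in_spacers = TRUE)
  oracle <- brute_force_ecm(seq, allow_cys_in_spacers = TRUE)
  expect_identical(length(loose), length(oracle))
  expect_true(length(loose) >= length(strict))
})

test_that("classify_by_spacing matches the bundled templates", {
  tm <- default_templates()
  mk <- function(sp) list(spacers = as.integer(sp))
  expect_identical(classify_by_spacing(mk(c(9, 12, 19, 20, 3)), tm), "I")
  expect_identical(classify_by_spacing(mk(c(7, 13, 8, 23, 6)), tm), "II")
  expect_identical(classify_by_spacing(mk(c(5, 5, 5, 5, 5)), tm),
                   character(0))
})

test_that("template overlaps equal the Cartesian-product oracle", {
  tm <- default_templates()
  # brute force: enumerate all 5-tuples over the union of template values
  # and record which tuples match two or more templates
  grids <- lapply(1:5, function(k) {
    sort(unique(unlist(lapply(tm, function(t) t$allowed[[k]]))))
  })
  tuples <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  n_match <- apply(tuples, 1, function(sp) {
    sum(vapply(tm, function(t) {
      all(vapply(1:5, function(k) sp[k] %in% t$allowed[[k]], logical(1)))
    }, logical(1)))
  })
  overlap_oracle <- tuples[n_match >= 2, , drop = FALSE]
  for (r in seq_len(nrow(overlap_oracle))) {
    sp <- as.integer(overlap_oracle[r, ])
    expect_gte(length(classify_by_spacing(list(spacers = sp), tm)), 2)
  }
  # and the implementation finds no overlap the oracle missed
  single <- tuples[n_match == 1, , drop = FALSE]
  idx <- seq_len(min(nrow(single), 200))
  for (r in idx) {
    sp <- as.integer(single[r, ])
    expect_length(classify_by_spacing(list(spacers = sp), tm), 1)
  }
})

test_that("classify_by_similarity scores identity and breaks ties", {
  ref_seq <- paste(rep(c("C", "A", "R", "N", "D"), 10), collapse = "")
  refs <- data.frame(type_name = c("I", "II"), id = c("r1", "r2"),
                     seq = c("CKCKCKCKCK", ref_seq),
                     stringsAsFactors = FALSE)
  hit <- classify_by_similarity(ref_seq, refs)
  expect_identical(hit$type_name, "II")
  expect_equal(hit$identity, 100)
  # Hamming distance 1 on a length-50 reference: 49/50 = 98%
  query <- ref_seq
  substr(query, 10, 10) <- "W"
  hit <- classify_by_similarity(query, refs)
  expect_identical(hit$type_name, "II")
  expect_equal(hit$identity, 98)
  # exact tie: first reference in table order wins
  refs2 <- data.frame(type_name = c("V", "VII"), id = c("a", "b"),
                      seq = c(ref_seq, ref_seq), stringsAsFactors = FALSE)
  expect_identical(classify_by_similarity(ref_seq, refs2)$type_name, "V")
  expect_error(classify_by_similarity("CC", refs2[0, ]), "reference")
})

test_that("classify_proteome handles edge cases", {
  empty <- classify_proteome(stats::setNames(character(0), character(0)))
  expect_identical(nrow(empty$results), 0L)
  expect_identical(nrow(empty$summary), 0L)

  # ECM present but outside every template, no fallback
  seq <- paste0("C", strrep("A", 35), "C", strrep("A", 35), "CC",
                strrep("A", 35), "CAC", strrep("A", 35), "C",
                strrep("A", 35), "C")
  out <- classify_proteome(c(p = seq))
  expect_identical(out$results$assigned_type, "unclassified")
  expect_identical(out$results$method, "none")
})

test_that("classification is deterministic and summary counts add up", {
  sim <- generate_proteome(c(I = 5, VIII = 4, XIII = 3), n_decoys = 9,
                           seed = 77)
  a <- classify_proteome(sim$proteins)
  b <- classify_proteome(sim$proteins)
  expect_identical(a, b)
  n_classified <- sum(!a$results$assigned_type %in% c("no_ecm", "unclassified"))
  expect_identical(sum(a$summary$count), n_classified)
})

test_that("consensus_logo_counts conserves column sums", {
  cc <- consensus_logo_counts(c("ACD", "ACD", "ACD"))
  expect_true(all(colSums(cc) == 3))
  expect_identical(max(cc), 3L)
  cc2 <- consensus_logo_counts(c("ACD", "AWD"))
  expect_identical(sort(cc2[, 2][cc2[, 2] > 0]), c(C = 1L, W = 1L))
  cc3 <- consensus_logo_counts(c("A-D", "ACD"))
  expect_identical(unname(cc3["-", 2]), 1L)
  expect_error(consensus_logo_counts(c("AC", "ACD")), "length")
})
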