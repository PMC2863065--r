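test_that("the toy design matrix matches its hand enumeration", {
  dm <- build_design_matrix(toy_gene(), uniform_model(5L))
  expect_equal(dm$entries, toy_dm_expected(), tolerance = 1e-12)
  # cross-isoform singleton entries are structurally zero
  expect_identical(dm$entries["G1.2", "G1.1"], 0)
  expect_identical(dm$entries["G1.1", "G1.2"], 0)
  expect_equal(design_matrix_rank(dm), 2L)
  expect_equal(unname(dm$column_mass), c(1, 1), tolerance = 1e-9)
})

test_that("a single-isoform gene gives the 1x1 unit matrix", {
  g <- gene("G", list(transcript("t1", "G", strrep("ACGT", 10L))))
  dm <- build_design_matrix(g, uniform_model(6L))
  expect_equal(unname(dm$entries), matrix(1), tolerance = 1e-12)
})

test_that("design matrices agree entry-wise with brute-force enumeration", {
  skew <- read_model(seq(0, 1, length.out = 64),
                     1 + seq(0, 1, length.out = 64)^2,
                     c(`7` = 0.4, `11` = 0.6))
  for (seed in 1:4) {
    g <- random_gene(n_isoforms = 2L + (seed %% 2L), seed = seed + 20L)
    dm <- build_design_matrix(g, skew)
    oracle <- brute_design_matrix(g, skew)
    expect_equal(dim(dm$entries), dim(oracle))
    oracle <- oracle[rownames(dm$entries), , drop = FALSE]
    expect_equal(unname(dm$entries), unname(oracle), tolerance = 1e-12)
    expect_equal(unname(colSums(dm$entries)),
                 rep(1, ncol(dm$entries)), tolerance = 1e-9)
  }
})

test_that("transcripts shorter than every read length are refused", {
  g <- gene("G", list(transcript("t1", "G", strrep("ACGT", 30L)),
                      transcript("t2", "G", "ACGTACG")))
  expect_error(build_design_matrix(g, uniform_model(25L)), "t2")
})

test_that("rank reduction keeps singletons, merges small rows, and flags duplicates", {
  g3 <- random_gene(n_isoforms = 3L, seed = 9L)
  dm <- build_design_matrix(g3, uniform_model(8L))
  singles <- reduce_to_full_rank(dm, "singletons_only")
  expect_equal(dim(singles$entries), c(3L, 3L))
  expect_true(all(lengths(singles$subsets) == 1L))
  expect_equal(design_matrix_rank(singles), 3L)

  merged <- reduce_to_full_rank(dm, "merge_small", threshold = 0.05)
  expect_equal(unname(colSums(merged$entries)), rep(1, 3), tolerance = 1e-9)
  expect_equal(design_matrix_rank(merged), 3L)

  dup <- gene("G", list(transcript("t1", "G", strrep("ACGT", 12L)),
                        transcript("t2", "G", strrep("ACGT", 12L))))
  dmdup <- build_design_matrix(dup, uniform_model(6L))
  expect_error(reduce_to_full_rank(dmdup), "indistinguishable")
  expect_error(reduce_to_full_rank(dmdup, "singletons_only"), "t1")
})

test_that("multiread masking removes exactly the shared mass", {
  g <- toy_gene()
  # a second gene containing the all-C reads (and nothing else shared)
  other <- gene("G2", list(transcript("G2.1", "G2",
                                      paste0("GGGGGGG", strrep("C", 10L)))))
  idx <- build_kmer_index(list(g, other), k = 8L)
  dm <- apply_multiread_mask(g, uniform_model(5L), idx)
  full <- toy_dm_expected()
  # all 6 C-only windows of T1 (mass 6/23) and of T2 (6/13) are skipped
  expect_equal(dm$entries["G1.1+G1.2", ], c(G1.1 = 3 / 23, G1.2 = 3 / 13),
               tolerance = 1e-12)
  expect_equal(dm$entries["G1.1", "G1.1"], full["G1.1", "G1.1"])
  expect_equal(unname(dm$column_mass + dm$skipped_mass), c(1, 1),
               tolerance = 1e-9)
  expect_equal(unname(dm$skipped_mass), c(6 / 23, 6 / 13), tolerance = 1e-12)

  # no shared sequence: masking is a no-op
  a <- gene("A", list(transcript("A.1", "A", strrep("AC", 30L))))
  b <- gene("B", list(transcript("B.1", "B", strrep("GT", 30L))))
  idx2 <- build_kmer_index(list(a, b), k = 8L)
  expect_equal(apply_multiread_mask(a, uniform_model(10L), idx2)$entries,
               build_design_matrix(a, uniform_model(10L))$entries)

  # every read shared with a paralog: inestimable
  twin1 <- gene("P1", list(transcript("P1.1", "P1", strrep("ACGT", 15L))))
  twin2 <- gene("P2", list(transcript("P2.1", "P2", strrep("ACGT", 15L))))
  idx3 <- build_kmer_index(list(twin1, twin2), k = 8L)
  expect_error(apply_multiread_mask(twin1, uniform_model(10L), idx3),
               "inestimable")
})

test_that("masked matrices match brute-force enumeration with a membership test", {
  g <- sim_gene(exons = c(60L, 30L, 60L), seed = 31L)
  seqs <- transcript_seqs(g)
  # a paralog carrying a 50-base block lifted from g's first exon, so the
  # mask genuinely bites, plus an unrelated gene
  paralog <- gene("P", list(transcript("P.1", "P",
    paste0(strrep("GA", 10L), substr(seqs[1], 5L, 54L), strrep("TC", 10L)))))
  unrelated <- make_gene(fixture_spec("cassette_exon",
                                      exons = c(50L, 20L, 50L), seed = 77L,
                                      gene_id = "U"))
  all_genes <- list(g, paralog, unrelated)
  idx <- build_kmer_index(all_genes, k = 12L)
  model <- uniform_model(15L)
  dm <- apply_multiread_mask(g, model, idx)
  expect_true(any(dm$skipped_mass > 0.05))
  # brute force: accumulate only windows absent from the other genes
  others <- unlist(lapply(all_genes[-1], transcript_seqs))
  oracle <- matrix(0, nrow(dm$entries), ncol(dm$entries),
                   dimnames = dimnames(dm$entries))
  for (j in seq_along(seqs)) {
    h <- discretize(model, nchar(seqs[j]))
    for (i in seq_along(h$k)) {
      s <- substr(seqs[j], h$k[i], h$k[i] + h$m[i] - 1L)
      if (any(vapply(others, function(t) grepl(s, t, fixed = TRUE),
                     logical(1)))) next
      memb <- which(vapply(seqs, function(t) grepl(s, t, fixed = TRUE),
                           logical(1)))
      lab <- paste(names(seqs)[memb], collapse = "+")
      oracle[lab, j] <- oracle[lab, j] + h$p[i]
    }
  }
  expect_equal(dm$entries, oracle, tolerance = 1e-12)
})
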