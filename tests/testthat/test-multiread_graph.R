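# 72-nt proline tRNA shared (up to variation) across an Arabidopsis gene
# family; any two transcripts containing it share all 48 of its 25-mers.
TRNA_PRO <- paste0("gggcatttggtctagtggtatgattctcgctttgggtgcgagaggtcccgag",
                   "ttcgattctcggaatgcccc")

test_that("the k-mer index maps shared sequence to all carrying genes", {
  pair <- make_gene(fixture_spec("paralog_pair", exons = c(120L, 100L),
                                 seed = 8L, gene_id = "P"))
  idx <- build_kmer_index(pair, k = 25L)
  shared <- idx$table[, list(n = length(unique(gene_id))), by = "kmer"]
  expect_gte(sum(shared$n == 2L), 72L - 25L + 1L)

  one <- gene("G", list(transcript("G.1", "G", strrep("ACGTT", 5L))))
  idx1 <- build_kmer_index(list(one), k = 25L)
  expect_equal(nrow(idx1$table), 1L)

  expect_error(build_kmer_index(pair, k = 4L), "at least 8")
  tiny <- gene("T", list(transcript("T.1", "T", "ACGTACGT")))
  expect_warning(build_kmer_index(list(tiny), k = 25L), "no k-mers")
})

test_that("two genes carrying the tRNA-Pro repeat share its 48 25-mers", {
  set.seed(41)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  g1 <- gene("TR1", list(transcript("TR1.1", "TR1",
                                    paste0(pad(30), TRNA_PRO, pad(30)))))
  g2 <- gene("TR2", list(transcript("TR2.1", "TR2",
                                    paste0(pad(25), TRNA_PRO, pad(40)))))
  idx <- build_kmer_index(list(g1, g2), k = 25L)
  shared <- idx$table[, list(n = length(unique(gene_id))), by = "kmer"]
  expect_gte(sum(shared$n == 2L), 48L)
  part <- connected_components(idx, list(g1, g2))
  expect_equal(part$components, list(c("TR1", "TR2")))
})

test_that("connected components follow reachability, not just direct sharing", {
  set.seed(10)
  blockX <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  blockY <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  mk <- function(id, s) gene(id, list(transcript(paste0(id, ".1"), id, s)))
  A <- mk("A", paste0(blockX, pad(40)))
  B <- mk("B", paste0(pad(20), blockX, pad(20), blockY))  # bridges A and C
  C <- mk("C", paste0(blockY, pad(40)))
  D <- mk("D", pad(80))
  genes <- list(A, B, C, D)
  idx <- build_kmer_index(genes, k = 25L)
  part <- connected_components(idx, genes)
  expect_equal(part$components, list(c("A", "B", "C"), "D"))
  r <- component_report(part)
  expect_equal(r$n_components, 2L)
  expect_equal(r$mean_size, 2)
  expect_equal(r$n_genes / r$n_components, r$mean_size)
  expect_equal(r$size_histogram$n_components[r$size_histogram$size == 1], 1L)
})

test_that("partitions match a brute-force pairwise-substring DFS oracle", {
  brute_partition <- function(genes, k) {
    ids <- vapply(genes, `[[`, character(1), "id")
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ki <- unlist(lapply(transcript_seqs(genes[[i]]), function(s) {
          if (nchar(s) < k) character(0)
          else substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
        }))
        shared <- any(vapply(transcript_seqs(genes[[j]]), function(s) {
          any(stringi::stri_detect_fixed(s, unique(ki)))
        }, logical(1)))
        adj[i, j] <- adj[j, i] <- shared
      }
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[1]
        stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        stack <- c(stack, which(adj[v, ] & is.na(comp)))
      }
    }
    out <- lapply(split(ids, comp), sort)
    unname(out[order(-lengths(out), vapply(out, `[`, character(1), 1))])
  }

  set.seed(99)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  blocks <- replicate(4, pad(20))
  genes <- lapply(1:14, function(i) {
    s <- if (i <= 8) paste0(pad(15), sample(blocks, 1), pad(15)) else pad(50)
    gene(paste0("g", i), list(transcript(paste0("g", i, ".1"),
                                         paste0("g", i), s)))
  })
  idx <- build_kmer_index(genes, k = 12L)
  part <- connected_components(idx, genes)
  expect_equal(part$components, brute_partition(genes, 12L))
  # partition property: disjoint and covering
  all_ids <- sort(unlist(part$components))
  expect_equal(all_ids, sort(vapply(genes, `[[`, character(1), "id")))
  # invariant to input order
  perm <- sample(seq_along(genes))
  idx2 <- build_kmer_index(genes[perm], k = 12L)
  part2 <- connected_components(idx2, genes[perm])
  expect_equal(part2$components, part$components)
})

test_that("strand and entropy options change sharing as designed", {
  s <- "ACGTTGCAAGGCTTACGATCCGTAAGGT"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  g1 <- gene("F", list(transcript("F.1", "F", s)))
  g2 <- gene("R", list(transcript("R.1", "R", rc)))
  idx_fwd <- build_kmer_index(list(g1, g2), k = 25L)
  expect_equal(connected_components(idx_fwd, list(g1, g2))$components,
               list("F", "R"))
  idx_rc <- build_kmer_index(list(g1, g2), k = 25L, both_strands = TRUE)
  expect_equal(connected_components(idx_rc, list(g1, g2))$components,
               list(c("F", "R")))

  low <- gene("L1", list(transcript("L1.1", "L1", strrep("A", 40L))))
  low2 <- gene("L2", list(transcript("L2.1", "L2", strrep("A", 40L))))
  idx_all <- build_kmer_index(list(low, low2), k = 25L)
  expect_equal(length(connected_components(idx_all,
                                           list(low, low2))$components), 1L)
  suppressWarnings({
    idx_ent <- build_kmer_index(list(low, low2), k = 25L, min_entropy = 1)
  })
  expect_equal(length(connected_components(idx_ent,
                                           list(low, low2))$components), 2L)
})
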