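test_that("uniform model discretizes to equal feasible-window masses", {
  h <- discretize(uniform_model(5L), 27L)
  expect_length(h$p, 23L)
  expect_equal(h$p, rep(1 / 23, 23))
  expect_equal(h$k, 1:23)
  expect_error(discretize(uniform_model(30L), 20L), "feasible")
  m2 <- uniform_model(c(`25` = 0.5, `35` = 0.5))
  expect_equal(sum(m2$length_pmf), 1)
  expect_equal(start_density(m2, 0.1), start_density(m2, 0.9))
})

test_that("discretize is a proper pmf for arbitrary models and lengths", {
  skew <- read_model(seq(0, 1, length.out = 101),
                     exp(-3 * seq(0, 1, length.out = 101)),
                     c(`20` = 0.3, `30` = 0.5, `45` = 0.2))
  for (L in c(45L, 60L, 137L, 1200L)) {
    h <- discretize(skew, L)
    expect_equal(sum(h$p), 1, tolerance = 1e-9)
    expect_true(all(h$k + h$m - 1L <= L))
  }
  # lengths below the shortest read are infeasible
  expect_error(discretize(skew, 19L), "feasible")
})

test_that("the empirical read model recovers flat and skewed start distributions", {
  tx <- list(transcript("tx", "G", strrep("A", 10000L)))
  set.seed(11)
  n <- 100000L
  al <- data.frame(read_id = as.character(seq_len(n)), transcript_id = "tx",
                   start = sample.int(10000L - 29L, n, replace = TRUE),
                   length = 30L)
  m <- estimate_read_model(al, tx)
  expect_equal(m$length_pmf, c(`30` = 1))
  # oracle: the 50-bin empirical histogram of the draws; KDE must agree
  # within 5% absolute everywhere (the last bin dips because reads cannot
  # start in the final m - 1 bases, and both estimates show it)
  centers <- seq(0.01, 0.99, length.out = 50)
  emp <- tabulate(findInterval(al$start / 10000, seq(0, 1, 0.02),
                               rightmost.closed = TRUE), 50) / n / 0.02
  expect_lt(max(abs(start_density(m, centers) - emp)), 0.05)
  # and it is flat away from the boundary
  expect_lt(max(abs(start_density(m, centers[3:48]) - 1)), 0.05)

  # 80% of starts in the first half
  k1 <- sample.int(4985L, round(0.8 * n), replace = TRUE)
  k2 <- 4986L + sample.int(4985L, n - length(k1), replace = TRUE)
  al$start <- sample(c(k1, k2))
  m2 <- estimate_read_model(al, tx)
  u <- seq(0, 1, length.out = 2001)
  f <- start_density(m2, u)
  mass_lower <- sum(diff(u[u <= 0.5]) * (head(f[u <= 0.5], -1) +
                                         tail(f[u <= 0.5], -1)) / 2)
  expect_equal(mass_lower, 0.8, tolerance = 0.03)
})

test_that("read model estimation enforces its preconditions", {
  tx <- list(transcript("tx", "G", strrep("A", 100L)))
  al <- data.frame(read_id = "r", transcript_id = "tx", start = 1L,
                   length = 10L)
  expect_error(estimate_read_model(al, tx), "at least 100")
  al2 <- al[rep(1, 200), ]
  al2$transcript_id <- "nope"
  expect_error(estimate_read_model(al2, tx), "unknown transcript")
  al3 <- al[rep(1, 200), ]
  al3$start <- 95L
  expect_error(estimate_read_model(al3, tx), "coordinates")
})

test_that("KDE recovers a known generating density (L1 error bound)", {
  true_u <- seq(0, 1, length.out = 201)
  true_f <- 2 - 2 * true_u + 0.5  # decreasing linear, renormalized inside
  gen <- read_model(true_u, true_f, 30L)
  L <- 8000L
  h <- discretize(gen, L)
  set.seed(99)
  cells <- sample.int(length(h$p), 100000L, replace = TRUE, prob = h$p)
  al <- data.frame(read_id = "r", transcript_id = "tx", start = h$k[cells],
                   length = 30L)
  est <- estimate_read_model(al, list(transcript("tx", "G", strrep("A", L))))
  grid <- seq(0, 1, length.out = 512)
  l1 <- mean(abs(start_density(est, grid) - start_density(gen, grid)))
  expect_lt(l1, 0.1)
})

test_that("nebulization fragments stay in range and skew the start density", {
  neb <- simulate_nebulization(10000L, 5000L, 500L, 800L,
                               read_length_pmf = 30L, seed = 5L)
  frag <- neb$meta$fragment_lengths
  expect_true(all(frag >= 500L & frag <= 800L))
  expect_equal(model_integral(neb), 1, tolerance = 1e-6)
  # same seed, same model
  neb2 <- simulate_nebulization(10000L, 5000L, 500L, 800L,
                                read_length_pmf = 30L, seed = 5L)
  expect_identical(neb$start_f, neb2$start_f)
  # flatness rejected on 20 bins of the recorded starts
  ct <- table(cut(neb$meta$starts, breaks = seq(0, 1, length.out = 21)))
  expect_lt(suppressWarnings(chisq.test(ct)$p.value), 0.01)
  expect_error(simulate_nebulization(10L, 600L, 700L, 800L, 30L), "frag_min")
})

test_that("read models round-trip through their text serialization", {
  neb <- simulate_nebulization(2000L, 3000L, 500L, 800L,
                               read_length_pmf = c(`25` = 0.4, `30` = 0.6),
                               seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_read_model(neb, path)
  back <- read_read_model(path)
  expect_equal(back$start_f, neb$start_f, tolerance = 1e-12)
  expect_equal(back$length_pmf, neb$length_pmf)
  expect_equal(back$source, "nebulization")
})

test_that("alignments load from TSV and SAM identically", {
  g <- sim_gene()
  model <- uniform_model(25L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sam <- withr::local_tempfile(fileext = ".sam")
  al <- make_alignments(g, c(0.6, 0.4), 300L, model, seed = 3L,
                        tsv = tsv, sam = sam)
  from_tsv <- read_alignments(tsv)
  expect_equal(from_tsv, al)
  skip_if_not_installed("Rsamtools")
  from_sam <- read_alignments(sam)
  o <- order(from_sam$read_id)
  expect_equal(from_sam$start[o], al$start)
  expect_equal(from_sam$length[o], al$length)
  expect_equal(from_sam$transcript_id[o], al$transcript_id)
})
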