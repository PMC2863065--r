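# Shared fixtures, built in code.

# The classic two-isoform cassette-exon toy: homopolymer exon runs make the
# three compatibility subsets visible by eye.
toy_gene <- function() {
  make_gene(fixture_spec("cassette_exon", exons = c(7L, 10L, 10L),
                         letters = c("A", "U", "C")))
}

# Hand-enumerated design matrix of the toy under uniform starts, read
# length 5: of T1's 23 windows, 14 contain a U ({T1}), 3 are all-A and 6
# all-C (both shared); of T2's 13 windows, 4 span the A|C junction ({T2}),
# 3 are all-A and 6 all-C.
toy_dm_expected <- function() {
  matrix(c(14 / 23, 0, 9 / 23,
           0, 4 / 13, 9 / 13),
         nrow = 3, ncol = 2,
         dimnames = list(c("G1.1", "G1.2", "G1.1+G1.2"), c("G1.1", "G1.2")))
}

# Realistic random-base cassette-exon gene for simulation tests.
sim_gene <- function(exons = c(120L, 60L, 130L), seed = 101L) {
  make_gene(fixture_spec("cassette_exon", exons = exons, seed = seed))
}

# Small random multi-isoform gene for property sweeps.
random_gene <- function(n_isoforms = 2L, seed = 1L) {
  ev <- if (n_isoforms == 3L) {
    fixture_spec("cassette_exon", exons = c(40L, 20L, 25L, 35L),
                 n_isoforms = 3L, seed = seed)
  } else {
    fixture_spec("cassette_exon", exons = c(40L, 25L, 35L), seed = seed)
  }
  make_gene(ev)
}

# Trapezoid integral of a read model's start density.
model_integral <- function(m) {
  sum(diff(m$start_u) * (head(m$start_f, -1) + tail(m$start_f, -1)) / 2)
}

# Independent brute-force design matrix: enumerate every feasible window,
# classify by base-R substring search, accumulate the discretized mass.
# Shares no code with build_design_matrix() beyond discretize().
brute_design_matrix <- function(gene, model) {
  seqs <- transcript_seqs(gene)
  L <- nchar(seqs)
  n <- length(seqs)
  rows <- list()
  for (j in seq_len(n)) {
    h <- discretize(model, L[j])
    for (i in seq_along(h$k)) {
      s <- substr(seqs[j], h$k[i], h$k[i] + h$m[i] - 1L)
      memb <- which(vapply(seqs, function(t) grepl(s, t, fixed = TRUE),
                           logical(1)))
      lab <- paste(names(seqs)[memb], collapse = "+")
      if (is.null(rows[[lab]])) rows[[lab]] <- numeric(n)
      rows[[lab]][j] <- rows[[lab]][j] + h$p[i]
    }
  }
  do.call(rbind, rows)
}
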