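.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic test gene
#'
#' Describes an alternative-splicing event from which [make_gene()] builds
#' deterministic fixture transcripts. Segment semantics by event type:
#' \describe{
#'   \item{cassette_exon}{Segments are exons; the full isoform includes all
#'     of them, the others each skip one internal exon (2 isoforms skip the
#'     second segment; `n_isoforms = 3` also skips the third).}
#'   \item{intron_retention}{Three segments exon/intron/exon; isoform 1
#'     retains the intron, isoform 2 splices it out.}
#'   \item{alt_donor, alt_acceptor}{Three segments; the middle segment is
#'     the extension included by isoform 1 at the upstream (donor) or
#'     downstream (acceptor) splice site and absent from isoform 2.}
#'   \item{paralog_pair}{Two single-isoform genes whose otherwise random
#'     transcripts embed one shared block (`shared_block` bases), so they
#'     are joined in the k-mer sharing graph.}
#' }
#'
#' @param event_type One of `"cassette_exon"`, `"intron_retention"`,
#'   `"alt_donor"`, `"alt_acceptor"`, `"paralog_pair"`.
#' @param exons Segment lengths in bases.
#' @param n_isoforms Number of isoforms (2, or 3 for cassette exons with 4
#'   segments).
#' @param seed Seed for random-base segments.
#' @param letters Optional one letter per segment: segments become
#'   homopolymer runs, giving human-readable toy genes (e.g. the classic
#'   A/U/C cassette example).
#' @param gene_id Gene identifier (paralog pairs get `_1`/`_2` suffixes).
#' @param shared_block Shared block length for `paralog_pair` (default 72).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(event_type = c("cassette_exon", "intron_retention",
                                        "alt_donor", "alt_acceptor",
                                        "paralog_pair"),
                         exons, n_isoforms = 2L, seed = 17L, letters = NULL,
                         gene_id = "G1", shared_block = 72L) {
  event_type <- match.arg(event_type)
  exons <- as.integer(exons)
  if (any(exons <= 0L)) stop("segment lengths must be positive", call. = FALSE)
  n_isoforms <- as.integer(n_isoforms)
  if (event_type == "cassette_exon") {
    need <- n_isoforms + 1L
    if (length(exons) != need || n_isoforms < 2L || n_isoforms > 3L) {
      stop("cassette_exon with ", n_isoforms, " isoforms needs ", need,
           " exon lengths", call. = FALSE)
    }
  } else if (event_type == "paralog_pair") {
    if (length(exons) != 2L || n_isoforms != 2L) {
      stop("paralog_pair needs two transcript lengths and n_isoforms = 2",
           call. = FALSE)
    }
    if (any(exons < shared_block)) {
      stop("paralog transcripts must be at least shared_block long",
           call. = FALSE)
    }
  } else {
    if (length(exons) != 3L || n_isoforms != 2L) {
      stop(event_type, " needs three segment lengths and n_isoforms = 2",
           call. = FALSE)
    }
  }
  if (!is.null(letters) && length(letters) != length(exons)) {
    stop("need one letter per segment", call. = FALSE)
  }
  structure(list(event_type = event_type, exons = exons,
                 n_isoforms = n_isoforms, seed = as.integer(seed),
                 letters = letters, gene_id = gene_id,
                 shared_block = as.integer(shared_block)),
            class = "fixture_spec")
}

#' Build a synthetic gene (or paralog pair) from a fixture specification
#'
#' Deterministic for a given spec: the same seed always produces identical
#' sequences. With `letters = c("A", "U", "C")` and exons `c(7, 10, 10)` the
#' cassette-exon event reproduces the classic two-isoform toy
#' (`AAAAAAAUUUUUUUUUUCCCCCCCCCC` / `AAAAAAACCCCCCCCCC`).
#'
#' @param spec A [fixture_spec()].
#' @param fasta Optional path; when given, the gene is also written as
#'   FASTA with `gene=` header tokens.
#' @return A [gene()], or a list of two genes for `paralog_pair`.
#' @export
make_gene <- function(spec, fasta = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  segs <- if (is.null(spec$letters)) {
    vapply(spec$exons, .random_bases, character(1))
  } else {
    strrep(spec$letters, spec$exons)
  }
  g <- switch(
    spec$event_type,
    cassette_exon = {
      iso <- list(paste(segs, collapse = ""))
      for (drop in seq_len(spec$n_isoforms - 1L) + 1L) {
        iso <- c(iso, paste(segs[-drop], collapse = ""))
      }
      .fixture_gene(spec$gene_id, iso)
    },
    intron_retention = .fixture_gene(spec$gene_id, list(
      paste(segs, collapse = ""), paste(segs[c(1L, 3L)], collapse = "")
    )),
    alt_donor = .fixture_gene(spec$gene_id, list(
      paste(segs, collapse = ""), paste(segs[c(1L, 3L)], collapse = "")
    )),
    alt_acceptor = .fixture_gene(spec$gene_id, list(
      paste(segs, collapse = ""), paste(segs[c(1L, 3L)], collapse = "")
    )),
    paralog_pair = {
      block <- .random_bases(spec$shared_block)
      mk <- function(i) {
        pad <- spec$exons[i] - spec$shared_block
        left <- pad %/% 2L
        s <- paste0(
          if (left > 0L) .random_bases(left) else "",
          block,
          if (pad - left > 0L) .random_bases(pad - left) else ""
        )
        gid <- paste0(spec$gene_id, "_", i)
        gene(gid, list(transcript(paste0(gid, ".1"), gid, s)))
      }
      list(mk(1L), mk(2L))
    }
  )
  if (!is.null(fasta)) {
    write_gene_fasta(if (inherits(g, "gene")) list(g) else g, fasta)
  }
  g
}

.fixture_gene <- function(gid, iso_seqs) {
  gene(gid, lapply(seq_along(iso_seqs), function(i) {
    transcript(paste0(gid, ".", i), gid, iso_seqs[[i]])
  }))
}

#' Write genes as a transcript FASTA
#'
#' Headers follow the `>transcript_id gene=gene_id` convention read back by
#' [load_transcripts()].
#'
#' @param genes List of [gene()] objects (or a single gene).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  if (inherits(genes, "gene")) genes <- list(genes)
  lines <- unlist(lapply(genes, function(g) {
    unlist(lapply(g$transcripts, function(tx) {
      c(paste0(">", tx$id, " gene=", g$id), tx$sequence)
    }), use.names = FALSE)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-read alignment records
#'
#' Like [simulate_reads()] but keeps each read as an alignment record
#' (read id, source transcript, 1-based start, length), suitable for
#' file-level round trips. Records always satisfy
#' `start + length - 1 <= L`. Optionally writes a TSV, a minimal SAM and a
#' truth table (true mixture and per-read isoform of origin).
#'
#' @param gene A [gene()] object.
#' @param phi True isoform proportions.
#' @param R Number of reads.
#' @param model A [read_model()].
#' @param seed Integer seed.
#' @param tsv,sam,truth Optional output paths.
#' @return Data frame of alignment records (invisibly when `tsv` is given).
#' @export
make_alignments <- function(gene, phi, R, model, seed = 17L,
                            tsv = NULL, sam = NULL, truth = NULL) {
  stopifnot(inherits(gene, "gene"), inherits(model, "read_model"), R >= 0)
  L <- transcript_lengths(gene)
  .check_simplex(phi, "phi")
  set.seed(as.integer(seed))
  w <- phi * L
  origin <- sample.int(length(L), size = R, replace = TRUE, prob = w / sum(w))
  start <- integer(R)
  len <- integer(R)
  for (j in seq_along(L)) {
    sel <- origin == j
    if (!any(sel)) next
    h <- discretize(model, L[j])
    cell <- sample.int(length(h$p), size = sum(sel), replace = TRUE,
                       prob = h$p)
    start[sel] <- h$k[cell]
    len[sel] <- h$m[cell]
  }
  df <- data.frame(
    read_id = sprintf("r%06d", seq_len(R)),
    transcript_id = names(L)[origin],
    start = start,
    length = len,
    stringsAsFactors = FALSE
  )
  if (!is.null(tsv)) {
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sam)) .write_sam(df, gene, sam)
  if (!is.null(truth)) {
    tr <- data.frame(transcript_id = names(L), phi_true = phi,
                     reads = tabulate(origin, nbins = length(L)))
    write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.null(tsv)) df else invisible(df)
}

# Minimal single-end SAM against the transcriptome.
.write_sam <- function(df, gene, path) {
  seqs <- transcript_seqs(gene)
  L <- transcript_lengths(gene)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(L), "\tLN:", L))
  body <- paste(df$read_id, 0L, df$transcript_id, df$start, 255L,
                paste0(df$length, "M"), "*", 0L, 0L,
                substring(seqs[df$transcript_id], df$start,
                          df$start + df$length - 1L),
                "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Count subset assignments of observed alignments
#'
#' Classifies each alignment's read sequence (taken from its recorded
#' transcript window) into the gene's compatibility subsets.
#'
#' @param alignments Data frame with `transcript_id`, `start`, `length`
#'   (e.g. from [read_alignments()]); records for transcripts outside the
#'   gene are ignored.
#' @param gene A [gene()] object.
#' @return A [subset_counts()] over the gene's realized subsets.
#' @export
count_subsets <- function(alignments, gene) {
  stopifnot(inherits(gene, "gene"), is.data.frame(alignments))
  seqs <- transcript_seqs(gene)
  keep <- alignments$transcript_id %in% names(seqs)
  al <- alignments[keep, , drop = FALSE]
  ms <- sort(unique(as.integer(al$length)))
  universe <- if (length(ms)) enumerate_subsets(gene, ms) else list()
  counts <- stats::setNames(rep.int(0, length(universe)), names(universe))
  if (nrow(al)) {
    L <- nchar(seqs)[al$transcript_id]
    if (any(al$start < 1L) || any(al$start + al$length - 1L > L)) {
      stop("alignment coordinates exceed transcript bounds", call. = FALSE)
    }
    reads <- substring(seqs[al$transcript_id], al$start,
                       al$start + al$length - 1L)
    labs <- vapply(reads, function(s) {
      hits <- which(stringi::stri_detect_fixed(seqs, s))
      paste(names(seqs)[hits], collapse = "+")
    }, character(1), USE.NAMES = FALSE)
    tab <- table(labs)
    counts[names(tab)] <- as.numeric(tab)
  }
  subset_counts(counts, total = nrow(al))
}
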