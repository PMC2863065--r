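#' @importFrom stats approxfun density quantile rmultinom runif pchisq pnorm
#' @importFrom utils head tail read.table write.table
NULL

# Canonical nucleotide form: upper case, U -> T, strict ACGT alphabet.
.canonical_seq <- function(x, id = "<sequence>") {
  x <- chartr("u", "t", chartr("U", "T", toupper(x)))
  x <- toupper(x)
  if (any(!nzchar(x))) {
    stop("empty sequence for ", id, call. = FALSE)
  }
  bad <- stringi::stri_detect_regex(x, "[^ACGT]")
  if (any(bad)) {
    stop("sequence for ", paste(id[bad], collapse = ", "),
         " contains characters outside {A,C,G,T,U}", call. = FALSE)
  }
  x
}

#' Construct a transcript
#'
#' A transcript is one splice isoform of a gene: an identifier, the gene it
#' belongs to, and its nucleotide sequence. Sequences are canonicalized to
#' DNA alphabet (U is treated as T) so RNA-style input and DNA FASTA
#' interoperate; any other character is an error.
#'
#' @param id Transcript identifier (non-empty string).
#' @param gene_id Identifier of the parent gene.
#' @param sequence Nucleotide sequence over A, C, G, T/U.
#' @return An object of class `transcript` with fields `id`, `gene_id`,
#'   `sequence` (canonical form) and `length` in bases.
#' @export
#' @examples
#' tx <- transcript("T1", "G1", "AAAAAAAUUUUUUUUUUCCCCCCCCCC")
#' tx$length
transcript <- function(id, gene_id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- .canonical_seq(sequence, id)
  structure(
    list(id = id, gene_id = gene_id, sequence = sequence,
         length = nchar(sequence)),
    class = "transcript"
  )
}

#' Construct a gene from its known isoforms
#'
#' @param id Gene identifier.
#' @param transcripts List of [transcript()] objects, all sharing this gene's
#'   id. Order is preserved; isoform indices used throughout the package
#'   refer to this order.
#' @return An object of class `gene`.
#' @export
gene <- function(id, transcripts) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.list(transcripts), length(transcripts) >= 1L)
  ok <- vapply(transcripts, inherits, logical(1), "transcript")
  if (!all(ok)) stop("all elements of 'transcripts' must be transcript objects")
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id within gene ", id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  gids <- vapply(transcripts, `[[`, character(1), "gene_id")
  if (!all(gids == id)) {
    stop("transcripts ", paste(ids[gids != id], collapse = ", "),
         " do not belong to gene ", id, call. = FALSE)
  }
  names(transcripts) <- ids
  structure(list(id = id, transcripts = transcripts), class = "gene")
}

#' @export
print.gene <- function(x, ...) {
  L <- transcript_lengths(x)
  cat("gene ", x$id, ": ", length(L), " isoform(s)\n", sep = "")
  for (i in seq_along(L)) {
    cat("  ", names(L)[i], " (", L[i], " nt)\n", sep = "")
  }
  invisible(x)
}

#' Transcript sequences / lengths of a gene
#'
#' @param gene A [gene()] object.
#' @return Named character vector of sequences, or named integer vector of
#'   lengths, ordered as the gene's isoforms.
#' @export
transcript_seqs <- function(gene) {
  vapply(gene$transcripts, `[[`, character(1), "sequence")
}

#' @rdname transcript_seqs
#' @export
transcript_lengths <- function(gene) {
  vapply(gene$transcripts, `[[`, integer(1), "length")
}

# Label for a subset of isoform indices, by transcript id ("T1+T2" style).
.subset_label <- function(members, gene) {
  ids <- names(gene$transcripts)
  vapply(members, function(ix) paste(ids[ix], collapse = "+"), character(1))
}

#' Load transcripts grouped into genes
#'
#' Two input routes are supported. (1) A transcript FASTA whose headers carry
#' the parent gene as a `gene=<id>` token, e.g. `>AT1G75410.1 gene=AT1G75410`.
#' (2) A genome FASTA plus a GFF3 annotation: mRNA/transcript features are
#' grouped under their `Parent` gene and spliced transcript sequences are
#' assembled from their exons (reverse-complemented on the minus strand).
#'
#' Exact duplicate records (same id, same sequence) are dropped; the same id
#' with a different sequence is an error. Genes and transcripts are returned
#' in lexicographic id order so downstream matrices are reproducible.
#'
#' @param fasta Path to the transcript FASTA (route 1) or genome FASTA
#'   (route 2).
#' @param annotation Optional path to a GFF3 annotation; supplying it selects
#'   route 2.
#' @return Named list of [gene()] objects.
#' @export
load_transcripts <- function(fasta, annotation = NULL) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta, call. = FALSE)
  if (is.null(annotation)) {
    .load_transcript_fasta(fasta)
  } else {
    .load_gff3_transcripts(fasta, annotation)
  }
}

.load_transcript_fasta <- function(fasta) {
  seqs <- Biostrings::readBStringSet(fasta)
  headers <- names(seqs)
  tid <- sub("\\s.*$", "", headers)
  gid <- rep(NA_character_, length(headers))
  m <- regmatches(headers, regexpr("gene=\\S+", headers))
  has <- grepl("gene=\\S+", headers)
  gid[has] <- sub("^gene=", "", m)
  if (any(!has)) {
    stop("no gene=<id> token in FASTA header(s): ",
         paste(tid[!has], collapse = ", "), call. = FALSE)
  }
  .assemble_genes(tid, gid, as.character(seqs))
}

.assemble_genes <- function(tid, gid, seq) {
  seq <- .canonical_seq(seq, tid)
  # drop exact duplicate records; same id + different sequence is an error
  dup <- duplicated(paste0(tid, "\r", seq))
  tid <- tid[!dup]; gid <- gid[!dup]; seq <- seq[!dup]
  if (anyDuplicated(tid)) {
    stop("duplicate transcript id with differing sequence: ",
         paste(unique(tid[duplicated(tid)]), collapse = ", "), call. = FALSE)
  }
  genes <- lapply(sort(unique(gid)), function(g) {
    o <- which(gid == g)[order(tid[gid == g])]
    gene(g, lapply(o, function(i) transcript(tid[i], g, seq[i])))
  })
  names(genes) <- sort(unique(gid))
  genes
}

.load_gff3_transcripts <- function(fasta, annotation) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("the GFF3 route requires the rtracklayer package", call. = FALSE)
  }
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(annotation, format = "gff3")
  type <- as.character(gff$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_tx) || !any(is_exon)) {
    stop("GFF3 must contain mRNA/transcript and exon features", call. = FALSE)
  }
  tx <- gff[is_tx]
  tx_id <- as.character(tx$ID)
  tx_parent <- vapply(tx$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  if (any(is.na(tx_parent))) {
    stop("mRNA feature(s) without Parent gene: ",
         paste(tx_id[is.na(tx_parent)], collapse = ", "), call. = FALSE)
  }
  exons <- gff[is_exon]
  ex_parent <- vapply(exons$Parent, function(p) as.character(p[[1]]), character(1))
  seqs <- character(length(tx_id))
  for (i in seq_along(tx_id)) {
    ex <- exons[ex_parent == tx_id[i]]
    if (length(ex) == 0L) stop("transcript ", tx_id[i], " has no exons", call. = FALSE)
    ex <- ex[order(GenomicRanges::start(ex))]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chrom %in% names(genome)) {
      stop("sequence ", chrom, " absent from genome FASTA", call. = FALSE)
    }
    pieces <- Biostrings::DNAStringSet(
      genome[[chrom]],
      start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex)
    )
    spliced <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (as.character(GenomicRanges::strand(ex))[1] == "-") {
      spliced <- Biostrings::reverseComplement(spliced)
    }
    seqs[i] <- as.character(spliced)
  }
  .assemble_genes(tx_id, tx_parent, seqs)
}

#' Classify a read sequence into a compatibility subset
#'
#' A read is compatible with every isoform whose sequence contains the read
#' as an exact contiguous substring (alignment, and therefore mismatch
#' tolerance, is upstream of this model). The set of compatible isoform
#' indices is the read's compatibility subset; reads matching no isoform
#' (e.g. reads containing bases absent from every isoform) fall outside the
#' model and return `NULL`.
#'
#' @param read_seq Read nucleotide sequence (U allowed, treated as T).
#' @param gene A [gene()] object.
#' @return Sorted integer vector of compatible isoform indices, or `NULL`.
#' @export
#' @examples
#' g <- make_gene(fixture_spec("cassette_exon", exons = c(7, 10, 10),
#'                             letters = c("A", "U", "C")))
#' classify_read("UUU", g)       # cassette-exon read: isoform 1 only
#' classify_read("CCCCC", g)     # shared exon: both isoforms
#' classify_read("GGG", g)       # incompatible: NULL
classify_read <- function(read_seq, gene) {
  stopifnot(is.character(read_seq), length(read_seq) == 1L)
  if (!nzchar(read_seq)) stop("empty read sequence", call. = FALSE)
  s <- .canonical_seq(read_seq, "read")
  hits <- which(stringi::stri_detect_fixed(transcript_seqs(gene), s))
  if (length(hits) == 0L) return(NULL)
  sort(hits)
}

# Enumerate and classify every feasible (start, length) window of every
# isoform. Returns the gene's realized subset universe (canonical order:
# cardinality, then indices) and, per transcript, the window coordinates
# with the index of the subset each window classifies into. This single
# enumeration backs subset enumeration, design-matrix construction and the
# read simulator, so all three agree cell-for-cell.
.classify_cells <- function(gene, m_values) {
  seqs <- transcript_seqs(gene)
  n <- length(seqs)
  L <- nchar(seqs)
  m_values <- sort(unique(as.integer(m_values)))
  if (length(m_values) == 0L || any(m_values < 1L)) {
    stop("read lengths must be positive integers", call. = FALSE)
  }
  cells <- vector("list", n)
  keys_all <- character(0)
  for (j in seq_len(n)) {
    ks <- integer(0); ms <- integer(0); key <- character(0)
    for (m in m_values[m_values <= L[j]]) {
      k <- seq_len(L[j] - m + 1L)
      subs <- substring(seqs[j], k, k + m - 1L)
      memb <- matrix(FALSE, nrow = length(k), ncol = n)
      memb[, j] <- TRUE
      for (t in seq_len(n)[-j]) {
        memb[, t] <- stringi::stri_detect_fixed(seqs[t], subs)
      }
      ks <- c(ks, k)
      ms <- c(ms, rep.int(m, length(k)))
      key <- c(key, apply(memb, 1L, function(r) paste(which(r), collapse = "+")))
    }
    cells[[j]] <- list(k = ks, m = ms, key = key)
    keys_all <- c(keys_all, unique(key))
  }
  keys <- unique(keys_all)
  members <- lapply(strsplit(keys, "+", fixed = TRUE), as.integer)
  ord <- order(lengths(members),
               vapply(members, function(ix) paste(sprintf("%09d", ix), collapse = ","),
                      character(1)))
  members <- members[ord]
  keys <- keys[ord]
  for (j in seq_len(n)) {
    cells[[j]]$subset <- match(cells[[j]]$key, keys)
    cells[[j]]$key <- NULL
  }
  subsets <- members
  names(subsets) <- .subset_label(members, gene)
  list(subsets = subsets, cells = cells)
}

#' Enumerate the realized compatibility subsets of a gene
#'
#' Lists every non-empty compatibility subset realized by at least one
#' (start, length) read on at least one isoform, for the given read lengths.
#' At most `2^n - 1` subsets exist for `n` isoforms; far fewer are usually
#' realized. Order is canonical (increasing cardinality, then indices) so
#' design matrices and count tables are byte-for-byte reproducible.
#'
#' @param gene A [gene()] object.
#' @param read_lengths Integer vector of read lengths to consider.
#' @return Named list of sorted integer vectors (names are `+`-joined
#'   transcript ids).
#' @export
#' @examples
#' g <- make_gene(fixture_spec("cassette_exon", exons = c(7, 10, 10),
#'                             letters = c("A", "U", "C")))
#' names(enumerate_subsets(g, 5L))  # three subsets
enumerate_subsets <- function(gene, read_lengths) {
  .classify_cells(gene, read_lengths)$subsets
}
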