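# data.table is used via :: throughout; declare awareness so [.data.table
# keeps its semantics when called from this namespace (and from tests).
.datatable.aware <- TRUE

# Unique k-mers of a sequence (empty if shorter than k).
.kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, 1:(L - k + 1L), k:L))
}

.revcomp <- function(s) chartr("ACGT", "TGCA", stringi::stri_reverse(s))

# Shannon entropy (bits) of the base composition of each k-mer.
.base_entropy <- function(kmers) {
  vapply(kmers, function(s) {
    p <- table(strsplit(s, "", fixed = TRUE)[[1]])
    p <- p / sum(p)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a k-mer index over a gene set
#'
#' Hash table mapping every nucleotide k-mer occurring in any transcript
#' isoform to the set of genes containing it. This index drives both the
#' multiread adjustment of the design matrix
#' ([apply_multiread_mask()]) and the gene-sharing graph
#' ([connected_components()]).
#'
#' @param genes List of [gene()] objects.
#' @param k K-mer size in bases (default 25; minimum 8).
#' @param both_strands If `TRUE`, k-mers are canonicalized with their
#'   reverse complement so that opposite-strand matches are shared keys.
#'   Default `FALSE`: transcript space has known orientation.
#' @param min_entropy Optional base-composition entropy threshold (bits);
#'   k-mers below it are excluded. Low-complexity k-mers are kept by
#'   default — dropping them noticeably shrinks the large components they
#'   create, and the filter exists to study exactly that effect.
#' @return Object of class `kmer_index` with the k-mer table and the gene
#'   sequences (needed for exact containment checks during masking).
#' @export
build_kmer_index <- function(genes, k = 25L, both_strands = FALSE,
                             min_entropy = NULL) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be at least 8", call. = FALSE)
  stopifnot(is.list(genes), all(vapply(genes, inherits, logical(1), "gene")))
  gene_ids <- vapply(genes, `[[`, character(1), "id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  names(genes) <- gene_ids
  gene_seqs <- lapply(genes, transcript_seqs)
  pieces <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    km <- unique(unlist(lapply(gene_seqs[[i]], .kmers, k = k),
                        use.names = FALSE))
    if (length(km) == 0L) {
      warning("gene ", gene_ids[i], ": all transcripts shorter than k = ", k,
              "; gene contributes no k-mers", call. = FALSE)
      next
    }
    if (both_strands) km <- unique(pmin(km, .revcomp(km)))
    if (!is.null(min_entropy)) km <- km[.base_entropy(km) >= min_entropy]
    if (length(km)) {
      pieces[[i]] <- data.table::data.table(kmer = km, gene_id = gene_ids[i])
    }
  }
  tab <- data.table::rbindlist(pieces)
  if (nrow(tab)) data.table::setkeyv(tab, "kmer")
  structure(list(k = k, table = tab, gene_seqs = gene_seqs,
                 both_strands = both_strands),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k = ", x$k, ", ", nrow(x$table), " (kmer, gene) pairs",
      " over ", length(x$gene_seqs), " gene(s)\n", sep = "")
  invisible(x)
}

# Gene ids whose indexed k-mers intersect the k-mers of `seq`.
.lookup_genes <- function(index, seq) {
  km <- .kmers(seq, index$k)
  if (length(km) == 0L || nrow(index$table) == 0L) return(character(0))
  if (index$both_strands) km <- unique(pmin(km, .revcomp(km)))
  hit <- index$table[data.table::data.table(kmer = km), on = "kmer",
                     nomatch = NULL]
  unique(hit$gene_id)
}

#' Partition genes into k-mer-sharing connected components
#'
#' Two genes are joined by an (undirected) edge when their transcripts share
#' a common k-nucleotide substring; the graph's connected components are
#' maximal sets of mutually reachable genes and define the groups whose
#' isoforms must be estimated jointly (or whose shared reads must be
#' discarded) to handle multireads coherently.
#'
#' @param index A [build_kmer_index()].
#' @param genes The same gene list the index was built over (or a character
#'   vector of gene ids).
#' @return Object of class `component_partition`: list of components (each a
#'   sorted character vector of gene ids, ordered by decreasing size) plus
#'   per-gene membership.
#' @export
connected_components <- function(index, genes) {
  stopifnot(inherits(index, "kmer_index"))
  ids <- if (is.character(genes)) genes else
    vapply(genes, `[[`, character(1), "id")
  tab <- index$table
  edges <- if (nrow(tab)) {
    tab[, if (.N > 1L) list(a = gene_id[1L], b = gene_id[-1L]), by = "kmer"]
  } else NULL
  g <- igraph::graph_from_data_frame(
    if (!is.null(edges) && nrow(edges)) unique(edges[, c("a", "b")])
    else data.frame(a = character(0), b = character(0)),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(x) sort(unname(x)))
  members <- members[order(-lengths(members),
                           vapply(members, `[`, character(1), 1L))]
  names(members) <- NULL
  membership <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(members)) membership[members[[i]]] <- i
  structure(list(components = members, membership = membership,
                 k = index$k),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  r <- component_report(x)
  cat("k-mer sharing partition (k = ", x$k, "): ", r$n_genes, " gene(s) in ",
      r$n_components, " component(s); mean size ",
      format(r$mean_size, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Summarize a component partition
#'
#' @param partition A [connected_components()] result.
#' @param n_largest How many of the largest components to list.
#' @return List with `n_components`, `n_genes`, `mean_size`,
#'   `size_histogram` (data frame size / n_components) and `largest`
#'   (data frame component / size / members).
#' @export
component_report <- function(partition, n_largest = 10L) {
  stopifnot(inherits(partition, "component_partition"))
  sizes <- lengths(partition$components)
  hist <- as.data.frame(table(size = sizes), stringsAsFactors = FALSE)
  names(hist) <- c("size", "n_components")
  hist$size <- as.integer(hist$size)
  top <- head(seq_along(sizes), n_largest)
  list(
    n_components = length(sizes),
    n_genes = sum(sizes),
    mean_size = sum(sizes) / length(sizes),
    size_histogram = hist,
    largest = data.frame(
      component = top,
      size = sizes[top],
      members = vapply(partition$components[top], paste,
                       character(1), collapse = ","),
      row.names = NULL
    )
  )
}

#' Write a component partition as TSV
#'
#' @param partition A [connected_components()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_components <- function(partition, path) {
  df <- data.frame(
    component_id = rep(seq_along(partition$components),
                       lengths(partition$components)),
    size = rep(lengths(partition$components),
               lengths(partition$components)),
    gene_id = unlist(partition$components, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
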