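#' @importFrom tools file_ext
NULL

.new_design_matrix <- function(entries, subsets, gene, lengths,
                               column_mass = NULL, masked = FALSE,
                               reduced = "none") {
  if (is.null(column_mass)) column_mass <- colSums(entries)
  structure(
    list(entries = entries, subsets = subsets,
         transcript_ids = colnames(entries), gene_id = gene$id,
         lengths = lengths, column_mass = column_mass,
         skipped_mass = 1 - column_mass, masked = masked, reduced = reduced),
    class = "design_matrix"
  )
}

#' Build the design matrix of subset probabilities
#'
#' Entry (i, j) is the probability that a read drawn from transcript j falls
#' into compatibility subset i: every feasible window (k, m) of transcript j
#' is classified against all of the gene's isoforms and the window's mass
#' under the discretized read model is accumulated onto the row of the
#' resulting subset. Without multiread masking each column therefore sums
#' to 1 over the realized subsets, and an entry is identically zero whenever
#' the subset does not contain the column's isoform.
#'
#' @param gene A [gene()] object.
#' @param model A [read_model()].
#' @return Object of class `design_matrix`: `entries` (subsets x isoforms),
#'   the subset index sets, per-column retained mass and the isoform
#'   lengths needed for the length-deweighting step of estimation.
#' @export
#' @examples
#' g <- make_gene(fixture_spec("cassette_exon", exons = c(7, 10, 10),
#'                             letters = c("A", "U", "C")))
#' build_design_matrix(g, uniform_model(5L))
build_design_matrix <- function(gene, model) {
  .design_matrix_impl(gene, model, kmer_index = NULL)
}

#' Build a multiread-masked design matrix
#'
#' Identical to [build_design_matrix()] except that every candidate window
#' whose sequence also occurs in another gene of the target set (a potential
#' multiread) contributes no mass. Observed reads mapping to more than one
#' gene can then be discarded consistently: the per-column retained mass
#' recorded here is exactly the discarded probability, and the estimator
#' renormalizes the fitted coefficients accordingly. Candidate genes are
#' screened through a k-mer index before the exact substring test.
#'
#' @inheritParams build_design_matrix
#' @param kmer_index A [build_kmer_index()] built over all genes in the
#'   target set (including this one).
#' @return A masked `design_matrix`; column sums may be below 1.
#' @export
apply_multiread_mask <- function(gene, model, kmer_index) {
  stopifnot(inherits(kmer_index, "kmer_index"))
  .design_matrix_impl(gene, model, kmer_index = kmer_index)
}

.design_matrix_impl <- function(gene, model, kmer_index = NULL) {
  stopifnot(inherits(gene, "gene"), inherits(model, "read_model"))
  L <- transcript_lengths(gene)
  n <- length(L)
  ms <- as.integer(names(model$length_pmf))[model$length_pmf > 0]
  short <- L < min(ms)
  if (any(short)) {
    stop("isoform(s) shorter than every modeled read length: ",
         paste(names(L)[short], collapse = ", "), call. = FALSE)
  }
  cc <- .classify_cells(gene, ms)
  n_sub <- length(cc$subsets)
  entries <- matrix(0, nrow = n_sub, ncol = n,
                    dimnames = list(names(cc$subsets), names(L)))
  seqs <- transcript_seqs(gene)
  for (j in seq_len(n)) {
    h <- discretize(model, L[j])
    cells <- cc$cells[[j]]
    # discretize() and .classify_cells() enumerate windows identically:
    # lengths in increasing order, starts 1..L-m+1 within each length
    stopifnot(length(h$k) == length(cells$k))
    p <- h$p
    if (!is.null(kmer_index)) {
      multi <- .flag_multireads(seqs[j], cells$k, cells$m, gene$id, kmer_index)
      p[multi] <- 0
    }
    acc <- rowsum(p, group = cells$subset)
    entries[as.integer(rownames(acc)), j] <- acc[, 1L]
  }
  keep <- rowSums(entries) > 0
  entries <- entries[keep, , drop = FALSE]
  subsets <- cc$subsets[keep]
  cm <- colSums(entries)
  if (!is.null(kmer_index) && any(cm <= 0)) {
    stop("gene ", gene$id, " is inestimable after discarding multireads: ",
         "isoform(s) with zero retained mass: ",
         paste(names(L)[cm <= 0], collapse = ", "), call. = FALSE)
  }
  .new_design_matrix(entries, subsets, gene, L,
                     column_mass = cm, masked = !is.null(kmer_index))
}

# TRUE for each window whose substring also occurs in another gene.
# Candidate genes come from the k-mer index (genes sharing any k-mer with
# this transcript); windows shorter than the index k fall back to scanning
# every other gene.
.flag_multireads <- function(seq_j, k, m, gene_id, kmer_index) {
  subs <- substring(seq_j, k, k + m - 1L)
  other_ids <- setdiff(names(kmer_index$gene_seqs), gene_id)
  if (length(other_ids) == 0L) return(rep.int(FALSE, length(subs)))
  if (min(m) >= kmer_index$k) {
    hits <- .lookup_genes(kmer_index, seq_j)
    other_ids <- intersect(other_ids, hits)
    if (length(other_ids) == 0L) return(rep.int(FALSE, length(subs)))
  }
  multi <- rep.int(FALSE, length(subs))
  for (g in other_ids) {
    for (s in kmer_index$gene_seqs[[g]]) {
      todo <- !multi
      if (!any(todo)) return(multi)
      multi[todo] <- stringi::stri_detect_fixed(s, subs[todo])
    }
  }
  multi
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design matrix for gene ", x$gene_id, ": ",
      nrow(x$entries), " subset(s) x ", ncol(x$entries), " isoform(s)",
      if (x$masked) " [multiread-masked]", "\n", sep = "")
  print(round(x$entries, 4))
  if (x$masked) {
    cat("retained column mass:",
        paste(format(x$column_mass, digits = 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Numerical column rank of a design matrix
#'
#' @param dm A `design_matrix`.
#' @param tol Singular values above `tol` count toward the rank.
#' @return Integer rank.
#' @export
design_matrix_rank <- function(dm, tol = 1e-10) {
  stopifnot(inherits(dm, "design_matrix"))
  d <- svd(dm$entries, nu = 0, nv = 0)$d
  sum(d > tol)
}

#' Reduce a design matrix to full column rank
#'
#' The number of possible subsets grows as `2^n - 1`, but uninteresting
#' categories can be combined or ignored: `singletons_only` keeps exactly
#' the n single-isoform rows (which always yield a full-rank matrix when the
#' isoforms are distinguishable), and `merge_small` pools rows carrying
#' total mass below `threshold` into one composite row. The result is
#' verified to have full column rank; indistinguishable isoforms (e.g.
#' duplicate sequences) are reported as an error.
#'
#' @param dm A `design_matrix`.
#' @param strategy One of `"all_subsets"`, `"singletons_only"`,
#'   `"merge_small"`.
#' @param threshold Row-mass threshold for `merge_small` (default 1e-4).
#' @return A full-rank `design_matrix`.
#' @export
reduce_to_full_rank <- function(dm,
                                strategy = c("all_subsets", "singletons_only",
                                             "merge_small"),
                                threshold = 1e-4) {
  stopifnot(inherits(dm, "design_matrix"))
  strategy <- match.arg(strategy)
  entries <- dm$entries
  subsets <- dm$subsets
  n <- ncol(entries)
  if (strategy == "singletons_only") {
    singleton_of <- rep(NA_integer_, nrow(entries))
    single <- lengths(subsets) == 1L
    singleton_of[single] <- vapply(subsets[single], `[`, integer(1), 1L)
    missing <- setdiff(seq_len(n), singleton_of[single])
    if (length(missing) > 0L) {
      .stop_indistinguishable(entries, dm$transcript_ids,
        extra = paste0("isoform(s) with no uniquely mapping read: ",
                       paste(dm$transcript_ids[missing], collapse = ", ")))
    }
    ord <- order(singleton_of[single])
    keep <- which(single)[ord]
    entries <- entries[keep, , drop = FALSE]
    subsets <- subsets[keep]
  } else if (strategy == "merge_small") {
    mass <- rowSums(entries)
    small <- mass < threshold
    if (sum(small) >= 2L) {
      pooled <- colSums(entries[small, , drop = FALSE])
      entries <- rbind(entries[!small, , drop = FALSE], pooled = pooled)
      subsets <- c(subsets[!small],
                   list(pooled = sort(unique(unlist(subsets[small])))))
    }
  }
  d <- svd(entries, nu = 0, nv = 0)$d
  if (sum(d > 1e-10) < n) {
    .stop_indistinguishable(entries, dm$transcript_ids)
  }
  .new_design_matrix(entries, subsets, list(id = dm$gene_id), dm$lengths,
                     column_mass = dm$column_mass, masked = dm$masked,
                     reduced = strategy)
}

.stop_indistinguishable <- function(entries, ids, extra = NULL) {
  groups <- character(0)
  seen <- rep(FALSE, ncol(entries))
  for (j in seq_len(ncol(entries))) {
    if (seen[j]) next
    same <- which(vapply(seq_len(ncol(entries)), function(l) {
      max(abs(entries[, l] - entries[, j])) < 1e-10
    }, logical(1)))
    if (length(same) > 1L) {
      groups <- c(groups, paste(ids[same], collapse = " = "))
      seen[same] <- TRUE
    }
  }
  msg <- "design matrix is rank deficient"
  if (length(groups)) {
    msg <- paste0(msg, "; indistinguishable isoform group(s): ",
                  paste(groups, collapse = "; "))
  }
  if (!is.null(extra)) msg <- paste0(msg, "; ", extra)
  stop(msg, call. = FALSE)
}

#' Write a design matrix as TSV
#'
#' Rows are labeled by `+`-joined member transcript ids.
#'
#' @param dm A `design_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  df <- data.frame(subset = rownames(dm$entries), dm$entries,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
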