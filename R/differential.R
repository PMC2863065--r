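.singleton_labels <- function(counts) {
  names(counts)[!grepl("+", names(counts), fixed = TRUE)]
}

#' Is a gene testable for differential splicing?
#'
#' A gene is tested only if, pooling both conditions, at least one read maps
#' to the unique region of each of at least two isoforms — i.e. at least two
#' singleton subsets carry one or more reads. Without such reads the subset
#' counts carry no information about a change in isoform composition.
#'
#' @param counts_a,counts_b [subset_counts()] for the two conditions,
#'   sharing a subset universe.
#' @return `TRUE` or `FALSE`.
#' @export
is_testable <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "subset_counts"),
            inherits(counts_b, "subset_counts"))
  labs <- union(names(counts_a$counts), names(counts_b$counts))
  single <- labs[!grepl("+", labs, fixed = TRUE)]
  if (length(single) < 2L) return(FALSE)
  pooled <- vapply(single, function(s) {
    sum(counts_a$counts[s], counts_b$counts[s], na.rm = TRUE)
  }, numeric(1))
  sum(pooled >= 1) >= 2L
}

#' Chi-square test for differential splicing
#'
#' Pearson chi-square test of independence on the subsets x conditions
#' contingency table of read counts. Subsets empty in both conditions are
#' dropped; degrees of freedom are (kept subsets - 1). Untestable genes
#' (see [is_testable()]) are returned as a skip, not an error, with `p = NA`.
#' No continuity correction is applied; a warning is emitted when any
#' expected cell falls below 5.
#'
#' @inheritParams is_testable
#' @param gene_id Optional gene identifier carried into the result.
#' @param phi_a,phi_b Optional estimated isoform proportions per condition;
#'   when supplied, the main-isoform difference is reported (see
#'   [main_isoform_delta()]).
#' @return Object of class `splice_test`: `gene_id`, `testable`, `chi2`,
#'   `df`, `p`, and when proportions were given, `main_isoform_phi` and
#'   `delta_main`.
#' @export
splice_chisq_test <- function(counts_a, counts_b, gene_id = NA_character_,
                              phi_a = NULL, phi_b = NULL) {
  if (!is_testable(counts_a, counts_b)) {
    return(structure(list(gene_id = gene_id, testable = FALSE,
                          chi2 = NA_real_, df = NA_integer_, p = NA_real_),
                     class = "splice_test"))
  }
  labs <- union(names(counts_a$counts), names(counts_b$counts))
  a <- stats::setNames(rep.int(0, length(labs)), labs)
  b <- a
  a[names(counts_a$counts)] <- counts_a$counts
  b[names(counts_b$counts)] <- counts_b$counts
  tab <- cbind(a = a, b = b)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected cell count below 5 for gene ", gene_id,
            "; chi-square approximation may be inaccurate", call. = FALSE)
  }
  res <- list(gene_id = gene_id, testable = TRUE,
              chi2 = unname(ht$statistic), df = unname(ht$parameter),
              p = unname(ht$p.value))
  if (!is.null(phi_a) && !is.null(phi_b)) {
    res$main_isoform_phi <- rbind(a = phi_a, b = phi_b)
    res$delta_main <- main_isoform_delta(phi_a, phi_b)
  }
  structure(res, class = "splice_test")
}

#' @export
print.splice_test <- function(x, ...) {
  if (!x$testable) {
    cat("gene ", x$gene_id, ": not testable (needs reads in the unique",
        " regions of >= 2 isoforms)\n", sep = "")
    return(invisible(x))
  }
  cat("gene ", x$gene_id, ": chi2 = ", format(x$chi2, digits = 5),
      ", df = ", x$df, ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  if (!is.null(x$delta_main)) {
    cat("  main-isoform proportion difference: ",
        format(x$delta_main, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment with an FDR decision
#'
#' Standard step-up false discovery rate control: q-values are the BH
#' adjusted p-values and hypotheses with q at or below `fdr` are rejected.
#'
#' @param pvalues P-values in \[0, 1\] (NA allowed; never rejected).
#' @param fdr Target false discovery rate (default 0.01).
#' @return List with `q` (adjusted p-values) and `reject` (logical).
#' @export
bh_adjust <- function(pvalues, fdr = 0.01) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Two-proportion z-test for differential gene expression
#'
#' Compares, between two samples, the proportion of reads assigned to a gene
#' relative to each sample's total read count: z = (p1 - p2) /
#' sqrt(p (1 - p) (1/n1 + 1/n2)) with pooled p = (r1 + r2) / (n1 + n2),
#' referred to the standard normal (two-sided). With the very large totals
#' of sequencing experiments the normal reference is accurate. A pooled
#' proportion of exactly 0 or 1 is degenerate: z = 0, p = 1, flagged.
#'
#' @param r1,r2 Reads for the gene in each sample.
#' @param n1,n2 Total reads in each sample.
#' @param gene_id Optional identifier carried into the result.
#' @return Object of class `expr_test`: `z`, `p`, `p1`, `p2`, `n1`, `n2`,
#'   `degenerate`.
#' @export
#' @examples
#' diffexpr_ztest(100, 10000, 200, 10000)$z  # about -5.82
diffexpr_ztest <- function(r1, n1, r2, n2, gene_id = NA_character_) {
  stopifnot(n1 > 0, n2 > 0, r1 >= 0, r2 >= 0, r1 <= n1, r2 <= n2)
  p1 <- r1 / n1
  p2 <- r2 / n2
  pool <- (r1 + r2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(structure(list(gene_id = gene_id, z = 0, p = 1, p1 = p1, p2 = p2,
                          n1 = n1, n2 = n2, degenerate = TRUE),
                     class = "expr_test"))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  structure(list(gene_id = gene_id, z = z, p = 2 * pnorm(-abs(z)),
                 p1 = p1, p2 = p2, n1 = n1, n2 = n2, degenerate = FALSE),
            class = "expr_test")
}

#' @export
print.expr_test <- function(x, ...) {
  cat("gene ", x$gene_id, ": z = ", format(x$z, digits = 5),
      ", p = ", format.pval(x$p, digits = 4),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Difference in main-isoform proportion between conditions
#'
#' The main isoform is the most abundant isoform in the first condition
#' (ties broken by lowest index); the returned value is the absolute change
#' in its proportion. Values of 0.15 or more flag biologically substantial
#' shifts; values near 1 indicate switch-like on/off regulation.
#'
#' @param phi_a,phi_b Isoform proportions (simplex) in conditions a and b.
#' @param symmetric If `TRUE`, return the maximum absolute per-isoform
#'   difference instead of anchoring on condition a's main isoform.
#' @return Absolute difference in \[0, 1\].
#' @export
main_isoform_delta <- function(phi_a, phi_b, symmetric = FALSE) {
  if (length(phi_a) != length(phi_b)) {
    stop("phi vectors differ in length", call. = FALSE)
  }
  .check_simplex(phi_a, "phi_a")
  .check_simplex(phi_b, "phi_b")
  if (symmetric) return(max(abs(phi_a - phi_b)))
  j <- which.max(phi_a)
  abs(phi_a[j] - phi_b[j])
}

#' Differential splicing across many genes
#'
#' Applies [splice_chisq_test()] per gene and BH adjustment across the
#' testable genes at the given FDR.
#'
#' @param counts_a,counts_b Named lists of [subset_counts()] (same gene
#'   names in both).
#' @param fdr Target false discovery rate.
#' @return Data frame with one row per gene: `gene_id`, `testable`, `chi2`,
#'   `df`, `p`, `q`, `significant`.
#' @export
diff_splice_table <- function(counts_a, counts_b, fdr = 0.01) {
  genes <- intersect(names(counts_a), names(counts_b))
  tests <- lapply(genes, function(g) {
    splice_chisq_test(counts_a[[g]], counts_b[[g]], gene_id = g)
  })
  df <- data.frame(
    gene_id = genes,
    testable = vapply(tests, `[[`, logical(1), "testable"),
    chi2 = vapply(tests, `[[`, numeric(1), "chi2"),
    df = vapply(tests, function(t) as.numeric(t$df), numeric(1)),
    p = vapply(tests, `[[`, numeric(1), "p"),
    row.names = NULL
  )
  adj <- bh_adjust(df$p, fdr = fdr)
  df$q <- adj$q
  df$significant <- adj$reject
  df
}

#' Differential expression across many genes
#'
#' Applies [diffexpr_ztest()] row-wise and BH adjustment at the given FDR.
#'
#' @param counts Data frame with columns `gene_id`, `r1`, `r2`.
#' @param n1,n2 Total reads in each sample.
#' @param fdr Target false discovery rate.
#' @return Data frame with `gene_id`, `p1`, `p2`, `z`, `p`, `q`,
#'   `significant`.
#' @export
diff_expr_table <- function(counts, n1, n2, fdr = 0.01) {
  stopifnot(all(c("gene_id", "r1", "r2") %in% names(counts)))
  tests <- Map(diffexpr_ztest, counts$r1, n1, counts$r2, n2, counts$gene_id)
  df <- data.frame(
    gene_id = counts$gene_id,
    p1 = vapply(tests, `[[`, numeric(1), "p1"),
    p2 = vapply(tests, `[[`, numeric(1), "p2"),
    z = vapply(tests, `[[`, numeric(1), "z"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    row.names = NULL
  )
  adj <- bh_adjust(df$p, fdr = fdr)
  df$q <- adj$q
  df$significant <- adj$reject
  df
}
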