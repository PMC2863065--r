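#' Subset read counts for one gene
#'
#' Observed counts of reads per compatibility subset. Names follow the
#' package's canonical subset labels (`+`-joined transcript ids). `total`
#' is the total number of reads for the gene and defaults to the sum of the
#' counts; it may exceed that sum when counts are restricted to a reduced
#' subset collection.
#'
#' @param counts Named non-negative integer vector.
#' @param total Total reads R for the gene.
#' @return Object of class `subset_counts`.
#' @export
subset_counts <- function(counts, total = sum(counts)) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0), total >= sum(counts) - 1e-9)
  structure(list(counts = counts, total = as.numeric(total)),
            class = "subset_counts")
}

#' @export
print.subset_counts <- function(x, ...) {
  cat("subset counts (R = ", x$total, "):\n", sep = "")
  print(x$counts)
  invisible(x)
}

# Align observed counts to a design matrix's rows (zero-fill absent rows).
.align_counts <- function(y, dm) {
  stopifnot(inherits(y, "subset_counts"))
  v <- stats::setNames(rep.int(0, nrow(dm$entries)), rownames(dm$entries))
  hit <- intersect(names(y$counts), names(v))
  v[hit] <- y$counts[hit]
  # counts for rows merged into a pooled composite are re-pooled
  if ("pooled" %in% names(v)) {
    v["pooled"] <- v["pooled"] + sum(y$counts[setdiff(names(y$counts), names(v))])
  }
  v
}

# Iterated (feasible) weighted least squares for y ~ R * P %*% beta with
# diagonal weights 1/Var(Y_i), Var estimated as R * pi * (1 - pi) from the
# previous iterate. OLS start; a variance floor keeps weights finite.
.fwls <- function(P, yv, R, passes = 2L, tol = NULL, var_floor = 0.25) {
  X <- R * P
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-14) {
    stop("singular weighted least squares system", call. = FALSE)
  }
  b <- solve(XtX, crossprod(X, yv))
  it <- 0L
  repeat {
    it <- it + 1L
    pi_hat <- as.vector(P %*% b)
    w <- 1 / pmax(R * pi_hat * (1 - pi_hat), var_floor)
    Xw <- X * sqrt(w)
    b_new <- solve(crossprod(Xw), crossprod(Xw, yv * sqrt(w)))
    done <- if (is.null(tol)) it >= passes else
      (max(abs(b_new - b)) < tol || it >= 50L)
    b <- b_new
    if (done) break
  }
  list(beta_raw = as.vector(b), iterations = it)
}

# Truncate to [0,1] then renormalize to the simplex. Renormalization also
# absorbs the global scale factor a multiread-masked fit carries, so the
# same step recovers beta in both the masked and unmasked cases.
.finish_beta <- function(beta_raw) {
  b <- pmin(pmax(beta_raw, 0), 1)
  truncated <- any(abs(b - beta_raw) > 1e-12)
  s <- sum(b)
  if (s <= 0) {
    b <- rep.int(1 / length(b), length(b))
    truncated <- TRUE
  } else {
    b <- b / s
  }
  list(beta = b, truncated = truncated)
}

#' Estimate transcript sampling probabilities by feasible weighted least squares
#'
#' Fits the linear model Y = R P beta, where Y are the subset counts, P the
#' design matrix and beta_j the probability that one of the gene's reads
#' originates from isoform j. Each Y_i is binomial(R, pi_i); via the normal
#' approximation the weighted least squares solution with weights 1/Var(Y_i)
#' is the BLUE, and since the variances are unknown they are estimated from
#' the previous iterate (ordinary least squares start, two reweighting
#' passes by default). Out-of-range components are truncated at 0 or 1 and
#' the vector renormalized to sum to 1. For multiread-masked matrices the
#' fitted coefficients are proportional to beta and the same renormalization
#' recovers it.
#'
#' @param dm A full-column-rank `design_matrix` (see
#'   [reduce_to_full_rank()]).
#' @param y A [subset_counts()].
#' @param min_reads Guard for the normal approximation (default 20):
#'   estimation refuses genes with fewer total reads.
#' @param passes Number of reweighting passes (default 2).
#' @param tol If supplied, iterate to convergence at this tolerance instead
#'   of a fixed pass count (capped at 50 iterations).
#' @return Named numeric beta vector on the simplex, with attributes
#'   `truncated` (logical), `iterations` and `beta_raw` (pre-truncation
#'   solution).
#' @export
estimate_beta <- function(dm, y, min_reads = 20, passes = 2L, tol = NULL) {
  stopifnot(inherits(dm, "design_matrix"))
  if (y$total < min_reads) {
    stop("gene has ", y$total, " reads; at least ", min_reads,
         " are required for the normal approximation", call. = FALSE)
  }
  if (ncol(dm$entries) == 1L) {
    return(structure(stats::setNames(1, dm$transcript_ids),
                     truncated = FALSE, iterations = 0L, beta_raw = 1))
  }
  yv <- .align_counts(y, dm)
  fit <- .fwls(dm$entries, yv, y$total, passes = passes, tol = tol)
  fin <- .finish_beta(fit$beta_raw)
  structure(stats::setNames(fin$beta, dm$transcript_ids),
            truncated = fin$truncated, iterations = fit$iterations,
            beta_raw = fit$beta_raw)
}

#' Convert sampling probabilities to isoform proportions (and back)
#'
#' Under length-proportional sampling, beta_j = phi_j L_j / sum_k phi_k L_k.
#' Given beta on the simplex the phi are uniquely determined:
#' phi_j = (beta_j / L_j) / sum_k (beta_k / L_k). `phi_to_beta` is the
#' inverse map.
#'
#' @param beta,phi Probability vector on the simplex.
#' @param lengths Transcript lengths L_j in bases.
#' @return The converted probability vector.
#' @export
#' @examples
#' beta_to_phi(c(0.5, 0.5), c(27, 17))  # (17/44, 27/44)
beta_to_phi <- function(beta, lengths) {
  .check_simplex(beta, "beta")
  if (any(lengths <= 0)) stop("transcript lengths must be positive", call. = FALSE)
  stopifnot(length(beta) == length(lengths))
  w <- beta / lengths
  w / sum(w)
}

#' @rdname beta_to_phi
#' @export
phi_to_beta <- function(phi, lengths) {
  .check_simplex(phi, "phi")
  if (any(lengths <= 0)) stop("transcript lengths must be positive", call. = FALSE)
  stopifnot(length(phi) == length(lengths))
  w <- phi * lengths
  w / sum(w)
}

.check_simplex <- function(p, what) {
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop(what, " must be a probability vector summing to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Empirical confidence intervals for isoform proportions
#'
#' Parametric bootstrap: B multinomial count vectors of size R are simulated
#' from the fitted subset probabilities, phi is re-estimated for each, and
#' percentile intervals are returned at each requested level. Deterministic
#' given the seed.
#'
#' @inheritParams estimate_beta
#' @param levels Confidence level(s) in (0, 1).
#' @param B Number of bootstrap replicates (default 200; below 50 a warning
#'   is emitted).
#' @param seed Integer seed.
#' @param keep_draws If `TRUE`, attach the bootstrap phi draws.
#' @return Object of class `phi_ci`: a named list (one element per level) of
#'   isoform x (lower, upper) matrices.
#' @export
bootstrap_ci <- function(dm, y, levels = 0.95, B = 200L, seed = 1L,
                         min_reads = 20, passes = 2L, keep_draws = FALSE) {
  stopifnot(inherits(dm, "design_matrix"))
  if (any(levels <= 0 | levels >= 1)) {
    stop("confidence levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (B < 50L) warning("B = ", B, " bootstrap replicates is very small")
  n <- ncol(dm$entries)
  beta_hat <- estimate_beta(dm, y, min_reads = min_reads, passes = passes)
  if (n == 1L) {
    ci <- lapply(levels, function(l) {
      matrix(1, 1L, 2L, dimnames = list(dm$transcript_ids, c("lower", "upper")))
    })
    names(ci) <- as.character(levels)
    return(structure(list(ci = ci, levels = levels, draws = NULL),
                     class = "phi_ci"))
  }
  pi_hat <- pmax(as.vector(dm$entries %*% beta_hat), 0)
  prob <- c(pi_hat, max(0, 1 - sum(pi_hat)))
  prob <- prob / sum(prob)
  set.seed(as.integer(seed))
  Y <- rmultinom(B, size = y$total, prob = prob)
  phis <- matrix(NA_real_, nrow = n, ncol = B,
                 dimnames = list(dm$transcript_ids, NULL))
  P <- dm$entries
  R <- y$total
  for (b in seq_len(B)) {
    fb <- .finish_beta(.fwls(P, Y[seq_len(nrow(P)), b], R,
                             passes = passes)$beta_raw)
    phis[, b] <- beta_to_phi(fb$beta, dm$lengths)
  }
  ci <- lapply(levels, function(l) {
    a <- (1 - l) / 2
    t(apply(phis, 1L, quantile, probs = c(a, 1 - a), names = FALSE))
  })
  ci <- lapply(ci, function(m) {
    dimnames(m) <- list(dm$transcript_ids, c("lower", "upper")); m
  })
  names(ci) <- as.character(levels)
  structure(list(ci = ci, levels = levels,
                 draws = if (keep_draws) phis else NULL),
            class = "phi_ci")
}

#' Quantify the isoform mixture of one gene
#'
#' Full pipeline: build the design matrix from the read model (multiread-
#' masked when a k-mer index is supplied), reduce it to full column rank,
#' estimate beta by feasible weighted least squares, convert to isoform
#' proportions phi and attach empirical bootstrap confidence intervals.
#'
#' @inheritParams estimate_beta
#' @param gene A [gene()] object.
#' @param model A [read_model()].
#' @param kmer_index Optional [build_kmer_index()] over the full gene set;
#'   triggers multiread masking.
#' @param strategy Rank-reduction strategy, see [reduce_to_full_rank()].
#' @param level Confidence level for the reported interval.
#' @param B Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `isoform_estimate` with fields `gene_id`,
#'   `transcript_ids`, `beta`, `phi`, `ci`, `R`, `level` and `diagnostics`;
#'   `as.data.frame()` yields the tabular form.
#' @export
quantify_gene <- function(gene, model, y, kmer_index = NULL,
                          strategy = "all_subsets", level = 0.95,
                          B = 200L, seed = 1L, min_reads = 20) {
  stopifnot(inherits(gene, "gene"))
  dm <- if (is.null(kmer_index)) build_design_matrix(gene, model)
        else apply_multiread_mask(gene, model, kmer_index)
  dm <- reduce_to_full_rank(dm, strategy)
  beta <- estimate_beta(dm, y, min_reads = min_reads)
  phi <- beta_to_phi(as.numeric(beta), dm$lengths)
  ci <- bootstrap_ci(dm, y, levels = level, B = B, seed = seed,
                     min_reads = min_reads)
  structure(
    list(gene_id = gene$id, transcript_ids = dm$transcript_ids,
         beta = as.numeric(beta), phi = stats::setNames(phi, dm$transcript_ids),
         ci = ci$ci[[1]], R = y$total, level = level,
         diagnostics = list(truncated = attr(beta, "truncated"),
                            iterations = attr(beta, "iterations"),
                            masked = dm$masked, strategy = strategy)),
    class = "isoform_estimate"
  )
}

#' @export
print.isoform_estimate <- function(x, ...) {
  cat("isoform estimate for gene ", x$gene_id, " (R = ", x$R, " reads)\n",
      sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.isoform_estimate <- function(x, ...) {
  data.frame(
    gene_id = x$gene_id,
    transcript_id = x$transcript_ids,
    phi = as.numeric(x$phi),
    ci_low = x$ci[, "lower"],
    ci_high = x$ci[, "upper"],
    beta = x$beta,
    R = x$R,
    truncated = x$diagnostics$truncated,
    row.names = NULL
  )
}
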