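#' Simulate subset counts for a known isoform mixture
#'
#' Each read selects an isoform with probability proportional to its length
#' and concentration in the mixture (phi_j L_j / sum_k phi_k L_k), draws a
#' start position k and length m from the discretized read model for that
#' isoform, and the window's nucleotide sequence is classified against all
#' isoforms to determine its compatibility subset. Reads are error-free, so
#' every simulated read classifies into a realized subset. Sampling is
#' vectorized through multinomial draws over isoforms and windows, which is
#' distributionally identical to the per-read procedure.
#'
#' @param gene A [gene()] object.
#' @param phi Isoform proportions (simplex, in the gene's isoform order).
#' @param R Number of reads to simulate.
#' @param model A [read_model()].
#' @param seed Integer seed; the same seed yields identical counts.
#' @return A [subset_counts()] over the gene's realized subsets, with
#'   attribute `origin` giving the per-isoform read totals.
#' @export
simulate_reads <- function(gene, phi, R, model, seed = 17L) {
  stopifnot(inherits(gene, "gene"), inherits(model, "read_model"), R >= 0)
  L <- transcript_lengths(gene)
  .check_simplex(phi, "phi")
  stopifnot(length(phi) == length(L))
  ms <- as.integer(names(model$length_pmf))[model$length_pmf > 0]
  infeasible <- L < min(ms)
  if (any(infeasible)) {
    stop("isoform(s) shorter than every modeled read length: ",
         paste(names(L)[infeasible], collapse = ", "), call. = FALSE)
  }
  cc <- .classify_cells(gene, ms)
  counts <- stats::setNames(rep.int(0, length(cc$subsets)), names(cc$subsets))
  set.seed(as.integer(seed))
  w <- phi * L
  nj <- as.vector(rmultinom(1L, size = R, prob = w / sum(w)))
  for (j in seq_along(L)) {
    if (nj[j] == 0L) next
    h <- discretize(model, L[j])
    cell_counts <- as.vector(rmultinom(1L, size = nj[j], prob = h$p))
    acc <- rowsum(cell_counts, group = cc$cells[[j]]$subset)
    counts[as.integer(rownames(acc))] <- counts[as.integer(rownames(acc))] +
      acc[, 1L]
  }
  y <- subset_counts(counts, total = R)
  attr(y, "origin") <- stats::setNames(nj, names(L))
  y
}

#' Specification of a simulation mixture study
#'
#' @param gene A [gene()] object.
#' @param phi True isoform proportions.
#' @param R Reads per replicate.
#' @param replicates Number of replicates.
#' @param seed Study seed; replicate seeds are derived as `seed + replicate`.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(gene, phi, R, replicates = 500L, seed = 17L) {
  stopifnot(inherits(gene, "gene"), R > 0, replicates >= 1L)
  .check_simplex(phi, "phi")
  stopifnot(length(phi) == length(gene$transcripts), all(phi >= 0))
  structure(list(gene = gene, phi = phi, R = as.integer(R),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Run a replicated recovery and coverage study
#'
#' For each replicate, reads are simulated from the generator model at the
#' true mixture, phi is estimated using a design matrix built from the
#' estimation model, and (optionally) empirical confidence intervals are
#' computed and checked against the truth. Passing different generator and
#' estimation models quantifies the bias introduced by assuming the wrong
#' read position distribution (e.g. a uniform model on skewed data).
#'
#' @param spec A [mixture_spec()].
#' @param generator_model [read_model()] used to simulate reads.
#' @param estimation_model [read_model()] used to build the design matrix
#'   (defaults to the generator model: the matched case).
#' @param levels Confidence levels to track coverage for.
#' @param B Bootstrap replicates per confidence interval; `B = 0` skips
#'   interval computation (coverage reported as `NA`).
#' @param strategy Rank-reduction strategy.
#' @return Object of class `simulation_study`: per-replicate phi estimates,
#'   their mean, and per-level / per-isoform empirical coverage.
#' @export
run_simulation_study <- function(spec, generator_model,
                                 estimation_model = generator_model,
                                 levels = c(0.65, 0.90, 0.95),
                                 B = 200L, strategy = "all_subsets") {
  stopifnot(inherits(spec, "mixture_spec"),
            inherits(generator_model, "read_model"),
            inherits(estimation_model, "read_model"))
  gene <- spec$gene
  dm <- reduce_to_full_rank(build_design_matrix(gene, estimation_model),
                            strategy)
  n <- ncol(dm$entries)
  reps <- spec$replicates
  phi_hat <- matrix(NA_real_, nrow = reps, ncol = n,
                    dimnames = list(NULL, dm$transcript_ids))
  covered <- array(NA, dim = c(reps, length(levels), n),
                   dimnames = list(NULL, as.character(levels),
                                   dm$transcript_ids))
  do_ci <- B > 0L
  for (r in seq_len(reps)) {
    y <- simulate_reads(gene, spec$phi, spec$R, generator_model,
                        seed = spec$seed + r)
    beta <- estimate_beta(dm, y)
    phi_hat[r, ] <- beta_to_phi(as.numeric(beta), dm$lengths)
    if (do_ci) {
      ci <- bootstrap_ci(dm, y, levels = levels, B = B,
                         seed = spec$seed + r + 1000000L)
      for (li in seq_along(levels)) {
        m <- ci$ci[[li]]
        covered[r, li, ] <- spec$phi >= m[, "lower"] & spec$phi <= m[, "upper"]
      }
    }
  }
  coverage <- apply(covered, c(2L, 3L), mean)
  structure(
    list(gene_id = gene$id, phi_true = spec$phi, R = spec$R,
         replicates = reps, levels = levels, phi_hat = phi_hat,
         mean_phi = colMeans(phi_hat), coverage = coverage,
         generator = generator_model$source,
         estimator = estimation_model$source),
    class = "simulation_study"
  )
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("simulation study: gene ", x$gene_id, ", ", x$replicates,
      " replicates x ", x$R, " reads\n", sep = "")
  cat("  generator model: ", x$generator, "; estimation model: ",
      x$estimator, "\n", sep = "")
  tab <- rbind(`true phi` = x$phi_true, `mean estimate` = x$mean_phi)
  print(round(tab, 4))
  if (!all(is.na(x$coverage))) {
    cat("empirical CI coverage:\n")
    print(round(x$coverage, 4))
  }
  invisible(x)
}

#' Tabulate a simulation study
#'
#' @param x A `simulation_study`.
#' @param ... Unused.
#' @return Data frame with one row per isoform: true phi, mean and SD of
#'   the estimates, and coverage per level.
#' @export
as.data.frame.simulation_study <- function(x, ...) {
  df <- data.frame(
    gene_id = x$gene_id,
    transcript_id = colnames(x$phi_hat),
    phi_true = x$phi_true,
    phi_mean = x$mean_phi,
    phi_sd = apply(x$phi_hat, 2L, stats::sd),
    row.names = NULL
  )
  for (li in seq_along(x$levels)) {
    df[[paste0("coverage_", x$levels[li])]] <- x$coverage[li, ]
  }
  df
}
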