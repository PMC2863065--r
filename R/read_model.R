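# Trapezoid integral on a grid.
.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

# Gaussian KDE on [0,1] with boundary reflection at 0 and 1, evaluated on a
# regular grid. Bandwidth defaults to Silverman's rule on the raw data.
.kde01 <- function(x, bandwidth = NULL, n_grid = 512L) {
  stopifnot(length(x) >= 2L, all(x >= 0), all(x <= 1))
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 0.05
  }
  aug <- c(x, -x, 2 - x)
  d <- density(aug, bw = bandwidth, from = 0, to = 1, n = n_grid)
  f <- 3 * d$y                        # the two reflected copies triple n
  f <- pmax(f, 0)
  f <- f / .trapz(d$x, f)
  list(u = d$x, f = f, bandwidth = bandwidth)
}

.normalize_length_pmf <- function(length_pmf) {
  if (is.numeric(length_pmf) && is.null(names(length_pmf)) &&
      length(length_pmf) == 1L) {
    length_pmf <- stats::setNames(1, as.character(as.integer(length_pmf)))
  }
  if (is.null(names(length_pmf))) {
    stop("length_pmf must be a single read length or a named probability vector",
         call. = FALSE)
  }
  m <- as.integer(names(length_pmf))
  if (anyNA(m) || any(m < 1L)) stop("read lengths must be positive integers", call. = FALSE)
  p <- as.numeric(length_pmf)
  if (any(p < 0) || sum(p) <= 0) stop("length_pmf must be non-negative with positive mass", call. = FALSE)
  o <- order(m)
  stats::setNames(p[o] / sum(p[o]), as.character(m[o]))
}

#' Construct a read model
#'
#' A read model is the package's representation of the joint distribution of
#' read start position and read length: a start-position density on the
#' relative coordinate u = k/L in \[0,1\], and a probability mass function
#' over read lengths. The two are treated as independent and combined (then
#' renormalized over the feasible window set) when discretized onto a
#' particular transcript length by [discretize()].
#'
#' @param start_u Grid of relative positions in \[0,1\] (increasing).
#' @param start_f Density values on the grid (non-negative); renormalized to
#'   integrate to 1.
#' @param length_pmf Single read length, or named vector mapping length to
#'   probability (normalized to sum to 1).
#' @param source Free-text label recording where the model came from.
#' @param meta Optional list of extra metadata (e.g. simulator by-products).
#' @return An object of class `read_model`.
#' @export
read_model <- function(start_u, start_f, length_pmf, source = "custom",
                       meta = list()) {
  stopifnot(is.numeric(start_u), is.numeric(start_f),
            length(start_u) == length(start_f), length(start_u) >= 2L,
            !is.unsorted(start_u), all(start_u >= 0), all(start_u <= 1))
  if (any(start_f < 0)) stop("start density must be non-negative", call. = FALSE)
  z <- .trapz(start_u, start_f)
  if (z <= 0) stop("start density has zero mass", call. = FALSE)
  start_f <- start_f / z
  pmf <- .normalize_length_pmf(length_pmf)
  m <- structure(
    list(start_u = start_u, start_f = start_f, length_pmf = pmf,
         source = source, meta = meta),
    class = "read_model"
  )
  m$.fun <- approxfun(start_u, start_f, rule = 2)
  m
}

#' Evaluate a model's start-position density
#'
#' @param model A [read_model()].
#' @param u Relative positions in \[0,1\].
#' @return Density values.
#' @export
start_density <- function(model, u) {
  stopifnot(inherits(model, "read_model"))
  model$.fun(u)
}

#' @export
print.read_model <- function(x, ...) {
  m <- as.integer(names(x$length_pmf))
  cat("read model [", x$source, "]\n", sep = "")
  cat("  start density on ", length(x$start_u), "-point grid, integral ",
      format(.trapz(x$start_u, x$start_f), digits = 8), "\n", sep = "")
  cat("  read lengths: ", min(m), "-", max(m), " nt (",
      length(m), " value(s))\n", sep = "")
  invisible(x)
}

#' Uniform read model
#'
#' The classical assumption: reads sample start positions uniformly along
#' the transcript. Useful as a baseline and for demonstrating the bias that
#' a wrong positional model introduces.
#'
#' @param read_length Single read length or named length pmf.
#' @return A [read_model()] with a flat start density.
#' @export
#' @examples
#' discretize(uniform_model(5L), 27L)  # 23 equally likely starts
uniform_model <- function(read_length) {
  read_model(c(0, 1), c(1, 1), read_length, source = "uniform")
}

#' Estimate a read model from observed alignments
#'
#' Kernel density estimation (Gaussian kernel, Silverman's rule bandwidth by
#' default, boundary reflection at 0 and 1) of the relative read start
#' positions k/L observed across transcripts, plus the empirical read-length
#' distribution. With millions of reads available per experiment these
#' distributions are properties of the protocol and can be estimated to high
#' accuracy; a configurable floor guards against estimating from too few
#' alignments.
#'
#' @param alignments Data frame with columns `transcript_id`, `start`
#'   (1-based) and `length`, e.g. from [read_alignments()].
#' @param transcripts Named list of [transcript()] objects, a [gene()], or a
#'   list of genes, used to resolve transcript lengths.
#' @param bandwidth Optional KDE bandwidth on the relative-position scale.
#' @param min_alignments Minimum number of alignments required (default 100).
#' @return A [read_model()] with `source = "empirical"`.
#' @export
estimate_read_model <- function(alignments, transcripts, bandwidth = NULL,
                                min_alignments = 100L) {
  stopifnot(is.data.frame(alignments),
            all(c("transcript_id", "start", "length") %in% names(alignments)))
  if (nrow(alignments) < min_alignments) {
    stop("only ", nrow(alignments), " alignments; at least ", min_alignments,
         " are required to estimate a read model", call. = FALSE)
  }
  tx_len <- .resolve_tx_lengths(transcripts)
  idx <- match(alignments$transcript_id, names(tx_len))
  if (anyNA(idx)) {
    stop("alignments reference unknown transcript(s): ",
         paste(unique(alignments$transcript_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  L <- tx_len[idx]
  if (any(L <= 0)) stop("zero-length transcript in lookup", call. = FALSE)
  k <- as.numeric(alignments$start)
  m <- as.integer(alignments$length)
  if (any(k < 1) || any(m < 1) || any(k + m - 1 > L)) {
    stop("alignment coordinates violate 1 <= start, start + length - 1 <= L",
         call. = FALSE)
  }
  kd <- .kde01(k / L, bandwidth = bandwidth)
  pmf <- table(m) / length(m)
  read_model(kd$u, kd$f, stats::setNames(as.numeric(pmf), names(pmf)),
             source = "empirical",
             meta = list(n_alignments = nrow(alignments),
                         bandwidth = kd$bandwidth))
}

.resolve_tx_lengths <- function(transcripts) {
  if (inherits(transcripts, "gene")) transcripts <- list(transcripts)
  if (is.list(transcripts) && all(vapply(transcripts, inherits, logical(1), "gene"))) {
    transcripts <- unlist(lapply(transcripts, `[[`, "transcripts"),
                          recursive = FALSE, use.names = FALSE)
  }
  if (is.numeric(transcripts) && !is.null(names(transcripts))) {
    return(transcripts)
  }
  stopifnot(is.list(transcripts))
  len <- vapply(transcripts, `[[`, integer(1), "length")
  names(len) <- vapply(transcripts, `[[`, character(1), "id")
  len
}

#' Discretize a read model onto a transcript of length L
#'
#' Forms the joint start/length mass function over the feasible window set
#' \{(k, m): 1 <= k, k + m - 1 <= L\} as the product of the start density
#' evaluated at k/L and the length pmf, renormalized to sum to exactly 1.
#'
#' @param model A [read_model()].
#' @param L Transcript length in bases.
#' @return Object of class `km_pmf`: parallel vectors `k`, `m`, `p` plus `L`.
#' @export
discretize <- function(model, L) {
  stopifnot(inherits(model, "read_model"), length(L) == 1L, L >= 1)
  L <- as.integer(L)
  ms <- as.integer(names(model$length_pmf))
  keep <- model$length_pmf > 0 & ms <= L
  ms <- ms[keep]
  if (length(ms) == 0L) {
    stop("no feasible read: transcript length ", L,
         " is below every modeled read length", call. = FALSE)
  }
  pm <- model$length_pmf[keep]
  k <- unlist(lapply(ms, function(m) seq_len(L - m + 1L)), use.names = FALSE)
  m <- rep.int(ms, L - ms + 1L)
  p <- model$.fun(k / L) * rep.int(as.numeric(pm), L - ms + 1L)
  p[p < 0] <- 0
  s <- sum(p)
  if (s <= 0) stop("start density places no mass on the feasible region", call. = FALSE)
  structure(list(k = k, m = m, p = p / s, L = L), class = "km_pmf")
}

#' Simulate cDNA fragmentation by nebulization
#'
#' Emulates gas-shear fragmentation: each full-length molecule is recursively
#' split at a uniformly random position until every piece is no longer than
#' `frag_max`; pieces whose length falls within `[frag_min, frag_max]` are
#' retained (shorter shards are lost to size selection) and a read start is
#' recorded at each retained fragment's 5' end, as a position relative to
#' the original molecule. The recorded starts yield a markedly non-uniform
#' start-position density, reproducing the enrichment near the 5' terminus
#' seen in nebulized libraries.
#'
#' @param n_molecules Number of molecules to fragment.
#' @param molecule_length Length of each molecule in nucleotides.
#' @param frag_min,frag_max Retained fragment size range in nucleotides
#'   (defaults 500 and 800).
#' @param read_length_pmf Read length (or named pmf) attached to the
#'   resulting model.
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param both_ends If `TRUE`, also record a start at each retained
#'   fragment's 3' end, mirrored into 5' coordinates (a library sequenced
#'   from both fragment ends). Default `FALSE` (single-end).
#' @return A [read_model()] with `source = "nebulization"`; `meta` carries
#'   the retained fragment lengths and the raw relative starts.
#' @export
simulate_nebulization <- function(n_molecules, molecule_length,
                                  frag_min = 500L, frag_max = 800L,
                                  read_length_pmf, seed = 17L,
                                  both_ends = FALSE) {
  stopifnot(n_molecules >= 1L, molecule_length >= 2L)
  if (!(frag_min < frag_max && frag_max < molecule_length)) {
    stop("need frag_min < frag_max < molecule_length", call. = FALSE)
  }
  set.seed(as.integer(seed))
  start <- rep.int(0L, n_molecules)          # 0-based piece offsets
  len <- rep.int(as.integer(molecule_length), n_molecules)
  repeat {
    big <- len > frag_max
    if (!any(big)) break
    cut <- 1L + as.integer(floor(runif(sum(big)) * (len[big] - 1L)))
    start <- c(start[!big], start[big], start[big] + cut)
    len <- c(len[!big], cut, len[big] - cut)
  }
  keep <- len >= frag_min & len <= frag_max
  if (sum(keep) < 2L) {
    stop("fewer than 2 fragments retained; increase n_molecules", call. = FALSE)
  }
  rel <- start[keep] / molecule_length
  if (both_ends) {
    rel <- c(rel, 1 - (start[keep] + len[keep]) / molecule_length)
  }
  kd <- .kde01(rel)
  read_model(kd$u, kd$f, read_length_pmf, source = "nebulization",
             meta = list(fragment_lengths = len[keep], starts = rel,
                         bandwidth = kd$bandwidth, seed = as.integer(seed)))
}

#' Serialize / load a read model as a plain-text table
#'
#' The table has three columns: `part` (`start` or `length`), `x` (grid
#' position or read length) and `value` (density or probability).
#'
#' @param model A [read_model()].
#' @param path File path.
#' @return `write_read_model` returns `path` invisibly; `read_read_model`
#'   returns the reconstructed [read_model()].
#' @export
write_read_model <- function(model, path) {
  stopifnot(inherits(model, "read_model"))
  df <- rbind(
    data.frame(part = "start", x = model$start_u, value = model$start_f),
    data.frame(part = "length", x = as.integer(names(model$length_pmf)),
               value = as.numeric(model$length_pmf))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# isoformlm read model; source=", model$source), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_model
#' @export
read_read_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  src <- if (grepl("source=", hdr)) sub(".*source=", "", hdr) else "file"
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  st <- df[df$part == "start", ]
  le <- df[df$part == "length", ]
  read_model(st$x, st$value,
             stats::setNames(le$value, as.character(as.integer(le$x))),
             source = src)
}

#' Read alignments from TSV, SAM or BAM
#'
#' The TSV route expects columns `read_id`, `transcript_id`, `start`,
#' `length` (header optional if in that order). SAM/BAM files must be
#' aligned against the transcriptome; the start is the POS field and the
#' length is the aligned query width. SAM input is converted in a temporary
#' directory via Rsamtools.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"sam"` or `"bam"`.
#' @return Data frame with columns `read_id`, `transcript_id`, `start`,
#'   `length`.
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") {
    df <- data.table::fread(path, header = "auto", data.table = FALSE)
    if (!all(c("read_id", "transcript_id", "start", "length") %in% names(df))) {
      if (ncol(df) < 4L) stop("alignment TSV needs 4 columns", call. = FALSE)
      names(df)[1:4] <- c("read_id", "transcript_id", "start", "length")
    }
    return(df[, c("read_id", "transcript_id", "start", "length")])
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM input requires the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, file.path(tempdir(), basename(path)),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "flag")
    )
  )[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  data.frame(
    read_id = res$qname[mapped],
    transcript_id = as.character(res$rname[mapped]),
    start = res$pos[mapped],
    length = res$qwidth[mapped],
    stringsAsFactors = FALSE
  )
}
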