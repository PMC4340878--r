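#' Log-odds scoring matrix from a probability matrix
#'
#' Entries are `log2` ratios of the (optionally pseudocount-regularized)
#' motif probabilities to the background:
#' `log2(((ppm + pc * bg) / (1 + pc)) / bg)`, in bits.
#'
#' @param ppm w x 4 probability matrix (columns ACGT).
#' @param background Length-4 background probability vector.
#' @param pseudocount Background-proportional pseudocount; 0 leaves
#'   impossible bases at `-Inf`.
#' @return w x 4 log-odds matrix in bits.
#' @export
make_log_odds <- function(ppm, background, pseudocount = 0) {
  if (any(background <= 0)) stop("background entries must be > 0")
  stopifnot(abs(sum(background) - 1) < 1e-6)
  reg <- sweep(ppm, 2L, background * pseudocount, `+`) / (1 + pseudocount)
  lo <- log2(sweep(reg, 2L, background, `/`))
  colnames(lo) <- DNA_BASES
  lo
}

#' Exact p-values for PWM scores by dynamic programming
#'
#' Discretizes the log-odds entries to `granularity`-bit bins and convolves
#' the per-column score distributions under the 0-order background model,
#' yielding the exact null distribution of the (binned) score and hence
#' `P(score >= s)` for every attainable score. Scanning uses the same binned
#' matrix, so lookups are exact rather than approximate.
#'
#' @param log_odds w x 4 log-odds matrix (finite entries).
#' @param background Length-4 background vector.
#' @param granularity Bin width in bits.
#' @return A `score_pvalue_lookup`: integer matrix `kmat` (binned scores),
#'   `granularity`, integer score support `bins`, and `tail` with
#'   `tail[i] = P(score >= bins[i])`.
#' @export
exact_score_pvalues <- function(log_odds, background, granularity = 0.01) {
  if (!all(is.finite(log_odds))) {
    stop("log-odds entries must be finite (use a pseudocount)")
  }
  w <- nrow(log_odds)
  if (w * granularity / 2 > 0.5) {
    warning("granularity too coarse: worst-case rounding error ",
            w * granularity / 2, " bits")
  }
  kmat <- round(log_odds / granularity)
  storage.mode(kmat) <- "integer"
  lo_min <- sum(apply(kmat, 1L, min))
  lo_max <- sum(apply(kmat, 1L, max))
  # pmf over the integer support, convolved column by column
  pmf <- numeric(lo_max - lo_min + 1L)
  cur_min <- 0L
  pmf[1L] <- 1
  cur <- 1
  for (j in seq_len(w)) {
    row <- kmat[j, ]
    lo_j <- min(row); hi_j <- max(row)
    new_min <- cur_min + lo_j
    new <- numeric(length(cur) + hi_j - lo_j)
    for (b in 1:4) {
      off <- row[b] - lo_j
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_min <- new_min
  }
  stopifnot(abs(sum(cur) - 1) < 1e-9)
  tail <- rev(cumsum(rev(cur)))
  structure(list(kmat = kmat, granularity = granularity,
                 bins = seq.int(cur_min, by = 1L, length.out = length(cur)),
                 tail = tail),
            class = "score_pvalue_lookup")
}

#' Look up tail p-values for binned scores
#' @param lookup A `score_pvalue_lookup`.
#' @param kscore Integer binned score(s) (sums over `lookup$kmat` rows).
#' @return `P(score >= kscore)`; 1 below the support, 0 above it.
#' @export
lookup_pvalue <- function(lookup, kscore) {
  i <- kscore - lookup$bins[1L] + 1L
  n <- length(lookup$tail)
  ifelse(i < 1L, 1, ifelse(i > n, 0, lookup$tail[pmax(pmin(i, n), 1L)]))
}

score_positions <- function(b, kmat) {
  w <- nrow(kmat)
  m <- length(b) - w + 1L
  if (m < 1L) return(integer(0))
  acc <- integer(m)
  for (j in seq_len(w)) {
    acc <- acc + kmat[j, b[seq_len(m) + j - 1L]]
  }
  acc
}

#' Scan a genome for motif occurrences
#'
#' Scores every position on the requested strands against the binned
#' log-odds matrix and reports positions whose exact p-value is at or below
#' the threshold. Reverse-strand matches are reported by their
#' forward-coordinate start. Circular genomes are scanned across the origin.
#'
#' @param genome A `genome_sequence`.
#' @param log_odds w x 4 log-odds matrix (bits), e.g. from
#'   [make_log_odds()].
#' @param p_threshold Report sites with `pvalue <= p_threshold`.
#' @param strands `"both"`, `"+"`, or `"-"`.
#' @param background Background for the null distribution; defaults to the
#'   genome's own base composition.
#' @param granularity Score bin width in bits.
#' @return A data frame of `motif_site`s sorted by position then strand
#'   (`+` before `-`): `position` (1-based forward start), `strand`,
#'   `matched_seq` (site sequence on its own strand), `score` (bits),
#'   `pvalue`.
#' @export
scan_genome <- function(genome, log_odds, p_threshold = 1e-4,
                        strands = "both", background = NULL,
                        granularity = 0.01) {
  w <- nrow(log_odds)
  if (w > genome$length) stop("motif wider than the genome")
  if (is.null(background)) {
    counts <- base_counts(genome$sequence)
    background <- counts / sum(counts)
  }
  lookup <- exact_score_pvalues(log_odds, background, granularity)
  b <- seq_to_int(genome$sequence)
  L <- genome$length
  if (genome$circular) b <- c(b, b[seq_len(w - 1L)])
  do_strand <- function(strand) {
    kmat <- if (strand == "+") lookup$kmat else {
      k <- lookup$kmat[rev(seq_len(w)), 4:1, drop = FALSE]
      colnames(k) <- DNA_BASES
      k
    }
    ks <- score_positions(b, kmat)
    p <- lookup_pvalue(lookup, ks)
    hit <- which(p <= p_threshold)
    if (!length(hit)) return(NULL)
    seqs <- substring(paste(DNA_BASES[b], collapse = ""), hit, hit + w - 1L)
    if (strand == "-") seqs <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
    data.frame(position = hit, strand = strand, matched_seq = seqs,
               score = ks[hit] * lookup$granularity, pvalue = p[hit],
               stringsAsFactors = FALSE)
  }
  parts <- switch(strands,
                  both = list(do_strand("+"), do_strand("-")),
                  `+` = list(do_strand("+")),
                  `-` = list(do_strand("-")),
                  stop("strands must be 'both', '+' or '-'"))
  sites <- do.call(rbind, parts)
  if (is.null(sites)) {
    sites <- data.frame(position = integer(), strand = character(),
                        matched_seq = character(), score = numeric(),
                        pvalue = numeric(), stringsAsFactors = FALSE)
  }
  sites <- sites[order(sites$position, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Attach the best motif occurrence to each peak
#'
#' For each peak, picks the scanned site with the smallest p-value whose
#' midpoint falls inside the peak interval and fills the peak's motif
#' columns; peaks without any such site keep `NA` (absent motif).
#'
#' @param peaks A `peak_table`.
#' @param sites Scan output from [scan_genome()].
#' @param width Motif width in bp.
#' @return The peak table with `motif_start`, `motif_end`, `motif_seq`
#'   filled where a site was found.
#' @export
assign_motifs_to_peaks <- function(peaks, sites, width) {
  if (!nrow(sites)) return(peaks)
  mid <- sites$position + (width - 1) / 2
  for (i in seq_len(nrow(peaks))) {
    inside <- which(mid >= peaks$start[i] & mid <= peaks$end[i])
    if (!length(inside)) next
    best <- inside[order(sites$pvalue[inside], sites$position[inside])][1L]
    peaks$motif_start[i] <- sites$position[best]
    peaks$motif_end[i] <- sites$position[best] + width - 1L
    peaks$motif_seq[i] <- sites$matched_seq[best]
  }
  validate_peaks(peaks)
}

#' Summit-motif geometry statistics
#'
#' For each peak carrying a motif interval, the distance from the summit to
#' the motif midpoint `(motif_start + motif_end)/2` is computed with exact
#' half-integer arithmetic and compared against the threshold (inclusive).
#' Peaks without a motif are excluded from `n_with_motif`.
#'
#' @param peaks A `peak_table` with motif columns.
#' @param threshold Distance threshold in bp.
#' @return A `geometry_report`: `n_peaks`, `n_with_motif`,
#'   `n_within_threshold`, `threshold`, and a `distances` data frame with
#'   one row per peak.
#' @export
summit_motif_geometry <- function(peaks, threshold = 50) {
  mid <- (peaks$motif_start + peaks$motif_end) / 2
  distance <- abs(peaks$summit - mid)
  structure(list(
    n_peaks = nrow(peaks),
    n_with_motif = sum(!is.na(distance)),
    n_within_threshold = sum(distance <= threshold, na.rm = TRUE),
    threshold = threshold,
    distances = data.frame(summit = peaks$summit, motif_midpoint = mid,
                           distance = distance)
  ), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf(
    "<geometry_report> %d peaks: %d with motif, %d within %g bp of the summit\n",
    x$n_peaks, x$n_with_motif, x$n_within_threshold, x$threshold))
  invisible(x)
}

#' Write motif sites as BED6+ or TSV
#' @param sites Scan output from [scan_genome()].
#' @param path Output path.
#' @param genome_name Chromosome name (BED only).
#' @param width Motif width.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_motif_sites <- function(sites, path, genome_name = "genome",
                              width, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     genome_name, sites$position - 1L,
                     sites$position + width - 1L, sites$matched_seq,
                     formatC(sites$score, format = "fg"), sites$strand,
                     formatC(sites$pvalue, format = "e", digits = 3))
    writeLines(lines, path)
  }
  invisible(path)
}
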