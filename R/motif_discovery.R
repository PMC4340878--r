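#' Motif-discovery parameters
#'
#' @param w_min,w_max Candidate motif widths (bp); every width in the range
#'   is fitted and the best is chosen by penalized log-likelihood ratio.
#' @param window Width (bp) of the summit-centred sequence windows.
#' @param em_tol Relative log-likelihood change declaring EM convergence.
#' @param em_max_iter Iteration cap per EM run.
#' @param n_seeds Number of word-based restarts per width (the most frequent
#'   w-mers across both strands of the input).
#' @param seed_iters EM iterations given to each restart before the best
#'   restart is run to convergence.
#' @param pseudocount Added per base in the M-step (regularizes the matrix
#'   and prevents log(0)).
#' @param rng_seed Seed; discovery is deterministic given it.
#' @return A `discovery_params` list.
#' @export
discovery_params <- function(w_min = 6L, w_max = 20L, window = 400L,
                             em_tol = 1e-6, em_max_iter = 500L,
                             n_seeds = 20L, seed_iters = 5L,
                             pseudocount = 0.5, rng_seed = 1L) {
  stopifnot(w_min >= 2, w_min <= w_max, w_max <= window,
            em_tol > 0, em_max_iter >= 1, n_seeds >= 1)
  structure(as.list(environment()), class = "discovery_params")
}

#' Extract summit-centred sequence windows
#'
#' One window per peak, positions `[summit - window/2, summit + window/2 - 1]`
#' (left-inclusive, exactly `window` bases). Windows wrap on circular
#' genomes; on linear genomes out-of-range windows are truncated with a
#' warning.
#'
#' @param peaks A `peak_table`.
#' @param genome A `genome_sequence`.
#' @param window Window width in bp.
#' @return Character vector of uppercase sequences, one per peak.
#' @export
extract_summit_windows <- function(peaks, genome, window = 400L) {
  if (window > genome$length) stop("window wider than the genome")
  half <- window %/% 2L
  vapply(peaks$summit, function(summit) {
    start <- summit - half
    end <- start + window - 1L
    if (!genome$circular && (start < 1L || end > genome$length)) {
      warning("window truncated at a linear genome end (summit ", summit, ")")
      start <- max(start, 1L)
      end <- min(end, genome$length)
    }
    genome_subseq(genome, start, end)
  }, "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

seq_to_int <- function(seq) {
  match(strsplit(seq, "")[[1L]], DNA_BASES)
}

int_revcomp <- function(b) rev(5L - b)

# 0-order background from the input windows, symmetrized over complements so
# that the same model scores both strands (A/T and C/G pooled).
estimate_background <- function(seqs_int) {
  counts <- numeric(4L)
  for (b in seqs_int) counts <- counts + tabulate(b, 4L)
  counts <- counts + rev(counts)  # complement symmetry: A<->T, C<->G
  counts / sum(counts)
}

# reverse-complemented probability (or log-probability) matrix:
# row j <-> row w+1-j, base <-> complement (column 1<->4, 2<->3)
ppm_revcomp <- function(ppm) {
  out <- ppm[rev(seq_len(nrow(ppm))), rev(seq_len(4L)), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Discover one motif by ZOOPS expectation-maximization
#'
#' Fits, for every candidate width, a two-component mixture in which each
#' sequence contains either zero or one motif occurrence (ZOOPS): hidden
#' variables are occurrence, offset and strand; the E-step computes posterior
#' site locations under the current position probability matrix versus a
#' 0-order background estimated from the input; the M-step re-estimates the
#' matrix (with pseudocount) and the site prior. Each width restarts from the
#' most frequent w-mers and the best restart is run to convergence. The final
#' width maximizes the log-likelihood ratio against the pure-background model
#' penalized BIC-style by `3w/2 * log(total scanned positions)`.
#'
#' @param sequences Character vector (>= 2) of ACGT sequences.
#' @param params A [discovery_params()] list.
#' @return A `motif_model`: `width`, `ppm` (w x 4), `background`, `nsites`
#'   (sequences with posterior site probability > 0.5), `site_assignments`
#'   (data frame: sequence index, offset, strand, posterior), `loglik_ratio`,
#'   `evalue_estimate` (a rough restart-corrected transform of the penalized
#'   likelihood ratio, not a MEME E-value), `consensus`, `palindromicity`,
#'   and `significant` (`FALSE` when no width beats the background model).
#' @export
discover_motif_zoops <- function(sequences, params = discovery_params()) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGT]", sequences))) stop("sequences must be ACGT only")
  set.seed(params$rng_seed)
  seqs_int <- lapply(sequences, seq_to_int)
  bg <- estimate_background(seqs_int)
  widths <- seq.int(params$w_min, params$w_max)
  fits <- lapply(widths, function(w) {
    fit_zoops_width(seqs_int, w, bg, params)
  })
  # BIC-style width penalty: 3w free matrix parameters, one observation per
  # sequence (ZOOPS: each sequence contributes at most one site)
  n_obs <- length(seqs_int)
  penalized <- vapply(seq_along(widths), function(i) {
    fits[[i]]$loglik_ratio - 1.5 * widths[i] * log(n_obs)
  }, 0)
  best <- which.max(penalized)
  fit <- fits[[best]]
  w_best <- widths[best]
  # flank trimming: alignment freedom lets uninformative edge columns ride
  # along; drop flanks whose likelihood contribution nsites*KL(col||bg) is
  # below the chi-square(3) 1% critical value, then refit at that width
  keep <- trim_flanks(fit$ppm, bg, max(fit$nsites, 1L), params$w_min)
  if (length(keep) < w_best) {
    pre <- precompute_width(seqs_int, length(keep), bg)
    fit <- run_em(pre, fit$ppm[keep, , drop = FALSE], 0.5, bg, params,
                  max_iter = params$em_max_iter, report = TRUE)
    w_best <- length(keep)
    penalized[best] <- fit$loglik_ratio - 1.5 * w_best * log(n_obs)
  }
  n_starts <- length(widths) * params$n_seeds
  model <- structure(list(
    width = w_best,
    ppm = fit$ppm,
    background = stats::setNames(bg, DNA_BASES),
    nsites = fit$nsites,
    site_assignments = fit$site_assignments,
    loglik_ratio = fit$loglik_ratio,
    penalized_llr = penalized[best],
    evalue_estimate = n_starts * exp(-max(penalized[best], 0)),
    consensus = iupac_consensus(fit$ppm),
    palindromicity = palindromicity_score(fit$ppm),
    significant = penalized[best] > 0
  ), class = "motif_model")
  model
}

# Indices of columns kept after trimming uninformative flanks. A column is
# informative when nsites * KL(column || background) exceeds half the
# chi-square(3 df) 1% critical value, the likelihood-ratio scale on which a
# column's 3 free parameters pay for themselves.
trim_flanks <- function(ppm, bg, nsites, w_min) {
  w <- nrow(ppm)
  contrib <- vapply(seq_len(w), function(j) {
    nsites * sum(ppm[j, ] * log(ppm[j, ] / bg))
  }, 0)
  thr <- stats::qchisq(0.99, df = 3) / 2
  lo <- 1L; hi <- w
  while (lo < hi && contrib[lo] < thr && hi - lo + 1L > w_min) lo <- lo + 1L
  while (hi > lo && contrib[hi] < thr && hi - lo + 1L > w_min) hi <- hi - 1L
  seq.int(lo, hi)
}

# Fit ZOOPS EM at one width: n_seeds word restarts for seed_iters each, the
# best by log likelihood run to convergence.
fit_zoops_width <- function(seqs_int, w, bg, params) {
  pre <- precompute_width(seqs_int, w, bg)
  seeds <- seed_words(seqs_int, w, params$n_seeds)
  runs <- lapply(seeds, function(word) {
    ppm0 <- seed_ppm(word, bg)
    run_em(pre, ppm0, gamma = 0.5, bg, params,
           max_iter = params$seed_iters, report = FALSE)
  })
  best <- which.max(vapply(runs, `[[`, 0, "loglik"))
  run_em(pre, runs[[best]]$ppm, runs[[best]]$gamma, bg, params,
         max_iter = params$em_max_iter, report = TRUE)
}

# Per-sequence, per-width precomputation: linear index matrices into a
# column-major w x 4 log-probability matrix, plus background window scores.
precompute_width <- function(seqs_int, w, bg) {
  log_bg <- log(bg)
  lapply(seqs_int, function(b) {
    m <- length(b) - w + 1L
    if (m < 1L) stop("sequence shorter than motif width")
    idx <- outer(seq_len(m), seq_len(w) - 1L, `+`)   # m x w base positions
    base <- matrix(b[idx], m, w)
    lin <- sweep((base - 1L) * w, 2L, seq_len(w), `+`)  # lp[j + (b-1)*w]
    cs <- c(0, cumsum(log_bg[b]))
    bg_win <- cs[seq_len(m) + w] - cs[seq_len(m)]
    list(m = m, base = base, lin = lin, bg_win = bg_win)
  })
}

# Candidate w-mer starting points: every w-mer in the input (both strands)
# is scored by the summed log-enrichment (observed vs background-expected
# count) of its constituent k-mers (k = 6), so words built from
# over-represented cores rank first even when no two sites are identical.
# Deterministic: ties broken by the word string.
seed_words <- function(seqs_int, w, n, k = 6L) {
  k <- min(k, w)
  strands <- unlist(lapply(seqs_int, function(b) {
    list(b, int_revcomp(b))
  }), recursive = FALSE)
  kmer_codes <- function(b) {
    m <- length(b) - k + 1L
    code <- integer(m)
    for (j in seq_len(k)) code <- code + (b[seq_len(m) + j - 1L] - 1L) * 4L^(j - 1L)
    code + 1L
  }
  codes <- lapply(strands, kmer_codes)
  counts <- tabulate(unlist(codes), 4L^k)
  # expected count of each k-mer under the 0-order composition of the input
  base_tot <- numeric(4L)
  for (b in strands) base_tot <- base_tot + tabulate(b, 4L)
  q <- base_tot / sum(base_tot)
  digits <- function(code) (code - 1L) %/% 4L^(seq_len(k) - 1L) %% 4L + 1L
  logq <- log(q)
  exp_lp <- vapply(seq_len(4L^k), function(cd) sum(logq[digits(cd)]), 0)
  # pseudocount 5 damps the enrichment of rare (AT-rich) words whose
  # expected counts are tiny, which would otherwise swamp true motif cores
  n_pos <- length(unlist(codes))
  enrich <- log((counts + 5) / (n_pos * exp(exp_lp) + 5))
  span <- w - k + 1L
  best <- lapply(seq_along(strands), function(si) {
    e <- enrich[codes[[si]]]
    m_w <- length(strands[[si]]) - w + 1L
    if (m_w < 1L) return(NULL)
    cs <- c(0, cumsum(e))
    score <- cs[seq_len(m_w) + span] - cs[seq_len(m_w)]
    s <- paste(DNA_BASES[strands[[si]]], collapse = "")
    data.frame(word = substring(s, seq_len(m_w), seq_len(m_w) + w - 1L),
               score = score, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, best)
  all <- all[order(-all$score, all$word), , drop = FALSE]
  unique(all$word)[seq_len(min(n, length(unique(all$word))))]
}

seed_ppm <- function(word, bg) {
  b <- seq_to_int(word)
  w <- length(b)
  ppm <- matrix(rep(0.15, 4L * w), w, 4L, dimnames = list(NULL, DNA_BASES))
  ppm[cbind(seq_len(w), b)] <- 0.55
  ppm
}

run_em <- function(pre, ppm, gamma, bg, params, max_iter, report = TRUE) {
  w <- nrow(ppm)
  n <- length(pre)
  pc <- params$pseudocount
  obj_prev <- -Inf
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- log(ppm)
    lp_rc <- log(ppm_revcomp(ppm))
    counts <- matrix(0, w, 4L)
    Q <- numeric(n)
    loglik <- 0
    for (i in seq_len(n)) {
      p <- pre[[i]]
      s_f <- rowSums(matrix(lp[p$lin], p$m, w)) - p$bg_win
      s_r <- rowSums(matrix(lp_rc[p$lin], p$m, w)) - p$bg_win
      off <- log(gamma) - log(2 * p$m)
      z <- logsumexp(c(s_f, s_r)) + off
      logden <- logsumexp(c(log1p(-gamma), z))
      loglik <- loglik + logden
      r_f <- exp(s_f + off - logden)
      r_r <- exp(s_r + off - logden)
      Q[i] <- sum(r_f) + sum(r_r)
      for (b in 1:4) {
        sel <- p$base == b
        cf <- colSums(r_f * sel)
        cr <- colSums(r_r * sel)
        counts[, b] <- counts[, b] + cf
        # a reverse-strand site reads the complement right-to-left
        counts[, 5L - b] <- counts[, 5L - b] + rev(cr)
      }
    }
    # EM guarantee: the (pseudocount-penalized) objective never decreases
    obj <- loglik + pc * sum(lp)
    if (obj < obj_prev - 1e-6 * max(1, abs(obj_prev))) {
      stop("EM objective decreased: ", obj_prev, " -> ", obj)
    }
    converged <- is.finite(obj_prev) &&
      abs(obj - obj_prev) <= params$em_tol * max(1, abs(obj_prev))
    obj_prev <- obj
    ppm <- (counts + pc) / (rowSums(counts) + 4 * pc)
    colnames(ppm) <- DNA_BASES
    gamma <- min(max(mean(pmin(Q, 1)), 1e-6), 1 - 1e-6)
    if (converged) break
  }
  if (!report) {
    return(list(ppm = ppm, gamma = gamma, loglik = loglik))
  }
  # final E-step quantities for reporting
  lp <- log(ppm); lp_rc <- log(ppm_revcomp(ppm))
  assign_rows <- lapply(seq_len(n), function(i) {
    p <- pre[[i]]
    s_f <- rowSums(matrix(lp[p$lin], p$m, w)) - p$bg_win
    s_r <- rowSums(matrix(lp_rc[p$lin], p$m, w)) - p$bg_win
    off <- log(gamma) - log(2 * p$m)
    z <- logsumexp(c(s_f, s_r)) + off
    logden <- logsumexp(c(log1p(-gamma), z))
    q_i <- exp(z - logden)
    best_f <- which.max(s_f); best_r <- which.max(s_r)
    on_fwd <- s_f[best_f] >= s_r[best_r]
    data.frame(sequence = i,
               offset = if (on_fwd) best_f else best_r,
               strand = if (on_fwd) "+" else "-",
               posterior = q_i,
               loglik = logden,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, assign_rows)
  list(ppm = ppm, gamma = gamma, loglik = sum(assignments$loglik),
       loglik_ratio = sum(assignments$loglik),
       nsites = sum(assignments$posterior > 0.5),
       site_assignments = assignments)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf(
    "<motif_model> width %d, %d sites, consensus %s\n  palindromicity %.3f, LLR %.1f%s\n",
    x$width, x$nsites, x$consensus, x$palindromicity, x$loglik_ratio,
    if (x$significant) "" else " (no significant motif)"))
  invisible(x)
}

#' @export
plot.motif_model <- function(x, ...) {
  ic <- apply(x$ppm, 1L, function(p) {
    sum(ifelse(p > 0, p * log2(p / x$background), 0))
  })
  graphics::barplot(ic, names.arg = strsplit(x$consensus, "")[[1L]],
                    ylab = "information (bits)", xlab = "position",
                    main = "motif information content", ...)
  invisible(x)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' IUPAC degenerate consensus of a probability matrix
#'
#' Per column, the set of bases with probability at or above the threshold
#' maps to the IUPAC degenerate code; an empty set falls back to the argmax
#' base. `bracket = TRUE` prints multi-base columns as `[GT]` instead of the
#' one-letter code.
#'
#' @param ppm w x 4 probability matrix (columns ACGT).
#' @param include_threshold Inclusion threshold per base.
#' @param bracket Emit bracketed base sets for degenerate columns.
#' @return Consensus string of length w.
#' @export
iupac_consensus <- function(ppm, include_threshold = 0.25, bracket = FALSE) {
  apply(ppm, 1L, function(p) {
    keep <- DNA_BASES[p >= include_threshold]
    if (!length(keep)) keep <- DNA_BASES[which.max(p)]
    if (length(keep) == 1L) keep else if (bracket) {
      paste0("[", paste(keep, collapse = ""), "]")
    } else {
      IUPAC_CODES[[paste(keep, collapse = "")]]
    }
  }) |> paste(collapse = "")
}

#' Palindromicity of a probability matrix
#'
#' The mean, over columns i, of the probability that a base drawn from
#' column i equals the complement of a base drawn from the mirrored column
#' w+1-i: \eqn{(1/w)\sum_i \sum_b p_{i,b}\, p_{w+1-i,\mathrm{comp}(b)}}.
#' Equals 1 for a deterministic perfect palindrome and
#' \eqn{\sum_b q_b q_{\mathrm{comp}(b)}} (0.25 at uniform q) for
#' background-like columns.
#'
#' @param ppm w x 4 probability matrix (columns ACGT).
#' @return Score in \[0, 1\].
#' @export
palindromicity_score <- function(ppm) {
  w <- nrow(ppm)
  rc <- ppm_revcomp(ppm)
  mean(vapply(seq_len(w), function(i) sum(ppm[i, ] * rc[i, ]), 0))
}
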