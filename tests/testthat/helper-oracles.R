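# Independent oracles and fixture builders, deliberately written as plain,
# slow reference code so they share nothing with the package's vectorized
# implementations.

# 50-term upper-tail Poisson sum: P(X >= k) = sum_{j>=k} e^-l l^j / j!
oracle_poisson_tail <- function(k, lambda, terms = 50L) {
  j <- seq.int(k, k + terms)
  sum(exp(-lambda + j * log(lambda) - lfactorial(j)))
}

# Brute-force PWM score tail probabilities by full word enumeration.
oracle_word_pvalue <- function(kmat, background, kscore) {
  w <- nrow(kmat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  total <- 0
  for (r in seq_len(nrow(words))) {
    s <- 0
    for (j in seq_len(w)) s <- s + kmat[j, words[r, j]]
    if (s >= kscore) total <- total + prod(background[words[r, ]])
  }
  total
}

# Plain-loop reimplementation of the peak caller on a circular genome,
# following the published procedure step by step.
oracle_call_peaks <- function(ip, ctl, params) {
  L <- length(ip)
  scale <- sum(ip) / sum(ctl)
  w <- params$window_size
  circ_sum <- function(track, s, e) {
    idx <- ((s:e - 1) %% L) + 1
    sum(track[idx])
  }
  genome_rate <- sum(ctl) * scale / L
  lambda_at <- function(s, e) {
    mid <- (s + e) / 2
    rate <- genome_rate
    for (span in params$local_lambda_spans) {
      a <- ceiling(mid - span / 2)
      b <- a + span - 1
      rate <- max(rate, circ_sum(ctl, a, b) * scale / span)
    }
    rate * w
  }
  starts <- seq(1, L, by = params$step)
  kept <- list()
  for (s in starts) {
    e <- s + w - 1
    k <- circ_sum(ip, s, e)
    lam <- lambda_at(s, e)
    score <- -10 * stats::ppois(k - 1, lam, lower.tail = FALSE,
                                log.p = TRUE) / log(10)
    if (score > params$score_min) kept[[length(kept) + 1]] <- c(s, e)
  }
  if (!length(kept)) return(data.frame(start = integer(), end = integer(),
                                       summit = integer(), fold = numeric()))
  regions <- list(kept[[1]])
  for (i in seq_along(kept)[-1]) {
    last <- regions[[length(regions)]]
    if (kept[[i]][1] <= last[2] + params$merge_gap + 1) {
      regions[[length(regions)]][2] <- max(last[2], kept[[i]][2])
    } else {
      regions[[length(regions) + 1]] <- kept[[i]]
    }
  }
  if (length(regions) > 1) {
    last <- regions[[length(regions)]]
    if (last[2] > L && regions[[1]][1] + L <= last[2] + params$merge_gap + 1) {
      regions[[1]] <- c(last[1], max(last[2], regions[[1]][2] + L))
      regions[[length(regions)]] <- NULL
    }
  }
  rows <- lapply(regions, function(r) {
    pos <- r[1]:r[2]
    cov <- ip[((pos - 1) %% L) + 1]
    summit <- pos[which.max(cov)]
    sw_s <- summit - w %/% 2
    sw_e <- sw_s + w - 1
    k <- circ_sum(ip, sw_s, sw_e)
    lam <- lambda_at(sw_s, sw_e)
    data.frame(start = r[1], end = r[2], summit = summit, fold = k / lam)
  })
  out <- do.call(rbind, rows)
  out <- out[out$fold > params$fold_min, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# 400-bp GC-rich window with one site planted at a random offset.
make_window_with_site <- function(site, window = 400, gc = 0.72) {
  b <- sample(c("A", "C", "G", "T"), window, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  o <- sample(seq_len(window - nchar(site) + 1), 1)
  b[o:(o + nchar(site) - 1)] <- strsplit(site, "")[[1]]
  paste(b, collapse = "")
}

random_window <- function(window = 400, gc = 0.72) {
  paste(sample(c("A", "C", "G", "T"), window, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Majority-rule consensus of aligned sites with N at columns where the top
# base is below the majority fraction.
oracle_majority_consensus <- function(sites, majority = 0.5) {
  mat <- do.call(rbind, strsplit(sites, ""))
  paste(apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) >= majority) names(tab)[1] else "N"
  }), collapse = "")
}

# Hamming distance ignoring N positions in the reference.
hamming_vs_consensus <- function(x, ref) {
  xs <- strsplit(x, "")[[1]]
  rs <- strsplit(ref, "")[[1]]
  sum(xs != rs & rs != "N")
}

# Small three-gene annotation used across annotation tests:
#   geneA + strand, start 10000, operon with geneB;
#   geneC - strand, start 8000 (facing geneA across an intergenic region)
toy_genes <- function() {
  data.frame(
    locus_tag = c("geneA", "geneB", "geneC"),
    gene_name = NA_character_,
    strand = c("+", "+", "-"),
    start_codon = c(10000L, 11000L, 8000L),
    end = c(10900L, 11900L, 7200L),
    tu_id = c("tuAB", "tuAB", "tuC"),
    stringsAsFactors = FALSE
  )
}
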