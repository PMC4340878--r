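#' Upper-tail Poisson p-value and enrichment score
#'
#' `poisson_tail_pvalue(k, lambda)` returns \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Poisson}(\lambda)}; `peak_score()` is the companion
#' \eqn{-10\log_{10}(p)} score used to rank and filter enriched windows
#' (score > 100 is equivalent to p < 1e-10). Both are computed in log space
#' so deeply enriched windows do not underflow to score `Inf`.
#'
#' @param k Non-negative integer count(s) observed.
#' @param lambda Positive expected count(s) under the background model.
#' @return `poisson_tail_pvalue`: p-value(s) in (0, 1]. `peak_score`: the
#'   corresponding score(s), 0 when `k = 0`.
#' @examples
#' poisson_tail_pvalue(0, 5)   # 1
#' peak_score(10, 2)           # ~43.4
#' @export
poisson_tail_pvalue <- function(k, lambda) {
  check_poisson_args(k, lambda)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' @rdname poisson_tail_pvalue
#' @export
peak_score <- function(k, lambda) {
  check_poisson_args(k, lambda)
  logp <- stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  -10 * logp / log(10)
}

check_poisson_args <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  invisible(TRUE)
}

#' Peak-calling parameters
#'
#' Defaults implement the stringent cutoffs used for the NdgR regulon:
#' retained windows must have \eqn{-10\log_{10}(p) > 100} (p < 1e-10) and
#' summit fold enrichment > 3.
#'
#' @param window_size Sliding-window width in bp.
#' @param step Window step in bp (`window_size >= step`).
#' @param score_min Minimum \eqn{-10\log_{10}(p)} score (exclusive).
#' @param fold_min Minimum fold enrichment (exclusive).
#' @param local_lambda_spans Spans (bp) over which the local background rate
#'   is estimated; the genome-wide rate is always included as a floor.
#' @param merge_gap Retained windows closer than this many bp are merged
#'   into one peak.
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(window_size = 300L, step = 50L,
                             score_min = 100, fold_min = 3,
                             local_lambda_spans = c(1000L, 5000L, 10000L),
                             merge_gap = 100L) {
  stopifnot(score_min >= 0, fold_min >= 1, window_size >= step, step >= 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 score_min = score_min, fold_min = fold_min,
                 local_lambda_spans = as.integer(local_lambda_spans),
                 merge_gap = as.integer(merge_gap)),
            class = "peak_call_params")
}

# Sum of track over [start, end] (1-based inclusive) with optional circular
# wrap, via a cumulative-sum lookup. cs = c(0, cumsum(track)).
window_sums <- function(cs, starts, ends, L, circular) {
  starts0 <- starts; ends0 <- ends
  if (circular) {
    total <- cs[L + 1L]
    starts <- ((starts - 1L) %% L) + 1L
    ends <- ((ends - 1L) %% L) + 1L
    wrap <- ends < starts
    out <- numeric(length(starts))
    out[!wrap] <- cs[ends[!wrap] + 1L] - cs[starts[!wrap]]
    out[wrap] <- (total - cs[starts[wrap]]) + cs[ends[wrap] + 1L]
    out
  } else {
    starts <- pmax(starts0, 1L); ends <- pmin(ends0, L)
    bad <- ends < starts
    out <- cs[pmax(ends, 1L) + 1L] - cs[pmin(starts, L + 1L)]
    out[bad] <- 0
    out
  }
}

# Effective bp covered by a clipped span on a linear genome (for rate
# estimation the sum must be divided by the bases actually covered).
span_widths <- function(starts, ends, L, circular) {
  if (circular) {
    pmin(ends - starts + 1L, L)
  } else {
    pmax(pmin(ends, L) - pmax(starts, 1L) + 1L, 0L)
  }
}

#' Call enriched peaks from IP and control coverage
#'
#' Slides windows across the genome, scores each window's IP count against a
#' MACS-style local Poisson background (the maximum over several spans of the
#' library-size-scaled control rate, floored by the genome-wide rate), keeps
#' windows with `score > score_min`, merges retained windows within
#' `merge_gap`, places the summit at the leftmost maximum of IP coverage
#' inside each merged region, and finally drops peaks whose summit-window
#' fold enrichment is not greater than `fold_min`.
#'
#' @param ip_track,control_track Per-base count vectors of equal length.
#' @param params A [peak_call_params()] list.
#' @param circular Should windows wrap around the origin?
#' @return A `peak_table` data frame sorted by coordinate, with one row per
#'   peak (`start`, `end`, `summit`, `score`, `fold_enrichment`; motif
#'   columns `NA` until a motif stage fills them).
#' @export
call_peaks <- function(ip_track, control_track, params = peak_call_params(),
                       circular = TRUE) {
  L <- length(ip_track)
  if (L == 0L || length(control_track) != L) {
    stop("IP and control tracks must be non-empty and of equal length")
  }
  total_ip <- sum(ip_track)
  total_ctl <- sum(control_track)
  if (total_ip <= 0) stop("IP track has zero total coverage")
  if (total_ctl <= 0) {
    warning("all-zero control track; falling back to the genome-wide IP rate")
    control_scaled <- rep(total_ip / L, L)
  } else {
    control_scaled <- control_track * (total_ip / total_ctl)
  }
  w <- params$window_size
  starts <- seq.int(1L, if (circular) L else max(L - w + 1L, 1L),
                    by = params$step)
  ends <- starts + w - 1L
  cs_ip <- c(0, cumsum(as.numeric(ip_track)))
  cs_ctl <- c(0, cumsum(control_scaled))

  ip_counts <- window_sums(cs_ip, starts, ends, L, circular)
  lambda <- local_lambda(cs_ctl, starts, ends, L, circular, params)
  score <- peak_score(round(ip_counts), lambda)

  keep <- which(score > params$score_min)
  if (!length(keep)) return(empty_peak_table())

  regions <- merge_windows(starts[keep], ends[keep], params$merge_gap, L,
                           circular)
  peaks <- lapply(regions, function(r) {
    summit <- region_summit(ip_track, r[1L], r[2L], L)
    sw_start <- summit - w %/% 2L
    sw_end <- sw_start + w - 1L
    k <- window_sums(cs_ip, sw_start, sw_end, L, circular)
    lam <- local_lambda(cs_ctl, sw_start, sw_end, L, circular, params)
    eff_w <- span_widths(sw_start, sw_end, L, circular)
    data.frame(start = r[1L], end = r[2L],
               summit = summit,
               score = peak_score(round(k), lam),
               fold_enrichment = k / lam * (w / eff_w),
               motif_start = NA_integer_, motif_end = NA_integer_,
               motif_seq = NA_character_, stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, peaks)
  peaks <- peaks[peaks$fold_enrichment > params$fold_min, , drop = FALSE]
  if (!nrow(peaks)) return(empty_peak_table())
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  validate_peaks(peaks)
}

empty_peak_table <- function() {
  validate_peaks(data.frame(
    start = integer(), end = integer(), summit = integer(),
    score = numeric(), fold_enrichment = numeric(),
    motif_start = integer(), motif_end = integer(),
    motif_seq = character(), stringsAsFactors = FALSE))
}

wrap_coord <- function(x, L) ((x - 1L) %% L) + 1L

# Expected count for windows [starts, ends]: max over configured spans
# (centered on the window) of the scaled-control mean rate, floored by the
# genome-wide rate, times the window width.
local_lambda <- function(cs_ctl, starts, ends, L, circular, params) {
  w <- params$window_size
  mid <- (starts + ends) / 2
  genome_rate <- cs_ctl[L + 1L] / L
  rate <- rep(genome_rate, length(starts))
  for (span in params$local_lambda_spans) {
    s <- as.integer(ceiling(mid - span / 2))
    e <- s + span - 1L
    sums <- window_sums(cs_ctl, s, e, L, circular)
    widths <- span_widths(s, e, L, circular)
    rate <- pmax(rate, ifelse(widths > 0, sums / widths, 0))
  }
  rate * pmin(w, ends - starts + 1L)
}

# Merge sorted candidate windows whose gaps are <= merge_gap; on circular
# genomes a last region reaching past the origin (end > L) is joined with a
# first region it overlaps/abuts, and the merged region keeps unwrapped
# coordinates (end may exceed L for an origin-spanning peak).
merge_windows <- function(starts, ends, merge_gap, L, circular) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  regions <- list(c(starts[1L], ends[1L]))
  for (i in seq_along(starts)[-1L]) {
    last <- regions[[length(regions)]]
    if (starts[i] <= last[2L] + merge_gap + 1L) {
      regions[[length(regions)]][2L] <- max(last[2L], ends[i])
    } else {
      regions[[length(regions) + 1L]] <- c(starts[i], ends[i])
    }
  }
  if (circular && length(regions) > 1L) {
    first <- regions[[1L]]; last <- regions[[length(regions)]]
    if (last[2L] > L && first[1L] + L <= last[2L] + merge_gap + 1L) {
      regions[[1L]] <- c(last[1L], max(last[2L], first[2L] + L))
      regions[[length(regions)]] <- NULL
    }
  }
  regions
}

# Leftmost position (in the region's own, possibly unwrapped, coordinates)
# of maximal IP coverage within [start, end].
region_summit <- function(ip_track, start, end, L) {
  pos <- seq.int(start, end)
  idx <- ((pos - 1L) %% L) + 1L
  pos[which.max(ip_track[idx])]
}

#' Apply the peak score/fold filters to an existing peak table
#'
#' @param peaks A `peak_table`.
#' @param score_min,fold_min Exclusive cutoffs (defaults as in
#'   [peak_call_params()]).
#' @return The rows passing both filters.
#' @export
filter_peaks <- function(peaks, score_min = 100, fold_min = 3) {
  out <- peaks[peaks$score > score_min & peaks$fold_enrichment > fold_min, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
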