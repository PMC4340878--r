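#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes a target gene's qPCR cycle threshold against a reference
#' (housekeeping) gene and a calibrator sample:
#' `fold = efficiency^-((ct_target - ct_reference) -
#' (ct_target_calibrator - ct_reference_calibrator))`, with perfect
#' amplification efficiency 2 by default.
#'
#' @param ct_target,ct_reference Cycle values of the target and reference
#'   gene in the sample (vectors recycle elementwise).
#' @param ct_target_calibrator,ct_reference_calibrator Cycle values in the
#'   calibrator (control) sample.
#' @param efficiency Amplification efficiency per cycle.
#' @return Normalized fold value(s); 1 when the sample equals the
#'   calibrator.
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_calibrator,
                                ct_reference_calibrator,
                                efficiency = 2) {
  if (missing(ct_target_calibrator) || missing(ct_reference_calibrator)) {
    stop("calibrator cycle values are required")
  }
  stopifnot(all(is.finite(c(ct_target, ct_reference,
                            ct_target_calibrator, ct_reference_calibrator))))
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  efficiency^(-ddct)
}

geometric_mean <- function(x) exp(mean(log(x)))

cell_stats <- function(design) {
  cells <- expand.grid(D = 0:1, N = 0:1)
  means <- numeric(4L)
  cvs <- numeric(4L)
  for (j in seq_len(nrow(cells))) {
    v <- design$value[design$D == cells$D[j] & design$N == cells$N[j]]
    if (!length(v)) {
      stop("missing factorial cell (D=", cells$D[j], ", N=", cells$N[j], ")")
    }
    if (any(v <= 0)) stop("expression values must be > 0")
    means[j] <- geometric_mean(v)
    cvs[j] <- if (length(v) > 1L) stats::sd(v) / mean(v) else 0
  }
  if (any(means == 0)) stop("zero cell mean")
  list(cells = cells, means = means, cvs = cvs)
}

#' Classify the feed-forward-loop logic of a 2x2 factorial design
#'
#' Takes replicated normalized expression of one target gene under the four
#' combinations of stress (D) and regulator genotype (N), binarizes the cell
#' means against `theta` times the (0,0) baseline, infers the signs of the
#' D->target and N->target edges from `alpha`-fold contrasts (the N edge is
#' judged primarily under stress, falling back to the unstressed contrast),
#' and labels the circuit: both edges activating is a coherent type-1
#' feed-forward loop (C1-FFL, with an OR or AND gate read off the truth
#' table); an activating D edge with a repressing N edge is an incoherent
#' type-1 loop (I1-FFL). The stress->regulator edge is taken as activating,
#' established independently of this data.
#'
#' @param design Data frame with columns `D`, `N` (0/1) and `value`
#'   (replicated normalized expression, baseline cell (0,0) centred at 1);
#'   a `gene` column, if present, must be constant.
#' @param theta ON threshold: cell is ON when its mean is at least
#'   `theta` times the (0,0) mean.
#' @param alpha Fold change declaring an edge sign.
#' @param max_cv Replicate coefficient of variation above which the result
#'   is flagged low-confidence.
#' @return An `ffl_classification`: `gene`, `cell_means`, `truth_table`,
#'   `edge_signs` (`D` and `N`, each `"+"`, `"-"` or `"0"`), `ffl_type`
#'   (`"C1-FFL"`, `"I1-FFL"`, `"not-FFL"`), `gate` (`"OR"`, `"AND"`,
#'   `"undetermined"`; coherent loops only), `low_confidence`.
#' @export
classify_ffl <- function(design, theta = 2, alpha = 2, max_cv = 0.75) {
  gene <- if (!is.null(design$gene)) {
    g <- unique(design$gene)
    if (length(g) != 1L) stop("classify_ffl expects one gene at a time")
    g
  } else NA_character_
  st <- cell_stats(design)
  m <- st$means
  names(m) <- sprintf("D%d_N%d", st$cells$D, st$cells$N)
  e00 <- m[["D0_N0"]]; e01 <- m[["D0_N1"]]
  e10 <- m[["D1_N0"]]; e11 <- m[["D1_N1"]]

  truth <- stats::setNames(as.integer(m >= theta * e00), names(m))

  d_sign <- if (e10 >= alpha * e00 || e11 >= alpha * e01) "+"
    else if (e10 <= e00 / alpha || e11 <= e01 / alpha) "-"
    else "0"
  n_sign <- if (e11 >= alpha * e10) "+"
    else if (e11 <= e10 / alpha) "-"
    else if (e01 >= alpha * e00) "+"
    else if (e01 <= e00 / alpha) "-"
    else "0"

  ffl_type <- if (d_sign == "+" && n_sign == "+") "C1-FFL"
    else if (d_sign == "+" && n_sign == "-") "I1-FFL"
    else "not-FFL"
  gate <- if (ffl_type == "C1-FFL") {
    if (truth[["D1_N0"]] == 1L && truth[["D0_N1"]] == 1L) "OR"
    else if (truth[["D1_N1"]] == 1L && truth[["D1_N0"]] == 0L &&
             truth[["D0_N1"]] == 0L) "AND"
    else "undetermined"
  } else NA_character_

  structure(list(gene = gene, cell_means = m, truth_table = truth,
                 edge_signs = c(D = d_sign, N = n_sign),
                 ffl_type = ffl_type, gate = gate,
                 low_confidence = any(st$cvs > max_cv)),
            class = "ffl_classification")
}

#' @export
print.ffl_classification <- function(x, ...) {
  cat(sprintf("<ffl_classification> %s: %s%s  edges D%s N%s%s\n",
              if (is.na(x$gene)) "(gene)" else x$gene,
              x$ffl_type,
              if (!is.na(x$gate)) paste0(" (", x$gate, " gate)") else "",
              x$edge_signs[["D"]], x$edge_signs[["N"]],
              if (x$low_confidence) "  [low confidence]" else ""))
  cat("  cell means:",
      paste(sprintf("%s=%.3g", names(x$cell_means), x$cell_means),
            collapse = "  "), "\n")
  invisible(x)
}

#' Classify every gene in a factorial expression table
#'
#' @param expr Long data frame with columns `gene`, `D`, `N`, `replicate`,
#'   `value` (as produced by [simulate_expression()]).
#' @param ... Passed to [classify_ffl()].
#' @return A data frame with one row per gene: `gene`, `ffl_type`, `gate`,
#'   `edge_D`, `edge_N`, `low_confidence`.
#' @export
classify_ffl_table <- function(expr, ...) {
  genes <- unique(expr$gene)
  rows <- lapply(genes, function(g) {
    cls <- classify_ffl(expr[expr$gene == g, , drop = FALSE], ...)
    data.frame(gene = g, ffl_type = cls$ffl_type,
               gate = ifelse(is.na(cls$gate), "", cls$gate),
               edge_D = cls$edge_signs[["D"]],
               edge_N = cls$edge_signs[["N"]],
               low_confidence = cls$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
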