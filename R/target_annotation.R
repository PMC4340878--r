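#' Summit-annotation parameters
#'
#' Distance rules for assigning a peak summit to genes, all measured along
#' each gene's own strand from its annotated start codon. A gene is called
#' directly regulated when the summit lies at most `upstream_max` bp upstream
#' or `downstream_max` bp downstream of its start codon (bounds inclusive).
#' A summit matching no gene that way is annotated intragenic when it sits
#' inside a gene body at least `intragenic_min_from_start` bp past the start
#' codon and at least `intragenic_min_to_next` bp upstream of the next
#' downstream start codon.
#'
#' @param upstream_max,downstream_max,intragenic_min_from_start,intragenic_min_to_next
#'   Distances in bp, all non-negative.
#' @return An `annotation_params` list.
#' @export
annotation_params <- function(upstream_max = 500L, downstream_max = 100L,
                              intragenic_min_from_start = 100L,
                              intragenic_min_to_next = 500L) {
  stopifnot(upstream_max >= 0, downstream_max >= 0,
            intragenic_min_from_start >= 0, intragenic_min_to_next >= 0)
  structure(list(upstream_max = as.integer(upstream_max),
                 downstream_max = as.integer(downstream_max),
                 intragenic_min_from_start = as.integer(intragenic_min_from_start),
                 intragenic_min_to_next = as.integer(intragenic_min_to_next)),
            class = "annotation_params")
}

# Signed distance from a gene's start codon to the summit, measured along
# the gene's strand: negative = upstream of the start codon.
signed_distance <- function(summit, start_codon, strand) {
  ifelse(strand == "+", summit - start_codon, start_codon - summit)
}

#' Classify a peak summit against the gene models
#'
#' Applies the two distance rules (see [annotation_params()]); the upstream
#' rule takes precedence over the intragenic rule. When genes on opposite
#' strands both match one shared intergenic summit, all matches are returned
#' with `divergent_flag = TRUE` (a divergent promoter).
#'
#' @param summit 1-based summit coordinate.
#' @param genes Gene-model data frame (see [load_annotation()]).
#' @param params An [annotation_params()] list.
#' @param genome_length Optional; when given, summits are validated against
#'   it and wrapped into range on circular genomes.
#' @param circular Wrap out-of-range summits instead of erroring.
#' @return A data frame of assignments: `locus_tag`, `category`
#'   (`"upstream"`, `"intragenic"`, or `"none"`), `divergent_flag`,
#'   `signed_distance`. A summit matching nothing yields one `"none"` row
#'   with `locus_tag = NA`.
#' @export
classify_summit <- function(summit, genes, params = annotation_params(),
                            genome_length = NULL, circular = TRUE) {
  if (!is.null(genome_length)) {
    if (circular) {
      summit <- ((summit - 1L) %% genome_length) + 1L
    } else if (summit < 1L || summit > genome_length) {
      stop("summit ", summit, " outside genome of length ", genome_length)
    }
  }
  d <- signed_distance(summit, genes$start_codon, genes$strand)
  hit <- which(d >= -params$upstream_max & d <= params$downstream_max)
  if (length(hit)) {
    divergent <- length(hit) > 1L &&
      length(unique(genes$strand[hit])) == 2L
    return(data.frame(locus_tag = genes$locus_tag[hit],
                      category = "upstream",
                      divergent_flag = divergent,
                      signed_distance = d[hit],
                      stringsAsFactors = FALSE))
  }
  # intragenic rule: summit inside a gene body, far enough from its start,
  # far enough upstream of the next downstream start codon
  lo <- pmin(genes$start_codon, genes$end)
  hi <- pmax(genes$start_codon, genes$end)
  inside <- which(summit >= lo & summit <= hi)
  for (g in inside) {
    from_start <- d[g]
    if (from_start < params$intragenic_min_from_start) next
    downstream <- if (genes$strand[g] == "+") {
      cand <- genes$start_codon[genes$start_codon > summit]
      if (length(cand)) min(cand) - summit else Inf
    } else {
      cand <- genes$start_codon[genes$start_codon < summit]
      if (length(cand)) summit - max(cand) else Inf
    }
    if (downstream >= params$intragenic_min_to_next) {
      return(data.frame(locus_tag = genes$locus_tag[g],
                        category = "intragenic",
                        divergent_flag = FALSE,
                        signed_distance = from_start,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(locus_tag = NA_character_, category = "none",
             divergent_flag = FALSE, signed_distance = NA_real_,
             stringsAsFactors = FALSE)
}

#' Build the regulon table from called peaks
#'
#' Classifies every peak summit, marks each upstream-matched gene as a
#' direct target, expands direct hits through the gene's transcription unit
#' (every gene downstream of it in transcription order becomes an operon
#' member), and flags intragenic hits (which attribute only the containing
#' gene, with no operon expansion). Records are deduplicated by locus tag
#' with evidence flags merged, and ordered by locus tag, so the output is
#' independent of peak order.
#'
#' @param peaks A `peak_table`.
#' @param genes,tus Gene models and transcription units (see
#'   [load_annotation()]).
#' @param params An [annotation_params()] list.
#' @param genome_length,circular Passed to [classify_summit()].
#' @return A data frame with one row per regulon gene: `locus_tag`,
#'   `gene_name`, logical flags `direct`, `intragenic`, `divergent`,
#'   `operon_member`, a printable `note` (`"*"`, `"I"`, `"D"` combinations),
#'   and `source_peaks` (comma-separated indices into `peaks`). Peaks
#'   matching no gene are reported in the `"unassigned"` attribute.
#' @export
build_regulon <- function(peaks, genes, tus, params = annotation_params(),
                          genome_length = NULL, circular = TRUE) {
  records <- list()
  unassigned <- integer()
  add_record <- function(locus, direct, intragenic, divergent, operon, peak_i) {
    prev <- records[[locus]]
    if (is.null(prev)) {
      prev <- list(direct = FALSE, intragenic = FALSE, divergent = FALSE,
                   operon_member = FALSE, peaks = integer())
    }
    records[[locus]] <<- list(
      direct = prev$direct || direct,
      intragenic = prev$intragenic || intragenic,
      divergent = prev$divergent || divergent,
      operon_member = prev$operon_member || operon,
      peaks = sort(unique(c(prev$peaks, peak_i)))
    )
  }
  tu_downstream <- function(locus) {
    tu_id <- genes$tu_id[match(locus, genes$locus_tag)]
    ord <- tus$gene_order[[match(tu_id, tus$tu_id)]]
    ord[seq_along(ord) > match(locus, ord)]
  }
  for (i in seq_len(nrow(peaks))) {
    asn <- classify_summit(peaks$summit[i], genes, params,
                           genome_length = genome_length, circular = circular)
    if (all(asn$category == "none")) {
      unassigned <- c(unassigned, i)
      next
    }
    for (j in seq_len(nrow(asn))) {
      locus <- asn$locus_tag[j]
      if (asn$category[j] == "upstream") {
        add_record(locus, direct = TRUE, intragenic = FALSE,
                   divergent = asn$divergent_flag[j], operon = FALSE, i)
        for (member in tu_downstream(locus)) {
          add_record(member, direct = FALSE, intragenic = FALSE,
                     divergent = FALSE, operon = TRUE, i)
        }
      } else if (asn$category[j] == "intragenic") {
        add_record(locus, direct = TRUE, intragenic = TRUE,
                   divergent = FALSE, operon = FALSE, i)
      }
    }
  }
  loci <- sort(names(records))
  out <- data.frame(
    locus_tag = loci,
    gene_name = genes$gene_name[match(loci, genes$locus_tag)],
    direct = vapply(records[loci], `[[`, TRUE, "direct"),
    intragenic = vapply(records[loci], `[[`, TRUE, "intragenic"),
    divergent = vapply(records[loci], `[[`, TRUE, "divergent"),
    operon_member = vapply(records[loci], function(r) {
      r$operon_member && !r$direct
    }, TRUE),
    source_peaks = vapply(records[loci], function(r) {
      paste(r$peaks, collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  out$note <- regulon_note(out)
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}

regulon_note <- function(regulon) {
  vapply(seq_len(nrow(regulon)), function(i) {
    flags <- c(if (regulon$direct[i]) "*",
               if (regulon$intragenic[i]) "I",
               if (regulon$divergent[i]) "D")
    paste(flags, collapse = ", ")
  }, "")
}

#' Write a regulon table as TSV
#' @param regulon Output of [build_regulon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulon <- function(regulon, path) {
  utils::write.table(
    regulon[c("locus_tag", "gene_name", "note", "source_peaks")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
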