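#' Construct a genome sequence object
#'
#' A `genome_sequence` is the coordinate frame for every other object in the
#' package: a single bacterial chromosome stored as an ACGT string with
#' 1-based inclusive coordinates. Circular genomes wrap all interval
#' arithmetic modulo the genome length.
#'
#' @param sequence Character scalar over the alphabet ACGT (lower case is
#'   uppercased). Characters outside ACGT, including N, are rejected.
#' @param name Sequence identifier used as the chromosome name in BED and
#'   bedGraph output.
#' @param circular Logical; should coordinate arithmetic wrap around the
#'   origin? Defaults to `TRUE` (bacterial chromosome convention used by the
#'   simulator; set `FALSE` for genuinely linear chromosomes).
#' @return An object of class `genome_sequence` with fields `name`,
#'   `sequence`, `circular` and `length`.
#' @export
genome_sequence <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- gregexpr("[^ACGT]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop("non-ACGT character '", substr(sequence, bad[1L], bad[1L]),
         "' at position ", bad[1L])
  }
  structure(
    list(name = name, sequence = sequence, circular = isTRUE(circular),
         length = nchar(sequence)),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  gc <- gc_fraction(x)
  cat(sprintf("<genome_sequence> %s: %d bp, %s, GC %.1f%%\n",
              x$name, x$length, if (x$circular) "circular" else "linear",
              100 * gc))
  invisible(x)
}

#' GC fraction of a genome
#' @param genome A `genome_sequence`.
#' @return Fraction of G+C bases in (0,1).
#' @export
gc_fraction <- function(genome) {
  counts <- base_counts(genome$sequence)
  (counts[["C"]] + counts[["G"]]) / sum(counts)
}

base_counts <- function(sequence) {
  tab <- table(factor(strsplit(sequence, "")[[1L]], levels = DNA_BASES))
  as.vector(tab) |> stats::setNames(DNA_BASES)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Extract a subsequence with circular wrapping
#'
#' Coordinates are 1-based inclusive. On a circular genome, `end` may exceed
#' the genome length (or `start` drop below 1); the extracted sequence wraps
#' across the origin. On a linear genome out-of-range coordinates are an
#' error.
#'
#' @param genome A `genome_sequence`.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Character scalar of length `end - start + 1`.
#' @export
genome_subseq <- function(genome, start, end) {
  stopifnot(start <= end)
  L <- genome$length
  if (end - start + 1 > L) stop("requested window longer than the genome")
  if (start >= 1 && end <= L) {
    return(substr(genome$sequence, start, end))
  }
  if (!genome$circular) {
    stop("coordinates [", start, ",", end, "] outside linear genome of length ", L)
  }
  idx <- ((seq.int(start, end) - 1L) %% L) + 1L
  paste(strsplit(genome$sequence, "")[[1L]][idx], collapse = "")
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a FASTA file. A bacterial chromosome is expected, so a
#'   multi-record file is an error unless `record` names the wanted record.
#' @param circular Passed to [genome_sequence()].
#' @param record Optional record name selecting one sequence from a
#'   multi-record file.
#' @return A validated `genome_sequence`; input is uppercased.
#' @export
load_genome <- function(path, circular = TRUE, record = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  if (is.null(record)) {
    if (length(set) > 1L) {
      stop("FASTA has ", length(set),
           " records; select one with `record=`")
    }
    record <- names(set)[1L]
  }
  record_name <- sub("\\s.*$", "", record)
  hit <- which(sub("\\s.*$", "", names(set)) == record_name)
  if (length(hit) != 1L) stop("record '", record, "' not found in ", path)
  seq <- as.character(set[[hit]])
  genome_sequence(seq, name = record_name, circular = circular)
}

#' Write a genome to FASTA
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models and transcription units
#'
#' Accepts either a tab-separated gene table with columns `locus_tag`,
#' `gene_name`, `strand`, `start_codon`, `end`, `tu_id`, or a minimal GFF3
#' file whose `gene` features carry `locus_tag` (or `ID`) and `tu_id`
#' attributes. `start_codon` is always the translation-start base, so it is
#' numerically greater than `end` for minus-strand genes.
#'
#' @param path Path to the annotation file.
#' @return A list with `genes` (data frame, one row per gene) and `tus`
#'   (data frame with `tu_id`, `strand`, and a `gene_order` list column of
#'   locus tags in transcription order).
#' @export
load_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  genes <- if (grepl("^##gff-version", first)) {
    parse_gff3_genes(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus_tag", "strand", "start_codon", "end", "tu_id")
    missing <- setdiff(need, names(df))
    if (length(missing)) stop("annotation missing columns: ",
                              paste(missing, collapse = ", "))
    if (is.null(df$gene_name)) df$gene_name <- NA_character_
    df[c("locus_tag", "gene_name", "strand", "start_codon", "end", "tu_id")]
  }
  validate_annotation(genes)
}

parse_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- Filter(function(f) length(f) == 9L && f[[3L]] == "gene", fields)
  if (!length(rows)) stop("no gene features in ", path)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) == 2L) m[[2L]] else NA_character_
  }
  genes <- do.call(rbind, lapply(rows, function(f) {
    a <- f[[9L]]
    locus <- attr_get(a, "locus_tag")
    if (is.na(locus)) locus <- attr_get(a, "ID")
    strand <- f[[7L]]
    lo <- as.integer(f[[4L]]); hi <- as.integer(f[[5L]])
    data.frame(
      locus_tag = locus,
      gene_name = attr_get(a, "gene_name"),
      strand = strand,
      start_codon = if (strand == "+") lo else hi,
      end = if (strand == "+") hi else lo,
      tu_id = attr_get(a, "tu_id"),
      stringsAsFactors = FALSE
    )
  }))
  genes
}

#' Validate gene models and derive transcription units
#'
#' Checks locus-tag uniqueness, start/end orientation per strand, and strand
#' consistency within each transcription unit, then orders each unit's genes
#' in transcription order (ascending start codons on `+`, descending on `-`).
#'
#' @param genes Data frame with the gene-table columns (see
#'   [load_annotation()]).
#' @return A list with validated `genes` and derived `tus`.
#' @export
validate_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$locus_tag)) {
    stop("duplicate locus_tag: ",
         paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  if (any(plus & genes$start_codon >= genes$end)) {
    stop("plus-strand gene with start_codon >= end: ",
         genes$locus_tag[which(plus & genes$start_codon >= genes$end)[1L]])
  }
  if (any(!plus & genes$start_codon <= genes$end)) {
    stop("minus-strand gene with start_codon <= end: ",
         genes$locus_tag[which(!plus & genes$start_codon <= genes$end)[1L]])
  }
  tu_rows <- split(seq_len(nrow(genes)), genes$tu_id)
  tu_ids <- names(tu_rows)
  strands <- character(length(tu_ids))
  orders <- vector("list", length(tu_ids))
  for (i in seq_along(tu_ids)) {
    idx <- tu_rows[[i]]
    s <- unique(genes$strand[idx])
    if (length(s) != 1L) stop("transcription unit ", tu_ids[i], " mixes strands")
    strands[i] <- s
    orders[[i]] <- genes$locus_tag[idx][
      order(genes$start_codon[idx], decreasing = s == "-")]
  }
  tus <- data.frame(tu_id = tu_ids, strand = strands, stringsAsFactors = FALSE)
  tus$gene_order <- orders
  list(genes = genes, tus = tus)
}

#' Write a gene table
#' @param genes Gene-model data frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table
#'
#' Parses the tab-separated peak dialect used for the packaged NdgR binding
#' regions: interval columns are printed as `"start-end"`, the score column
#' is \eqn{-10 \log_{10}(p)}, and `"N.A."` is the only recognized
#' missing-value token (absent motif).
#'
#' @param path Path to the TSV.
#' @return A `peak_table` data frame with columns `start`, `end`, `summit`,
#'   `score`, `fold_enrichment`, `motif_start`, `motif_end`, `motif_seq`.
#' @export
load_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("peak_position", "summit", "score", "fold_enrichment",
            "motif_position", "consensus_sequence")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("peak table missing columns: ",
                            paste(missing, collapse = ", "))
  iv <- parse_interval(df$peak_position)
  miv <- parse_interval(df$motif_position, allow_na = TRUE)
  peaks <- data.frame(
    start = iv$start, end = iv$end,
    summit = as.integer(df$summit),
    score = as.numeric(df$score),
    fold_enrichment = as.numeric(df$fold_enrichment),
    motif_start = miv$start, motif_end = miv$end,
    motif_seq = ifelse(df$consensus_sequence == "N.A.", NA_character_,
                       df$consensus_sequence),
    stringsAsFactors = FALSE
  )
  validate_peaks(peaks)
}

parse_interval <- function(x, allow_na = FALSE) {
  is_na <- x == "N.A."
  if (any(is_na) && !allow_na) stop("unexpected N.A. interval")
  ok <- grepl("^[0-9]+-[0-9]+$", x) | is_na
  if (!all(ok)) stop("malformed interval string: ", x[!ok][1L])
  start <- end <- rep(NA_integer_, length(x))
  parts <- strsplit(x[!is_na], "-", fixed = TRUE)
  start[!is_na] <- vapply(parts, function(p) as.integer(p[[1L]]), 0L)
  end[!is_na] <- vapply(parts, function(p) as.integer(p[[2L]]), 0L)
  list(start = start, end = end)
}

#' Validate a peak table
#'
#' Enforces the peak invariants: summit inside the interval, non-negative
#' score, positive fold enrichment, and motif interval length matching the
#' motif sequence.
#'
#' @param peaks Data frame of peaks.
#' @return The validated data frame, classed `peak_table`.
#' @export
validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  bad <- which(peaks$summit < peaks$start | peaks$summit > peaks$end)
  if (length(bad)) stop("summit outside peak interval in row ", bad[1L])
  if (any(peaks$score < 0)) stop("negative peak score")
  if (any(peaks$fold_enrichment <= 0)) stop("non-positive fold enrichment")
  has <- !is.na(peaks$motif_start)
  if (any(has & is.na(peaks$motif_seq))) {
    stop("motif interval without motif sequence")
  }
  width_ok <- peaks$motif_end[has] - peaks$motif_start[has] + 1L ==
    nchar(peaks$motif_seq[has])
  if (!all(width_ok)) stop("motif interval length != motif sequence length")
  class(peaks) <- unique(c("peak_table", class(peaks)))
  peaks
}

#' Write a peak table in the printed-table dialect
#' @param peaks A `peak_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  fmt_iv <- function(s, e) ifelse(is.na(s), "N.A.", paste0(s, "-", e))
  out <- data.frame(
    peak_position = fmt_iv(peaks$start, peaks$end),
    summit = peaks$summit,
    score = as.character(peaks$score),
    fold_enrichment = as.character(peaks$fold_enrichment),
    motif_position = fmt_iv(peaks$motif_start, peaks$motif_end),
    consensus_sequence = ifelse(is.na(peaks$motif_seq), "N.A.", peaks$motif_seq),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write peaks as BED6+
#'
#' The only place where the package leaves its 1-based inclusive coordinate
#' frame: BED chromStart is 0-based, chromEnd half-open. Extra columns carry
#' the summit, fold enrichment, and motif interval.
#'
#' @param peaks A `peak_table`.
#' @param path Output path.
#' @param genome_name Chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, genome_name = "genome") {
  fmt_iv <- function(s, e) ifelse(is.na(s), "N.A.", paste0(s - 1L, "-", e))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t.\t%d\t%s\t%s",
    genome_name, peaks$start - 1L, peaks$end,
    sprintf("peak_%d", seq_len(nrow(peaks))),
    as.character(peaks$score),
    peaks$summit,
    as.character(peaks$fold_enrichment),
    fmt_iv(peaks$motif_start, peaks$motif_end)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-base coverage track as bedGraph
#' @param track Integer or numeric vector of per-base counts (index = 1-based
#'   genome coordinate).
#' @param path Output path.
#' @param genome_name Chromosome name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, genome_name = "genome") {
  r <- S4Vectors::Rle(as.numeric(track))
  gr <- GenomicRanges::GRanges(
    genome_name,
    IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(r)))[
      seq_along(S4Vectors::runLength(r))],
      width = S4Vectors::runLength(r)),
    score = S4Vectors::runValue(r)
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track back into a per-base vector
#' @param path bedGraph path.
#' @param genome_length Genome length; zero-coverage tails are padded.
#' @return Numeric vector of length `genome_length`.
#' @export
load_bedgraph <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- numeric(genome_length)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  v <- gr$score
  for (i in seq_along(gr)) track[s[i]:e[i]] <- v[i]
  track
}

#' Write a motif model in MEME minimal format
#'
#' Emits a version-4 minimal motif file (alphabet, background frequencies and
#' a letter-probability matrix with `w` and `nsites` header fields), the
#' interchange format understood by the MEME suite tools.
#'
#' @param motif A `motif_model` (see [discover_motif_zoops()]) or any list
#'   with `ppm`, `background`, `nsites` and optionally `evalue_estimate`.
#' @param path Output path.
#' @param name Motif name written to the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif, path, name = "MOTIF_1") {
  ppm <- motif$ppm
  bg <- motif$background
  w <- nrow(ppm)
  ev <- if (is.null(motif$evalue_estimate)) 0 else motif$evalue_estimate
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1L], bg[2L], bg[3L], bg[4L]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
            w, motif$nsites, ev),
    apply(ppm, 1L, function(row) sprintf("%.6f %.6f %.6f %.6f",
                                         row[1L], row[2L], row[3L], row[4L]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a MEME minimal motif file
#' @param path Path to a minimal MEME motif file.
#' @return A list with `ppm`, `background`, `nsites`, `evalue_estimate`,
#'   `name`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  bg <- c(0.25, 0.25, 0.25, 0.25)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(tok[c(2L, 4L, 6L, 8L)])
  }
  m_i <- grep("^MOTIF", lines)
  if (!length(m_i)) stop("no MOTIF block in ", path)
  name <- strsplit(lines[m_i[1L]], "\\s+")[[1L]][2L]
  h_i <- grep("^letter-probability matrix", lines)
  hdr <- lines[h_i[1L]]
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), hdr))[[1L]]
    if (length(m) == 2L) as.numeric(m[[2L]]) else NA_real_
  }
  w <- as.integer(get_field("w"))
  nsites <- as.integer(get_field("nsites"))
  rows <- lines[(h_i[1L] + 1L):(h_i[1L] + w)]
  ppm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  colnames(ppm) <- DNA_BASES
  names(bg) <- DNA_BASES
  list(ppm = ppm, background = bg, nsites = nsites,
       evalue_estimate = get_field("E"), name = name)
}

#' Packaged NdgR binding-region table
#'
#' The 19 genome-scale NdgR binding regions of *Streptomyces coelicolor*
#' (peak interval, summit, \eqn{-10\log_{10}(p)} score, fold enrichment, and
#' the located 15-bp motif where present), shipped as a plain-text fixture.
#'
#' @return A `peak_table` with 19 rows.
#' @export
ndgr_peaks <- function() {
  load_peak_table(system.file("extdata", "ndgr_peaks_table1.tsv",
                              package = "regulonscope", mustWork = TRUE))
}

#' Packaged NdgR regulon table
#'
#' The 34 genes of the NdgR regulon with evidence flags: `*` = direct
#' binding, `I` = intragenic binding, `D` = divergent shared promoter; rows
#' without a flag are operon members carried along by a directly bound
#' leading gene.
#'
#' @return A data frame with columns `locus_tag`, `gene_name`, `note`, and
#'   logical evidence flags `direct`, `intragenic`, `divergent`,
#'   `operon_member`.
#' @export
ndgr_regulon <- function() {
  df <- utils::read.delim(
    system.file("extdata", "ndgr_regulon_table2.tsv",
                package = "regulonscope", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  df$note[is.na(df$note)] <- ""
  df$direct <- grepl("*", df$note, fixed = TRUE)
  df$intragenic <- grepl("I", df$note, fixed = TRUE)
  df$divergent <- grepl("D", df$note, fixed = TRUE)
  df$operon_member <- !df$direct
  df
}
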