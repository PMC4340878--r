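#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study system at desk scale: a high-GC (72%) circular chromosome,
#' operon-structured gene models, 15-bp imperfect-palindrome binding sites
#' sampled from the packaged binding-site alignment, Poisson background
#' coverage with localized IP enrichment, and 2x2 factorial qPCR-style
#' expression with multiplicative noise.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param genome_length Genome size in bp.
#' @param gc_content GC fraction in \[0, 1\] (0.72 mirrors the organism).
#' @param n_tus Number of transcription units (>= 3; the first two form a
#'   divergent pair sharing one intergenic region, the last carries a long
#'   gene eligible for intragenic binding).
#' @param genes_per_tu Length-2 integer range; each unit's gene count is
#'   drawn uniformly from it.
#' @param n_planted_sites Number of planted binding sites (site 1 is the
#'   shared divergent site; the rest go upstream of other unit leaders).
#' @param planted_pwm Position probability matrix (w x 4, columns ACGT) the
#'   planted site sequences are sampled from, or a consensus string planted
#'   verbatim. `NULL` uses [table1_site_pwm()].
#' @param background_rate Mean background reads per base (lambda).
#' @param enrichment_fold Peak-center IP rate multiplier.
#' @param max_fold Cap on the summed enrichment multiplier where kernels of
#'   neighbouring sites overlap.
#' @param peak_halfwidth Half-width (bp) of the triangular enrichment kernel.
#' @param read_length Nominal read length (bp), kept as provenance metadata.
#' @param expression_noise_cv Coefficient of variation of the lognormal
#'   multiplicative expression noise.
#' @param n_replicates Replicates per factorial cell.
#' @param site_upstream_offset Distance (bp) from a planted site's center to
#'   the downstream unit-leading start codon.
#' @param n_intragenic_sites 0 or 1 extra site planted inside the long gene.
#' @param gene_length,long_gene_length,intra_tu_gap,min_tu_gap,divergent_gap
#'   Landscape geometry (bp). `min_tu_gap` keeps upstream regions of
#'   neighbouring units from overlapping so planted sites map to exactly one
#'   unit under the annotation rules.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       gc_content = 0.72,
                       n_tus = 8L,
                       genes_per_tu = c(1L, 4L),
                       n_planted_sites = 6L,
                       planted_pwm = NULL,
                       background_rate = 2,
                       enrichment_fold = 10,
                       max_fold = enrichment_fold,
                       peak_halfwidth = 150L,
                       read_length = 36L,
                       expression_noise_cv = 0.2,
                       n_replicates = 3L,
                       site_upstream_offset = 100L,
                       n_intragenic_sites = 0L,
                       gene_length = 900L,
                       long_gene_length = 2500L,
                       intra_tu_gap = 50L,
                       min_tu_gap = 800L,
                       divergent_gap = 240L) {
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  stopifnot(genome_length > 0, n_tus >= 3, background_rate > 0,
            enrichment_fold > 1, peak_halfwidth > 0,
            expression_noise_cv >= 0, n_replicates >= 1,
            n_planted_sites >= 0, n_intragenic_sites %in% c(0L, 1L))
  if (n_planted_sites > n_tus - 1L) {
    stop("n_planted_sites may be at most n_tus - 1 ",
         "(the divergent pair shares one site)")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys match the [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
load_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' Position probability matrix of the packaged binding-site alignment
#'
#' Estimated from the 18 printed 15-bp site sequences of the packaged
#' NdgR peak table, with a pseudocount per base, so synthetic data share the
#' real motif's statistics (including its imperfect palindromicity).
#'
#' @param pseudocount Added to each base count before normalization.
#' @return A 15 x 4 matrix with columns A, C, G, T; rows sum to 1.
#' @export
table1_site_pwm <- function(pseudocount = 0.5) {
  sites <- ndgr_peaks()$motif_seq
  sites_pwm(sites[!is.na(sites)], pseudocount)
}

#' Position probability matrix from aligned site sequences
#' @param sites Character vector of equal-length site sequences.
#' @param pseudocount Added to each base count.
#' @return A w x 4 probability matrix (columns ACGT).
#' @export
sites_pwm <- function(sites, pseudocount = 0.5) {
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must share one width")
  mat <- do.call(rbind, strsplit(sites, ""))
  ppm <- t(apply(mat, 2L, function(col) {
    counts <- table(factor(col, levels = DNA_BASES))
    (as.vector(counts) + pseudocount) / (length(col) + 4 * pseudocount)
  }))
  colnames(ppm) <- DNA_BASES
  ppm
}

#' Generate a random genome
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A `genome_sequence` named `"synthetic"`.
#' @export
generate_genome <- function(config, seed = config$seed) {
  set.seed(seed)
  gc <- config$gc_content
  bases <- sample(DNA_BASES, config$genome_length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome_sequence(paste(bases, collapse = ""), name = "synthetic",
                  circular = TRUE)
}

#' Generate an operon landscape with planted binding sites
#'
#' Lays out non-overlapping transcription units on both strands, always
#' including one divergent pair sharing an intergenic region and one long
#' gene eligible for intragenic binding; plants motif sites (sampled from
#' `config$planted_pwm`) at fixed offsets upstream of unit-leading start
#' codons (and optionally inside the long gene); splices the site sequences
#' into the genome; and records every placement plus the implied true
#' regulon in a ground-truth object.
#'
#' @param genome A `genome_sequence` (its sequence is modified at the
#'   planted positions).
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with `genome` (sites spliced in), `genes`, `tus`, and
#'   `ground_truth` (fields `sites`, `peak_centers`, `true_regulon`,
#'   `ffl_spec`).
#' @export
generate_regulatory_landscape <- function(genome, config,
                                          seed = config$seed) {
  set.seed(seed + 1L)
  L <- genome$length
  n_tus <- config$n_tus
  glen <- config$gene_length
  gap_in <- config$intra_tu_gap

  n_genes <- sample(seq.int(config$genes_per_tu[1L], config$genes_per_tu[2L]),
                    n_tus, replace = TRUE)
  # the divergent pair leaders and the long-gene unit
  gene_lengths <- lapply(seq_len(n_tus), function(i) rep(glen, n_genes[i]))
  if (n_genes[n_tus] < 2L) n_genes[n_tus] <- 2L
  gene_lengths[[n_tus]] <- c(config$long_gene_length,
                             rep(glen, n_genes[n_tus] - 1L))
  spans <- vapply(gene_lengths, function(gl) {
    as.integer(sum(gl) + (length(gl) - 1L) * gap_in)
  }, 0L)

  # units 1 and 2 form one block: unit 1 on -, divergent_gap, unit 2 on +
  block_spans <- c(spans[1L] + config$divergent_gap + spans[2L],
                   spans[-(1:2)])
  n_blocks <- length(block_spans)
  need <- sum(block_spans) + n_blocks * config$min_tu_gap
  if (need > L) {
    stop("infeasible packing: ", need, " bp needed on a ", L,
         " bp genome; reduce n_tus or genes_per_tu")
  }
  slack <- L - need
  extra <- if (slack > 0) {
    as.vector(stats::rmultinom(1L, slack, rep(1 / n_blocks, n_blocks)))
  } else rep(0L, n_blocks)
  gaps <- config$min_tu_gap + extra
  # gap i precedes block i; the gap before block 1 doubles as the
  # origin-spanning gap back from the last block
  block_starts <- integer(n_blocks)
  pos <- 1L
  for (i in seq_len(n_blocks)) {
    pos <- pos + gaps[i]
    block_starts[i] <- pos
    pos <- pos + block_spans[i]
  }
  strands <- c("-", "+",
               sample(c("+", "-"), max(n_tus - 3L, 0L), replace = TRUE), "+")

  genes_list <- list()
  tu_meta <- list()
  lay_tu <- function(tu_id, strand, left, gl) {
    # genes laid left-to-right within [left, left+span-1]; transcription
    # order follows the strand
    n <- length(gl)
    starts <- left + cumsum(c(0L, gl[-n] + gap_in))
    ends <- starts + gl - 1L
    if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
    data.frame(
      locus_tag = sprintf("%s_g%d", tu_id, seq_len(n)),
      gene_name = NA_character_,
      strand = strand,
      start_codon = if (strand == "+") starts else ends,
      end = if (strand == "+") ends else starts,
      tu_id = tu_id,
      stringsAsFactors = FALSE
    )
  }
  # divergent pair: unit 1 genes transcribed leftwards from the right end of
  # its span; unit 2 rightwards after the shared intergenic gap
  genes_list[[1L]] <- lay_tu("tu01", "-", block_starts[1L], gene_lengths[[1L]])
  genes_list[[2L]] <- lay_tu("tu02", "+",
                             block_starts[1L] + spans[1L] + config$divergent_gap,
                             gene_lengths[[2L]])
  for (i in seq.int(3L, n_tus)) {
    tu_id <- sprintf("tu%02d", i)
    # long-gene unit must run + with the long gene first so the intragenic
    # site sits deep inside it
    gl <- gene_lengths[[i]]
    genes_list[[i]] <- lay_tu(tu_id, strands[i], block_starts[i - 1L], gl)
  }
  genes <- do.call(rbind, genes_list)
  ann <- validate_annotation(genes)

  # ---- plant sites -------------------------------------------------------
  pwm <- config$planted_pwm
  if (is.null(pwm)) pwm <- table1_site_pwm()
  consensus_mode <- is.character(pwm)
  w <- if (consensus_mode) nchar(pwm) else nrow(pwm)

  leader_of <- function(tu_id) {
    ord <- ann$tus$gene_order[[match(tu_id, ann$tus$tu_id)]]
    genes[match(ord[1L], genes$locus_tag), ]
  }
  site_rows <- list()
  add_site <- function(center, strand_site, site_type, target_tus,
                       target_genes) {
    seq_site <- if (consensus_mode) pwm else sample_from_pwm(pwm)
    if (strand_site == "-") seq_site <- revcomp(seq_site)
    start <- as.integer(center - w %/% 2L)
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      position = start, center = as.integer(center),
      strand = strand_site, sequence = seq_site, site_type = site_type,
      target_tus = paste(target_tus, collapse = ","),
      target_genes = paste(target_genes, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  tu_genes <- function(tu_id) ann$tus$gene_order[[match(tu_id, ann$tus$tu_id)]]

  n_sites <- config$n_planted_sites
  if (n_sites >= 1L) {
    s1 <- leader_of("tu01")$start_codon  # minus-strand leader (right end)
    s2 <- leader_of("tu02")$start_codon
    center <- as.integer(floor((s1 + s2) / 2))
    add_site(center, sample(c("+", "-"), 1L), "divergent",
             c("tu01", "tu02"), c(tu_genes("tu01"), tu_genes("tu02")))
  }
  if (n_sites >= 2L) {
    for (i in seq.int(3L, n_sites + 1L)) {
      tu_id <- sprintf("tu%02d", i)
      ld <- leader_of(tu_id)
      center <- if (ld$strand == "+") {
        ld$start_codon - config$site_upstream_offset
      } else {
        ld$start_codon + config$site_upstream_offset
      }
      add_site(center, sample(c("+", "-"), 1L), "upstream", tu_id,
               tu_genes(tu_id))
    }
  }
  if (config$n_intragenic_sites == 1L) {
    tu_id <- sprintf("tu%02d", n_tus)
    long_gene <- leader_of(tu_id)
    center <- long_gene$start_codon +
      (if (long_gene$strand == "+") 600L else -600L)
    add_site(center, sample(c("+", "-"), 1L), "intragenic", tu_id,
             long_gene$locus_tag)
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(position = integer(), center = integer(),
               strand = character(), sequence = character(),
               site_type = character(), target_tus = character(),
               target_genes = character(), stringsAsFactors = FALSE)

  seq_chars <- strsplit(genome$sequence, "")[[1L]]
  for (i in seq_len(nrow(sites))) {
    idx <- ((seq.int(sites$position[i], by = 1L, length.out = w) - 1L) %% L) + 1L
    seq_chars[idx] <- strsplit(sites$sequence[i], "")[[1L]]
  }
  genome$sequence <- paste(seq_chars, collapse = "")

  true_regulon <- sort(unique(unlist(
    strsplit(sites$target_genes[sites$site_type != "none"], ","))))

  # factorial-logic ground truth for the expression stage: one planted FFL
  # spec per directly bound leading gene (type alternates C1-OR / I1)
  direct <- unlist(lapply(seq_len(nrow(sites)), function(i) {
    strsplit(sites$target_tus[i], ",")[[1L]]
  }))
  leaders <- vapply(unique(direct), function(tu) {
    ann$tus$gene_order[[match(tu, ann$tus$tu_id)]][1L]
  }, "")
  ffl_spec <- if (length(leaders)) {
    data.frame(
      gene = unname(leaders),
      type = rep(c("C1-OR", "I1"), length.out = length(leaders)),
      induction = 8,
      repression = 4,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene = character(), type = character(),
               induction = numeric(), repression = numeric(),
               stringsAsFactors = FALSE)
  }

  list(genome = genome, genes = ann$genes, tus = ann$tus,
       ground_truth = list(sites = sites,
                           peak_centers = sites$center,
                           true_regulon = true_regulon,
                           ffl_spec = ffl_spec))
}

sample_from_pwm <- function(ppm) {
  paste(vapply(seq_len(nrow(ppm)), function(i) {
    sample(DNA_BASES, 1L, prob = ppm[i, ])
  }, ""), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x Character scalar over ACGT.
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate IP and control coverage tracks
#'
#' Control coverage is Poisson with the configured background rate; IP
#' coverage is Poisson with rate
#' \eqn{\lambda_{bg} (1 + (f - 1) k(d))} where `k` is a triangular kernel of
#' the configured half-width centred on each planted site (`k(0) = 1`,
#' `k(d) = 0` beyond the half-width). Overlapping kernels are summed and the
#' multiplier capped at `config$max_fold`.
#'
#' @param genome A `genome_sequence` (supplies length and circularity).
#' @param ground_truth Ground truth from
#'   [generate_regulatory_landscape()] (only `sites$center` is used).
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with integer vectors `ip` and `control` and the `rate`
#'   multiplier vector used for the IP expectation.
#' @export
simulate_chip_coverage <- function(genome, ground_truth, config,
                                   seed = config$seed) {
  set.seed(seed + 2L)
  L <- genome$length
  hw <- config$peak_halfwidth
  lam <- config$background_rate
  mult <- rep(1, L)
  for (center in ground_truth$sites$center) {
    d <- seq.int(-hw + 1L, hw - 1L)
    pos <- ((center + d - 1L) %% L) + 1L
    mult[pos] <- mult[pos] + (config$enrichment_fold - 1) * (1 - abs(d) / hw)
  }
  mult <- pmin(mult, config$max_fold)
  ip <- stats::rpois(L, lam * mult)
  control <- stats::rpois(L, lam)
  list(ip = ip, control = control, rate = mult)
}

#' Simulate 2x2 factorial expression data
#'
#' Emits normalized expression for every combination of stress
#' (D in \{0,1\}) and regulator genotype (N in \{0,1\}), replicated, with
#' mean-preserving lognormal multiplicative noise. Noiseless cell means per
#' planted logic:
#' \describe{
#'   \item{C1-OR}{1 at (0,0); `induction` whenever d = 1 or n = 1.}
#'   \item{C1-AND}{1 except `induction` at (1,1).}
#'   \item{I1}{1 at d = 0; `induction` at (1,0); `induction/repression`
#'     at (1,1).}
#' }
#'
#' @param ffl_spec Data frame with columns `gene`, `type`
#'   (`"C1-OR"`, `"C1-AND"`, `"I1"`), `induction`, `repression`.
#' @param config A [sim_config()] (noise CV and replicate count).
#' @param seed Seed (defaults to `config$seed`).
#' @return A long data frame: `gene`, `D`, `N`, `replicate`, `value`.
#' @export
simulate_expression <- function(ffl_spec, config, seed = config$seed) {
  if (config$expression_noise_cv < 0) stop("noise CV must be >= 0")
  set.seed(seed + 3L)
  cv <- config$expression_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  cells <- expand.grid(D = 0:1, N = 0:1)
  rows <- lapply(seq_len(nrow(ffl_spec)), function(i) {
    spec <- ffl_spec[i, ]
    mu <- vapply(seq_len(nrow(cells)), function(j) {
      ffl_cell_mean(spec$type, cells$D[j], cells$N[j],
                    spec$induction, spec$repression)
    }, 0)
    do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
      vals <- if (cv == 0) rep(mu[j], config$n_replicates) else
        stats::rlnorm(config$n_replicates,
                      meanlog = log(mu[j]) - sdlog^2 / 2, sdlog = sdlog)
      data.frame(gene = spec$gene, D = cells$D[j], N = cells$N[j],
                 replicate = seq_len(config$n_replicates), value = vals,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ffl_cell_mean <- function(type, d, n, induction, repression) {
  switch(type,
    "C1-OR" = if (d == 1 || n == 1) induction else 1,
    "C1-AND" = if (d == 1 && n == 1) induction else 1,
    "I1" = if (d == 0) 1 else if (n == 0) induction else induction / repression,
    stop("unknown FFL type: ", type)
  )
}

#' Write a ground-truth object as JSON
#' @param ground_truth Ground truth from [generate_regulatory_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
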