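test_that("upstream/downstream boundaries are inclusive exactly", {
  genes <- toy_genes()[1, ]  # + strand, start codon 10000
  p <- annotation_params()
  cls <- function(s) classify_summit(s, genes, p)
  expect_equal(cls(9500)$category, "upstream")    # -500 in
  expect_equal(cls(9500)$signed_distance, -500)
  expect_equal(cls(9499)$category, "none")        # -501 out
  expect_equal(cls(10100)$category, "upstream")   # +100 in
  # +101 is past the downstream bound; with no other gene nearby it falls
  # through to the intragenic rule instead
  expect_equal(cls(10101)$category, "intragenic")
})

test_that("minus-strand distances run against the coordinate axis", {
  genes <- toy_genes()[3, ]  # - strand, start codon 8000
  p <- annotation_params()
  expect_equal(classify_summit(8500, genes, p)$signed_distance, -500)
  expect_equal(classify_summit(8500, genes, p)$category, "upstream")
  expect_equal(classify_summit(8501, genes, p)$category, "none")
  expect_equal(classify_summit(7900, genes, p)$signed_distance, 100)
})

test_that("a shared intergenic summit flags both divergent genes", {
  genes <- toy_genes()  # geneC (-, start 8000) faces geneA (+, start 10000)
  genes$start_codon[1] <- 8300L; genes$end[1] <- 9200L
  genes$start_codon[2] <- 9300L; genes$end[2] <- 10200L
  asn <- classify_summit(8150, genes, annotation_params())
  expect_equal(nrow(asn), 2)
  expect_setequal(asn$locus_tag, c("geneA", "geneC"))
  expect_true(all(asn$divergent_flag))
})

test_that("intragenic rule needs distance from both start codons", {
  genes <- data.frame(
    locus_tag = c("big", "next"), gene_name = NA, strand = "+",
    start_codon = c(1000L, 3900L), end = c(3000L, 4800L),
    tu_id = c("t1", "t2"), stringsAsFactors = FALSE)
  p <- annotation_params()
  # 150 bp past the start, 2750 bp from the next start: intragenic
  asn <- classify_summit(1150, genes, p)
  expect_equal(asn$category, "intragenic")
  expect_equal(asn$locus_tag, "big")
  # too close to the start codon (<100): upstream rule catches it instead
  expect_equal(classify_summit(1050, genes, p)$category, "upstream")
  # deep in the gene but far from the next start: still intragenic
  expect_equal(classify_summit(2990, genes, p)$category, "intragenic")
  # when the summit comes within 500 bp of the next start codon, the
  # upstream rule for that downstream gene takes precedence
  close_next <- genes; close_next$start_codon[2] <- 3300L
  close_next$end[2] <- 4200L
  asn <- classify_summit(2990, close_next, p)
  expect_equal(asn$category, "upstream")
  expect_equal(asn$locus_tag, "next")
})

test_that("operon expansion mirrors a six-gene block from one hit", {
  genes <- data.frame(
    locus_tag = sprintf("cys%d", 1:6), gene_name = NA, strand = "+",
    start_codon = seq(5000L, by = 1000L, length.out = 6),
    end = seq(5900L, by = 1000L, length.out = 6),
    tu_id = "cysTU", stringsAsFactors = FALSE)
  tus <- validate_annotation(genes)$tus
  peaks <- validate_peaks(data.frame(
    start = 4600L, end = 5100L, summit = 4900L, score = 200,
    fold_enrichment = 5, motif_start = NA_integer_, motif_end = NA_integer_,
    motif_seq = NA_character_))
  reg <- build_regulon(peaks, genes, tus)
  expect_equal(nrow(reg), 6)
  expect_equal(sum(reg$direct), 1)
  expect_equal(sum(reg$operon_member), 5)
  expect_equal(reg$locus_tag[reg$direct], "cys1")
})

test_that("intragenic hits do not expand through the operon", {
  genes <- data.frame(
    locus_tag = c("big", "tail"), gene_name = NA, strand = "+",
    start_codon = c(1000L, 3100L), end = c(3000L, 4000L),
    tu_id = "t1", stringsAsFactors = FALSE)
  tus <- validate_annotation(genes)$tus
  peaks <- validate_peaks(data.frame(
    start = 1200L, end = 1700L, summit = 1500L, score = 150,
    fold_enrichment = 4, motif_start = NA_integer_, motif_end = NA_integer_,
    motif_seq = NA_character_))
  reg <- build_regulon(peaks, genes, tus)
  expect_equal(reg$locus_tag, "big")
  expect_true(reg$direct && reg$intragenic)
  expect_equal(reg$note, "*, I")
})

test_that("regulon output is independent of peak order and peak-free input", {
  genes <- toy_genes()
  tus <- validate_annotation(genes)$tus
  mk_peak <- function(summit) data.frame(
    start = summit - 200L, end = summit + 200L, summit = summit,
    score = 150, fold_enrichment = 4, motif_start = NA_integer_,
    motif_end = NA_integer_, motif_seq = NA_character_)
  peaks <- validate_peaks(rbind(mk_peak(9600), mk_peak(8400)))
  fwd <- build_regulon(peaks, genes, tus)
  rev_ <- build_regulon(validate_peaks(peaks[2:1, ]), genes, tus)
  expect_equal(fwd[setdiff(names(fwd), "source_peaks")],
               rev_[setdiff(names(rev_), "source_peaks")])

  empty <- build_regulon(peaks[0, ], genes, tus)
  expect_equal(nrow(empty), 0)
})

test_that("unmatched peaks land in the sidecar report, not the regulon", {
  genes <- toy_genes()
  tus <- validate_annotation(genes)$tus
  peaks <- validate_peaks(data.frame(
    start = 100L, end = 500L, summit = 300L, score = 150,
    fold_enrichment = 4, motif_start = NA_integer_, motif_end = NA_integer_,
    motif_seq = NA_character_))
  reg <- build_regulon(peaks, genes, tus)
  expect_equal(nrow(reg), 0)
  expect_equal(attr(reg, "unassigned"), 1L)
})

test_that("called peaks on synthetic data rebuild the true regulon", {
  for (s in 1:10) {
    cfg <- sim_config(seed = 200 + s)
    land <- generate_regulatory_landscape(generate_genome(cfg), cfg)
    cov <- simulate_chip_coverage(land$genome, land$ground_truth, cfg)
    peaks <- call_peaks(cov$ip, cov$control)
    reg <- build_regulon(peaks, land$genes, land$tus,
                         genome_length = land$genome$length)
    expect_identical(sort(reg$locus_tag), land$ground_truth$true_regulon)
  }
})
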