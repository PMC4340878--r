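test_that("log-odds construction follows the definition", {
  ppm <- matrix(c(1, 0, 0, 0), 1, dimnames = list(NULL, c("A", "C", "G", "T")))
  lo <- make_log_odds(ppm, rep(0.25, 4), 0)
  expect_equal(unname(lo[1, "A"]), 2)          # log2(1 / 0.25)
  expect_equal(unname(lo[1, "C"]), -Inf)

  bg <- c(0.14, 0.36, 0.36, 0.14)
  same <- matrix(rep(bg, each = 5), 5, 4, dimnames = list(NULL, names(bg)))
  expect_equal(unname(make_log_odds(same, bg, 0)),
               matrix(0, 5, 4), tolerance = 1e-12)

  reg <- make_log_odds(ppm, rep(0.25, 4), 0.5)
  expect_true(all(is.finite(reg)))
  expect_error(make_log_odds(ppm, c(0, 0.5, 0.25, 0.25)), "background")
})

test_that("DP score distribution is exact at the extremes", {
  # width-3 deterministic matrix, uniform background
  ppm <- matrix(0, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ppm[cbind(1:3, c(1, 2, 3))] <- 1
  lo <- make_log_odds(ppm, rep(0.25, 4), 1e-9)
  lk <- exact_score_pvalues(lo, rep(0.25, 4))
  kmax <- sum(apply(lk$kmat, 1, max))
  expect_equal(lookup_pvalue(lk, kmax), (1 / 4)^3, tolerance = 1e-9)
  kmin <- sum(apply(lk$kmat, 1, min))
  expect_equal(lookup_pvalue(lk, kmin), 1)
  expect_true(all(diff(lk$tail) <= 0))
})

test_that("DP equals brute-force enumeration over 50 random matrices", {
  set.seed(123)
  for (trial in 1:50) {
    w <- sample(2:6, 1)
    ppm <- matrix(rgamma(4 * w, 1), w, 4)
    ppm <- ppm / rowSums(ppm)
    colnames(ppm) <- c("A", "C", "G", "T")
    bg <- rgamma(4, 2); bg <- bg / sum(bg)
    lo <- make_log_odds(ppm, bg, 0.5)
    lk <- exact_score_pvalues(lo, bg)
    probe <- lk$bins[round(seq(1, length(lk$bins), length.out = 3))]
    for (kscore in probe) {
      expect_equal(lookup_pvalue(lk, kscore),
                   oracle_word_pvalue(lk$kmat, bg, kscore),
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate thresholds and planted words scan correctly", {
  set.seed(20)
  g_lin <- genome_sequence(random_window(300), circular = FALSE)
  ppm <- sites_pwm("GTCCACCCACCGGAC", pseudocount = 0.1)
  bg <- rep(0.25, 4)
  lo <- make_log_odds(ppm, bg, 0)
  # p = 1 returns every position on both strands on a linear genome
  all_hits <- scan_genome(g_lin, lo, p_threshold = 1, background = bg)
  expect_equal(nrow(all_hits), 2 * (300 - 15 + 1))

  # one planted consensus word at a tight threshold
  seq2 <- paste0(random_window(150), "GTCCACCCACCGGAC", random_window(150))
  g2 <- genome_sequence(seq2, circular = FALSE)
  hits <- scan_genome(g2, lo, p_threshold = 1e-7, background = bg)
  expect_equal(hits$position, 151)
  expect_equal(hits$matched_seq, "GTCCACCCACCGGAC")

  # strand symmetry: scanning the reverse complement mirrors the site set
  g2rc <- genome_sequence(revcomp(seq2), circular = FALSE)
  hits_rc <- scan_genome(g2rc, lo, p_threshold = 1e-7, background = bg)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_equal(hits_rc$position, g2$length - (hits$position + 15 - 1) + 1)
  expect_equal(hits_rc$strand, chartr("+-", "-+", hits$strand))
  expect_equal(hits_rc$score, hits$score)
})

test_that("p-values decrease as scores increase in scan output", {
  set.seed(30)
  g <- genome_sequence(random_window(2000), circular = FALSE)
  ppm <- sites_pwm(c("GTCCAC", "GTCCAC", "GTCGAC"), pseudocount = 0.5)
  lo <- make_log_odds(ppm, rep(0.25, 4), 0)
  hits <- scan_genome(g, lo, p_threshold = 1, background = rep(0.25, 4))
  o <- order(hits$score)
  expect_true(all(diff(hits$pvalue[o]) <= 1e-12))
})

test_that("summit-motif geometry reproduces the published counts", {
  geom <- summit_motif_geometry(ndgr_peaks(), threshold = 50)
  expect_equal(geom$n_with_motif, 18)
  expect_equal(geom$n_within_threshold, 13)
  # hand-checked row: summit 6015210 vs motif 6015204-6015218 -> distance 1
  d <- geom$distances
  expect_equal(d$distance[d$summit == 6015210], 1)
  # hand-checked boundary row: summit 2261945 vs 2261989-2262003 -> 51, out
  expect_equal(d$distance[d$summit == 2261945], 51)

  expect_equal(summit_motif_geometry(ndgr_peaks()[0, ])$n_with_motif, 0)
  inf <- summit_motif_geometry(ndgr_peaks(), threshold = Inf)
  expect_equal(inf$n_within_threshold, inf$n_with_motif)
})

test_that("scan hits attach to peaks by midpoint containment", {
  cfg <- sim_config(seed = 41, n_planted_sites = 3,
                    planted_pwm = "GTCCACCCACCGGAC")
  land <- generate_regulatory_landscape(generate_genome(cfg), cfg)
  ppm <- sites_pwm("GTCCACCCACCGGAC", pseudocount = 0.1)
  counts <- table(factor(strsplit(land$genome$sequence, "")[[1]],
                         levels = c("A", "C", "G", "T")))
  bg <- as.vector(counts) / sum(counts)
  lo <- make_log_odds(ppm, bg, 0)
  sites <- scan_genome(land$genome, lo, p_threshold = 1e-7, background = bg)
  expect_setequal(land$ground_truth$sites$position,
                  intersect(sites$position, land$ground_truth$sites$position))
  centers <- land$ground_truth$sites$center
  peaks <- validate_peaks(data.frame(
    start = centers - 200L, end = centers + 200L, summit = centers,
    score = 200, fold_enrichment = 5, motif_start = NA_integer_,
    motif_end = NA_integer_, motif_seq = NA_character_))
  with_motifs <- assign_motifs_to_peaks(peaks, sites, 15L)
  expect_true(all(!is.na(with_motifs$motif_start)))
  geom <- summit_motif_geometry(with_motifs, 50)
  expect_equal(geom$n_within_threshold, 3)
})
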