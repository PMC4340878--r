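test_that("summit windows are exact, counted, and wrap on circular genomes", {
  g <- generate_genome(sim_config(seed = 6, genome_length = 5000))
  peaks <- validate_peaks(data.frame(
    start = 900L, end = 1100L, summit = 1000L, score = 150,
    fold_enrichment = 4, motif_start = NA_integer_, motif_end = NA_integer_,
    motif_seq = NA_character_))
  win <- extract_summit_windows(peaks, g, 400L)
  expect_equal(nchar(win), 400)
  expect_equal(win, substr(g$sequence, 800, 1199))

  # circular wrap against the doubled-string oracle
  pk2 <- peaks; pk2$summit <- 50L; pk2$start <- 40L; pk2$end <- 60L
  wrapped <- extract_summit_windows(validate_peaks(pk2), g, 400L)
  doubled <- paste0(g$sequence, g$sequence)
  expect_equal(wrapped, substr(doubled, 50 - 200 + 5000, 50 + 199 + 5000))

  # linear genomes truncate with a warning
  lin <- genome_sequence(g$sequence, circular = FALSE)
  expect_warning(tw <- extract_summit_windows(validate_peaks(pk2), lin, 400L),
                 "truncated")
  expect_equal(nchar(tw), 249)

  expect_error(extract_summit_windows(peaks, g, 6000L), "wider")

  many <- validate_peaks(peaks[rep(1, 19), ])
  expect_length(extract_summit_windows(many, g, 400L), 19)
})

test_that("an identical planted 15-mer is recovered at width 15", {
  word <- "GTCCACCCACCGGAC"
  set.seed(77)
  seqs <- replicate(18, make_window_with_site(word))
  m <- discover_motif_zoops(seqs, discovery_params(rng_seed = 7))
  expect_true(m$significant)
  expect_equal(m$width, 15)
  expect_equal(m$nsites, 18)
  argmax <- paste(c("A", "C", "G", "T")[apply(m$ppm, 1, which.max)],
                  collapse = "")
  expect_true(argmax %in% c(word, revcomp(word)))
  # ZOOPS: at most one site per sequence
  expect_lte(m$nsites, length(seqs))
  expect_true(all(m$site_assignments$posterior <= 1 + 1e-9))
})

test_that("pure background yields no significant motif", {
  set.seed(99)
  seqs <- replicate(12, random_window())
  m <- discover_motif_zoops(seqs, discovery_params(rng_seed = 3))
  expect_false(m$significant)
})

test_that("reverse-complementing all inputs mirrors the model", {
  word <- "GTCCACCCACCGGAC"
  set.seed(55)
  seqs <- replicate(14, make_window_with_site(word))
  m_fwd <- discover_motif_zoops(seqs, discovery_params(rng_seed = 5))
  m_rev <- discover_motif_zoops(vapply(seqs, revcomp, "", USE.NAMES = FALSE),
                                discovery_params(rng_seed = 5))
  expect_equal(m_rev$loglik_ratio, m_fwd$loglik_ratio, tolerance = 1e-3)
  expect_equal(m_rev$width, m_fwd$width)
  rc <- m_fwd$ppm[rev(seq_len(nrow(m_fwd$ppm))), 4:1]
  colnames(rc) <- colnames(m_fwd$ppm)
  direct_err <- max(abs(m_rev$ppm - m_fwd$ppm))
  mirror_err <- max(abs(m_rev$ppm - rc))
  expect_lt(min(direct_err, mirror_err), 0.02)
})

test_that("IUPAC consensus maps probability columns to degenerate codes", {
  expect_equal(iupac_consensus(matrix(c(1, 0, 0, 0), 1)), "A")
  expect_equal(iupac_consensus(matrix(c(0, 0, 0.5, 0.5), 1)), "K")
  expect_equal(iupac_consensus(matrix(c(0, 0, 0.5, 0.5), 1), bracket = TRUE),
               "[GT]")
  # all below threshold: argmax fallback
  expect_equal(iupac_consensus(matrix(c(0.4, 0.3, 0.2, 0.1), 1),
                               include_threshold = 0.5), "A")
  # first column of the packaged site alignment: G 14/18, T 4/18
  sites <- ndgr_peaks()$motif_seq
  ppm0 <- sites_pwm(sites[!is.na(sites)], pseudocount = 0)
  expect_equal(iupac_consensus(ppm0[1, , drop = FALSE], 0.15, bracket = TRUE),
               "[GT]")
  expect_equal(unname(ppm0[1, "G"]), 14 / 18)
  expect_equal(unname(ppm0[1, "T"]), 4 / 18)
})

test_that("palindromicity is 1 for perfect palindromes, 0.25 at uniform", {
  pal <- "GTCCACGTGGAC"  # its own reverse complement
  expect_equal(revcomp(pal), pal)
  ind <- diag(4)[match(strsplit(pal, "")[[1]], c("A", "C", "G", "T")), ]
  colnames(ind) <- c("A", "C", "G", "T")
  expect_equal(palindromicity_score(ind), 1.0)
  expect_equal(palindromicity_score(matrix(0.25, 9, 4)), 0.25)
})

test_that("the packaged site alignment is more palindromic than shuffles", {
  sites <- ndgr_peaks()$motif_seq
  ppm <- sites_pwm(sites[!is.na(sites)])
  obs <- palindromicity_score(ppm)
  set.seed(10)
  shuffled <- replicate(1000, {
    palindromicity_score(ppm[sample(nrow(ppm)), , drop = FALSE])
  })
  expect_gt(obs, mean(shuffled))
})
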