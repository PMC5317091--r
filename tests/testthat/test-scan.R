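CORE <- "nAACCGTTnnAACGGTTn"

test_that("scanning finds a single planted exact site", {
  set.seed(41)
  word <- "AAACCGTTGAAACGGTTT"
  repeat {
    bg <- random_genome_seq(200)
    seq <- paste0(substr(bg, 1, 90), word, substr(bg, 109, 200))
    ok <- oracle_scan(seq, CORE, 0)
    if (nrow(ok) == 1 && ok$start == 91) break
  }
  g <- genome_record(seq, circular = FALSE)
  hits <- scan_genome(g, CORE, max_mismatch = 0)
  expect_equal(hits$start, 91L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$matched_seq, word)
  expect_equal(hits$central_dinuc, "GA")
  expect_equal(as.character(hits$orientation), "forward")
})

test_that("a pattern longer than the genome is rejected", {
  expect_error(scan_genome(genome_record("ACGT"), "ACGTA"), "longer")
})

test_that("scan agrees with naive enumeration on random cases", {
  set.seed(42)
  for (i in 1:30) {
    L <- sample(100:800, 1)
    w <- sample(4:10, 1)
    seq <- random_genome_seq(L)
    pat <- random_pattern_text(w)
    m <- sample(0:3, 1)
    circ <- sample(c(TRUE, FALSE), 1)
    got <- scan_genome(genome_record(seq, circular = circ), pat,
                       max_mismatch = m, circular = circ)
    want <- oracle_scan(seq, pat, m, circular = circ)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("hit sets are nested across mismatch budgets", {
  set.seed(43)
  g <- genome_record(random_genome_seq(2000), circular = FALSE)
  prev <- integer(0)
  for (m in 0:4) {
    cur <- scan_genome(g, "ACGNNCGT", max_mismatch = m)$start
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("scanning the reverse-complemented genome mirrors positions", {
  set.seed(44)
  for (i in 1:5) {
    seq <- random_genome_seq(1500)
    g <- genome_record(seq, circular = FALSE)
    hits <- scan_genome(g, CORE, max_mismatch = 3)
    rcg <- genome_record(reverse_complement(seq), circular = FALSE)
    rhits <- scan_genome(rcg, CORE, max_mismatch = 3)
    expect_setequal(rhits$start, 1500 - hits$end + 1L)
  }
})

test_that("circular scanning reports origin-wrapping windows once", {
  word <- "AAACCGTTGAAACGGTTT"
  # split the word across the coordinate origin: last 8 bases | ... | first 10
  seq <- paste0(substr(word, 11, 18), strrep("C", 200), substr(word, 1, 10))
  g_circ <- genome_record(seq, circular = TRUE)
  hits <- scan_genome(g_circ, CORE, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, nchar(seq) - 10L + 1L)
  expect_equal(hits$end, 8L)  # end < start marks the wrap
  g_lin <- genome_record(seq, circular = FALSE)
  expect_equal(nrow(scan_genome(g_lin, CORE, max_mismatch = 0)), 0L)
})

test_that("consensus search covers both strands and deviation budgets", {
  rex <- "TTGTGAANNNNTTCACAA"
  site <- "CTGTGAATCAATTCACAT"
  seq <- paste0(strrep("G", 60), site, strrep("G", 60))
  g <- genome_record(seq, circular = FALSE)
  hits2 <- consensus_site_search(g, rex, max_dev = 2)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$mismatches, 2L)
  expect_equal(hits2$start, 61L)
  expect_equal(nrow(consensus_site_search(g, rex, max_dev = 1)), 0L)

  # a non-palindromic consensus present only as its reverse complement
  cons <- "AACGTAGG"
  seq2 <- paste0(strrep("C", 40), reverse_complement(cons), strrep("C", 40))
  stopifnot(nrow(oracle_scan(seq2, cons, 0)) == 0)
  g2 <- genome_record(seq2, circular = FALSE)
  hits <- consensus_site_search(g2, cons, max_dev = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 41L)
})

test_that("central dinucleotide reads off the middle pair", {
  expect_equal(central_dinucleotide("AAACCGTTGAAACGGTTT", CORE), "GA")
  expect_equal(central_dinucleotide("AAACCGTTTCAACGGTTT", CORE), "TC")
  expect_error(central_dinucleotide("AAACCGTTGAAACGGTT", strrep("N", 17)),
               "odd-length")
})

test_that("orientation calls are Hamming-nearest with honest ties", {
  alph <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(alph, alph, paste0))
  hd <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  for (d in dinucs) {
    dg <- hd(d, "GA"); dt <- hd(d, "TC")
    want <- if (dg < dt) "forward" else if (dt < dg) "reverse" else "ambiguous"
    expect_equal(as.character(classify_orientation(d)), want, label = d)
  }
  expect_equal(as.character(classify_orientation("NA")), "ambiguous")
})

test_that("conservation profiles flag stratum-dependent conservation", {
  # identical sites: fully conserved
  sites <- tibble::tibble(
    start = 1:10, end = 18L, strand = "+", mismatches = 0L,
    matched_seq = rep("AAACCGTTGAAACGGTTT", 10),
    central_dinuc = "GA", orientation = factor("forward")
  )
  prof <- conservation_profile(sites)
  expect_equal(prof$modal_freq, rep(1, 18))
  expect_true(all(prof$conserved))
  expect_equal(attr(prof, "n_sites"), 10L)
  # column counts sum to n_sites
  expect_equal(prof$A + prof$C + prof$G + prof$T, rep(10L, 18))

  # position 1 fixed to A among clean sites, randomized among noisy ones
  set.seed(51)
  noisy <- sites
  noisy$mismatches <- 3L
  noisy$matched_seq <- vapply(1:10, function(i) {
    paste0(sample(c("C", "G", "T"), 1), substr(sites$matched_seq[i], 2, 18))
  }, character(1))
  all_sites <- dplyr::bind_rows(sites, noisy)
  p_clean <- conservation_profile(all_sites, max_mismatch = 1)
  p_all <- conservation_profile(all_sites, max_mismatch = 4)
  expect_true(p_clean$conserved[1])
  expect_false(p_all$conserved[1])

  empty <- conservation_profile(sites[0, ])
  expect_equal(attr(empty, "n_sites"), 0L)
  expect_equal(nrow(empty), 0L)
})
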