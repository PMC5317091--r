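toy_features <- function(strands) {
  tibble::tibble(
    locus_tag = c("g1", "g2"),
    ftype = factor("CDS", levels = c("CDS", "rRNA", "tRNA", "other")),
    start = c(100L, 600L), end = c(400L, 900L), strand = strands
  )
}

toy_site <- function(start, end) {
  tibble::tibble(
    start = start, end = end, strand = "+", mismatches = 0L,
    matched_seq = strrep("A", end - start + 1), central_dinuc = "GA",
    orientation = factor("forward", levels = c("forward", "reverse", "ambiguous"))
  )
}

test_that("strand geometry drives intergenic classification", {
  g <- genome_record(strrep("A", 1000), circular = FALSE)
  conv <- classify_site_context(toy_site(450L, 467L), toy_features(c("+", "-")), g)
  expect_equal(as.character(conv$cls), "intergenic_convergent")
  expect_equal(conv$left_gene, "g1")
  expect_equal(conv$right_gene, "g2")
  expect_equal(conv$dist_left, 49L)
  expect_equal(conv$dist_right, 132L)

  div <- classify_site_context(toy_site(450L, 467L), toy_features(c("-", "+")), g)
  expect_equal(as.character(div$cls), "intergenic_divergent")

  codir <- classify_site_context(toy_site(450L, 467L), toy_features(c("+", "+")), g)
  expect_equal(as.character(codir$cls), "intergenic_codirectional")

  over <- classify_site_context(toy_site(395L, 412L), toy_features(c("+", "-")), g)
  expect_equal(as.character(over$cls), "coding_overlap")
})

test_that("linear genomes produce edge calls and empty tables warn", {
  g <- genome_record(strrep("A", 1000), circular = FALSE)
  edge <- classify_site_context(toy_site(10L, 27L), toy_features(c("+", "-")), g)
  expect_equal(as.character(edge$cls), "edge")

  empty <- toy_features(c("+", "-"))[0, ]
  expect_warning(
    calls <- classify_site_context(toy_site(450L, 467L), empty, g),
    "empty feature table"
  )
  expect_equal(as.character(calls$cls), "edge")
})

test_that("context calls match a brute-force oracle on synthetic fixtures", {
  cfg <- sim_config(length = 30000L, n_sites = 12L,
                    mismatch_spec = rep(0L, 12L), seed = 71)
  fix <- simulate_study(cfg)
  sites <- scan_genome(fix$genome, "nAACCGTTnnAACGGTTn", 0)
  calls <- classify_site_context(sites, fix$features, fix$genome)
  want <- oracle_context(sites, fix$features, fix$genome$length)
  expect_equal(as.character(calls$cls), want)
  expect_equal(as.character(calls$cls)[match(fix$truth$start, calls$start)],
               fix$truth$cls)
  # partition: every site gets exactly one class
  expect_equal(sum(context_summary(calls)$n), nrow(sites))
})

test_that("classification is invariant under rotation of the circle", {
  cfg <- sim_config(length = 20000L, n_sites = 8L,
                    mismatch_spec = rep(0L, 8L), seed = 72)
  fix <- simulate_study(cfg)
  L <- fix$genome$length
  sites <- scan_genome(fix$genome, "nAACCGTTnnAACGGTTn", 0)
  base <- classify_site_context(sites, fix$features, fix$genome)

  # rotate so that no feature or site straddles the new origin
  gaps <- attr(fix$features, "gaps")
  r <- gaps$gap_start[nrow(gaps)]  # cut inside the last internal gap
  stopifnot(!any(sites$start < r & sites$end >= r))
  rot <- function(x) (x - r) %% L + 1L
  g2 <- genome_record(
    paste0(substr(fix$genome$sequence, r, L),
           substr(fix$genome$sequence, 1, r - 1)),
    circular = TRUE
  )
  f2 <- dplyr::arrange(
    dplyr::mutate(fix$features, start = rot(start), end = rot(end)),
    start
  )
  attr(f2, "gaps") <- NULL
  s2 <- dplyr::arrange(
    dplyr::mutate(sites, start = rot(start), end = rot(end)), start
  )
  rotated <- classify_site_context(s2, f2, g2)
  m <- match(rot(base$start), rotated$start)
  expect_equal(as.character(rotated$cls)[m], as.character(base$cls))
})

test_that("upstream distances are strand-aware gaps", {
  expect_equal(upstream_distance(50L, 100L, 401L, 900L, "+"), 300L)
  expect_equal(upstream_distance(383L, 400L, 401L, 900L, "+"), 0L)
  expect_equal(upstream_distance(501L, 518L, 100L, 400L, "-"), 100L)
  expect_equal(upstream_distance(50L, 100L, 401L, 900L, "+",
                                 convention = "offset"), 301L)
  expect_error(upstream_distance(395L, 412L, 100L, 400L, "+"), "overlap")
})

test_that("replichore halves split the circle at ori + ceil(L/2)", {
  expect_equal(as.character(replichore_assign(250, ori = 1, L = 1000)), "first")
  expect_equal(as.character(replichore_assign(501, ori = 1, L = 1000)), "second")
  expect_equal(as.character(replichore_assign(100, ori = 800, L = 1000)), "first")
  expect_error(replichore_assign(0, 1, 1000), "\\[1, L\\]")
  for (L in c(10L, 11L)) {
    for (ori in c(1L, 4L, L)) {
      halves <- replichore_assign(1:L, ori, L)
      expect_equal(sum(halves == "first"), ceiling(L / 2))
    }
  }
})

test_that("replichore dinucleotide tables detect planted asymmetry", {
  L <- 10000L
  mk_sites <- function(starts, dinucs) {
    tibble::tibble(start = starts, central_dinuc = dinucs)
  }
  # GA exclusively first half, TC exclusively second
  s <- mk_sites(c(seq(100, 4900, length.out = 15),
                  seq(5100, 9900, length.out = 15)),
                c(rep("GA", 15), rep("TC", 15)))
  tab <- replichore_dinucleotide_table(s, ori = 1, L = L)
  expect_lt(tab$p_value, 1e-4)

  single <- replichore_dinucleotide_table(mk_sites(100, "GA"), ori = 1, L = L)
  expect_equal(single$p_value, 1)

  # independence: false-positive rate stays nominal over seeded repeats
  set.seed(73)
  hits <- 0L
  for (i in 1:20) {
    s0 <- mk_sites(sample.int(L, 40), sample(c("GA", "TC"), 40, replace = TRUE))
    if (replichore_dinucleotide_table(s0, ori = 1, L = L)$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_lte(hits, 4L)
})

test_that("cumulative GC skew follows its construction and symmetry", {
  sk <- cumulative_gc_skew(genome_record("GGGGCCCC"))
  expect_equal(sk$skew, c(1, 2, 3, 4, 3, 2, 1, 0))
  expect_equal(attr(sk, "max_pos"), 4L)

  flat <- cumulative_gc_skew(genome_record("ATATAT", circular = FALSE))
  expect_equal(flat$skew, rep(0, 6))

  set.seed(74)
  s <- random_genome_seq(500)
  fwd <- cumulative_gc_skew(genome_record(s))$skew
  bwd <- cumulative_gc_skew(genome_record(reverse_complement(s)))$skew
  total <- fwd[500]
  # per-base contributions reverse and flip sign under reverse complement
  expect_equal(bwd + 0, -(total - c(fwd[499:1], 0)) + 0)
})
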