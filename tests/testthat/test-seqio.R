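test_that("FASTA reading normalizes case and maps ambiguity codes to N", {
  p <- write_temp_fasta(c(">x", "acgt"))
  g <- read_genome_fasta(p)
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$length, 4L)
  expect_true(g$circular)

  p2 <- write_temp_fasta(c(">x", "ACGTRY"))
  expect_warning(g2 <- read_genome_fasta(p2), "mapped to N")
  expect_equal(g2$sequence, "ACGTNN")

  p3 <- write_temp_fasta(character(0))
  expect_error(read_genome_fasta(p3))
  expect_error(genome_record("ACXT"), "non-nucleotide")
})

test_that("multi-record FASTA needs an explicit record id", {
  p <- write_temp_fasta(c(">a", "AAAA", ">b", "CCCC"))
  expect_error(read_genome_fasta(p), "records")
  g <- read_genome_fasta(p, id = "b")
  expect_equal(g$sequence, "CCCC")
  expect_equal(g$id, "b")
})

test_that("GC content matches composition and excludes N", {
  expect_equal(gc_content(genome_record("ATGC")), 0.5)
  expect_equal(gc_content(genome_record("GGCC")), 1.0)
  expect_equal(gc_content(genome_record("GGCCNNNN")), 1.0)
  expect_error(gc_content(genome_record("NNNN")), "no A/C/G/T")
})

test_that("GC content is strand-symmetric", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_genome_seq(200)
    both <- paste0(s, reverse_complement(s))
    expect_equal(gc_content(genome_record(both)),
                 gc_content(genome_record(s)))
  }
})

test_that("feature coverage equals the interval union", {
  g <- genome_record(strrep("A", 1000), circular = FALSE)
  tab1 <- tibble::tibble(locus_tag = "g1", ftype = factor("CDS"),
                         start = 1L, end = 500L, strand = "+")
  expect_equal(feature_coverage_fraction(tab1, g), 0.5)
  tab2 <- tibble::tibble(locus_tag = c("g1", "g2"), ftype = factor("CDS"),
                         start = c(1L, 401L), end = c(500L, 900L),
                         strand = "+")
  expect_equal(feature_coverage_fraction(tab2, g), 0.9)
  expect_error(
    feature_coverage_fraction(dplyr::mutate(tab2, end = c(500L, 1200L)), g),
    "bounds"
  )
})

test_that("coverage is invariant to permutation and interval splitting", {
  set.seed(21)
  g <- genome_record(strrep("A", 2000), circular = FALSE)
  for (i in 1:5) {
    n <- 8
    starts <- sample(1900, n)
    ends <- pmin(2000L, starts + sample(300, n))
    tab <- tibble::tibble(locus_tag = paste0("g", 1:n),
                          ftype = factor("CDS"),
                          start = as.integer(starts),
                          end = as.integer(ends), strand = "+")
    cov <- feature_coverage_fraction(tab, g)
    expect_equal(cov, oracle_coverage(starts, ends, 2000))
    perm <- tab[sample(n), ]
    expect_equal(feature_coverage_fraction(perm, g), cov)
    # split the first interval into two adjacent parts
    mid <- tab$start[1] + (tab$end[1] - tab$start[1]) %/% 2
    split <- dplyr::bind_rows(
      tab[-1, ],
      tibble::tibble(locus_tag = c("g1a", "g1b"), ftype = factor("CDS"),
                     start = c(tab$start[1], mid + 1L),
                     end = c(mid, tab$end[1]), strand = "+")
    )
    expect_equal(feature_coverage_fraction(split, g), cov)
  }
})

test_that("feature counts per type include zero classes", {
  empty <- tibble::tibble(locus_tag = character(), ftype = factor(character()),
                          start = integer(), end = integer(),
                          strand = character())
  expect_equal(count_features_by_type(empty)$n, rep(0L, 4))
  toy <- tibble::tibble(
    locus_tag = c("a", "b", "c"),
    ftype = factor(c("CDS", "CDS", "tRNA")),
    start = c(1L, 10L, 20L), end = c(5L, 15L, 25L), strand = "+"
  )
  cnt <- count_features_by_type(toy)
  expect_equal(cnt$n[cnt$ftype == "CDS"], 2L)
  expect_equal(cnt$n[cnt$ftype == "tRNA"], 1L)
  expect_equal(sum(cnt$n), 3L)
})

test_that("GFF3 round-trip preserves coordinates, strands and types", {
  tab <- tibble::tibble(
    locus_tag = c("g1", "g2", "g3"),
    ftype = factor(c("CDS", "tRNA", "CDS"), levels = c("CDS", "rRNA", "tRNA", "other")),
    start = c(100L, 550L, 600L), end = c(400L, 580L, 900L),
    strand = c("+", "+", "-")
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(tab, path, genome_id = "toy")
  back <- read_features(path, dialect = "gff3")
  expect_equal(back$locus_tag, tab$locus_tag)
  expect_equal(back$start, tab$start)
  expect_equal(back$end, tab$end)
  expect_equal(back$strand, tab$strand)
  expect_equal(as.character(back$ftype), as.character(tab$ftype))
})

test_that("GenBank feature tables parse locations and split joins", {
  gbk <- c(
    "LOCUS       toy                1000 bp    DNA     circular BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     gene            100..400",
    "                     /locus_tag=\"T_0001\"",
    "     CDS             100..400",
    "                     /locus_tag=\"T_0001\"",
    "     CDS             complement(600..900)",
    "                     /locus_tag=\"T_0002\"",
    "     CDS             join(10..20,30..40)",
    "                     /locus_tag=\"T_0003\"",
    "     tRNA            950..990",
    "                     /locus_tag=\"T_0004\"",
    "ORIGIN",
    "//"
  )
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk, path)
  tab <- read_features(path, dialect = "genbank")
  expect_equal(nrow(tab), 5L)  # join split into two parts
  j <- tab[tab$locus_tag == "T_0003", ]
  expect_equal(j$start, c(10L, 30L))
  expect_equal(j$end, c(20L, 40L))
  cmp <- tab[tab$locus_tag == "T_0002", ]
  expect_equal(cmp$strand, "-")
  expect_equal(cmp$start, 600L)
  expect_equal(as.character(tab$ftype[tab$locus_tag == "T_0004"]), "tRNA")
  expect_identical(read_features(path, dialect = "auto")$start, tab$start)

  bad <- c("LOCUS       toy", "FEATURES             Location/Qualifiers",
           "     CDS             10..x20")
  path2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(bad, path2)
  expect_error(read_features(path2, dialect = "genbank"), "malformed")
})
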