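#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genome generator. The defaults are
#' the package's reference study conditions for a desk-scale bacterial
#' chromosome carrying a REP-like palindromic repeat family: a 100 kb
#' circular sequence at G+C 0.451, 38 exact plus 5 one-mismatch planted
#' sites, 88% CDS coverage, a context mix in which sites prefer intergenic
#' intervals (13/38 coding, 9/38 convergent, 2/38 divergent, 14/38
#' co-directional), and central-dinucleotide bias GA/AA-dominant on the
#' first replichore half versus TC/TT on the second. The rationale for each
#' default is laid out in the methods vignette.
#'
#' @param length Genome length in bp (>= 1000).
#' @param markov_order Background order k for generation.
#' @param gc_target Target G+C fraction in (0, 1).
#' @param n_sites Number of planted sites; must equal
#'   `length(mismatch_spec)`.
#' @param mismatch_spec Integer vector of per-site mismatch counts.
#' @param dinuc_bias Named list `first` / `second`: distributions over
#'   central dinucleotides per replichore half.
#' @param gene_density Fraction of the genome covered by CDS features.
#' @param orientation_mix Named fractions of adjacent strand pairs
#'   `++`, `+-`, `-+`, `--`; must sum to 1.
#' @param context_mix Named fractions of planted-site placements over
#'   `coding`, `divergent`, `convergent`, `codirectional`; must sum to 1.
#' @param ori Replication origin coordinate used for half assignment.
#' @param min_gap Minimum intergenic gap in bp.
#' @param seed Integer seed; every stochastic choice of a run consumes one
#'   stream keyed by it, so fixtures are exactly reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(length = 100000L,
                       markov_order = 0L,
                       gc_target = 0.451,
                       n_sites = 43L,
                       mismatch_spec = c(rep(0L, 38L), rep(1L, 5L)),
                       dinuc_bias = list(
                         first = c(GA = 0.78, AA = 0.16, TA = 0.03, TC = 0.02, TT = 0.01),
                         second = c(TC = 0.66, TT = 0.20, TA = 0.06, GA = 0.05, AA = 0.03)
                       ),
                       gene_density = 0.88,
                       orientation_mix = c(`++` = 0.25, `+-` = 0.25,
                                           `-+` = 0.25, `--` = 0.25),
                       context_mix = c(coding = 13 / 38, divergent = 2 / 38,
                                       convergent = 9 / 38,
                                       codirectional = 14 / 38),
                       ori = 1L,
                       min_gap = 40L,
                       seed = NULL) {
  stopifnot(length >= 1000)
  if (!(gc_target > 0 && gc_target < 1)) abort("gc_target must be in (0, 1)")
  if (length(mismatch_spec) != n_sites) {
    abort("n_sites must equal length(mismatch_spec)")
  }
  if (abs(sum(orientation_mix) - 1) > 1e-8) abort("orientation_mix must sum to 1")
  if (abs(sum(context_mix) - 1) > 1e-8) abort("context_mix must sum to 1")
  if (!(gene_density > 0 && gene_density < 1)) abort("gene_density must be in (0, 1)")
  stopifnot(all(vapply(dinuc_bias, function(x) abs(sum(x) - 1) < 1e-8, logical(1))))
  structure(
    list(
      length = as.integer(length), markov_order = as.integer(markov_order),
      gc_target = gc_target, n_sites = as.integer(n_sites),
      mismatch_spec = as.integer(mismatch_spec), dinuc_bias = dinuc_bias,
      gene_density = gene_density, orientation_mix = orientation_mix,
      context_mix = context_mix, ori = as.integer(ori),
      min_gap = as.integer(min_gap), seed = seed
    ),
    class = "sim_config"
  )
}

.gc_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Generate a genome from an order-k Markov model
#'
#' Draws a sequence hitting `gc_target` in expectation. By default the
#' transition distribution is context-independent (parameterized directly by
#' the G+C target); an explicit `4^k x 4` transition matrix can be supplied
#' to generate from a non-trivial chain, e.g. to test background fitting.
#' The same seed always yields the identical sequence.
#'
#' @param config A [sim_config()].
#' @param trans Optional transition matrix over contexts (rows, lexicographic
#'   A<C<G<T) by next base (columns A, C, G, T).
#' @return A circular [genome_record()].
#' @export
generate_markov_genome <- function(config, trans = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$length
  k <- config$markov_order
  if (is.null(trans)) {
    codes <- sample.int(4L, L, replace = TRUE, prob = .gc_probs(config$gc_target))
  } else {
    stopifnot(nrow(trans) == 4^k, ncol(trans) == 4)
    if (k == 0L || all(abs(sweep(trans, 2, trans[1, ])) < 1e-12)) {
      codes <- sample.int(4L, L, replace = TRUE, prob = trans[1, ])
    } else {
      codes <- integer(L)
      codes[seq_len(k)] <- sample.int(4L, k, replace = TRUE)
      ctx <- sum((codes[seq_len(k)] - 1L) * 4L^((k - 1L):0))
      for (i in (k + 1L):L) {
        b <- sample.int(4L, 1L, prob = trans[ctx + 1L, ])
        codes[i] <- b
        ctx <- (ctx * 4L + (b - 1L)) %% 4L^k
      }
    }
  }
  genome_record(decode_seq(codes), id = "synthetic", circular = TRUE)
}

#' Generate a synthetic gene feature table
#'
#' Tiles the genome with non-overlapping CDS features whose lengths average
#' ~900 bp and whose gaps track `gene_density`, with strands drawn from a
#' two-state chain matching `orientation_mix`. Each intergenic gap's
#' orientation class (divergent / convergent / co-directional) is recorded
#' by construction in the `gaps` attribute, giving an unambiguous context
#' truth for planted sites.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_record()] (defines the length).
#' @return Feature tibble as in [read_features()], with attribute `gaps`:
#'   a tibble `gap_start`, `gap_end`, `cls`.
#' @export
generate_feature_table <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_record"))
  L <- genome$length
  d <- config$gene_density
  mean_gene <- 900
  if (mean_gene * (1 / d - 1) * 0.7 < config$min_gap) {
    abort("gene_density too high to leave gaps above min_gap")
  }
  mix <- config$orientation_mix
  p_plus_plus <- mix[["++"]] / (mix[["++"]] + mix[["+-"]])
  p_minus_plus <- mix[["-+"]] / (mix[["-+"]] + mix[["--"]])
  starts <- integer(0); ends <- integer(0)
  pos <- 1L
  repeat {
    glen <- max(200L, round(stats::rnorm(1, mean_gene, 150)))
    if (pos + glen - 1L > L - config$min_gap) break
    starts <- c(starts, pos); ends <- c(ends, pos + glen - 1L)
    gap <- max(config$min_gap,
               round(glen * (1 / d - 1) * runif(1, 0.7, 1.3)))
    pos <- pos + glen + gap
  }
  n <- length(starts)
  if (n < 2) abort("genome too short for feature tiling")
  strand <- character(n)
  strand[1] <- sample(c("+", "-"), 1L)
  for (i in 2:n) {
    p_plus <- if (strand[i - 1] == "+") p_plus_plus else p_minus_plus
    strand[i] <- if (runif(1) < p_plus) "+" else "-"
  }
  feats <- tibble(
    locus_tag = sprintf("SIM_%04d", seq_len(n)),
    ftype = .normalize_ftype(rep("CDS", n)),
    start = starts, end = ends, strand = strand
  )
  gap_cls <- function(a, b) {
    switch(paste0(a, b),
      "-+" = "divergent", "+-" = "convergent", "codirectional")
  }
  gaps <- tibble(
    gap_start = ends[-n] + 1L,
    gap_end = starts[-1] - 1L,
    cls = vapply(seq_len(n - 1L),
                 function(i) gap_cls(strand[i], strand[i + 1]), character(1))
  )
  attr(feats, "gaps") <- gaps
  attr(feats, "genome_id") <- genome$id
  feats
}

# Largest-remainder apportionment of n among the mix fractions.
.apportion <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant motif sites into a genome with a known truth table
#'
#' Overwrites `n_sites` non-overlapping windows of the genome with concrete
#' instantiations of the core pattern, each mutated at exactly the number of
#' non-wildcard positions given by `mismatch_spec`. The central dinucleotide
#' of each site is drawn from the `dinuc_bias` distribution of its
#' replichore half; other wildcard positions are drawn from a weak A/T
#' flank-consensus bias. When a feature table is supplied, placements follow
#' `context_mix` (inside a CDS, or wholly within an intergenic gap of the
#' requested orientation class) and never straddle feature boundaries, so
#' the context truth is unambiguous. After planting, the background is
#' scanned at the scrub budget and any accidental match is locally re-rolled
#' (never touching planted bases) until the only matches are the planted
#' ones.
#'
#' @param genome A [genome_record()].
#' @param core Pattern string or [parse_pattern()] object (even length).
#' @param config A [sim_config()].
#' @param features Optional feature tibble from [generate_feature_table()];
#'   without it, sites are placed anywhere.
#' @param scrub_budget Mismatch budget within which the background must stay
#'   free of accidental matches (default `max(4, mismatch_spec)`).
#' @return List with elements `genome` (modified record), `truth` (tibble
#'   `start`, `end`, `mismatches`, `central_dinuc`, `half`, `cls`), and
#'   `config`.
#' @export
plant_sites <- function(genome, core, config, features = NULL,
                        scrub_budget = NULL) {
  stopifnot(inherits(genome, "genome_record"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- parse_pattern(core)
  w <- p$length
  L <- genome$length
  n <- config$n_sites
  spec <- config$mismatch_spec
  scrub_budget <- scrub_budget %||% max(4L, spec, na.rm = TRUE)
  if (n == 0) {
    return(list(genome = genome,
                truth = .empty_truth(), config = config))
  }
  if (any(spec > w - length(p$wildcard_positions))) {
    abort("mismatch counts exceed non-wildcard positions")
  }
  if (n * w * 4 > L) abort("too many sites for this genome length")

  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]

  # placement compartments
  if (!is.null(features)) {
    gaps <- attr(features, "gaps")
    if (is.null(gaps)) gaps <- .gaps_from_features(features)
    cls_labels <- c("coding", "divergent", "convergent", "codirectional")
    counts <- .apportion(config$context_mix[cls_labels], n)
    classes <- sample(rep(cls_labels, counts))
  } else {
    classes <- rep("anywhere", n)
  }

  occupied <- matrix(integer(0), ncol = 2)
  margin <- 3L
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      s <- .propose_start(classes[i], features, w, margin, L)
      if (is.na(s)) next
      e <- s + w - 1L
      if (e > L) next
      if (nrow(occupied) > 0 &&
          any(s - w <= occupied[, 2] & e + w >= occupied[, 1])) next
      placed <- TRUE
      break
    }
    if (!placed) abort(sprintf("could not place site %d without overlap", i))
    occupied <- rbind(occupied, c(s, e))
    half <- replichore_assign(s, config$ori, L)
    inst <- .instantiate_core(p, half, config$dinuc_bias)
    mut <- .mutate_core(inst, p, spec[i])
    chars[s:e] <- mut$bases
    truth_rows[[i]] <- tibble(
      start = as.integer(s), end = as.integer(e), mismatches = spec[i],
      central_dinuc = paste(mut$bases[w / 2 + c(0L, 1L)], collapse = ""),
      half = as.character(half),
      cls = switch(classes[i],
        coding = "coding_overlap",
        divergent = "intergenic_divergent",
        convergent = "intergenic_convergent",
        codirectional = "intergenic_codirectional",
        anywhere = NA_character_
      )
    )
  }
  truth <- arrange(bind_rows(truth_rows), .data$start)

  chars <- .scrub_background(chars, p, truth, scrub_budget, config, genome$circular)
  g2 <- genome
  g2$sequence <- paste(chars, collapse = "")
  list(genome = g2, truth = truth, config = config)
}

.empty_truth <- function() {
  tibble(start = integer(), end = integer(), mismatches = integer(),
         central_dinuc = character(), half = character(), cls = character())
}

.gaps_from_features <- function(features) {
  env <- feature_envelopes(features)
  n <- nrow(env)
  if (n < 2) return(tibble(gap_start = integer(), gap_end = integer(), cls = character()))
  cls <- vapply(seq_len(n - 1L), function(i) {
    switch(paste0(env$strand[i], env$strand[i + 1]),
      "-+" = "divergent", "+-" = "convergent", "codirectional")
  }, character(1))
  tibble(gap_start = env$end[-n] + 1L, gap_end = env$start[-1] - 1L, cls = cls) %>%
    filter(.data$gap_end >= .data$gap_start)
}

.propose_start <- function(class, features, w, margin, L) {
  if (class == "anywhere") {
    return(sample.int(L - w + 1L, 1L))
  }
  if (class == "coding") {
    ok <- features[features$end - features$start + 1L >= w + 2L * margin, , drop = FALSE]
    if (nrow(ok) == 0) return(NA_integer_)
    g <- ok[sample.int(nrow(ok), 1L), ]
    return(g$start + margin + sample.int(g$end - g$start + 1L - w - 2L * margin + 1L, 1L) - 1L)
  }
  gaps <- attr(features, "gaps")
  ok <- gaps[gaps$cls == class &
               gaps$gap_end - gaps$gap_start + 1L >= w + 2L, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_integer_)
  g <- ok[sample.int(nrow(ok), 1L), ]
  g$gap_start + 1L + sample.int(g$gap_end - g$gap_start + 1L - w - 1L, 1L) - 1L
}

# Draw a concrete instantiation of the core for a site on a given half.
.instantiate_core <- function(p, half, dinuc_bias) {
  w <- p$length
  bases <- strsplit(p$bases, "", fixed = TRUE)[[1]]
  wild <- p$wildcard_positions
  c1 <- w %/% 2L; c2 <- c1 + 1L
  if (w %% 2L == 0L && all(c(c1, c2) %in% wild)) {
    dist <- dinuc_bias[[as.character(half)]]
    dn <- sample(names(dist), 1L, prob = dist)
    bases[c1] <- substring(dn, 1, 1)
    bases[c2] <- substring(dn, 2, 2)
    wild <- setdiff(wild, c(c1, c2))
  }
  # flank wildcards: weak A (left) / T (right) consensus bias
  left_bias <- c(A = 0.70, C = 0.05, G = 0.05, T = 0.20)
  right_bias <- c(A = 0.20, C = 0.05, G = 0.05, T = 0.70)
  for (j in wild) {
    bias <- if (j <= w / 2) left_bias else right_bias
    bases[j] <- sample(names(bias), 1L, prob = bias)
  }
  bases
}

.mutate_core <- function(bases, p, k) {
  if (k > 0) {
    fixed <- setdiff(seq_len(p$length), p$wildcard_positions)
    pos <- sample(fixed, k)
    for (j in pos) bases[j] <- sample(setdiff(.BASES, bases[j]), 1L)
  }
  list(bases = bases)
}

# Re-roll accidental background matches without touching planted bases.
.scrub_background <- function(chars, p, truth, budget, config, circular) {
  L <- length(chars)
  w <- p$length
  planted <- rep(FALSE, L)
  for (i in seq_len(nrow(truth))) planted[truth$start[i]:truth$end[i]] <- TRUE
  probs <- .gc_probs(config$gc_target)
  for (iter in seq_len(50L)) {
    g <- genome_record(paste(chars, collapse = ""), circular = circular)
    hits <- scan_genome(g, p, max_mismatch = budget, circular = circular)
    accidental <- setdiff(hits$start, truth$start)
    if (length(accidental) == 0) return(chars)
    for (s in accidental) {
      idx <- ((s - 1L):(s + w - 2L)) %% L + 1L
      free <- idx[!planted[idx]]
      if (length(free) == 0) {
        abort("accidental match inseparable from planted sites")
      }
      chars[free] <- .BASES[sample.int(4L, length(free), replace = TRUE, prob = probs)]
    }
  }
  abort("background scrubbing did not converge")
}

#' Run a full synthetic study
#'
#' One call that seeds the stream once and chains
#' [generate_markov_genome()], [generate_feature_table()] and
#' [plant_sites()], so a single integer reproduces the whole fixture.
#'
#' @param config A [sim_config()].
#' @param core Core pattern to plant (default the 18-nt palindrome core
#'   `nAACCGTTnnAACGGTTn`).
#' @return List `genome`, `features`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           core = "nAACCGTTnnAACGGTTn") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  quiet <- config
  quiet$seed <- NULL
  genome <- generate_markov_genome(quiet)
  features <- generate_feature_table(quiet, genome)
  planted <- plant_sites(genome, core, quiet, features = features)
  list(genome = planted$genome, features = features, truth = planted$truth,
       config = config)
}

#' Write a synthetic fixture to disk
#'
#' Emits the genome as FASTA, the features as GFF3, the planted-site truth
#' as TSV, and the configuration as a YAML reproducibility manifest:
#' re-running with the manifest's seed regenerates the identical fixture.
#'
#' @param genome A [genome_record()].
#' @param features Feature tibble.
#' @param truth Truth tibble from [plant_sites()].
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] to record as `config.yaml`.
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture <- function(genome, features, truth, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fasta")
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, fa)
  gff <- file.path(dir, "features.gff3")
  write_features_gff3(features, gff, genome_id = genome$id)
  tsv <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, tsv)
  paths <- c(fasta = fa, gff3 = gff, truth = tsv)
  if (!is.null(config)) {
    yml <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(config), yml)
    paths <- c(paths, manifest = yml)
  }
  invisible(paths)
}
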