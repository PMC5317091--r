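#' Run the full repeat-characterization pipeline
#'
#' Orchestrates the whole analysis for one genome and one core pattern:
#' genome summaries (length, G+C, CDS coverage, feature counts), a
#' mismatch-stratified scan, per-stratum conservation profiles, context
#' classification of every site, the central-dinucleotide table overall and
#' by replichore half, spatial uniformity of the zero-mismatch sites, and
#' observed-versus-expected enrichment per mismatch budget against a fitted
#' Markov background. Deterministic given inputs and `seed` (the seed feeds
#' the Monte Carlo expected-count estimator when enumeration is capped).
#'
#' @param genome A [genome_record()] or path to a FASTA file.
#' @param features Feature tibble, or path to a GFF3/GenBank file, or NULL
#'   (context section degrades to `edge` calls with a warning).
#' @param core Core pattern (default the 18-nt palindrome core).
#' @param ori Replication origin in bp; required for the replichore section
#'   and never guessed (use [cumulative_gc_skew()] for a hint).
#' @param max_mismatch Largest mismatch budget analyzed (default 4).
#' @param strand_stratum Mismatch stratum used for the central-dinucleotide
#'   and replichore tables (default 1: the zero- and one-mismatch sites that
#'   carry the directionality signal).
#' @param conserved_threshold Modal-frequency threshold for
#'   [conservation_profile()].
#' @param bg_order Markov background order for enrichment.
#' @param mc_samples Monte Carlo sample size for capped expected counts.
#' @param seed Optional integer seed.
#' @return An object of class `palcore_report`; see [tidy.palcore_report()]
#'   and [glance.palcore_report()], and [write_report()] to serialize.
#' @export
run_characterization <- function(genome, features = NULL,
                                 core = "nAACCGTTnnAACGGTTn",
                                 ori = 1L, max_mismatch = 4L,
                                 strand_stratum = 1L,
                                 conserved_threshold = 0.75,
                                 bg_order = 2L, mc_samples = 2e5,
                                 seed = NULL) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(features)) features <- read_features(features)
  if (!is.null(seed)) set.seed(seed)
  p <- parse_pattern(core)
  L <- genome$length

  genome_summary <- tibble(
    genome_id = genome$id, length = L, gc = gc_content(genome),
    cds_coverage = if (!is.null(features)) {
      feature_coverage_fraction(features, genome)
    } else NA_real_
  )
  feature_counts <- if (!is.null(features)) {
    count_features_by_type(features)
  } else NULL

  sites <- scan_genome(genome, p, max_mismatch = max_mismatch)
  strata <- 0:max_mismatch
  stratum_counts <- tibble(
    max_mismatch = strata,
    n_sites = vapply(strata, function(m) sum(sites$mismatches <= m), integer(1))
  )

  profiles <- lapply(strata, function(m) {
    conservation_profile(sites, max_mismatch = m,
                         threshold = conserved_threshold)
  })
  names(profiles) <- paste0("le_", strata)

  context <- classify_site_context(
    sites,
    features %||% tibble(
      locus_tag = character(), ftype = .normalize_ftype(character()),
      start = integer(), end = integer(), strand = character()
    ),
    genome
  )
  context_by_stratum <- lapply(strata, function(m) {
    context_summary(context[context$mismatches <= m, , drop = FALSE])
  })
  names(context_by_stratum) <- paste0("le_", strata)

  strand_sites <- sites[sites$mismatches <= strand_stratum, , drop = FALSE]
  dinuc_overall <- dplyr::count(strand_sites, .data$central_dinuc,
                                sort = TRUE)
  replichore <- replichore_dinucleotide_table(strand_sites, ori = ori, L = L)

  zero <- sites[sites$mismatches == 0, , drop = FALSE]
  spatial <- if (nrow(zero) >= 2) {
    spacing_uniformity(zero$start, L)
  } else NULL

  bg <- fit_markov(genome, order = bg_order)
  enr <- suppressWarnings(enrichment(
    stratum_counts$n_sites,
    vapply(strata, function(m) {
      expected_count(p, bg, L, max_mismatch = m, mc_samples = mc_samples)
    }, double(1))
  ))
  enr <- mutate(enr, max_mismatch = strata, .before = 1)

  structure(
    list(
      genome_summary = genome_summary,
      feature_counts = feature_counts,
      core = p,
      sites = sites,
      stratum_counts = stratum_counts,
      profiles = profiles,
      context = context,
      context_by_stratum = context_by_stratum,
      dinuc_overall = dinuc_overall,
      replichore = replichore,
      spatial = spatial,
      enrichment = enr,
      provenance = list(
        genome_id = genome$id, core = p$text, ori = ori,
        max_mismatch = max_mismatch, strand_stratum = strand_stratum,
        conserved_threshold = conserved_threshold, bg_order = bg_order,
        mc_samples = mc_samples, seed = seed,
        package_version = as.character(utils::packageVersion("palcore")),
        generated = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "palcore_report"
  )
}

#' @export
print.palcore_report <- function(x, ...) {
  gs <- x$genome_summary
  cat(sprintf(
    "<palcore_report> %s (%s bp, G+C %.1f%%%s)\n",
    gs$genome_id, format(gs$length, big.mark = ","), 100 * gs$gc,
    if (!is.na(gs$cds_coverage)) sprintf(", CDS coverage %.0f%%", 100 * gs$cds_coverage) else ""
  ))
  cat(sprintf("core %s\n", x$core$text))
  cat("sites per mismatch stratum:\n")
  print(as.data.frame(x$stratum_counts), row.names = FALSE)
  cat(sprintf("replichore association p = %.3g (%s)\n",
              x$replichore$p_value, x$replichore$method))
  invisible(x)
}

#' Tidy a characterization report into a per-site tibble
#'
#' @param x A `palcore_report`.
#' @param ... Unused.
#' @return The context-annotated site tibble, one row per site, with its
#'   replichore half added.
#' @method tidy palcore_report
#' @export
tidy.palcore_report <- function(x, ...) {
  L <- x$genome_summary$length
  x$context %>%
    mutate(half = replichore_assign(.data$start, x$provenance$ori, L))
}

#' One-row summary of a characterization report
#'
#' @param x A `palcore_report`.
#' @param ... Unused.
#' @return A one-row tibble: genome length, G+C, CDS coverage, exact-core
#'   and within-one-mismatch site counts, coding-overlap and convergent
#'   counts among exact sites, replichore association p, KS uniformity p,
#'   and the exact-core enrichment z.
#' @method glance palcore_report
#' @export
glance.palcore_report <- function(x, ...) {
  ctx0 <- x$context_by_stratum$le_0
  n_cls <- function(cls) ctx0$n[as.character(ctx0$cls) == cls]
  tibble(
    length = x$genome_summary$length,
    gc = x$genome_summary$gc,
    cds_coverage = x$genome_summary$cds_coverage,
    n_exact = x$stratum_counts$n_sites[x$stratum_counts$max_mismatch == 0],
    n_le1 = x$stratum_counts$n_sites[x$stratum_counts$max_mismatch == 1],
    coding_overlap_exact = n_cls("coding_overlap"),
    convergent_exact = n_cls("intergenic_convergent"),
    replichore_p = x$replichore$p_value,
    ks_p = if (!is.null(x$spatial)) x$spatial$ks_p else NA_real_,
    enrichment_z_exact = x$enrichment$z[x$enrichment$max_mismatch == 0]
  )
}

#' Serialize a report to JSON and TSV files
#'
#' Writes `report.json` plus `sites.tsv`, `context.tsv` and `profile.tsv`
#' (all strata stacked) so that every number in the JSON is recomputable
#' from the TSVs. Re-running on identical inputs yields identical files
#' apart from the provenance block's timestamp.
#'
#' @param report A `palcore_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sites_path <- file.path(dir, "sites.tsv")
  readr::write_tsv(
    report$sites %>% mutate(orientation = as.character(.data$orientation)),
    sites_path
  )
  ctx_path <- file.path(dir, "context.tsv")
  readr::write_tsv(
    report$context %>% mutate(
      cls = as.character(.data$cls),
      orientation = as.character(.data$orientation)
    ),
    ctx_path
  )
  prof_path <- file.path(dir, "profile.tsv")
  prof <- purrr::imap(report$profiles, function(pr, nm) {
    as_tibble(pr) %>% mutate(stratum = nm, .before = 1)
  })
  readr::write_tsv(bind_rows(prof), prof_path)

  json_path <- file.path(dir, "report.json")
  body <- list(
    genome = report$genome_summary,
    feature_counts = report$feature_counts,
    core = report$core$text,
    stratum_counts = report$stratum_counts,
    conserved_positions = lapply(report$profiles, function(pr) pr$position[pr$conserved]),
    context_by_stratum = report$context_by_stratum,
    central_dinucleotides = report$dinuc_overall,
    replichore = list(
      table = as.data.frame(report$replichore$table),
      p_value = report$replichore$p_value,
      method = report$replichore$method,
      ori = report$replichore$ori
    ),
    spatial = report$spatial,
    enrichment = report$enrichment,
    provenance = report$provenance
  )
  jsonlite::write_json(body, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(json = json_path, sites = sites_path, context = ctx_path,
              profile = prof_path))
}
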