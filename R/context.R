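.CONTEXT_CLASSES <- c("coding_overlap", "intergenic_divergent",
                      "intergenic_convergent", "intergenic_codirectional",
                      "edge")

#' Classify sites by genomic context
#'
#' Each site is related to the gene annotation: any >= 1 bp intersection with
#' a coding feature makes it `coding_overlap`; otherwise the flanking gene
#' pair (resolved circularly on a circular genome) determines the intergenic
#' class. Reading left to right, a `(-, +)` pair is `intergenic_divergent`
#' (the genes point away from each other, start to start — the interval type
#' enriched for regulatory sites), `(+, -)` is `intergenic_convergent` (stop
#' to stop), and `(+, +)` / `(-, -)` are `intergenic_codirectional`. On a
#' linear genome a site with no flank on one side is `edge`.
#'
#' Coding overlap is tested against `coding_types` features (default CDS
#' only), while flanks are resolved against the per-locus envelopes of
#' `flank_types` (default CDS, rRNA, tRNA): a gap bounded by a tRNA is still
#' a genuine gap.
#'
#' @param sites Site tibble from [scan_genome()].
#' @param features Feature tibble from [read_features()].
#' @param genome A [genome_record()].
#' @param coding_types Feature types that count as coding for overlap.
#' @param flank_types Feature types used to resolve flanking genes.
#' @return The site tibble with added columns `cls` (factor over the five
#'   classes), `left_gene`, `right_gene`, `dist_left`, `dist_right`.
#' @export
classify_site_context <- function(sites, features, genome,
                                  coding_types = "CDS",
                                  flank_types = c("CDS", "rRNA", "tRNA")) {
  stopifnot(inherits(genome, "genome_record"))
  L <- genome$length
  n <- nrow(sites)
  empty_cols <- function(cls) {
    sites %>% mutate(
      cls = factor(cls, levels = .CONTEXT_CLASSES),
      left_gene = NA_character_, right_gene = NA_character_,
      dist_left = NA_integer_, dist_right = NA_integer_
    )
  }
  if (nrow(features) == 0) {
    warn("empty feature table: all sites classified as edge")
    return(empty_cols(rep("edge", n)))
  }
  if (n == 0) return(empty_cols(character()))

  cds <- features[as.character(features$ftype) %in% coding_types, , drop = FALSE]
  env <- feature_envelopes(features, ftypes = flank_types)

  # site intervals, splitting origin-wrapping sites into two pieces
  wrap <- sites$end < sites$start
  site_ir <- IRanges::IRanges(
    start = c(sites$start, sites$start[wrap], rep(1L, sum(wrap))),
    end = c(ifelse(wrap, L, sites$end), rep(L, sum(wrap)), sites$end[wrap]),
    names = c(seq_len(n), which(wrap), which(wrap))
  )
  overlaps_cds <- rep(FALSE, n)
  if (nrow(cds) > 0) {
    hits <- IRanges::findOverlaps(
      site_ir, IRanges::IRanges(start = cds$start, end = cds$end)
    )
    overlaps_cds[unique(as.integer(names(site_ir)[S4Vectors::queryHits(hits)]))] <- TRUE
  }

  cls <- character(n)
  left_gene <- right_gene <- rep(NA_character_, n)
  dist_left <- dist_right <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (overlaps_cds[i]) {
      cls[i] <- "coding_overlap"
      next
    }
    s0 <- sites$start[i]; e0 <- sites$end[i]
    # envelopes overlapping the site are never its flanks
    ov_env <- env$start <= e0 & env$end >= s0
    cand <- env[!ov_env, , drop = FALSE]
    if (nrow(cand) == 0) {
      cls[i] <- "edge"
      next
    }
    dl <- (s0 - cand$end - 1L) %% L
    dr <- (cand$start - e0 - 1L) %% L
    if (!genome$circular) {
      dl[cand$end >= s0] <- NA
      dr[cand$start <= e0] <- NA
      if (all(is.na(dl)) || all(is.na(dr))) {
        cls[i] <- "edge"
        il <- which.min(dl); ir <- which.min(dr)
        if (length(il)) { left_gene[i] <- cand$locus_tag[il]; dist_left[i] <- dl[il] }
        if (length(ir)) { right_gene[i] <- cand$locus_tag[ir]; dist_right[i] <- dr[ir] }
        next
      }
    }
    il <- which.min(dl)
    ir <- which.min(dr)
    left_gene[i] <- cand$locus_tag[il]
    right_gene[i] <- cand$locus_tag[ir]
    dist_left[i] <- dl[il]
    dist_right[i] <- dr[ir]
    pair <- paste0(cand$strand[il], cand$strand[ir])
    cls[i] <- switch(pair,
      "-+" = "intergenic_divergent",
      "+-" = "intergenic_convergent",
      "intergenic_codirectional"
    )
  }
  sites %>% mutate(
    cls = factor(cls, levels = .CONTEXT_CLASSES),
    left_gene = left_gene, right_gene = right_gene,
    dist_left = dist_left, dist_right = dist_right
  )
}

#' Summarize context calls by class
#'
#' @param calls Output of [classify_site_context()].
#' @return Tibble with one row per context class and count `n` (zeros kept);
#'   counts sum to the number of sites.
#' @export
context_summary <- function(calls) {
  tibble(cls = factor(.CONTEXT_CLASSES, levels = .CONTEXT_CLASSES)) %>%
    left_join(dplyr::count(calls, .data$cls), by = "cls") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Distance from a site to a gene's 5' end
#'
#' Strand-aware upstream distance: the 5' coordinate is `start` for a `+`
#' gene and `end` for a `-` gene. With the default `"gap"` convention the
#' distance is the number of bases strictly between the site boundary
#' nearest the 5' coordinate and that coordinate (0 when immediately
#' adjacent); `"offset"` counts the coordinate difference (gap + 1). The
#' convention is explicit because published upstream distances rarely state
#' which was used. Vectorized; sites overlapping the gene are an error —
#' those belong to the coding-overlap path.
#'
#' @param site_start,site_end Site interval (1-based inclusive).
#' @param gene_start,gene_end,gene_strand Gene interval and strand.
#' @param convention `"gap"` (default) or `"offset"`.
#' @return Integer distance(s) in bp.
#' @export
#' @examples
#' upstream_distance(50, 100, 401, 900, "+")  # 300
upstream_distance <- function(site_start, site_end, gene_start, gene_end,
                              gene_strand, convention = c("gap", "offset")) {
  convention <- match.arg(convention)
  if (any(site_start <= gene_end & site_end >= gene_start)) {
    abort("site overlaps gene; use classify_site_context for coding overlaps")
  }
  five_prime <- ifelse(gene_strand == "+", gene_start, gene_end)
  gap <- ifelse(site_end < five_prime,
                five_prime - site_end - 1L,
                site_start - five_prime - 1L)
  as.integer(gap + if (convention == "offset") 1L else 0L)
}

#' Assign positions to replichore halves
#'
#' The first replichore is the half-open circular arc
#' `[ori, ori + ceiling(L/2))`; everything else is the second. Exactly
#' `ceiling(L/2)` positions map to `first` for any origin. The origin is a
#' required input (from literature or a cumulative-skew hint); it is never
#' guessed.
#'
#' @param position Positions in bp (vectorized).
#' @param ori Replication origin coordinate in bp.
#' @param L Genome length in bp.
#' @return Factor with levels `first`, `second`.
#' @export
#' @examples
#' replichore_assign(c(250, 501), ori = 1, L = 1000)
replichore_assign <- function(position, ori, L) {
  if (any(position < 1 | position > L) || ori < 1 || ori > L) {
    abort("position and ori must lie in [1, L]")
  }
  rel <- (position - ori) %% L
  factor(ifelse(rel < ceiling(L / 2), "first", "second"),
         levels = c("first", "second"))
}

#' Central-dinucleotide asymmetry between replichore halves
#'
#' Cross-tabulates the replichore half of each site (by its start
#' coordinate) against its central dinucleotide and tests for association
#' (Fisher's exact test, falling back to chi-square when the exact network
#' algorithm is infeasible). For nearly palindromic repeats whose central
#' pair encodes direction, an association indicates a leading/lagging-strand
#' preference.
#'
#' @param sites Site tibble with `start` and `central_dinuc`.
#' @param ori Replication origin in bp.
#' @param L Genome length in bp.
#' @return A list of class `replichore_table`: `table` (half x dinucleotide
#'   contingency table), `p_value`, `method`, `ori`.
#' @export
replichore_dinucleotide_table <- function(sites, ori, L) {
  half <- replichore_assign(sites$start, ori, L)
  tab <- table(half = half, dinuc = sites$central_dinuc)
  nz <- tab[, colSums(tab) > 0, drop = FALSE]
  nz <- nz[rowSums(nz) > 0, , drop = FALSE]
  if (nrow(nz) < 2 || ncol(nz) < 2) {
    p <- 1
    method <- "degenerate"
  } else {
    res <- tryCatch(
      list(p = fisher.test(nz, workspace = 2e7)$p.value, method = "fisher"),
      error = function(e) {
        list(p = suppressWarnings(chisq.test(nz)$p.value), method = "chisq")
      }
    )
    p <- res$p
    method <- res$method
  }
  structure(list(table = tab, p_value = p, method = method, ori = ori),
            class = "replichore_table")
}

#' @export
print.replichore_table <- function(x, ...) {
  cat(sprintf("<replichore x dinucleotide> ori = %d, %s p = %.3g\n",
              x$ori, x$method, x$p_value))
  print(x$table)
  invisible(x)
}

#' @rdname replichore_dinucleotide_table
#' @param x A `replichore_table`.
#' @param ... Unused.
#' @method tidy replichore_table
#' @export
tidy.replichore_table <- function(x, ...) {
  as_tibble(as.data.frame(x$table, stringsAsFactors = FALSE)) %>%
    rename(n = "Freq")
}

#' Cumulative GC skew along a genome
#'
#' Running cumulative sum of the per-base skew contribution (+1 for G, -1
#' for C, 0 otherwise). The global minimum and maximum positions are hints
#' for the replication origin and terminus on many bacterial chromosomes —
#' hints only: this package never predicts an origin itself.
#'
#' @param genome A [genome_record()].
#' @return Tibble `position`, `skew`, with attributes `min_pos` and
#'   `max_pos` (first position attaining each extremum).
#' @export
cumulative_gc_skew <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  codes <- encode_seq(genome$sequence)
  contrib <- (codes == 3L) - (codes == 2L)  # G minus C
  skew <- cumsum(contrib)
  out <- tibble(position = seq_along(skew), skew = skew)
  attr(out, "min_pos") <- which.min(skew)
  attr(out, "max_pos") <- which.max(skew)
  out
}
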