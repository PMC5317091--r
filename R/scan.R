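# Vectorized mismatch counts for every window start on an encoded genome.
# Returns an integer vector over starts 1..n_win.
.window_mismatches <- function(codes, pattern, n_win) {
  p <- parse_pattern(pattern)
  pat <- encode_seq(p$bases)
  mm <- integer(n_win)
  for (j in seq_len(p$length)) {
    if (pat[j] == 5L) next  # wildcard
    mm <- mm + (codes[j:(j + n_win - 1L)] != pat[j])
  }
  mm
}

.site_tibble <- function(seq2, starts, mm, w, L, strand) {
  even <- w %% 2L == 0L
  if (length(starts) == 0) {
    return(tibble(
      start = integer(), end = integer(), strand = character(),
      mismatches = integer(), matched_seq = character(),
      central_dinuc = character(),
      orientation = factor(character(),
                           levels = c("forward", "reverse", "ambiguous"))
    ))
  }
  matched <- substring(seq2, starts, starts + w - 1L)
  central <- if (even) substring(seq2, starts + w / 2L - 1L, starts + w / 2L) else NA_character_
  tibble(
    start = as.integer(starts),
    end = as.integer((starts + w - 1L - 1L) %% L + 1L),
    strand = strand,
    mismatches = as.integer(mm),
    matched_seq = matched,
    central_dinuc = central,
    orientation = if (even) classify_orientation(central) else factor(rep(NA, length(starts)), levels = c("forward", "reverse", "ambiguous"))
  )
}

#' Scan a genome for a degenerate pattern within a mismatch budget
#'
#' Reports every forward-strand window whose wildcard-aware Hamming distance
#' to the pattern is at most `max_mismatch`. Overlapping occurrences are all
#' reported (no masking), matching how raw occurrence counts of repeat
#' families are quoted. On a circular genome, windows wrapping the coordinate
#' origin are included once, with `end < start` marking the wrap.
#'
#' For an even-length pattern each hit also carries its central dinucleotide
#' (the two middle bases as read on the forward strand) and the orientation
#' class derived from it; for nearly palindromic repeats this dinucleotide is
#' what encodes strand directionality.
#'
#' @param genome A [genome_record()].
#' @param core Pattern string or [parse_pattern()] object.
#' @param max_mismatch Mismatch budget (>= 0) over non-wildcard positions.
#' @param circular Include wrap-around windows; defaults to the genome's
#'   circularity flag.
#' @return A tibble of site hits sorted by start: `start`, `end`, `strand`
#'   (always `"+"`), `mismatches`, `matched_seq`, `central_dinuc`,
#'   `orientation`.
#' @export
#' @examples
#' g <- genome_record("TTTTAAACCGTTGAAACGGTTTCCCC", circular = FALSE)
#' scan_genome(g, "nAACCGTTnnAACGGTTn", max_mismatch = 0)
scan_genome <- function(genome, core, max_mismatch = 0L,
                        circular = genome$circular) {
  stopifnot(inherits(genome, "genome_record"), max_mismatch >= 0)
  p <- parse_pattern(core)
  L <- genome$length
  w <- p$length
  if (w > L) abort("pattern longer than genome")
  seq2 <- if (circular && w > 1L) {
    paste0(genome$sequence, substr(genome$sequence, 1L, w - 1L))
  } else {
    genome$sequence
  }
  n_win <- if (circular) L else L - w + 1L
  codes <- encode_seq(seq2)
  mm <- .window_mismatches(codes, p, n_win)
  starts <- which(mm <= max_mismatch)
  .site_tibble(seq2, starts, mm[starts], w, L, strand = rep("+", length(starts)))
}

#' Search both strands for a (possibly non-palindromic) consensus
#'
#' Scans the forward strand with the consensus and with its reverse
#' complement, reporting all hits in forward-strand coordinates with a
#' `strand` mark. For a self-reverse-complementary consensus the second pass
#' would duplicate the first and is suppressed. Used e.g. for transcription
#' factor operator consensi with N spacers, where "deviations" are wildcard-
#' aware Hamming mismatches.
#'
#' @inheritParams scan_genome
#' @param consensus Pattern string or [parse_pattern()] object.
#' @param max_dev Maximum number of deviations (mismatches) tolerated.
#' @return Site tibble as in [scan_genome()] with `strand` in `{"+", "-"}`.
#' @export
consensus_site_search <- function(genome, consensus, max_dev = 0L,
                                  circular = genome$circular) {
  p <- parse_pattern(consensus)
  fwd <- scan_genome(genome, p, max_mismatch = max_dev, circular = circular)
  if (is_self_reverse_complement(p)) return(fwd)
  rev <- scan_genome(genome, reverse_complement(p),
                     max_mismatch = max_dev, circular = circular)
  rev$strand <- rep("-", nrow(rev))
  arrange(bind_rows(fwd, rev), .data$start, .data$strand)
}

#' Central dinucleotide of site hits
#'
#' The forward-strand bases at pattern positions `w/2` and `w/2 + 1` (for an
#' 18-mer: positions 9-10). Defined only for even-length patterns.
#'
#' @param matched_seq Character vector of matched site sequences, or a site
#'   tibble with a `matched_seq` column.
#' @param core The pattern the sites match (its length defines the center).
#' @return Character vector of 2-mers.
#' @export
central_dinucleotide <- function(matched_seq, core) {
  p <- parse_pattern(core)
  if (p$length %% 2L != 0L) abort("central pair undefined for odd-length pattern")
  if (is.data.frame(matched_seq)) matched_seq <- matched_seq$matched_seq
  substring(matched_seq, p$length / 2L, p$length / 2L + 1L)
}

#' Classify site orientation from the central dinucleotide
#'
#' For repeat families whose direction is written in the two central bases,
#' a site is `forward` when its central dinucleotide is Hamming-nearest to
#' `GA`, `reverse` when nearest to the complementary `TC`, and `ambiguous`
#' when equidistant (ties are never broken arbitrarily). Any `N` in the pair
#' is `ambiguous`.
#'
#' @param central Character vector of 2-mers.
#' @param forward_dinuc,reverse_dinuc The two anchor dinucleotides; the
#'   defaults `GA`/`TC` are mutually complementary.
#' @return Factor with levels forward, reverse, ambiguous.
#' @export
#' @examples
#' classify_orientation(c("GA", "TT", "TA"))
classify_orientation <- function(central, forward_dinuc = "GA",
                                 reverse_dinuc = "TC") {
  central <- toupper(central)
  c1 <- substring(central, 1, 1)
  c2 <- substring(central, 2, 2)
  d_f <- (c1 != substring(forward_dinuc, 1, 1)) + (c2 != substring(forward_dinuc, 2, 2))
  d_r <- (c1 != substring(reverse_dinuc, 1, 1)) + (c2 != substring(reverse_dinuc, 2, 2))
  out <- ifelse(d_f < d_r, "forward", ifelse(d_r < d_f, "reverse", "ambiguous"))
  out[grepl("N", central) | is.na(central)] <- "ambiguous"
  factor(out, levels = c("forward", "reverse", "ambiguous"))
}

#' Per-position conservation profile of a mismatch stratum
#'
#' Tallies base counts per pattern position over the matched sequences of the
#' sites in a mismatch stratum (all sites with `mismatches <= max_mismatch`),
#' and flags a position as conserved when its modal base frequency reaches
#' `threshold`. Comparing strata shows which positions stay conserved only
#' when few mismatches are allowed.
#'
#' @param sites Site tibble from [scan_genome()]; all hits must share one
#'   pattern length.
#' @param max_mismatch Stratum filter: keep sites with at most this many
#'   mismatches (default `Inf`, i.e. all).
#' @param threshold Modal-base frequency at or above which a position is
#'   flagged conserved (default 0.75).
#' @return An object of class `palcore_profile`: a tibble with one row per
#'   position (`position`, counts `A`/`C`/`G`/`T`, `modal_base`,
#'   `modal_freq`, `conserved`), with attributes `n_sites`, `stratum` and
#'   `threshold`.
#' @export
conservation_profile <- function(sites, max_mismatch = Inf, threshold = 0.75) {
  keep <- sites[sites$mismatches <= max_mismatch, , drop = FALSE]
  n <- nrow(keep)
  if (n > 0) {
    w <- unique(nchar(keep$matched_seq))
    if (length(w) != 1) abort("sites mix pattern lengths")
  } else {
    w <- 0L
  }
  rows <- purrr::map(seq_len(w), function(pos) {
    b <- substring(keep$matched_seq, pos, pos)
    cnt <- table(factor(b, levels = c(.BASES, "N")))
    cnt4 <- as.integer(cnt[.BASES])
    im <- which.max(cnt4)
    tibble(
      position = pos,
      A = cnt4[1], C = cnt4[2], G = cnt4[3], T = cnt4[4],
      modal_base = .BASES[im],
      modal_freq = cnt4[im] / n,
      conserved = cnt4[im] / n >= threshold
    )
  })
  out <- if (length(rows)) bind_rows(rows) else tibble(
    position = integer(), A = integer(), C = integer(), G = integer(),
    T = integer(), modal_base = character(), modal_freq = double(),
    conserved = logical()
  )
  structure(out,
    class = c("palcore_profile", class(out)),
    n_sites = n, stratum = max_mismatch, threshold = threshold
  )
}

#' @export
print.palcore_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation profile> stratum <= %s mismatches, %d sites; conserved positions: %s\n",
    format(attr(x, "stratum")), attr(x, "n_sites"),
    paste(x$position[x$conserved], collapse = ", ")
  ))
  NextMethod()
}

#' @rdname conservation_profile
#' @param x A `palcore_profile`.
#' @param ... Unused.
#' @method tidy palcore_profile
#' @export
tidy.palcore_profile <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(dplyr::all_of(.BASES),
                        names_to = "base", values_to = "count") %>%
    mutate(freq = ifelse(attr(x, "n_sites") > 0,
                         .data$count / attr(x, "n_sites"), NA_real_))
}
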