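#' Parse a degenerate, case-annotated nucleotide pattern
#'
#' Patterns are strings over A/C/G/T/N. Case carries a conservation
#' annotation: upper-case positions are highly conserved, lower-case weakly
#' conserved. `N`/`n` is a wildcard matching any base and never counts toward
#' mismatches. Matching itself is case-insensitive; case only annotates.
#'
#' @param text Pattern string, e.g. `"nAACCGTTnnAACGGTTn"`.
#' @return An object of class `degenerate_pattern` with fields `text`
#'   (original case), `bases` (upper-case), `length`, `wildcard_positions`
#'   (1-based positions holding N) and `conserved_positions` (upper-case
#'   non-N positions).
#' @export
#' @examples
#' p <- parse_pattern("nAACCGTTnnAACGGTTn")
#' p$wildcard_positions
parse_pattern <- function(text) {
  if (inherits(text, "degenerate_pattern")) return(text)
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) abort("empty pattern")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  upper <- toupper(chars)
  bad <- which(!upper %in% c(.BASES, "N"))
  if (length(bad)) {
    abort(sprintf(
      "invalid pattern character '%s' at position %d", chars[bad[1]], bad[1]
    ))
  }
  structure(
    list(
      text = text,
      bases = paste(upper, collapse = ""),
      length = length(chars),
      wildcard_positions = which(upper == "N"),
      conserved_positions = which(chars %in% .BASES)  # upper-case non-N
    ),
    class = "degenerate_pattern"
  )
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat(sprintf(
    "<degenerate_pattern> %s (w=%d, %d wildcard, %d conserved)\n",
    x$text, x$length, length(x$wildcard_positions), length(x$conserved_positions)
  ))
  invisible(x)
}

#' Wildcard-aware Hamming distance between a pattern and a window
#'
#' Counts the non-wildcard pattern positions where the window base differs
#' (case-insensitively). An `N` in the *window* at a non-wildcard pattern
#' position counts as a mismatch, so masked regions never produce phantom
#' exact hits. No gaps: patterns and windows must have equal length.
#'
#' @param pattern A [parse_pattern()] object or pattern string.
#' @param window Nucleotide string of the same length (vectorized).
#' @return Integer mismatch count(s).
#' @export
#' @examples
#' mismatch_count("TTGTGAANNNNTTCACAA", "CTGTGAATCAATTCACAT")
mismatch_count <- function(pattern, window) {
  p <- parse_pattern(pattern)
  if (any(nchar(window) != p$length)) {
    abort("window length differs from pattern length")
  }
  pat <- encode_seq(p$bases)
  keep <- setdiff(seq_len(p$length), p$wildcard_positions)
  vapply(toupper(window), function(w) {
    sum(encode_seq(w)[keep] != pat[keep])
  }, integer(1), USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' For a `degenerate_pattern`, the pattern is reversed and base-complemented
#' (N stays N) and the case annotation travels with its position. For a plain
#' character vector, each element is reverse-complemented.
#'
#' @param x A `degenerate_pattern` or character vector.
#' @return An object of the same type.
#' @export
#' @examples
#' reverse_complement("GA")
#' reverse_complement(parse_pattern("aAACCGTTgaAACGGTTt"))$text
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) revcomp_chr(x)

#' @export
reverse_complement.degenerate_pattern <- function(x) {
  parse_pattern(revcomp_chr(x$text))
}

#' Is a pattern identical to its own reverse complement?
#'
#' @param pattern A pattern or string; case is ignored.
#' @return Logical.
#' @export
is_self_reverse_complement <- function(pattern) {
  p <- parse_pattern(pattern)
  identical(p$bases, toupper(revcomp_chr(p$bases)))
}

#' Palindromic positions of a pattern
#'
#' The non-wildcard positions `i` whose base is the Watson-Crick complement
#' of the base at the mirror position `w + 1 - i`. Wildcard mirrors never
#' qualify: N complements nothing.
#'
#' @inheritParams mismatch_count
#' @return Sorted integer vector of 1-based positions.
#' @export
#' @examples
#' palindromic_positions("ACGT")
palindromic_positions <- function(pattern) {
  p <- parse_pattern(pattern)
  b <- strsplit(p$bases, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGTN", "TGCAN", b)
  mirror <- rev(b)
  which(b != "N" & mirror != "N" & mirror == comp)
}

#' Number of conserved palindromic positions
#'
#' Size of the intersection of [palindromic_positions()] with the pattern's
#' upper-case (highly conserved) positions.
#'
#' @inheritParams mismatch_count
#' @return Integer count.
#' @export
#' @examples
#' conserved_palindromic_count("aAACCGTTgaAACGGTTt")
conserved_palindromic_count <- function(pattern) {
  p <- parse_pattern(pattern)
  length(intersect(palindromic_positions(p), p$conserved_positions))
}

# Does the pattern tolerate overlapping itself at any shift 1..w-1?  Used to
# warn that the Poisson expected-count approximation ignores self-overlap.
.self_overlapping <- function(pattern) {
  p <- parse_pattern(pattern)
  b <- strsplit(p$bases, "", fixed = TRUE)[[1]]
  for (s in seq_len(p$length - 1L)) {
    a <- b[(s + 1L):p$length]
    c <- b[seq_len(p$length - s)]
    if (all(a == "N" | c == "N" | a == c)) return(TRUE)
  }
  FALSE
}
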