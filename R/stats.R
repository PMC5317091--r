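#' Fit an order-k Markov background to a genome
#'
#' Maximum-likelihood transition frequencies over all k-mer contexts, with a
#' pseudocount of 1 in every cell. If the genome is circular the context
#' continues across the coordinate origin. Windows containing N are skipped.
#' An order-2 background is the package default for enrichment: it controls
#' for dinucleotide and codon-adjacent composition without modeling genes.
#'
#' @param genome A [genome_record()].
#' @param order Markov order k in 0..3.
#' @return An object of class `markov_background`: `order`, `trans`
#'   (4^k x 4 matrix of transition probabilities), `initial` (distribution
#'   over the 4^k contexts), `trained_length`.
#' @export
fit_markov <- function(genome, order = 2L) {
  stopifnot(inherits(genome, "genome_record"))
  k <- as.integer(order)
  if (k < 0 || k > 3) abort("order must be in 0..3")
  L <- genome$length
  if (L < 4^(k + 1)) abort("genome too short for this order")
  s <- if (genome$circular && k > 0) {
    paste0(genome$sequence, substr(genome$sequence, 1L, k))
  } else {
    genome$sequence
  }
  g0 <- encode_seq(s) - 1L      # 0..3, N -> 4
  g0[g0 == 4L] <- NA_integer_
  n_ctx <- 4L^k
  n_win <- nchar(s) - k
  ctx <- integer(n_win)
  if (k > 0) {
    ctx <- 0L
    for (j in seq_len(k)) ctx <- ctx * 4L + g0[j:(j + n_win - 1L)]
  }
  nxt <- g0[(k + 1L):(k + n_win)]
  ok <- !is.na(ctx) & !is.na(nxt)
  counts <- matrix(1, nrow = n_ctx, ncol = 4L)  # pseudocount 1
  if (any(ok)) {
    tab <- table(factor(ctx[ok], levels = 0:(n_ctx - 1L)),
                 factor(nxt[ok], levels = 0:3))
    counts <- counts + unclass(tab)
  }
  trans <- counts / rowSums(counts)
  init <- rowSums(counts)
  structure(
    list(order = k, trans = unname(trans), initial = unname(init / sum(init)),
         trained_length = L),
    class = "markov_background"
  )
}

#' Build an order-0 background from base probabilities
#'
#' @param probs Length-4 probability vector over A, C, G, T.
#' @return A `markov_background` of order 0.
#' @export
markov_background_order0 <- function(probs = rep(0.25, 4)) {
  stopifnot(length(probs) == 4, all(probs >= 0))
  probs <- probs / sum(probs)
  structure(
    list(order = 0L, trans = matrix(probs, nrow = 1), initial = 1,
         trained_length = NA_integer_),
    class = "markov_background"
  )
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("<markov_background> order %d (trained on %s bp)\n",
              x$order, format(x$trained_length, big.mark = ",")))
  invisible(x)
}

# Probability of each word under the background.  `words` is an integer
# matrix (rows = words, codes 0..3).  Vectorized across rows.
.word_probs <- function(words, bg) {
  k <- bg$order
  w <- ncol(words)
  n <- nrow(words)
  stopifnot(w > k)
  p <- rep(1, n)
  if (k > 0) {
    ctx0 <- 0L
    for (j in seq_len(k)) ctx0 <- ctx0 * 4L + words[, j]
    p <- bg$initial[ctx0 + 1L]
  }
  for (j in (k + 1L):w) {
    ctx <- 0L
    if (k > 0) for (i in (j - k):(j - 1L)) ctx <- ctx * 4L + words[, i]
    p <- p * bg$trans[cbind(ctx + 1L, words[, j] + 1L)]
  }
  p
}

# Enumerate all concrete variants of a pattern within Hamming budget m at its
# non-wildcard positions.  Wildcards stay as NA columns.  Returns an integer
# matrix with codes 0..3 and NA at wildcards.
.enumerate_variants <- function(pat_codes0, wild, m) {
  fixed <- setdiff(seq_along(pat_codes0), wild)
  base <- matrix(pat_codes0, nrow = 1)
  out <- list(base)
  m <- min(m, length(fixed))
  if (m >= 1 && length(fixed) > 0) {
    for (sz in seq_len(m)) {
      subs <- utils::combn(fixed, sz)
      for (ci in seq_len(ncol(subs))) {
        pos <- subs[, ci]
        alts <- lapply(pos, function(p) setdiff(0:3, pat_codes0[p]))
        grid <- as.matrix(expand.grid(alts))
        block <- matrix(rep(pat_codes0, each = nrow(grid)),
                        nrow = nrow(grid))
        block[, pos] <- grid
        out[[length(out) + 1L]] <- block
      }
    }
  }
  do.call(rbind, out)
}

#' Expected count of a pattern under a Markov background
#'
#' `(L - w + 1)` times the background probability that a window matches the
#' pattern within `max_mismatch` wildcard-aware Hamming mismatches. Wildcard
#' positions marginalize over all four bases. The sum runs over every
#' concrete word consistent with the pattern at the given budget; when that
#' enumeration (including wildcard fills for order > 0 backgrounds) exceeds
#' `max_enum` words, the probability is instead estimated by Monte Carlo with
#' `mc_samples` windows drawn from the background (consuming the current RNG
#' stream). The calculation uses the stationary word-probability
#' approximation and ignores self-overlap corrections; a warning is issued
#' for self-overlapping patterns, for which the Poisson approximation
#' downstream is optimistic.
#'
#' @param pattern Pattern string or [parse_pattern()] object.
#' @param bg A `markov_background`.
#' @param L Genome length in bp.
#' @param max_mismatch Mismatch budget m (default 0).
#' @param max_enum Enumeration cap in words (default 4^10).
#' @param mc_samples Monte Carlo sample size beyond the cap.
#' @return Expected count (double).
#' @export
#' @examples
#' bg <- markov_background_order0()
#' expected_count("ANNA", bg, L = 1003)  # 1000 * 0.25^2
expected_count <- function(pattern, bg, L, max_mismatch = 0L,
                           max_enum = 4^10, mc_samples = 1e6) {
  p <- parse_pattern(pattern)
  w <- p$length
  if (w > L) abort("pattern longer than genome")
  if (w <= bg$order) abort("pattern shorter than background order + 1")
  if (.self_overlapping(p)) {
    warn(sprintf("pattern %s can overlap itself; expected counts ignore self-overlap", p$bases))
  }
  n_win <- L - w + 1
  pat0 <- encode_seq(p$bases) - 1L
  wild <- p$wildcard_positions
  fixed_d <- w - length(wild)
  m <- min(max_mismatch, fixed_d)
  n_var <- sum(vapply(0:m, function(i) choose(fixed_d, i) * 3^i, double(1)))
  n_words <- n_var * (if (bg$order > 0) 4^length(wild) else 1)
  if (n_words <= max_enum) {
    vars <- .enumerate_variants(pat0, wild, m)
    if (bg$order == 0) {
      probs4 <- bg$trans[1, ]
      pr <- rep(1, nrow(vars))
      for (j in setdiff(seq_len(w), wild)) pr <- pr * probs4[vars[, j] + 1L]
      return(n_win * sum(pr))
    }
    # order > 0: expand wildcards over all four bases
    total <- 0
    fills <- if (length(wild)) {
      as.matrix(expand.grid(rep(list(0:3), length(wild))))
    } else {
      matrix(integer(0), nrow = 1, ncol = 0)
    }
    for (vi in seq_len(nrow(vars))) {
      block <- matrix(rep(vars[vi, ], each = nrow(fills)), nrow = nrow(fills))
      if (length(wild)) block[, wild] <- fills
      total <- total + sum(.word_probs(block, bg))
    }
    return(n_win * total)
  }
  # Monte Carlo path
  samp <- .sample_windows(bg, w, mc_samples)
  keep <- setdiff(seq_len(w), wild)
  mm <- integer(mc_samples)
  for (j in keep) mm <- mm + (samp[, j] != pat0[j])
  n_win * mean(mm <= m)
}

# Draw n windows of length w from the background; integer matrix codes 0..3.
.sample_windows <- function(bg, w, n) {
  k <- bg$order
  out <- matrix(0L, nrow = n, ncol = w)
  ctx <- if (k > 0) {
    sample.int(4L^k, n, replace = TRUE, prob = bg$initial) - 1L
  } else {
    integer(n)
  }
  if (k > 0) {
    # decompose sampled contexts into their k bases
    tmp <- ctx
    for (j in k:1) {
      out[, j] <- tmp %% 4L
      tmp <- tmp %/% 4L
    }
  }
  cum <- t(apply(bg$trans, 1, cumsum))
  start <- max(k + 1L, 1L)
  for (j in start:w) {
    c_j <- 0L
    if (k > 0) for (i in (j - k):(j - 1L)) c_j <- c_j * 4L + out[, i]
    u <- runif(n)
    rows <- cum[c_j + 1L, , drop = FALSE]
    out[, j] <- (u > rows[, 1]) + (u > rows[, 2]) + (u > rows[, 3])
  }
  out
}

#' Overrepresentation statistics for observed vs expected counts
#'
#' For each pattern, `z = (observed - expected) / sqrt(expected)` and the
#' upper-tail Poisson p-value `P(X >= observed)` at mean `expected`;
#' `p_adj` is the Benjamini-Hochberg adjustment across the supplied batch
#' (optionally against a larger hypothesis family via `n_hypotheses`).
#'
#' @param observed Integer vector of observed counts.
#' @param expected Positive expected counts (recycled).
#' @param n_hypotheses Total number of hypotheses for the BH adjustment;
#'   defaults to `length(observed)`. Hypotheses beyond the batch are treated
#'   as having p = 1.
#' @return Tibble with columns `observed`, `expected`, `z`, `p`, `p_adj`.
#' @export
#' @examples
#' enrichment(38, 1)
enrichment <- function(observed, expected, n_hypotheses = length(observed)) {
  if (any(expected <= 0)) abort("expected must be > 0")
  z <- (observed - expected) / sqrt(expected)
  p <- ppois(observed - 1, expected, lower.tail = FALSE)
  tibble(
    observed = observed, expected = expected, z = z, p = p,
    p_adj = .bh_adjust(p, n_hypotheses)
  )
}

# BH against a family of m hypotheses of which only these p-values are < 1.
.bh_adjust <- function(p, m) {
  m <- max(m, length(p))
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' De novo discovery of overrepresented spacer palindromes
#'
#' Enumerates, in one pass per arm length and spacer length, every occurrence
#' of `X . N^s . revcomp(X)` — an inverted repeat with arm `X` and an
#' unconstrained spacer — and scores each observed arm/spacer candidate
#' against the background with a Poisson upper tail. Benjamini-Hochberg
#' adjustment is performed across the full hypothesis family (all `4^a` arms
#' for every arm length and spacer; unobserved candidates carry p = 1).
#' Candidates whose cores are sub- or super-patterns of a more significant
#' candidate are merged away.
#'
#' @param genome A [genome_record()].
#' @param arm_len Integer vector of arm lengths (default 6:8).
#' @param spacer_len Integer vector of spacer lengths (default 2:4).
#' @param top_n Number of candidates to return.
#' @param bg Optional `markov_background`; fitted at `bg_order` if NULL.
#' @param bg_order Order for the fitted background (default 2).
#' @param alpha BH significance level used for the `significant` flag.
#' @return Tibble `arm`, `spacer`, `core`, `observed`, `expected`, `z`, `p`,
#'   `p_adj`, `significant`, sorted by adjusted significance.
#' @export
discover_palindromes <- function(genome, arm_len = 6:8, spacer_len = 2:4,
                                 top_n = 20L, bg = NULL, bg_order = 2L,
                                 alpha = 0.01) {
  stopifnot(inherits(genome, "genome_record"))
  L <- genome$length
  if (L < 2 * min(arm_len) + min(spacer_len)) {
    return(tibble(
      arm = character(), spacer = integer(), core = character(),
      observed = integer(), expected = double(), z = double(),
      p = double(), p_adj = double(), significant = logical()
    ))
  }
  if (is.null(bg)) bg <- fit_markov(genome, order = bg_order)
  g0 <- encode_seq(genome$sequence) - 1L
  g0[g0 == 4L] <- NA_integer_
  cand <- list()
  for (a in arm_len) {
    if (L < 2 * a + min(spacer_len)) next
    codes <- .roll_codes(g0, a)
    rcmap <- .revcomp_code_map(a)
    for (s in spacer_len) {
      span <- 2L * a + s
      if (L < span) next
      n_start <- L - span + 1L
      arm_code <- codes[seq_len(n_start)]
      ds_code <- codes[seq_len(n_start) + a + s]
      hit <- !is.na(arm_code) & !is.na(ds_code) &
        ds_code == rcmap[arm_code + 1L]
      if (!any(hit)) next
      cnt <- tabulate(arm_code[hit] + 1L, nbins = 4L^a)
      nz <- which(cnt > 0L)
      arms <- vapply(nz - 1L, .decode_code, character(1), a = a)
      cand[[length(cand) + 1L]] <- tibble(
        arm = arms, spacer = as.integer(s),
        core = paste0(arms, strrep("N", s), revcomp_chr(arms)),
        observed = cnt[nz]
      )
    }
  }
  if (length(cand) == 0) {
    return(tibble(
      arm = character(), spacer = integer(), core = character(),
      observed = integer(), expected = double(), z = double(),
      p = double(), p_adj = double(), significant = logical()
    ))
  }
  out <- bind_rows(cand)
  out$expected <- vapply(out$core, function(core) {
    suppressWarnings(expected_count(core, bg, L, max_mismatch = 0L))
  }, double(1), USE.NAMES = FALSE)
  m_total <- sum(4^arm_len) * length(spacer_len)
  est <- enrichment(out$observed, out$expected, n_hypotheses = m_total)
  out$z <- est$z
  out$p <- est$p
  out$p_adj <- est$p_adj
  out <- arrange(out, .data$p, dplyr::desc(.data$observed))
  out <- .merge_related_cores(out)
  out$significant <- out$p_adj <= alpha
  head(out, top_n)
}

# Rolling base-4 codes of all a-mers; NA where a window touches an N.
.roll_codes <- function(g0, a) {
  n <- length(g0) - a + 1L
  code <- integer(n)
  for (j in seq_len(a)) code <- code * 4L + g0[j:(j + n - 1L)]
  code
}

# Map word code -> code of its reverse complement, for words of length a.
.revcomp_code_map <- function(a) {
  v <- 0:(4L^a - 1L)
  tmp <- v
  r <- integer(length(v))
  for (j in seq_len(a)) {
    digit <- tmp %% 4L
    tmp <- tmp %/% 4L
    r <- r * 4L + (3L - digit)
  }
  r
}

.decode_code <- function(code, a) {
  out <- character(a)
  for (j in a:1) {
    out[j] <- .BASES[code %% 4L + 1L]
    code <- code %/% 4L
  }
  paste(out, collapse = "")
}

# Drop candidates whose core is a sub- or super-pattern of an already kept,
# more significant core (input sorted by significance).
.merge_related_cores <- function(tbl) {
  kept <- logical(nrow(tbl))
  kept_cores <- list()
  for (i in seq_len(nrow(tbl))) {
    core_i <- tbl$core[i]
    related <- any(vapply(kept_cores, .cores_related, logical(1), y = core_i))
    if (!related) {
      kept[i] <- TRUE
      kept_cores[[length(kept_cores) + 1L]] <- core_i
    }
  }
  tbl[kept, , drop = FALSE]
}

# TRUE if one core pattern can be aligned inside the other such that at every
# overlapping position the shorter (or either, at equal length) is N or equal.
.cores_related <- function(x, y) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  nx <- length(xs); ny <- length(ys)
  for (o in 0:(ny - nx)) {
    seg <- ys[(o + 1):(o + nx)]
    if (all(xs == "N" | seg == "N" | xs == seg)) return(TRUE)
  }
  FALSE
}

#' Spatial uniformity statistics for site positions
#'
#' One-sample Kolmogorov-Smirnov test of `positions / L` against the uniform
#' distribution, plus the coefficient of variation of circular gaps between
#' consecutive sites. Both are reported, neither thresholded: "weak
#' clustering" of repeat sites has no canonical statistic.
#'
#' @param positions Site positions in bp (1..L); at least 2.
#' @param L Genome length in bp.
#' @return One-row tibble `n_sites`, `ks_distance`, `ks_p`, `cv_spacing`.
#' @export
spacing_uniformity <- function(positions, L) {
  n <- length(positions)
  if (n < 2) abort("need at least two positions")
  if (any(positions < 1 | positions > L)) abort("positions outside [1, L]")
  ks <- suppressWarnings(ks.test(positions / L, "punif"))
  sp <- sort(positions)
  gaps <- c(diff(sp), L - sp[n] + sp[1])
  tibble(
    n_sites = n,
    ks_distance = unname(ks$statistic),
    ks_p = ks$p.value,
    cv_spacing = sd(gaps) / mean(gaps)
  )
}
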