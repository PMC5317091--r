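# Independent brute-force oracles used to cross-check the implementation.

# Naive per-window mismatch enumeration.
oracle_scan <- function(seq, pattern, max_mismatch, circular = FALSE) {
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  w <- length(pat)
  L <- nchar(seq)
  s2 <- if (circular) paste0(seq, substr(seq, 1, w - 1)) else seq
  chars <- strsplit(toupper(s2), "", fixed = TRUE)[[1]]
  n_win <- if (circular) L else L - w + 1
  hits <- integer(0)
  mms <- integer(0)
  fixed <- pat != "N"
  for (i in seq_len(n_win)) {
    win <- chars[i:(i + w - 1)]
    mm <- sum(fixed & win != pat)
    if (mm <= max_mismatch) {
      hits <- c(hits, i)
      mms <- c(mms, mm)
    }
  }
  data.frame(start = hits, mismatches = mms)
}

# Interval-union coverage via a per-base logical mask.
oracle_coverage <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  mean(mask)
}

# Context classification by testing every site against every feature.
oracle_context <- function(sites, features, L, circular = TRUE) {
  cds <- features[as.character(features$ftype) == "CDS", , drop = FALSE]
  env <- palcore::feature_envelopes(features)
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites$start[i]; e <- sites$end[i]
    if (nrow(cds) > 0 && any(cds$start <= e & cds$end >= s)) {
      return("coding_overlap")
    }
    ov <- env$start <= e & env$end >= s
    cand <- env[!ov, , drop = FALSE]
    if (nrow(cand) == 0) return("edge")
    dl <- (s - cand$end - 1) %% L
    dr <- (cand$start - e - 1) %% L
    lg <- cand[which.min(dl), ]
    rg <- cand[which.min(dr), ]
    switch(paste0(lg$strand, rg$strand),
      "-+" = "intergenic_divergent",
      "+-" = "intergenic_convergent",
      "intergenic_codirectional")
  }, character(1))
}

random_genome_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

random_pattern_text <- function(w, p_wild = 0.2) {
  paste(sample(c("A", "C", "G", "T", "N"), w, replace = TRUE,
               prob = c(rep((1 - p_wild) / 4, 4), p_wild)), collapse = "")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
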