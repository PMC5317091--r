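#' Read features from a GenBank flat file
#'
#' A minimal parser for the FEATURES block of a GenBank flat file: feature
#' keys, simple / `complement()` / `join()` / `order()` locations, and the
#' `/locus_tag` qualifier. Compound locations are split into their parts,
#' each emitted as a row sharing the locus_tag. The `source` and `gene`
#' features are skipped (`gene` duplicates the typed feature it contains);
#' keys other than CDS/rRNA/tRNA are typed `other`. The ORIGIN sequence
#' block, if present, is ignored.
#'
#' @param path Path to a GenBank flat file.
#' @return Feature tibble as in [read_features()].
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  genome_id <- if (length(locus_line)) strsplit(trimws(locus_line[1]), "\\s+")[[1]][2] else NA_character_
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) abort(sprintf("no FEATURES block in %s", path))
  body <- lines[(fstart[1] + 1L):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]

  # A feature header has its key in columns 6-20; continuation lines are
  # indented by 21 spaces.
  is_header <- grepl("^ {5}\\S", body)
  if (!any(is_header)) {
    out <- tibble(
      locus_tag = character(), ftype = .normalize_ftype(character()),
      start = integer(), end = integer(), strand = character()
    )
    attr(out, "genome_id") <- genome_id
    return(out)
  }
  grp <- cumsum(is_header)
  feats <- split(body[grp > 0], grp[grp > 0])

  rows <- purrr::imap(feats, function(chunk, idx) {
    header <- chunk[1]
    key <- strsplit(trimws(header), "\\s+")[[1]][1]
    if (key %in% c("source", "gene")) return(NULL)
    # Location may continue over lines until the first qualifier (/...).
    rest <- sub("^ {5}\\S+\\s*", "", header)
    more <- chunk[-1]
    qual_start <- grep("^\\s*/", more)
    loc_extra <- if (length(qual_start)) {
      more[seq_len(qual_start[1] - 1L)]
    } else more
    loc <- gsub("\\s", "", paste(c(rest, trimws(loc_extra)), collapse = ""))
    parsed <- tryCatch(
      .parse_genbank_location(loc),
      error = function(e) {
        abort(sprintf(
          "malformed location in %s, feature record %s ('%s'): %s",
          path, idx, loc, conditionMessage(e)
        ))
      }
    )
    tag_line <- grep("/locus_tag=", chunk, value = TRUE)
    tag <- if (length(tag_line)) {
      gsub('"', "", sub("^.*?/locus_tag=", "", tag_line[1], perl = TRUE))
    } else {
      sprintf("feature_%05d", as.integer(idx))
    }
    tibble(
      locus_tag = tag, ftype_raw = key,
      start = unname(parsed$start), end = unname(parsed$end),
      strand = unname(parsed$strand)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(locus_tag = character(), ftype_raw = character(),
                  start = integer(), end = integer(), strand = character())
  }
  out <- out %>%
    mutate(ftype = .normalize_ftype(.data$ftype_raw)) %>%
    select("locus_tag", "ftype", "start", "end", "strand") %>%
    .sort_features()
  attr(out, "genome_id") <- genome_id
  out
}

# Parse a whitespace-stripped GenBank location string into parts.
.parse_genbank_location <- function(loc, strand = "+") {
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(.parse_genbank_location(inner, strand = if (strand == "+") "-" else "+"))
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- .split_toplevel(inner)
    parsed <- lapply(parts, .parse_genbank_location, strand = strand)
    return(list(
      start = unlist(lapply(parsed, `[[`, "start")),
      end = unlist(lapply(parsed, `[[`, "end")),
      strand = unlist(lapply(parsed, `[[`, "strand"))
    ))
  }
  # simple span: 10..20, single base 15, or fuzzy <10..>20
  m <- regmatches(loc, regexec("^[<>]?(\\d+)(\\.\\.[<>]?(\\d+))?$", loc))[[1]]
  if (length(m) == 0) stop("unrecognized location syntax")
  s <- as.integer(m[2])
  e <- if (nzchar(m[4])) as.integer(m[4]) else s
  if (s > e) stop("start greater than end")
  list(start = s, end = e, strand = strand)
}

# Split on commas not nested inside parentheses.
.split_toplevel <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- chars == "," & depth == 0
  grp <- cumsum(cut)
  pieces <- split(chars[!cut], grp[!cut])
  vapply(pieces, paste, character(1), collapse = "")
}
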