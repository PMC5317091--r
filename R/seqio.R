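#' Construct a genome record
#'
#' A light container for one chromosome: the sequence (upper-case ACGTN), its
#' length, and a circularity flag. Bacterial chromosomes are circular by
#' default; circularity matters for wrap-around scanning windows and for
#' resolving the flanking genes of sites near the coordinate origin.
#'
#' @param sequence Nucleotide string. Lower case is upper-cased; IUPAC
#'   ambiguity codes other than N are mapped to N with a warning, so that the
#'   mismatch model stays two-valued (match / mismatch / wildcard).
#' @param id Sequence identifier.
#' @param circular Logical circularity flag.
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `length` and `circular`.
#' @export
#' @examples
#' g <- genome_record("acgtACGT")
#' g$length
genome_record <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    iupac <- "RYSWKMBDHV"
    non_iupac <- gsub(sprintf("[%s]", iupac), "", bad)
    if (nzchar(non_iupac)) {
      abort(sprintf(
        "sequence contains non-nucleotide characters: %s",
        paste(unique(strsplit(non_iupac, "")[[1]]), collapse = ", ")
      ))
    }
    warn(sprintf(
      "%d IUPAC ambiguity bases (%s) mapped to N",
      nchar(bad), paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    ))
    s <- chartr(iupac, strrep("N", nchar(iupac)), s)
  }
  if (!nzchar(s)) abort("empty sequence")
  structure(
    list(id = id, sequence = s, length = nchar(s), circular = isTRUE(circular)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s: %s bp, %s\n", x$id,
    format(x$length, big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads one chromosome from a (possibly multi-record) FASTA file. The first
#' record is used unless `id` names another; multi-record files without an
#' `id` are rejected to avoid silently analyzing the wrong replicon.
#'
#' @param path Path to a FASTA file.
#' @param id Optional record identifier to select from a multi-record file.
#' @inheritParams genome_record
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, id = NULL, circular = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort(sprintf("no FASTA records in %s", path))
  nm <- sub("\\s.*$", "", names(set))
  if (is.null(id)) {
    if (length(set) > 1) {
      abort(sprintf(
        "%s holds %d records; pass `id` to choose one", path, length(set)
      ))
    }
    i <- 1L
  } else {
    i <- match(id, nm)
    if (is.na(i)) abort(sprintf("record '%s' not found in %s", id, path))
  }
  genome_record(as.character(set[[i]]), id = nm[i], circular = circular)
}

.FEATURE_TYPES <- c("CDS", "rRNA", "tRNA", "other")

.normalize_ftype <- function(x) {
  out <- ifelse(x %in% c("CDS", "rRNA", "tRNA"), x, "other")
  factor(out, levels = .FEATURE_TYPES)
}

# Canonical ordering shared by readers and the writer.
.sort_features <- function(tbl) {
  dplyr::arrange(tbl, .data$start, .data$end, .data$locus_tag)
}

#' Read a gene feature table
#'
#' Reads gene features from GFF3 (via rtracklayer) or from a GenBank flat
#' file (feature table only; the sequence block is ignored). All coordinates
#' are 1-based inclusive. GenBank `join(...)` / compound locations are split
#' into their parts, which share a `locus_tag`; downstream context
#' classification uses the per-locus envelope.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"`, `"genbank"`, or `"auto"` (guess from the file
#'   extension and content).
#' @param genome_id Identifier recorded alongside the table.
#' @return A tibble with columns `locus_tag`, `ftype` (factor CDS/rRNA/tRNA/
#'   other), `start`, `end`, `strand`, sorted by start, then end, then
#'   locus_tag.
#' @export
read_features <- function(path, dialect = c("auto", "gff3", "genbank"),
                          genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    dialect <- if (any(grepl("^LOCUS", first))) "genbank" else "gff3"
  }
  tbl <- switch(dialect,
    gff3 = .read_gff3(path),
    genbank = read_genbank_features(path)
  )
  tbl <- .sort_features(tbl)
  attr(tbl, "genome_id") <- genome_id %||% attr(tbl, "genome_id")
  tbl
}

.read_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("malformed GFF3 %s: %s", path, conditionMessage(e)))
  )
  if (length(gr) == 0) {
    return(tibble(
      locus_tag = character(), ftype = .normalize_ftype(character()),
      start = integer(), end = integer(), strand = character()
    ))
  }
  md <- as.data.frame(gr)
  tag <- md[["locus_tag"]] %||% md[["ID"]] %||% sprintf("feature_%05d", seq_len(nrow(md)))
  tag <- ifelse(is.na(tag), sprintf("feature_%05d", seq_len(nrow(md))), as.character(tag))
  strand <- as.character(md$strand)
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf(
      "GFF3 records without +/- strand: %s",
      paste(head(which(!strand %in% c("+", "-"))), collapse = ", ")
    ))
  }
  out <- tibble(
    locus_tag = tag,
    ftype = .normalize_ftype(as.character(md$type)),
    start = as.integer(md$start),
    end = as.integer(md$end),
    strand = strand
  )
  attr(out, "genome_id") <- as.character(md$seqnames[1])
  out
}

#' Write a feature table as GFF3
#'
#' @param features Feature tibble as returned by [read_features()].
#' @param path Output path.
#' @param genome_id Sequence identifier for column 1; defaults to the table's
#'   recorded genome id.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, genome_id = NULL) {
  genome_id <- genome_id %||% attr(features, "genome_id") %||% "genome"
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tpalcore\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
      genome_id, as.character(features$ftype), features$start, features$end,
      features$strand, features$locus_tag, features$locus_tag
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' G+C content of a genome
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from both the
#' numerator and the denominator.
#'
#' @param genome A [genome_record()].
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' gc_content(genome_record("ATGC"))
gc_content <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  codes <- encode_seq(genome$sequence)
  cnt <- tabulate(codes, nbins = 5L)
  denom <- sum(cnt[1:4])
  if (denom == 0) abort("sequence has no A/C/G/T bases")
  (cnt[2] + cnt[3]) / denom
}

#' Fraction of a genome covered by selected feature types
#'
#' Length of the union of the selected feature intervals divided by genome
#' length; overlapping features are counted once. The default `ftypes = "CDS"`
#' gives the protein-coding coverage commonly quoted for bacterial genomes.
#'
#' @param features Feature tibble.
#' @param genome A [genome_record()].
#' @param ftypes Feature types to include in the union.
#' @return Fraction in \[0, 1\].
#' @export
feature_coverage_fraction <- function(features, genome, ftypes = "CDS") {
  stopifnot(inherits(genome, "genome_record"))
  sel <- features[as.character(features$ftype) %in% ftypes, , drop = FALSE]
  if (nrow(sel) == 0) return(0)
  if (any(sel$start < 1 | sel$end > genome$length | sel$start > sel$end)) {
    abort("features outside genome bounds")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = sel$start, end = sel$end))
  sum(IRanges::width(ir)) / genome$length
}

#' Count features by type
#'
#' @param features Feature tibble.
#' @return A tibble with one row per feature type (CDS, rRNA, tRNA, other)
#'   and a count column `n`; types absent from the table get 0.
#' @export
count_features_by_type <- function(features) {
  tibble(ftype = factor(.FEATURE_TYPES, levels = .FEATURE_TYPES)) %>%
    left_join(
      dplyr::count(features, .data$ftype),
      by = "ftype"
    ) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Per-locus envelopes of a feature table
#'
#' Collapses split (compound-location) features to one interval per
#' locus_tag: minimum start to maximum end, keeping the strand. Used when a
#' gene must be treated as a single unit, e.g. when resolving the genes
#' flanking an intergenic site.
#'
#' @param features Feature tibble.
#' @param ftypes Feature types to retain before collapsing.
#' @return A tibble `locus_tag`, `ftype`, `start`, `end`, `strand`, sorted by
#'   start.
#' @export
feature_envelopes <- function(features, ftypes = c("CDS", "rRNA", "tRNA")) {
  features %>%
    filter(as.character(.data$ftype) %in% ftypes) %>%
    group_by(.data$locus_tag) %>%
    summarise(
      ftype = .data$ftype[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      .groups = "drop"
    ) %>%
    .sort_features()
}
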