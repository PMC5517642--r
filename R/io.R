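# Readers/writers for the external formats the tool touches.
#
# Conventions: all genomic intervals are 0-based half-open internally;
# conversion happens only at the I/O boundary (GFF3 is 1-based inclusive,
# BED already 0-based half-open). Tables are TSV with a header row.

#' Read a FASTA file
#'
#' U and T are both accepted and preserved as written. Record ids must be
#' unique and every record must have a non-empty sequence.
#'
#' @param path FASTA file (optionally gzipped).
#' @return data frame with columns `id`, `seq` and `qual` (always NA for
#'   FASTA), one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(hdr) == 0L)
    stop_fmt("%s: no FASTA header found (line 1)", path)
  if (length(nonblank) && nonblank[1L] < hdr[1L])
    stop_fmt("%s: sequence before first header (line %d)", path, nonblank[1L])
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids))) {
    bad <- hdr[!nzchar(ids)][1L]
    stop_fmt("%s: malformed (empty) header at line %d", path, bad)
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stop_fmt("%s: duplicate record id '%s' (line %d)",
             path, d, hdr[which(ids == d)[2L]])
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(nchar(seqs) == 0L)) {
    bad <- which(nchar(seqs) == 0L)[1L]
    stop_fmt("%s: empty sequence for record '%s' (line %d)",
             path, names(seqs)[bad], hdr[bad])
  }
  data.frame(id = names(seqs), seq = unname(seqs), qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data frame with `id` and `seq` columns, or a named character
#'   vector of sequences.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- data.frame(id = names(x), seq = unname(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line records; per-record validation of the separator line and of
#' quality-string length. The whole file is materialized; libraries at the
#' scale this package targets (collapsed afterwards) fit comfortably in
#' memory.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop_fmt("%s: truncated FASTQ record at record %d", path, n %/% 4L + 1L)
  if (n == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  i1 <- seq(1L, n, by = 4L)
  ids <- lines[i1]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop_fmt("%s: record %d does not start with '@'", path, bad[1L])
  sep <- lines[i1 + 2L]
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop_fmt("%s: record %d has malformed separator line", path, bad[1L])
  seqs <- lines[i1 + 1L]
  quals <- lines[i1 + 3L]
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop_fmt("%s: record %d quality length (%d) != sequence length (%d)",
             path, bad[1L], nchar(quals[bad[1L]]), nchar(seqs[bad[1L]]))
  data.frame(id = sub("^@", "", sub("\\s.*$", "", ids)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param x data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- x$qual
  if (is.null(qual) || all(is.na(qual)))
    qual <- vapply(nchar(x$seq), function(n) strrep("I", n), "")
  out <- character(4L * nrow(x))
  idx <- seq(1L, length(out), by = 4L)
  out[idx] <- paste0("@", x$id)
  out[idx + 1L] <- x$seq
  out[idx + 2L] <- "+"
  out[idx + 3L] <- qual
  writeLines(out, path)
  invisible(path)
}

FEATURE_CLASSES <- c("mirna_precursor", "mirna_mature", "tasirna_precursor",
                     "tasirna_mature", "transposon", "mrna")

#' Read feature annotations (GFF3 or BED)
#'
#' Coordinates are normalized to 0-based half-open: a GFF3 feature with
#' `start = s`, `end = e` (1-based inclusive) becomes `(s-1, e)`; BED
#' intervals pass through unchanged. For GFF3, the feature class is taken
#' from the type column, the family from a `family` attribute, and the
#' precursor link from `Parent`.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @return data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `feature_class`, `family_id`, `parent_id`.
#' @export
read_annotations <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "GFF3" else "BED")
  md <- S4Vectors::mcols(gr)
  n <- length(gr)
  grab <- function(col) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(e) if (length(e)) as.character(e[[1L]]) else NA_character_, "")
      }
      as.character(v)
    } else rep(NA_character_, n)
  }
  feature_id <- grab("ID")
  if (all(is.na(feature_id))) feature_id <- grab("Name")
  if (all(is.na(feature_id))) feature_id <- grab("name")
  if (all(is.na(feature_id))) feature_id <- paste0("feature_", seq_len(n))
  ann <- data.frame(
    feature_id = feature_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # rtracklayer imports as 1-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_class = if (dialect == "gff3") grab("type") else grab("feature_class"),
    family_id = grab("family"),
    parent_id = grab("Parent"),
    stringsAsFactors = FALSE
  )
  if (any(ann$start >= ann$end)) {
    bad <- which(ann$start >= ann$end)[1L]
    stop_fmt("%s: feature '%s' has start >= end after normalization",
             path, ann$feature_id[bad])
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    bad <- which(!ann$strand %in% c("+", "-"))[1L]
    stop_fmt("%s: feature '%s' has strand '%s' (must be + or -)",
             path, ann$feature_id[bad], ann$strand[bad])
  }
  mature <- ann$feature_class %in% c("mirna_mature", "tasirna_mature")
  if (any(mature & is.na(ann$parent_id)))
    stop_fmt("%s: mature feature '%s' lacks a Parent link",
             path, ann$feature_id[which(mature & is.na(ann$parent_id))[1L]])
  ann
}

#' Write feature annotations (GFF3 or BED)
#'
#' Inverse of [read_annotations()]; internal 0-based half-open coordinates
#' are converted back to the dialect's convention.
#'
#' @param ann annotation data frame as returned by [read_annotations()].
#' @param path output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    attrs <- paste0("ID=", ann$feature_id)
    has_fam <- !is.na(ann$family_id)
    attrs[has_fam] <- paste0(attrs[has_fam], ";family=", ann$family_id[has_fam])
    has_par <- !is.na(ann$parent_id)
    attrs[has_par] <- paste0(attrs[has_par], ";Parent=", ann$parent_id[has_par])
    lines <- paste(ann$chrom, "srnaspike", ann$feature_class,
                   ann$start + 1L, ann$end, ".", ann$strand, ".", attrs,
                   sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
  } else {
    lines <- paste(ann$chrom, ann$start, ann$end, ann$feature_id, 0L,
                   ann$strand, sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and validate a spike-in mix sheet
#'
#' TSV with header columns `set_id`, `core`, `molecules_per_ug`. Cores must
#' be exactly 13 nt over \{A,C,G,U/T\}, pairwise distinct, and every amount
#' strictly positive.
#'
#' @param path TSV path.
#' @return validated data frame (class `spikein_sheet`).
#' @export
read_spikein_sheet <- function(path) {
  if (!file.exists(path)) stop_fmt("spike-in sheet not found: %s", path)
  x <- read_tsv(path)
  validate_spikein_sheet(x)
}

#' Validate a spike-in sheet data frame
#'
#' @param x data frame with `set_id`, `core`, `molecules_per_ug`.
#' @return `x` with class `spikein_sheet` prepended.
#' @export
validate_spikein_sheet <- function(x) {
  need <- c("set_id", "core", "molecules_per_ug")
  if (!all(need %in% names(x)))
    stop_fmt("spike-in sheet must have columns %s", paste(need, collapse = ", "))
  x$core <- toupper(x$core)
  if (any(nchar(x$core) != 13L))
    stop_fmt("spike-in core '%s' is %d nt (must be exactly 13)",
             x$core[nchar(x$core) != 13L][1L],
             nchar(x$core[nchar(x$core) != 13L][1L]))
  if (any(grepl("[^ACGUT]", x$core)))
    stop_fmt("spike-in core '%s' contains non-ACGU characters",
             x$core[grepl("[^ACGUT]", x$core)][1L])
  if (anyDuplicated(u2t(x$core)))
    stop_fmt("duplicate spike-in core '%s'", x$core[duplicated(u2t(x$core))][1L])
  if (any(!is.finite(x$molecules_per_ug) | x$molecules_per_ug <= 0))
    stop_fmt("molecules_per_ug must be strictly positive (set '%s')",
             x$set_id[!is.finite(x$molecules_per_ug) | x$molecules_per_ug <= 0][1L])
  if (anyDuplicated(x$set_id))
    stop_fmt("duplicate set_id '%s'", x$set_id[duplicated(x$set_id)][1L])
  class(x) <- c("spikein_sheet", "data.frame")
  x
}

#' Read a transcript TPM table
#'
#' @param path TSV with columns `transcript_id` and `tpm` (e.g. distilled
#'   from upstream RSEM output).
#' @return data frame with those columns.
#' @export
read_tpm_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("transcript_id", "tpm") %in% names(x)))
    stop_fmt("TPM table must have columns transcript_id, tpm")
  if (any(!is.finite(x$tpm) | x$tpm < 0))
    stop_fmt("TPM values must be finite and non-negative")
  x
}

#' Read an ERCC spike-in concentration sheet
#'
#' @param path TSV with columns `ercc_id` and `molecules_per_ug` (known
#'   molecules added per microgram of total RNA).
#' @return data frame with those columns.
#' @export
read_ercc_sheet <- function(path) {
  x <- read_tsv(path)
  if (!all(c("ercc_id", "molecules_per_ug") %in% names(x)))
    stop_fmt("ERCC sheet must have columns ercc_id, molecules_per_ug")
  if (any(!is.finite(x$molecules_per_ug) | x$molecules_per_ug <= 0))
    stop_fmt("ERCC molecules_per_ug must be strictly positive")
  x
}

#' Read a degradome-derived sRNA:target pair list
#'
#' @param path TSV with columns `mature_id` and `partner_id`.
#' @return data frame with those columns.
#' @export
read_pairs <- function(path) {
  x <- read_tsv(path)
  if (!all(c("mature_id", "partner_id") %in% names(x)))
    stop_fmt("pair list must have columns mature_id, partner_id")
  x
}
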