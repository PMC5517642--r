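# Raw sRNA-Seq reads -> weighted per-locus counts against a composite of
# the reference genome and the spike-in sets. Reproduces the published
# processing: adapter trimming, read collapsing, perfect-match alignment
# with a multi-hit ceiling, and 1/n-hits weight sharing.

#' Trim 3' adapter from reads
#'
#' Removes everything from the leftmost full adapter occurrence onwards;
#' if no full occurrence exists, a terminal adapter prefix of at least
#' `min_overlap` nt is removed instead. Reads with no detectable adapter,
#' or whose insert falls outside `[min_len, max_len]`, are discarded
#' (returned as `NA`). Matching is exact (no mismatches).
#'
#' @param seqs character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum terminal adapter prefix length (default 8).
#' @param min_len,max_len retained insert size window (defaults 18 and 30,
#'   the analysed sRNA size range).
#' @return character vector, `NA` where the read was discarded; attribute
#'   `stats` holds input/kept/discard tallies.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 8L,
                         min_len = 18L, max_len = 30L) {
  if (!nzchar(adapter)) stop_fmt("adapter must be non-empty")
  seqs <- toupper(seqs)
  adapter <- u2t(adapter)
  n <- length(seqs)
  insert <- rep(NA_character_, n)
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  full <- which(pos > 0L)
  insert[full] <- substr(seqs[full], 1L, pos[full] - 1L)
  rest <- which(pos < 0L)
  if (length(rest)) {
    for (k in seq(min(nchar(adapter) - 1L, max(nchar(seqs[rest]))), min_overlap)) {
      if (length(rest) == 0L) break
      hit <- endsWith(seqs[rest], substr(adapter, 1L, k))
      idx <- rest[hit]
      insert[idx] <- substr(seqs[idx], 1L, nchar(seqs[idx]) - k)
      rest <- rest[!hit]
    }
  }
  found <- !is.na(insert)
  len_ok <- found & nchar(insert) >= min_len & nchar(insert) <= max_len
  insert[!len_ok] <- NA_character_
  attr(insert, "stats") <- c(total = n,
                             no_adapter = sum(!found),
                             bad_length = sum(found & !len_ok),
                             kept = sum(len_ok))
  insert
}

#' Collapse identical inserts into unique reads with counts
#'
#' @param inserts character vector of trimmed insert sequences (`NA`s,
#'   i.e. discarded reads, are ignored).
#' @return data frame with columns `seq` and `count`, sorted by
#'   decreasing count then sequence; `sum(count)` equals the number of
#'   non-NA inserts.
#' @export
collapse_reads <- function(inserts) {
  inserts <- inserts[!is.na(inserts)]
  tab <- table(inserts)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$seq), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# core-tag lookup: per read sequence, the index of the single sheet core it
# contains (NA: none; -1: ambiguous, i.e. >= 2 distinct cores)
match_cores <- function(seqs, sheet) {
  cores <- u2t(sheet$core)
  seqs <- u2t(seqs)
  idx <- rep(NA_integer_, length(seqs))
  ambiguous <- rep(FALSE, length(seqs))
  for (i in seq_along(cores)) {
    hit <- grepl(cores[i], seqs, fixed = TRUE)
    ambiguous <- ambiguous | (hit & !is.na(idx))
    idx[hit & is.na(idx)] <- i
  }
  idx[ambiguous] <- -1L
  idx
}

#' Count spike-in reads per set via 13 nt core tags
#'
#' A read is assigned to a set iff that set's 13 nt core occurs as a
#' substring of the read (U/T-canonicalized). Reads containing two or more
#' distinct cores are discarded with a warning.
#'
#' @param reads collapsed reads data frame (`seq`, `count`).
#' @param sheet validated [read_spikein_sheet()] sheet.
#' @return data frame `set_id`, `core`, `molecules_per_ug`, `count`
#'   (weighted read count per set, 0 for unseen sets), with attribute
#'   `ambiguous` (total count of discarded multi-core reads).
#' @export
count_spikein_tags <- function(reads, sheet) {
  sheet <- validate_spikein_sheet(as.data.frame(sheet))
  idx <- match_cores(reads$seq, sheet)
  amb <- sum(reads$count[!is.na(idx) & idx == -1L])
  if (amb > 0)
    warn_fmt("%g reads contained >= 2 distinct spike-in cores; discarded", amb)
  counts <- vapply(seq_len(nrow(sheet)), function(i)
    sum(reads$count[!is.na(idx) & idx == i]), 0)
  out <- data.frame(set_id = sheet$set_id, core = sheet$core,
                    molecules_per_ug = sheet$molecules_per_ug,
                    count = counts, stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- amb
  out
}

#' Perfect-match alignment of collapsed reads to a composite reference
#'
#' Finds every exact-match locus of each read on both strands of the
#' genome. Reads whose number of loci exceeds `max_hits` are discarded
#' entirely (the multi-hit ceiling of the published pipeline); each
#' retained hit carries weight `count / n_hits`, so a read's weights sum
#' to its count. When a spike-in sheet is supplied, reads carrying a 13 nt
#' core tag are routed to per-set pseudo-chromosomes (`spikein:<set_id>`)
#' rather than the genome; a core-carrying read that also matches the
#' genome is discarded with a warning (cores are genome-excluded by
#' design, so this indicates a corrupt sheet).
#'
#' @param reads collapsed reads data frame (`seq`, `count`).
#' @param genome genome as data frame, named character vector or
#'   `DNAStringSet`.
#' @param sheet optional spike-in sheet.
#' @param max_hits maximum perfect-match loci per read (default 100).
#' @return list with `hits` (data frame `read_seq`, `length`, `count`,
#'   `chrom`, `start` (0-based), `strand`, `n_hits`, `weight`, sorted by
#'   chrom, start, read_seq), `spikein` (per-set counts, if a sheet was
#'   given) and `stats` (a [library_stats()] data frame).
#' @export
align_perfect <- function(reads, genome, sheet = NULL, max_hits = 100L) {
  seqs_chr <- genome_as_character(genome)
  seqs <- u2t(reads$seq)
  counts <- reads$count
  core_idx <- if (!is.null(sheet)) match_cores(seqs, sheet) else
    rep(NA_integer_, length(seqs))

  gen <- find_perfect_hits(seqs, seqs_chr)

  # spike-in routing
  spike <- !is.na(core_idx) & core_idx > 0L
  cross <- spike & gen$n_hits > 0L
  if (any(cross)) {
    warn_fmt("%g reads match both a spike-in core and the genome; discarded",
             sum(counts[cross]))
    spike[cross] <- FALSE
    core_idx[cross] <- NA_integer_
  }
  genome_read <- is.na(core_idx) & gen$n_hits > 0L & gen$n_hits <= max_hits
  discarded_multi <- is.na(core_idx) & gen$n_hits > max_hits

  hit_rows <- gen$hits[gen$hits$read %in% which(genome_read), , drop = FALSE]
  n_hits <- gen$n_hits[hit_rows$read]
  hits <- data.frame(
    read_seq = seqs[hit_rows$read],
    length = nchar(seqs[hit_rows$read]),
    count = counts[hit_rows$read],
    chrom = hit_rows$chrom,
    start = hit_rows$start,
    strand = hit_rows$strand,
    n_hits = n_hits,
    weight = counts[hit_rows$read] / n_hits,
    stringsAsFactors = FALSE
  )
  if (!is.null(sheet)) {
    sp_tab <- count_spikein_tags(reads[spike | (!is.na(core_idx) & core_idx == -1L), ,
                                       drop = FALSE], sheet)
    sp_hits <- data.frame(
      read_seq = seqs[spike], length = nchar(seqs[spike]),
      count = counts[spike],
      chrom = paste0("spikein:", sheet$set_id[core_idx[spike]]),
      start = 0L, strand = "+", n_hits = 1L,
      weight = counts[spike], stringsAsFactors = FALSE)
    hits <- rbind(hits, sp_hits)
  } else sp_tab <- NULL
  hits <- hits[order(hits$chrom, hits$start, hits$read_seq), , drop = FALSE]
  rownames(hits) <- NULL

  stats <- library_stats(
    total_reads = sum(counts),
    genome_matching_read_total = sum(counts[genome_read]),
    spikein_read_total = sum(counts[spike]),
    unaligned = sum(counts[is.na(core_idx) & gen$n_hits == 0L]),
    discarded_multi = sum(counts[discarded_multi]))
  list(hits = hits, spikein = sp_tab, stats = stats)
}

# exact matching of variable-length reads against chromosomes, both
# strands, via per-length PDicts; returns 0-based starts on the plus
# reference coordinate system
find_perfect_hits <- function(seqs, chroms) {
  n_hits <- integer(length(seqs))
  rows <- list()
  if (length(seqs)) {
    subjects <- lapply(chroms, Biostrings::DNAString)
    ok <- grepl("^[ACGT]+$", seqs)   # reads with N etc. cannot match perfectly
    by_len <- split(which(ok), nchar(seqs[ok]))
    for (grp in by_len) {
      fwd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[grp]))
      rev <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(seqs[grp])))
      for (ci in seq_along(subjects)) {
        for (strand in c("+", "-")) {
          pd <- if (strand == "+") fwd else rev
          m <- Biostrings::matchPDict(pd, subjects[[ci]])
          st <- Biostrings::startIndex(m)
          cnt <- lengths(st)
          nz <- which(cnt > 0L)
          if (length(nz) == 0L) next
          n_hits[grp] <- n_hits[grp] + cnt
          rows[[length(rows) + 1L]] <- data.frame(
            read = rep(grp[nz], cnt[nz]),
            chrom = names(chroms)[ci],
            start = unlist(st[nz], use.names = FALSE) - 1L,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read = integer(), chrom = character(), start = integer(),
               strand = character(), stringsAsFactors = FALSE)
  list(hits = hits, n_hits = n_hits)
}

#' Library-level alignment statistics
#'
#' `genome_matching_read_total` counts reads (weighted by copy number)
#' with at least one retained hit to the reference proper; spike-in reads
#' are excluded from it, which makes it the RPM denominator. The spike-in
#' fraction of alignable reads is reported — in practice spike-ins should
#' consume only a small share (the published mixes used 1-2%).
#'
#' @param total_reads total collapsed-read mass entering alignment.
#' @param genome_matching_read_total weighted count of genome-matching
#'   reads.
#' @param spikein_read_total weighted count of spike-in reads.
#' @param unaligned,discarded_multi weighted counts of unaligned reads and
#'   of reads dropped by the multi-hit ceiling.
#' @return one-row data frame, including `alignable_fraction_spikein`.
#' @export
library_stats <- function(total_reads, genome_matching_read_total,
                          spikein_read_total, unaligned = 0,
                          discarded_multi = 0) {
  alignable <- genome_matching_read_total + spikein_read_total
  data.frame(
    total_reads = total_reads,
    genome_matching_read_total = genome_matching_read_total,
    spikein_read_total = spikein_read_total,
    unaligned = unaligned,
    discarded_multi = discarded_multi,
    alignable_fraction_spikein =
      if (alignable > 0) spikein_read_total / alignable else 0
  )
}

#' Process a small RNA library end to end
#'
#' Convenience wrapper: trim, collapse, align, count spike-ins.
#'
#' @param fastq data frame from [read_fastq()] (or a character vector of
#'   raw read sequences).
#' @param genome genome sequences.
#' @param sheet spike-in sheet (optional).
#' @param adapter 3' adapter sequence.
#' @param ... passed to [trim_adapter()] and [align_perfect()].
#' @inheritParams trim_adapter
#' @inheritParams align_perfect
#' @return as [align_perfect()], plus `reads` (collapsed reads) and
#'   `trim_stats`.
#' @export
process_library <- function(fastq, genome, sheet = NULL, adapter,
                            min_overlap = 8L, min_len = 18L, max_len = 30L,
                            max_hits = 100L) {
  seqs <- if (is.data.frame(fastq)) fastq$seq else fastq
  ins <- trim_adapter(seqs, adapter, min_overlap, min_len, max_len)
  reads <- collapse_reads(ins)
  aln <- align_perfect(reads, genome, sheet, max_hits)
  aln$reads <- reads
  aln$trim_stats <- attr(ins, "stats")
  aln
}
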