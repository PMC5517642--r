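# Self-contained synthetic fixtures with known ground truth: a random
# genome with planted miRNA hairpin loci, phased tasiRNA loci and
# transposons; a spike-in dilution series with per-21-mer lognormal
# cloning bias; and ERCC-like mRNA tables. Every quantity the pipeline
# estimates downstream is recorded as truth here.

MIRNA_PRE_LEN <- 120L
MIRNA_MATURE_OFF <- 50L
MIRNA_MATURE_LEN <- 21L
TASI_PRE_LEN <- 160L
TASI_PHASE_OFF <- 40L
TASI_REGISTERS <- 4L
TE_LEN <- 800L

#' Default 3' adapter used by the simulator
#' @export
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCT"

random_genome_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

sub_replace <- function(s, at, replacement) {
  paste0(substr(s, 1L, at - 1L), replacement,
         substr(s, at + nchar(replacement), nchar(s)))
}

count_occurrences <- function(pattern, genome_seq) {
  p <- Biostrings::DNAString(u2t(pattern))
  subj <- Biostrings::DNAString(genome_seq)
  Biostrings::countPattern(p, subj) +
    Biostrings::countPattern(Biostrings::reverseComplement(p), subj)
}

#' Generate a synthetic genome with planted sRNA loci
#'
#' Plants `n_mirna` miRNA precursor loci (each with one unique 21 nt
#' mature sequence occurring exactly once in the genome), `n_tasirna`
#' tasiRNA loci with `r TASI_REGISTERS` phased 21 nt registers, and
#' `n_transposon` transposon intervals, all non-overlapping on a random
#' background. Roughly every third miRNA joins the previous one's family
#' (suffix `b`), so family aggregation is exercised. Ground-truth
#' molecule amounts are drawn log-uniformly: mature miRNAs span 3 decades
#' (1e5--1e8 molecules/ug before anchoring), tasiRNA registers 1e6--1e7,
#' transposon siRNA pools dominate the library mass; when a spike-in
#' sheet is supplied, all endogenous amounts are rescaled by one global
#' factor so spike-ins make up `spikein_fraction` of the alignable
#' reads (relative levels are preserved). Precursor and
#' target transcript amounts
#' are derived from mature amounts at ratios of order 0.3--3, giving
#' non-trivial stoichiometries.
#'
#' @param n_mirna,n_tasirna,n_transposon feature counts.
#' @param size_bp genome length.
#' @param seed integer seed; identical parameters and seed give a
#'   byte-identical fixture.
#' @param spikein_sheet optional spike-in sheet; its cores are verified
#'   absent from the genome and its total molarity anchors
#'   `spikein_fraction`.
#' @param spikein_fraction target spike-in share of alignable reads
#'   (default 0.1 at desk-scale depths, so every calibration set except
#'   the most dilute one or two receives a usable read count; production
#'   libraries at full sequencing depth use a far smaller share, 1-2%).
#' @return list of class `synthetic_truth`: `genome` (named character),
#'   `annotations` (annotation data frame), `features` (mature features
#'   with true `molecules_per_ug` and read-sense `seq`), `transposons`
#'   (with true siRNA `molecules_per_ug` and class split), `transcripts`
#'   (precursor/target MPUs), `pairs` (mature family to target),
#'   `params`.
#' @export
make_genome <- function(n_mirna = 20L, n_tasirna = 4L, n_transposon = 10L,
                        size_bp = 100000L, seed = 1L,
                        spikein_sheet = NULL, spikein_fraction = 0.1) {
  set.seed(seed)
  lens <- c(rep(MIRNA_PRE_LEN, n_mirna), rep(TASI_PRE_LEN, n_tasirna),
            rep(TE_LEN, n_transposon))
  n_feat <- length(lens)
  slack <- size_bp - sum(lens) - 50L * (n_feat + 1L)
  if (slack < 0)
    stop_fmt("size_bp = %d too small to pack %d features", size_bp, n_feat)
  cuts <- sort(sample.int(slack + 1L, n_feat, replace = TRUE) - 1L)
  gaps <- 50L + diff(c(0L, cuts))
  starts <- cumsum(gaps) + cumsum(c(0L, lens[-n_feat]))  # 0-based
  strands <- sample(c("+", "-"), n_feat, replace = TRUE)
  genome <- random_genome_seq(size_bp)

  idx_mir <- seq_len(n_mirna)
  idx_tas <- n_mirna + seq_len(n_tasirna)
  idx_te <- n_mirna + n_tasirna + seq_len(n_transposon)

  # miRNA families: roughly every third locus is a 'b' member of the
  # previous family
  fam_num <- integer(n_mirna); member <- character(n_mirna)
  f <- 0L
  for (i in idx_mir) {
    if (i %% 3L == 0L && i > 1L) {
      fam_num[i] <- f; member[i] <- "b"
    } else {
      f <- f + 1L; fam_num[i] <- f; member[i] <- "a"
    }
  }
  mir_family <- sprintf("miR%03d", 100L + fam_num)
  mir_id <- paste0(mir_family, member)

  ann <- list(); feats <- list()
  plant_unique <- function(genome, at) {
    # redraw until the planted 21-mer occurs exactly once genome-wide
    repeat {
      mat <- random_genome_seq(MIRNA_MATURE_LEN)
      g2 <- sub_replace(genome, at, mat)
      if (count_occurrences(mat, g2) == 1L) return(g2)
    }
  }
  for (i in idx_mir) {
    pre_s <- starts[i]; pre_e <- pre_s + MIRNA_PRE_LEN
    mat_s <- pre_s + MIRNA_MATURE_OFF; mat_e <- mat_s + MIRNA_MATURE_LEN
    genome <- plant_unique(genome, mat_s + 1L)
    k <- which(idx_mir == i)
    ann[[length(ann) + 1L]] <- data.frame(
      feature_id = c(paste0(mir_id[k], "_pre"), mir_id[k]),
      chrom = "chr1", start = c(pre_s, mat_s), end = c(pre_e, mat_e),
      strand = strands[i],
      feature_class = c("mirna_precursor", "mirna_mature"),
      family_id = mir_family[k],
      parent_id = c(NA_character_, paste0(mir_id[k], "_pre")),
      stringsAsFactors = FALSE)
  }
  for (i in idx_tas) {
    k <- which(idx_tas == i)
    pre_s <- starts[i]; pre_e <- pre_s + TASI_PRE_LEN
    fam <- sprintf("TAS%d", k)
    reg_s <- pre_s + TASI_PHASE_OFF + (seq_len(TASI_REGISTERS) - 1L) * 21L
    ann[[length(ann) + 1L]] <- data.frame(
      feature_id = c(paste0(fam, "_pre"),
                     sprintf("%s_3D%d", fam, seq_len(TASI_REGISTERS))),
      chrom = "chr1",
      start = c(pre_s, reg_s), end = c(pre_e, reg_s + 21L),
      strand = strands[i],
      feature_class = c("tasirna_precursor", rep("tasirna_mature", TASI_REGISTERS)),
      family_id = fam,
      parent_id = c(NA_character_, rep(paste0(fam, "_pre"), TASI_REGISTERS)),
      stringsAsFactors = FALSE)
  }
  for (i in idx_te) {
    k <- which(idx_te == i)
    ann[[length(ann) + 1L]] <- data.frame(
      feature_id = sprintf("TE%03d", k), chrom = "chr1",
      start = starts[i], end = starts[i] + TE_LEN, strand = strands[i],
      feature_class = "transposon",
      family_id = sprintf("TE%03d", k), parent_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann)

  # scrub any spike-in core from the genome (outside planted matures)
  if (!is.null(spikein_sheet)) {
    mature_rows <- ann[ann$feature_class %in% c("mirna_mature", "tasirna_mature"), ]
    cores <- u2t(spikein_sheet$core)
    for (core in c(cores, revcomp(cores))) {
      repeat {
        at <- regexpr(core, genome, fixed = TRUE)
        if (at < 0L) break
        genome <- sub_replace(genome, at, random_genome_seq(nchar(core)))
      }
    }
    # re-verify planted matures survived scrubbing (collisions are ~1e-5)
    for (r in seq_len(nrow(mature_rows))) {
      s <- substr(genome, mature_rows$start[r] + 1L, mature_rows$end[r])
      if (count_occurrences(s, genome) != 1L)
        stop_fmt("core scrubbing corrupted a planted locus; use another seed")
    }
  }

  mature <- ann[ann$feature_class %in% c("mirna_mature", "tasirna_mature"), ,
                drop = FALSE]
  sense_seq <- function(r) {
    s <- substr(genome, mature$start[r] + 1L, mature$end[r])
    if (mature$strand[r] == "-") revcomp(s) else s
  }
  mature$seq <- vapply(seq_len(nrow(mature)), sense_seq, "")
  is_mir <- mature$feature_class == "mirna_mature"
  mature$molecules_per_ug <- NA_real_
  mature$molecules_per_ug[is_mir] <- 10^stats::runif(sum(is_mir), 5, 8)
  mature$molecules_per_ug[!is_mir] <- 10^stats::runif(sum(!is_mir), 6, 7)

  te <- ann[ann$feature_class == "transposon", , drop = FALSE]
  te_raw <- 10^stats::runif(nrow(te), 7, 8.5)
  if (!is.null(spikein_sheet)) {
    # one global factor brings endogenous mass to the target spike-in
    # share while preserving all relative levels
    if (spikein_fraction <= 0 || spikein_fraction >= 1)
      stop_fmt("spikein_fraction must be in (0, 1)")
    spike_total <- sum(spikein_sheet$molecules_per_ug)
    endo_target <- spike_total * (1 - spikein_fraction) / spikein_fraction
    sc <- endo_target / (sum(mature$molecules_per_ug) + sum(te_raw))
    mature$molecules_per_ug <- mature$molecules_per_ug * sc
    te_raw <- te_raw * sc
  }
  te$molecules_per_ug <- te_raw
  te$frac_23_24 <- 0.7   # plant siRNA pools are dominated by 23-24 nt reads

  fam_mpu <- tapply(mature$molecules_per_ug, mature$family_id, sum)
  fams <- names(fam_mpu)
  pre_of <- tapply(mature$parent_id, mature$family_id,
                   function(x) x[1L])   # one precursor per family here
  transcripts <- data.frame(
    transcript_id = c(unname(pre_of[fams]), paste0(fams, "_target")),
    type = rep(c("precursor", "target"), each = length(fams)),
    family_id = c(fams, fams),
    molecules_per_ug = c(unname(fam_mpu[fams]) / 10^stats::runif(length(fams), 0.1, 0.5),
                         unname(fam_mpu[fams]) / 10^stats::runif(length(fams), -0.5, 0.7)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(mature_id = fams,
                      partner_id = paste0(fams, "_target"),
                      stringsAsFactors = FALSE)

  structure(list(genome = c(chr1 = genome), annotations = ann,
                 features = mature, transposons = te,
                 transcripts = transcripts, pairs = pairs,
                 params = list(n_mirna = n_mirna, n_tasirna = n_tasirna,
                               n_transposon = n_transposon, size_bp = size_bp,
                               seed = seed, spikein_fraction = spikein_fraction)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d bp genome, %d mature sRNAs, %d transposons\n",
              nchar(x$genome[[1L]]), nrow(x$features), nrow(x$transposons)))
  invisible(x)
}

# decode member indices (1-based) into flank pairs and build the 21-mers;
# vectorized over j
member_sequence <- function(core, j, flank_len = 4L) {
  n_flank <- 4L^flank_len
  kmers <- all_kmers(flank_len, DNA_BASES)
  f5 <- kmers[(j - 1L) %/% n_flank + 1L]
  f3 <- kmers[(j - 1L) %% n_flank + 1L]
  paste0(f5, u2t(core), f3)
}

# per-set member weights under the lognormal ligation-efficiency model;
# unit mean so expected library composition equals molecule shares
member_weights <- function(molecules, n_members, bias_sd_log2) {
  sdlog <- bias_sd_log2 * log(2)
  bias <- stats::rlnorm(n_members, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  molecules / n_members * bias
}

#' Simulate spike-in-only reads
#'
#' Distributes each set's molecules uniformly over its `4^(2*flank_len)`
#' members, applies an independent unit-mean lognormal cloning bias per
#' member (`sd` of log2 bias = `bias_sd_log2`), and draws `depth` reads
#' multinomially. This isolates the mechanism by which averaging over a
#' set's many member sequences suppresses per-sequence cloning bias.
#'
#' @param sheet spike-in sheet.
#' @param depth number of reads.
#' @param bias_sd_log2 sd of the log2 per-member bias (default 1).
#' @param flank_len flank length (default 4).
#' @param seed integer seed.
#' @return data frame `seq`, `count` of distinct member reads (DNA
#'   alphabet, no adapter), with attribute `set_counts` (true per-set read
#'   totals).
#' @export
simulate_spikein_reads <- function(sheet, depth = 1e5, bias_sd_log2 = 1,
                                   flank_len = 4L, seed = 1L) {
  set.seed(seed)
  n_members <- 4L^(2L * flank_len)
  w <- unlist(lapply(sheet$molecules_per_ug, member_weights,
                     n_members = n_members, bias_sd_log2 = bias_sd_log2))
  counts <- as.vector(stats::rmultinom(1L, size = depth, prob = w))
  nz <- which(counts > 0L)
  set_i <- (nz - 1L) %/% n_members + 1L
  mem_j <- (nz - 1L) %% n_members + 1L
  seqs <- character(length(nz))
  for (s in unique(set_i)) {
    sel <- set_i == s
    seqs[sel] <- member_sequence(sheet$core[s], mem_j[sel], flank_len)
  }
  out <- data.frame(seq = seqs, count = counts[nz], stringsAsFactors = FALSE)
  attr(out, "set_counts") <- stats::setNames(
    vapply(seq_len(nrow(sheet)), function(s) sum(out$count[set_i == s]), 0),
    sheet$set_id)
  out
}

#' Simulate a full sRNA-Seq library
#'
#' Draws `depth` reads multinomially across endogenous mature sRNAs (with
#' a small, fixed isomiR offset profile of +/-1--2 nt), transposon siRNA
#' windows, and biased spike-in members, then appends the 3' adapter.
#' Endogenous reads carry no per-sequence bias; the lognormal bias model
#' applies to spike-in 21-mers, whose set-level averaging is the design
#' property under test.
#'
#' @param truth a [make_genome()] result.
#' @param sheet spike-in sheet.
#' @param depth library depth (default 2e5 reads).
#' @param bias_sd_log2 sd of log2 per-member spike-in bias (default 1).
#' @param adapter 3' adapter appended to every read.
#' @param seed integer seed.
#' @param windows_per_te distinct siRNA windows simulated per transposon.
#' @return list with `reads` (data frame `id`, `seq`, `qual`, exactly
#'   `depth` rows, shuffled), `expected` (expected read count per mature
#'   feature and transposon at this depth) and `set_expected` (expected
#'   spike-in reads per set).
#' @export
simulate_library <- function(truth, sheet, depth = 2e5, bias_sd_log2 = 1,
                             adapter = DEFAULT_ADAPTER, seed = 1L,
                             windows_per_te = 30L) {
  set.seed(seed)
  genome <- truth$genome[[1L]]
  feats <- truth$features
  iso_off <- c(-2L, -1L, 0L, 1L, 2L)
  iso_w <- c(0.03, 0.07, 0.80, 0.07, 0.03)

  cat_seq <- character(0L); cat_w <- numeric(0L); cat_src <- character(0L)
  for (r in seq_len(nrow(feats))) {
    len <- feats$end[r] - feats$start[r]
    for (k in seq_along(iso_off)) {
      s <- feats$start[r] + iso_off[k]
      sq <- substr(genome, s + 1L, s + len)
      if (feats$strand[r] == "-") sq <- revcomp(sq)
      cat_seq <- c(cat_seq, sq)
      cat_w <- c(cat_w, feats$molecules_per_ug[r] * iso_w[k])
      cat_src <- c(cat_src, feats$feature_id[r])
    }
  }
  te <- truth$transposons
  sirna_lens <- c(20L, 21L, 22L, 23L, 24L)
  for (r in seq_len(nrow(te))) {
    p2324 <- te$frac_23_24[r]
    len_p <- c(rep((1 - p2324) / 3, 3L), rep(p2324 / 2, 2L))
    lens <- sample(sirna_lens, windows_per_te, replace = TRUE, prob = len_p)
    st <- te$start[r] + sample.int(TE_LEN - 24L, windows_per_te, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), windows_per_te, replace = TRUE)
    sq <- substr(rep(genome, windows_per_te), st + 1L, st + lens)
    sq[strand == "-"] <- revcomp(sq[strand == "-"])
    cat_seq <- c(cat_seq, sq)
    cat_w <- c(cat_w, rep(te$molecules_per_ug[r] / windows_per_te, windows_per_te))
    cat_src <- c(cat_src, rep(te$feature_id[r], windows_per_te))
  }
  n_members <- 4L^8L
  spike_w <- unlist(lapply(sheet$molecules_per_ug, member_weights,
                           n_members = n_members, bias_sd_log2 = bias_sd_log2))
  w_all <- c(cat_w, spike_w)
  counts <- as.vector(stats::rmultinom(1L, size = depth, prob = w_all))

  n_endo <- length(cat_w)
  endo_counts <- counts[seq_len(n_endo)]
  sp_counts <- counts[-seq_len(n_endo)]
  nz <- which(sp_counts > 0L)
  set_i <- (nz - 1L) %/% n_members + 1L
  mem_j <- (nz - 1L) %% n_members + 1L
  sp_seq <- character(length(nz))
  for (s in unique(set_i)) {
    sel <- set_i == s
    sp_seq[sel] <- member_sequence(sheet$core[s], mem_j[sel], 4L)
  }

  seqs <- c(rep(cat_seq, endo_counts), rep(sp_seq, sp_counts[nz]))
  seqs <- paste0(seqs, adapter)
  ord <- sample.int(length(seqs))
  reads <- data.frame(id = sprintf("read%07d", seq_along(seqs)),
                      seq = seqs[ord],
                      qual = strrep("I", nchar(seqs[ord])),
                      stringsAsFactors = FALSE)

  tot_w <- sum(w_all)
  expected_feat <- tapply(cat_w, cat_src, sum) / tot_w * depth
  set_expected <- vapply(split(spike_w, rep(seq_len(nrow(sheet)),
                                            each = n_members)), sum, 0) /
    tot_w * depth
  list(reads = reads,
       expected = data.frame(feature_id = names(expected_feat),
                             expected_reads = unname(expected_feat),
                             stringsAsFactors = FALSE),
       set_expected = stats::setNames(set_expected, sheet$set_id))
}

#' Synthetic ERCC-like mRNA tables
#'
#' Emits an ERCC concentration sheet whose known amounts span >= 4
#' decades, a TPM table containing those ERCC rows with
#' `TPM = a * MPU * 10^eps`, `eps ~ N(0, noise_sd)`, and TPM rows for the
#' truth's precursor and target transcripts under the same
#' TPM-per-molecule factor.
#'
#' @param truth a [make_genome()] result.
#' @param ercc_n number of ERCC-like spike-ins (default 24).
#' @param noise_sd sd of the log10 TPM noise (default 0.05).
#' @param seed integer seed.
#' @param tpm_per_mpu proportionality factor `a` (default 1e-4, placing
#'   TPMs in a realistic 0.1--1000 range).
#' @return list with `tpm_table` (`transcript_id`, `tpm`) and
#'   `ercc_sheet` (`ercc_id`, `molecules_per_ug`).
#' @export
make_mrna_tables <- function(truth, ercc_n = 24L, noise_sd = 0.05,
                             seed = 1L, tpm_per_mpu = 1e-4) {
  if (ercc_n < 2L) stop_fmt("ercc_n must be >= 2")
  set.seed(seed)
  ercc_mpu <- 10^seq(3, 7, length.out = ercc_n)
  ercc_id <- sprintf("ERCC-%05d", seq_len(ercc_n))
  ercc_tpm <- tpm_per_mpu * ercc_mpu * 10^stats::rnorm(ercc_n, 0, noise_sd)
  tr <- truth$transcripts
  tr_tpm <- tpm_per_mpu * tr$molecules_per_ug * 10^stats::rnorm(nrow(tr), 0, noise_sd)
  list(
    tpm_table = data.frame(
      transcript_id = c(ercc_id, tr$transcript_id),
      tpm = c(ercc_tpm, tr_tpm), stringsAsFactors = FALSE),
    ercc_sheet = data.frame(ercc_id = ercc_id, molecules_per_ug = ercc_mpu,
                            stringsAsFactors = FALSE))
}
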