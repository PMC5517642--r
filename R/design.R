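# Spike-in design: position frequency matrix from abundant miRNAs,
# semi-random 13 nt core sampling, genome-exclusion filtering, flank
# expansion, MFE distribution matching and mix formulation.

#' Base-frequency matrix from abundant miRNAs
#'
#' Tallies base identities at miRNA positions 5--17 (counting from the 5'
#' end) over the top fraction of miRNAs ranked by abundance. The tally is
#' unweighted: each retained miRNA contributes one count per position.
#'
#' @param mirnas character vector of mature miRNA sequences (RNA or DNA
#'   alphabet); only sequences of length >= 17 are usable.
#' @param abundance numeric vector of abundances (e.g. mean RPM across
#'   libraries), same length as `mirnas`.
#' @param top_fraction fraction in (0,1] of most abundant miRNAs to retain
#'   (default 0.5, i.e. the top 50%).
#' @return 4 x 13 matrix (rows A,C,G,U; columns = miRNA positions 5--17),
#'   each column summing to 1.
#' @export
build_frequency_matrix <- function(mirnas, abundance, top_fraction = 0.5) {
  if (length(mirnas) != length(abundance))
    stop_fmt("mirnas and abundance must have the same length")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop_fmt("top_fraction must be in (0, 1]")
  if (any(abundance < 0)) stop_fmt("abundances must be >= 0")
  keep <- nchar(mirnas) >= 17L
  mirnas <- mirnas[keep]
  abundance <- abundance[keep]
  if (length(mirnas) == 0L)
    stop_fmt("no miRNA of length >= 17 available for the frequency matrix")
  n_top <- max(1L, ceiling(top_fraction * length(mirnas)))
  top <- t2u(mirnas[order(-abundance)][seq_len(n_top)])
  mat <- matrix(0, nrow = 4L, ncol = 13L,
                dimnames = list(RNA_BASES, paste0("pos", 5:17)))
  chars <- strsplit(substr(top, 5L, 17L), "", fixed = TRUE)
  for (ch in chars) {
    idx <- match(ch, RNA_BASES)
    if (anyNA(idx)) stop_fmt("miRNA sequence contains non-ACGU base")
    for (j in seq_len(13L)) mat[idx[j], j] <- mat[idx[j], j] + 1
  }
  sweep(mat, 2L, colSums(mat), "/")
}

#' Semi-randomly sample distinct 13 nt core sequences
#'
#' Each position is drawn independently from the corresponding column of
#' the base-frequency matrix. Duplicates are removed and resampled until
#' `n` distinct cores exist or a bounded number of rounds is exhausted.
#'
#' @param matrix 4 x 13 base-frequency matrix from
#'   [build_frequency_matrix()].
#' @param n number of distinct cores to return.
#' @param seed integer seed for reproducibility.
#' @param max_rounds resampling rounds before giving up.
#' @return character vector of `n` distinct 13 nt RNA sequences.
#' @export
sample_cores <- function(matrix, n, seed = 1L, max_rounds = 50L) {
  if (n < 1L) stop_fmt("n must be >= 1")
  stopifnot(nrow(matrix) == 4L, ncol(matrix) == 13L)
  set.seed(seed)
  draw <- function(m) {
    cols <- lapply(seq_len(13L), function(j)
      sample(RNA_BASES, m, replace = TRUE, prob = matrix[, j]))
    do.call(paste0, cols)
  }
  cores <- character(0L)
  for (round in seq_len(max_rounds)) {
    cores <- unique(c(cores, draw(n - length(cores))))
    if (length(cores) >= n) return(cores[seq_len(n)])
  }
  stop_fmt("could not sample %d distinct cores in %d rounds (matrix too degenerate)",
           n, max_rounds)
}

#' Remove cores that perfectly match the genome
#'
#' A core is excluded if it (or its reverse complement) occurs as an exact
#' substring anywhere in the genome, i.e. matching is checked on both
#' strands. U/T differences are canonicalized before matching.
#'
#' @param cores character vector of 13 nt cores.
#' @param genome data frame from [read_fasta()], named character vector, or
#'   `Biostrings::DNAStringSet`. May be empty (all cores pass).
#' @return the genome-clean subset of `cores`, with attribute
#'   `genome_clean = TRUE`.
#' @export
filter_genome_matching <- function(cores, genome) {
  seqs <- genome_as_character(genome)
  if (length(seqs) == 0L || length(cores) == 0L) {
    out <- cores
  } else {
    subject <- Biostrings::DNAStringSet(u2t(seqs))
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(u2t(cores)))
    pd_rev <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(cores)))
    hits <- rowSums(Biostrings::vcountPDict(pd_fwd, subject)) +
      rowSums(Biostrings::vcountPDict(pd_rev, subject))
    out <- cores[hits == 0L]
  }
  attr(out, "genome_clean") <- TRUE
  out
}

# accept the genome in any of the forms the package passes around
genome_as_character <- function(genome) {
  if (is.data.frame(genome)) {
    seqs <- genome$seq
    names(seqs) <- genome$id
    seqs
  } else if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    genome
  } else stop_fmt("unsupported genome representation")
}

#' Expand a core into its full flank set
#'
#' Adds every possible 5' and 3' flank of length `flank_len` over
#' \{A,C,G,U\}, yielding `4^(2*flank_len)` member sequences (65,536 21-mers
#' for the default 13 nt core and 4 nt flanks).
#'
#' @param core 13 nt core sequence.
#' @param flank_len flank length on each end (default 4).
#' @return character vector of member sequences (RNA alphabet), with
#'   attributes `core` and `flank_len`.
#' @export
expand_set <- function(core, flank_len = 4L) {
  if (flank_len < 1L) stop_fmt("flank_len must be >= 1")
  core <- t2u(core)
  flanks <- all_kmers(flank_len, RNA_BASES)
  members <- as.vector(outer(flanks, flanks,
                             function(f5, f3) paste0(f5, core, f3)))
  attr(members, "core") <- core
  attr(members, "flank_len") <- flank_len
  members
}

#' Select candidate sets whose MFE distribution matches a reference
#'
#' Ranks candidates by the two-sample Kolmogorov-Smirnov statistic between
#' their member MFE values and a reference distribution (typically MFEs of
#' annotated endogenous miRNAs) and returns the `k` best. Ties are broken
#' by lexicographic core order, which also makes the selection invariant to
#' candidate input order.
#'
#' @param candidates list, each element a list with `core` (13 nt string)
#'   and `mfe` (numeric vector of member MFE values, kcal/mol).
#' @param reference numeric vector of reference MFE values.
#' @param k number of sets to select.
#' @return the selected sublist, with attribute `report` (data frame of
#'   core and KS D for every candidate, in ranked order).
#' @export
select_sets <- function(candidates, reference, k) {
  if (length(reference) == 0L) stop_fmt("reference MFE distribution is empty")
  if (k > length(candidates))
    stop_fmt("k (%d) exceeds number of candidates (%d)", k, length(candidates))
  cores <- vapply(candidates, function(cn) t2u(cn$core), "")
  d <- vapply(candidates, function(cn) ks_statistic(cn$mfe, reference), 0)
  ord <- order(d, cores)
  report <- data.frame(core = cores[ord], ks_d = d[ord],
                       stringsAsFactors = FALSE)
  out <- candidates[ord[seq_len(k)]]
  attr(out, "report") <- report
  out
}

#' Formulate a spike-in mix spanning a dynamic range
#'
#' Assigns molecules-per-microgram amounts that are log10-equispaced from
#' `max_molecules_per_ug` down across `dynamic_range_log10` decades, one
#' amount per set in descending order, so the mix spans the dynamic range
#' of the sRNAs to be calibrated.
#'
#' @param cores character vector of selected core sequences (one per set).
#' @param dynamic_range_log10 decades spanned from the highest to the
#'   lowest amount (default 4).
#' @param max_molecules_per_ug amount for the first set.
#' @param set_ids optional set identifiers (default `spike_1..n`).
#' @return `spikein_sheet` data frame (`set_id`, `core`,
#'   `molecules_per_ug`).
#' @export
formulate_mix <- function(cores, dynamic_range_log10 = 4,
                          max_molecules_per_ug = 1e8,
                          set_ids = NULL) {
  n <- length(cores)
  if (n < 1L) stop_fmt("at least one set is required")
  if (dynamic_range_log10 <= 0) stop_fmt("dynamic_range_log10 must be > 0")
  if (max_molecules_per_ug <= 0) stop_fmt("max_molecules_per_ug must be > 0")
  if (is.null(set_ids)) set_ids <- sprintf("spike_%d", seq_len(n))
  amounts <- if (n == 1L) max_molecules_per_ug else
    10^seq(log10(max_molecules_per_ug),
           log10(max_molecules_per_ug) - dynamic_range_log10,
           length.out = n)
  validate_spikein_sheet(data.frame(
    set_id = set_ids, core = t2u(cores), molecules_per_ug = amounts,
    stringsAsFactors = FALSE))
}

#' Design configuration defaults
#'
#' @param n_candidates number of 13 nt cores to sample (default 1000).
#' @param flank_len flank length (default 4).
#' @param n_select number of sets in the final mix (default 8).
#' @param top_fraction abundance fraction for the frequency matrix
#'   (default 0.5).
#' @param seed integer seed.
#' @param mfe_backend `"internal_nussinov"` or `"external_rnafold"`.
#' @param mfe_sample_per_set members scored per candidate set (default
#'   2000; full enumeration with `Inf`).
#' @param min_hamming minimum pairwise Hamming distance between selected
#'   cores (default 4), keeping 13 nt tags unambiguous.
#' @return list of class `design_config`.
#' @export
design_config <- function(n_candidates = 1000L, flank_len = 4L,
                          n_select = 8L, top_fraction = 0.5, seed = 1L,
                          mfe_backend = c("internal_nussinov", "external_rnafold"),
                          mfe_sample_per_set = 2000L, min_hamming = 4L) {
  structure(list(n_candidates = n_candidates, flank_len = flank_len,
                 n_select = n_select, top_fraction = top_fraction,
                 seed = seed, mfe_backend = match.arg(mfe_backend),
                 mfe_sample_per_set = mfe_sample_per_set,
                 min_hamming = min_hamming),
            class = "design_config")
}

#' Run the full spike-in design algorithm
#'
#' Builds the position frequency matrix from the supplied miRNAs, samples
#' candidate cores, removes genome-matching ones, scores the MFE
#' distribution of each candidate's flank expansion on a seeded subsample
#' of members, ranks candidates by similarity (KS statistic) to the
#' endogenous miRNA MFE distribution, greedily enforces pairwise core
#' distinctness (Hamming distance >= `min_hamming`), and formulates the
#' mix.
#'
#' @param mirnas,abundance mature miRNA sequences and abundances.
#' @param genome genome sequences (see [filter_genome_matching()]).
#' @param config a [design_config()].
#' @param max_molecules_per_ug,dynamic_range_log10 mix parameters passed to
#'   [formulate_mix()].
#' @return list with `sheet` (spike-in sheet), `cores` (selected cores),
#'   `report` (per-candidate KS D), `matrix` (frequency matrix),
#'   `reference_mfe` (endogenous miRNA MFE values) and `mfe_backend`.
#' @export
design_spikeins <- function(mirnas, abundance, genome,
                            config = design_config(),
                            max_molecules_per_ug = 1e8,
                            dynamic_range_log10 = 4) {
  mat <- build_frequency_matrix(mirnas, abundance, config$top_fraction)
  cores <- sample_cores(mat, config$n_candidates, seed = config$seed)
  clean <- filter_genome_matching(cores, genome)
  if (length(clean) == 0L)
    stop_fmt("no genome-clean cores among %d candidates", length(cores))
  if (length(clean) < config$n_select)
    stop_fmt("only %d genome-clean cores; %d sets requested",
             length(clean), config$n_select)
  reference <- compute_mfe(mirnas, backend = config$mfe_backend)
  candidates <- lapply(seq_along(clean), function(i) {
    members <- expand_set(clean[i], config$flank_len)
    m <- length(members)
    take <- min(config$mfe_sample_per_set, m)
    set.seed(derive_seed(config$seed, i))
    sub <- if (take < m) members[sample.int(m, take)] else members
    list(core = clean[i], mfe = compute_mfe(sub, backend = config$mfe_backend))
  })
  ranked <- select_sets(candidates, reference, k = length(candidates))
  report <- attr(ranked, "report")
  # greedy pick down the ranking, enforcing core distinctness
  chosen <- character(0L)
  for (cand in ranked) {
    if (all(vapply(chosen, function(cc) hamming(cc, t2u(cand$core)), 0L) >=
            config$min_hamming))
      chosen <- c(chosen, t2u(cand$core))
    if (length(chosen) == config$n_select) break
  }
  if (length(chosen) < config$n_select)
    stop_fmt("could not find %d cores with pairwise Hamming >= %d",
             config$n_select, config$min_hamming)
  sheet <- formulate_mix(chosen, dynamic_range_log10, max_molecules_per_ug)
  list(sheet = sheet, cores = chosen, report = report, matrix = mat,
       reference_mfe = reference, mfe_backend = config$mfe_backend)
}
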