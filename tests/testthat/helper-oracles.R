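# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use different algorithms/code paths than
# the package implementation they check.

# brute-force both-strand substring scan: all 0-based start positions of
# `pattern` in the named character vector `chroms`
naive_scan <- function(pattern, chroms) {
  out <- list()
  rc <- srnaspike::revcomp(pattern)
  for (nm in names(chroms)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pattern else rc
      hits <- gregexpr(pat, chroms[[nm]], fixed = TRUE)[[1L]]
      # gregexpr misses overlapping occurrences; rescan manually
      starts <- integer(0L)
      from <- 1L
      repeat {
        p <- regexpr(pat, substr(chroms[[nm]], from, nchar(chroms[[nm]])),
                     fixed = TRUE)
        if (p < 0L) break
        starts <- c(starts, from + p - 2L)  # 0-based
        from <- from + p
      }
      if (length(starts))
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = starts, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), strand = character())
}

# exhaustive enumeration of all non-crossing structures with hairpin
# loops >= 3 nt, scoring each with the simplified pair energies; returns
# the minimum total energy (0 for the empty structure)
enumerate_mfe <- function(seq) {
  pe <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = , CG = -1.0, AT = , TA = -0.8, GT = , TG = -0.5, NA_real_)
  }
  b <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1L]]
  n <- length(b)
  structures <- function(i, j) {
    # list of pair-lists for subsequence i..j
    if (j - i < 4L) return(list(list()))
    res <- lapply(structures(i + 1L, j), identity)   # i unpaired
    for (k in (i + 4L):j) {
      if (is.na(pe(b[i], b[k]))) next
      left <- structures(i + 1L, k - 1L)
      right <- if (k < j) structures(k + 1L, j) else list(list())
      for (L in left) for (R in right)
        res[[length(res) + 1L]] <- c(list(c(i, k)), L, R)
    }
    res
  }
  energies <- vapply(structures(1L, n), function(s) {
    if (!length(s)) return(0)
    sum(vapply(s, function(p) pe(b[p[1L]], b[p[2L]]), 0))
  }, 0)
  min(energies, 0)
}

# small fixed spike-in sheet with pairwise-distant cores
toy_sheet <- function(n = 3L, max_amount = 1e6, range_log10 = 2) {
  cores <- c("ACGGAUCCGUUAG", "UUGCCAGAUCGAC", "GGAUUCGAACCGU",
             "CAACGUGGAUACG", "AGGCAUUGCAUCC", "UCGAGGAUAACGG",
             "GAUCCAUGGCAAU", "CCGUAAGCUGAUC")[seq_len(n)]
  srnaspike::formulate_mix(cores, range_log10, max_amount)
}

# a random genome guaranteed to avoid a set of cores
toy_genome <- function(size = 5000L, seed = 1L, avoid = character()) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), size, TRUE), collapse = "")
  for (core in c(avoid, srnaspike::revcomp(avoid))) {
    core <- chartr("U", "T", core)
    while (grepl(core, g, fixed = TRUE)) {
      at <- regexpr(core, g, fixed = TRUE)
      substr(g, at, at + nchar(core) - 1L) <-
        paste(sample(c("A", "C", "G", "T"), nchar(core), TRUE), collapse = "")
    }
  }
  c(chr1 = g)
}
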