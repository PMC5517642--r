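test_that("synthetic genome plants the requested loci with clean bookkeeping", {
  sheet <- toy_sheet(4)
  truth <- make_genome(n_mirna = 5, n_tasirna = 2, n_transposon = 3,
                       size_bp = 30000, seed = 3, spikein_sheet = sheet)
  ann <- truth$annotations
  expect_equal(sum(ann$feature_class == "mirna_mature"), 5L)
  expect_equal(sum(ann$feature_class == "mirna_precursor"), 5L)
  expect_equal(sum(ann$feature_class == "tasirna_mature"), 2L * 4L)
  expect_equal(sum(ann$feature_class == "transposon"), 3L)
  # every mature feature links to an annotated precursor
  mat <- ann[grepl("mature", ann$feature_class), ]
  expect_true(all(mat$parent_id %in% ann$feature_id))

  # planted mature sequences occur exactly once (both-strand scan oracle)
  for (r in seq_len(nrow(truth$features))) {
    hits <- naive_scan(truth$features$seq[r], truth$genome)
    expect_equal(nrow(hits), 1L, info = truth$features$feature_id[r])
  }
  # no spike-in core (either orientation) occurs in the genome
  for (core in sheet$core)
    expect_equal(nrow(naive_scan(chartr("U", "T", core), truth$genome)), 0L)
  # reproducibility
  truth2 <- make_genome(n_mirna = 5, n_tasirna = 2, n_transposon = 3,
                        size_bp = 30000, seed = 3, spikein_sheet = sheet)
  expect_identical(truth$genome, truth2$genome)
  expect_identical(truth$features$molecules_per_ug,
                   truth2$features$molecules_per_ug)
  expect_error(make_genome(n_mirna = 100, size_bp = 5000, seed = 1),
               "too small")
})

test_that("library simulation hits the requested depth and molecule shares", {
  sheet <- toy_sheet(4, max_amount = 1e7, range_log10 = 2)
  truth <- make_genome(n_mirna = 6, n_tasirna = 1, n_transposon = 2,
                       size_bp = 20000, seed = 5, spikein_sheet = sheet)
  sim <- simulate_library(truth, sheet, depth = 50000, bias_sd_log2 = 0,
                          seed = 9)
  expect_equal(nrow(sim$reads), 50000L)
  expect_identical(sim$reads,
                   simulate_library(truth, sheet, depth = 50000,
                                    bias_sd_log2 = 0, seed = 9)$reads)

  # with zero bias, per-feature read share ~ molecule share (3 multinomial SE)
  ins <- trim_adapter(sim$reads$seq, DEFAULT_ADAPTER)
  col <- collapse_reads(ins)
  aln <- align_perfect(col, truth$genome, sheet)
  q <- quantify_families(aln, truth$annotations)
  mirs <- truth$features[truth$features$feature_class == "mirna_mature", ]
  for (r in seq_len(nrow(mirs))) {
    exp_n <- sim$expected$expected_reads[sim$expected$feature_id ==
                                           mirs$feature_id[r]]
    obs <- sum(aln$hits$weight[aln$hits$start >= mirs$start[r] - 2 &
                                 aln$hits$start < mirs$end[r] &
                                 aln$hits$chrom == "chr1"])
    se <- sqrt(exp_n)
    expect_lt(abs(obs - exp_n), max(3 * se, 5), label = mirs$feature_id[r])
  }
})

test_that("averaging over many biased members stabilizes set-level recovery", {
  # relative spread of total ligation-efficiency-weighted mass: a 65,536-member
  # set is far tighter than a single-sequence spike-in of equal molarity
  set.seed(77)
  sd_set <- sd(replicate(20, sum(srnaspike:::member_weights(1e6, 65536, 1))))
  sd_single <- sd(replicate(20, sum(srnaspike:::member_weights(1e6, 1, 1))))
  expect_lt(sd_set / 1e6, sd_single / 1e6)
  expect_lt(sd_set / 1e6, 0.05)

  # and the read-level consequence: per-set counts across seeds stay close
  # to expectation under bias_sd_log2 = 1
  sheet <- toy_sheet(2, max_amount = 1e6, range_log10 = 0.5)
  counts <- replicate(5, {
    r <- simulate_spikein_reads(sheet, depth = 20000, bias_sd_log2 = 1,
                                seed = sample.int(1e6, 1))
    attr(r, "set_counts")[[1]]
  })
  exp_share <- sheet$molecules_per_ug[1] / sum(sheet$molecules_per_ug) * 20000
  expect_lt(sd(counts) / mean(counts), 0.05)
  expect_lt(abs(mean(counts) - exp_share) / exp_share, 0.05)
})

test_that("ERCC-like tables recover the TPM-per-molecule factor exactly at zero noise", {
  sheet <- toy_sheet(2)
  truth <- make_genome(n_mirna = 4, n_tasirna = 1, n_transposon = 2,
                       size_bp = 20000, seed = 6, spikein_sheet = sheet)
  tabs <- make_mrna_tables(truth, ercc_n = 12, noise_sd = 0, seed = 2)
  expect_equal(nrow(tabs$ercc_sheet), 12L)
  expect_true(all(tabs$ercc_sheet$ercc_id %in% tabs$tpm_table$transcript_id))
  expect_true(all(tabs$tpm_table$tpm > 0))
  out <- mrna_to_mpu(tabs$tpm_table, tabs$ercc_sheet, min_tpm = 0)
  expect_equal(out$curve$slope, 1, tolerance = 1e-9)
  expect_equal(out$curve$intercept, 4, tolerance = 1e-9)  # a = 1e-4
  # transcript MPUs equal the planted truth
  rec <- out$records
  idx <- match(truth$transcripts$transcript_id, rec$feature_id)
  expect_equal(rec$absolute_mpu[idx], truth$transcripts$molecules_per_ug,
               tolerance = 1e-9)
})
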