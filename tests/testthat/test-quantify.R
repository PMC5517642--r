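# helpers to build hit/annotation rows directly
hit_row <- function(start, len = 21L, strand = "+", weight = 1, chrom = "chr1",
                    count = 1) {
  data.frame(read_seq = strrep("A", len), length = len, count = count,
             chrom = chrom, start = start, strand = strand,
             n_hits = 1L, weight = weight, stringsAsFactors = FALSE)
}
anno_row <- function(id, start, end, class, strand = "+", family = id,
                     parent = NA_character_) {
  data.frame(feature_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, feature_class = class, family_id = family,
             parent_id = parent, stringsAsFactors = FALSE)
}

test_that("mature assignment applies the 20-22 nt and +/-2 nt containment rule", {
  ann <- anno_row("mirA", 100L, 121L, "mirna_mature", parent = "mirA_pre")
  # exact placement
  expect_equal(assign_mature(hit_row(100L), ann)$count, 1)
  # shifts of 1 and 2 nt accepted, 3 nt rejected
  expect_equal(assign_mature(hit_row(102L), ann)$count, 1)
  expect_equal(assign_mature(hit_row(98L), ann)$count, 1)
  expect_equal(assign_mature(hit_row(103L), ann)$count, 0)
  expect_equal(assign_mature(hit_row(97L), ann)$count, 0)
  # length gates: 20 and 22 in, 19 and 24 out
  expect_equal(assign_mature(hit_row(100L, len = 20L), ann)$count, 1)
  expect_equal(assign_mature(hit_row(100L, len = 22L), ann)$count, 1)
  expect_equal(assign_mature(hit_row(100L, len = 19L), ann)$count, 0)
  expect_equal(assign_mature(hit_row(100L, len = 24L), ann)$count, 0)
  # antisense hits never count toward a mature feature
  expect_equal(assign_mature(hit_row(100L, strand = "-"), ann)$count, 0)
})

test_that("siRNA assignment bins by length and splits multi-transposon weight", {
  tes <- rbind(anno_row("TE1", 1000L, 1800L, "transposon"),
               anno_row("TE2", 1790L, 2600L, "transposon"))
  # 24 nt antisense read inside TE1 -> 23-24 bin
  out <- assign_sirna(hit_row(1200L, len = 24L, strand = "-"), tes)
  expect_equal(out$count[out$feature_id == "TE1" & out$sclass == "siRNA_23_24"], 1)
  expect_equal(sum(out$count), 1)
  # length gates: 19 and 25 excluded, 20 included
  expect_equal(sum(assign_sirna(hit_row(1200L, len = 19L), tes)$count), 0)
  expect_equal(sum(assign_sirna(hit_row(1200L, len = 25L), tes)$count), 0)
  expect_equal(sum(assign_sirna(hit_row(1200L, len = 20L), tes)$count), 1)
  # a single-base overlap counts
  expect_equal(sum(assign_sirna(hit_row(980L, len = 21L), tes)$count), 1)
  expect_equal(sum(assign_sirna(hit_row(979L, len = 21L), tes)$count), 0)
  # read overlapping both transposons contributes half weight to each
  out <- assign_sirna(hit_row(1785L, len = 21L, weight = 1), tes)
  expect_equal(out$count[out$feature_id == "TE1" & out$sclass == "siRNA_20_22"], 0.5)
  expect_equal(out$count[out$feature_id == "TE2" & out$sclass == "siRNA_20_22"], 0.5)
})

test_that("family aggregation sums members and conserves mass", {
  pf <- data.frame(feature_id = c("miR169a", "miR169b", "miR169c", "miR157a"),
                   family_id = c("miR169", "miR169", "miR169", "miR157"),
                   count = c(1, 2, 3, 7))
  agg <- aggregate_families(pf)
  expect_equal(agg$count[agg$family_id == "miR169"], 6)
  expect_equal(agg$count[agg$family_id == "miR157"], 7)
  expect_equal(sum(agg$count), sum(pf$count))
  pf$family_id[1] <- NA
  expect_error(aggregate_families(pf), "lacks a family_id")
})

test_that("precursor totals sum their mature children", {
  ann <- rbind(anno_row("preA", 100L, 220L, "mirna_precursor"),
               anno_row("preB", 400L, 520L, "mirna_precursor"))
  mc <- data.frame(feature_id = c("miRa", "miRa.star", "miRb"),
                   parent_id = c("preA", "preA", "preB"),
                   count = c(5, 1.5, 0))
  out <- per_precursor_counts(mc, ann)
  expect_equal(out$count[out$precursor_id == "preA"], 6.5)
  expect_equal(out$count[out$precursor_id == "preB"], 0)
  mc$parent_id[3] <- "nosuch"
  expect_error(per_precursor_counts(mc, ann), "dangling parent_id")
})

test_that("length/base profile normalizes per occupied position", {
  reads <- data.frame(seq = c(strrep("A", 21), strrep("C", 21)),
                      count = c(3L, 3L))
  prof <- length_base_profile(reads, genome_matching_total = 6)
  expect_equal(unname(prof$rpm["21"]), 1e6)
  expect_true(all(prof$rpm[names(prof$rpm) != "21"] == 0))
  bf <- prof$base_freq[["21"]]
  expect_equal(unname(bf["A", 1]), 0.5)
  expect_equal(unname(bf["C", 1]), 0.5)
  expect_true(all(abs(colSums(bf) - 1) < 1e-12))
})

test_that("full quantification conserves assigned weight and flags overlaps", {
  ann <- rbind(
    anno_row("mirA", 1100L, 1121L, "mirna_mature", family = "miRA",
             parent = "mirA_pre"),
    anno_row("mirA_pre", 1050L, 1170L, "mirna_precursor", family = "miRA"),
    anno_row("TE1", 1000L, 1800L, "transposon"))
  hits <- rbind(hit_row(1100L, len = 21L, weight = 2, count = 2),
                hit_row(1400L, len = 24L, weight = 1))
  aln <- list(hits = hits,
              stats = library_stats(3, 3, 0))
  q <- quantify_families(aln, ann)
  # the mature read is inside TE1 as well -> double-assigned weight flagged
  expect_equal(q$double_assigned_weight, 2)
  expect_equal(sum(q$families$count[q$families$sclass == "miRNA"]), 2)
  expect_equal(sum(q$families$count[q$families$sclass == "siRNA_23_24"]), 1)
  expect_equal(q$precursors$count, 2)
  # rpm uses the genome-matching denominator
  expect_equal(q$families$rpm[q$families$family_id == "miRA"], 2 / 3 * 1e6)
})
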