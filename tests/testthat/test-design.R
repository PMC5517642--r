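test_that("frequency matrix tallies positions 5-17 of the most abundant miRNAs", {
  # degenerate composition: a single all-A miRNA
  m <- build_frequency_matrix(strrep("A", 21), 10)
  expect_equal(dim(m), c(4L, 13L))
  expect_true(all(m["A", ] == 1))

  # two equally abundant miRNAs differing only at position 5
  a <- strrep("G", 21)
  b <- paste0(strrep("G", 4), "C", strrep("G", 16))
  substr(a, 5, 5) <- "A"
  m <- build_frequency_matrix(c(a, b), c(5, 5), top_fraction = 1)
  expect_equal(m[, 1], c(A = 0.5, C = 0.5, G = 0, U = 0))
  expect_true(all(abs(colSums(m) - 1) < 1e-9))

  # only the top fraction contributes
  m <- build_frequency_matrix(c(strrep("A", 21), strrep("C", 21)),
                              c(100, 1), top_fraction = 0.5)
  expect_equal(unname(m["A", 1]), 1)

  expect_error(build_frequency_matrix("ACGU", 1), "length >= 17")
  expect_error(build_frequency_matrix(strrep("A", 21), 1, top_fraction = 0),
               "top_fraction")
})

test_that("core sampling is reproducible, distinct and matrix-driven", {
  degenerate <- matrix(0, 4, 13, dimnames = list(c("A", "C", "G", "U"), NULL))
  degenerate["G", ] <- 1
  expect_equal(sample_cores(degenerate, 1, seed = 3), strrep("G", 13))
  expect_error(sample_cores(degenerate, 2, seed = 3), "degenerate")

  uni <- matrix(0.25, 4, 13, dimnames = list(c("A", "C", "G", "U"), NULL))
  cores <- sample_cores(uni, 1000, seed = 9)
  expect_length(cores, 1000L)
  expect_false(anyDuplicated(cores) > 0)
  expect_true(all(nchar(cores) == 13L))
  expect_identical(cores, sample_cores(uni, 1000, seed = 9))

  # empirical frequency of a 0.9-weighted base within 3 binomial SEs
  skewed <- uni
  skewed[, 7] <- c(0.9, 0.05, 0.03, 0.02)
  n <- 10000L
  cores <- sample_cores(skewed, n, seed = 11)
  p_hat <- mean(substr(cores, 7, 7) == "A")
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("genome filtering removes cores matching either strand", {
  cores <- c("ACGGAUCCGUUAG", "UUGCCAGAUCGAC", "GGAUUCGAACCGU")
  expect_equal(as.character(filter_genome_matching(cores, character())), cores)

  # forward occurrence of core 1, reverse-complement occurrence of core 2
  g <- toy_genome(3000, seed = 2, avoid = cores)
  gseq <- g[["chr1"]]
  substr(gseq, 100, 112) <- chartr("U", "T", cores[1])
  substr(gseq, 500, 512) <- revcomp(cores[2])
  g2 <- c(chr1 = gseq)
  kept <- filter_genome_matching(cores, g2)
  expect_equal(as.character(kept), cores[3])
  expect_true(attr(kept, "genome_clean"))
})

test_that("genome filtering agrees with a brute-force both-strand scan", {
  set.seed(4)
  g <- toy_genome(50000, seed = 4)
  uni <- matrix(0.25, 4, 13, dimnames = list(c("A", "C", "G", "U"), NULL))
  cores <- sample_cores(uni, 60, seed = 5)
  # plant a few cores so the scan has positives
  gseq <- g[["chr1"]]
  substr(gseq, 1000, 1012) <- chartr("U", "T", cores[5])
  substr(gseq, 2000, 2012) <- revcomp(cores[10])
  g <- c(chr1 = gseq)
  kept <- filter_genome_matching(cores, g)
  oracle <- cores[vapply(cores, function(cc)
    nrow(naive_scan(chartr("U", "T", cc), g)) == 0L, TRUE)]
  expect_setequal(as.character(kept), oracle)
  expect_false(cores[5] %in% kept)
  expect_false(cores[10] %in% kept)
})

test_that("flank expansion enumerates every 5'/3' combination", {
  core <- "ACGGAUCCGUUAG"
  m1 <- expand_set(core, flank_len = 1)
  expect_length(m1, 16L)
  expect_false(anyDuplicated(m1) > 0)
  expect_true(all(nchar(m1) == 15L))
  expect_true(all(substr(m1, 2, 14) == core))
  for (fl in 2:3)
    expect_length(expand_set(core, fl), 4^(2 * fl))
})

test_that("set selection ranks by KS distance with a lexicographic tie-break", {
  set.seed(8)
  reference <- rnorm(300, mean = -5)
  cands <- list(
    list(core = "CCCCCCCCCCCCC", mfe = rnorm(300, mean = -9)),
    list(core = "AAAAAAAAAAAAA", mfe = reference),       # identical to reference
    list(core = "GGGGGGGGGGGGG", mfe = rnorm(300, mean = -5.4)))
  sel <- select_sets(cands, reference, k = 2)
  rep <- attr(sel, "report")
  expect_equal(rep$core[1], "AAAAAAAAAAAAA")
  expect_equal(rep$ks_d[1], 0)
  expect_equal(sel[[1]]$core, "AAAAAAAAAAAAA")

  # permutation invariance of the ranking
  sel2 <- select_sets(cands[c(3, 1, 2)], reference, k = 2)
  expect_equal(vapply(sel2, `[[`, "", "core"), vapply(sel, `[[`, "", "core"))

  expect_equal(length(select_sets(cands, reference, k = 3)), 3L)
  expect_error(select_sets(cands, reference, k = 4), "exceeds")
})

test_that("mix formulation spans the dynamic range log-equispaced", {
  one <- formulate_mix("ACGGAUCCGUUAG", 3, 5e7)
  expect_equal(one$molecules_per_ug, 5e7)

  mix <- toy_sheet(8, max_amount = 1e8, range_log10 = 3.5)
  steps <- diff(log10(mix$molecules_per_ug))
  expect_equal(steps, rep(-0.5, 7))
  expect_true(all(mix$molecules_per_ug > 0))
  expect_true(all(diff(mix$molecules_per_ug) < 0))
  expect_error(formulate_mix("ACGGAUCCGUUAG", 3, -1), "must be > 0")
})

test_that("the full design run yields a valid, distinct, genome-clean mix", {
  set.seed(21)
  mirnas <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = ""), "")
  abund <- 10^runif(30, 0, 3)
  genome <- toy_genome(20000, seed = 21)
  cfg <- design_config(n_candidates = 60, n_select = 4, seed = 2,
                       mfe_sample_per_set = 50)
  d <- design_spikeins(mirnas, abund, genome, cfg)
  expect_equal(nrow(d$sheet), 4L)
  clean <- filter_genome_matching(d$cores, genome)
  expect_length(as.character(clean), 4L)
  dists <- utils::combn(d$cores, 2, function(p)
    sum(strsplit(p[1], "")[[1]] != strsplit(p[2], "")[[1]]))
  expect_true(all(dists >= 4))
  expect_equal(attr(compute_mfe("ACGU"), "backend"), "internal_nussinov")
})
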