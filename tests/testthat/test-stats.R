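test_that("pooled t-test matches the closed form and edge cases", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand computation: means 2 and 5, pooled var 1, se = sqrt(2/3)
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  # zero variance, different means
  r <- two_sample_t(c(1, 1), c(2, 2))
  expect_equal(r$p_value, 0)
})

test_that("t statistic and p agree with the reference implementation", {
  set.seed(41)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    mine <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("KS statistic equals exhaustive ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 1), c(10, 11))$statistic, 1)

  # brute-force over a fine grid of evaluation points
  set.seed(42)
  for (i in 1:20) {
    x <- round(rnorm(sample(2:8, 1)), 1)
    y <- round(rnorm(sample(2:8, 1)), 1)
    grid <- seq(min(c(x, y)) - 1, max(c(x, y)) + 1, by = 0.01)
    d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
    expect_equal(ks_two_sample(x, y)$statistic, d_oracle, tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "empty sample")
})

test_that("KS test agrees with the reference asymptotic implementation", {
  set.seed(43)
  for (i in 1:100) {
    x <- rnorm(sample(10:40, 1))
    y <- rnorm(sample(10:40, 1), mean = runif(1, 0, 1.5))
    mine <- ks_two_sample(x, y)
    ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    # stats:::C_pKS2 truncates its series at ~1e-5 absolute accuracy for
    # lambda near 1; both implementations target the same asymptotic law
    expect_lt(abs(mine$p_value - ref$p.value), 5e-5)
  }
})

test_that("differential calls require both fold change and significance", {
  a <- matrix(c(10, 11, 9, 10), 2, 2, dimnames = list(c("f1", "f2"), NULL))
  expect_true(all(call_differential(a, a)$call == "ns"))

  # 4-fold with tiny variance -> called up in B
  a <- matrix(c(10, 10.1, 10, 9.9), 2, 2, dimnames = list(c("f1", "f2"), NULL))
  b <- a; b["f1", ] <- c(40, 40.4)
  res <- call_differential(a, b)
  expect_equal(res$call[res$family_id == "f1"], "up")
  expect_equal(res$call[res$family_id == "f2"], "ns")

  # same fold with huge variance -> ns
  b_noisy <- a; b_noisy["f1", ] <- c(2, 78)
  res <- call_differential(a, b_noisy)
  expect_equal(res$call[res$family_id == "f1"], "ns")

  # exchanging the groups swaps up and down
  res_fwd <- call_differential(a, b)
  res_rev <- call_differential(b, a)
  expect_equal(res_rev$call[res_fwd$call == "up"], "down")

  # families absent from one group are ns with a warning
  b_missing <- b[1, , drop = FALSE]
  expect_warning(res <- call_differential(a, b_missing), "missing")
  expect_equal(res$call[res$family_id == "f2"], "ns")
})

test_that("expression filter is inclusive at the threshold in every replicate", {
  m1 <- matrix(c(1.0, 1.0, 0.5, 2.0, 3, 4), 3, 2, byrow = TRUE,
               dimnames = list(c("fA", "fB", "fC"), NULL))
  m2 <- matrix(c(5, 1.0, 2, 2, 3, 4), 3, 2, byrow = TRUE,
               dimnames = list(c("fA", "fB", "fC"), NULL))
  kept <- filter_expressed(m1, m2, min_rpm = 1)
  expect_setequal(kept, c("fA", "fC"))
  # brute-force row scan oracle
  oracle <- rownames(m1)[apply(cbind(m1, m2) >= 1, 1, all)]
  expect_setequal(kept, oracle)
})

test_that("stoichiometry ratios, medians and drop accounting behave", {
  mat <- data.frame(feature_id = c("mA", "mB", "mC", "mD"),
                    mpu = c(100, 200, 900, 50))
  par <- data.frame(feature_id = c("pA", "pB", "pC", "pD"),
                    absolute_mpu = c(100, 100, 100, NA))
  pairs <- data.frame(mature_id = c("mA", "mB", "mC", "mD"),
                      partner_id = c("pA", "pB", "pC", "pD"))
  st <- stoichiometry(mat, par, pairs)
  expect_equal(st$ratios$ratio, c(1, 2, 9))
  expect_equal(st$median_ratio, 2)
  expect_equal(st$n_dropped, 1L)
  # scale consistency: multiplying all MPUs by c leaves ratios unchanged
  mat2 <- mat; mat2$mpu <- mat2$mpu * 7.3
  par2 <- par; par2$absolute_mpu <- par2$absolute_mpu * 7.3
  st2 <- stoichiometry(mat2, par2, pairs)
  expect_equal(st2$ratios$ratio, st$ratios$ratio, tolerance = 1e-12)
})
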