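test_that("folded_maf folds counts onto [0, 0.5] and rejects bad input", {
  expect_equal(folded_maf(70, 100), 0.30)
  expect_equal(folded_maf(50, 100), 0.50)
  expect_equal(folded_maf(0, 100), 0)
  expect_equal(folded_maf(c(10, 95), 100), c(0.10, 0.05))
  expect_error(folded_maf(1, 0), class = "ncd_undefined_input")
  expect_error(folded_maf(101, 100), class = "ncd_undefined_input")
})

test_that("ncd matches its closed form and the loop oracle", {
  expect_equal(ncd(c(0.4, 0.4, 0.4), 0.4), 0)
  expect_equal(ncd(c(0, 0, 0), 0.5), 0.5)
  expect_equal(ncd(c(0.5, 0.25, 0.0), 0.5), sqrt((0 + 0.0625 + 0.25) / 3))
  expect_equal(ncd(c(0.5, 0.25, 0.0), 0.5), ncd_loop_oracle(c(0.5, 0.25, 0.0), 0.5),
               tolerance = 1e-12)
  expect_error(ncd(numeric(), 0.5), class = "ncd_insufficient_data")
  expect_error(ncd(c(0.2), 0.6), class = "ncd_config_error")
  expect_error(ncd(c(0.2), 0), class = "ncd_config_error")
  expect_error(ncd(c(0.7), 0.5), class = "ncd_undefined_input")
})

test_that("ncd equals the loop oracle on 1000 random windows", {
  set.seed(11)
  for (i in 1:1000) {
    m <- runif(sample(1:40, 1), 0, 0.5)
    tf <- sample(c(0.3, 0.4, 0.5), 1)
    expect_equal(ncd(m, tf), ncd_loop_oracle(m, tf), tolerance = 1e-12)
  }
})

test_that("ncd respects its range bound and zero condition", {
  set.seed(12)
  for (i in 1:300) {
    m <- runif(sample(1:30, 1), 0, 0.5)
    tf <- runif(1, 0.05, 0.5)
    v <- ncd(m, tf)
    expect_gte(v, 0)
    expect_lte(v, max(tf, 0.5 - tf) + 1e-12)
    if (v == 0) expect_true(all(m == tf))
  }
  # permutation invariance
  m <- c(0.1, 0.3, 0.5, 0.02)
  expect_identical(ncd(m, 0.4), ncd(rev(m), 0.4))
  expect_identical(ncd(m, 0.4), ncd(m[c(3, 1, 4, 2)], 0.4))
})

test_that("ncd1 uses SNPs only; ncd2 adds FDs at frequency zero", {
  w <- window_sites(data.frame(
    pos = 1:7, kind = c("SNP", "SNP", rep("FD", 5)),
    maf = c(0.4, 0.4, rep(0, 5))))
  r1 <- ncd1(w, 0.4)
  expect_equal(r1$value, 0)
  expect_equal(r1$is_used, 2L)
  expect_equal(ncd1(window_sites(data.frame(pos = 1, kind = "SNP", maf = 0.1)),
                    0.5)$value, 0.4)
  w3 <- window_sites(data.frame(pos = 1:3, kind = "SNP", maf = c(0.5, 0.1, 0.3)))
  expect_equal(ncd1(w3, 0.3)$value, sqrt((0.04 + 0.04 + 0) / 3))

  # all-divergence limit: NCD2 = tf
  wfd <- window_sites(data.frame(pos = 1:10, kind = "FD", maf = 0))
  expect_equal(ncd2(wfd, 0.5)$value, 0.5)
  expect_error(ncd1(wfd, 0.5), class = "ncd_insufficient_data")
  w2 <- window_sites(data.frame(pos = 1:3, kind = c("SNP", "SNP", "FD"),
                                maf = c(0.5, 0.25, 0)))
  expect_equal(ncd2(w2, 0.5)$value, sqrt((0 + 0.0625 + 0.25) / 3))
  expect_equal(ncd2(w2, 0.5)$is_used, 3L)

  # appending one FD to a window sitting exactly at tf raises NCD2
  wa <- window_sites(data.frame(pos = 1, kind = "SNP", maf = 0.5))
  expect_equal(ncd2(wa, 0.5)$value, 0)
  wb <- window_sites(data.frame(pos = 1:2, kind = c("SNP", "FD"), maf = c(0.5, 0)))
  expect_equal(ncd2(wb, 0.5)$value, sqrt(0.125))
  expect_error(ncd2(window_sites(data.frame(pos = integer(), kind = character(),
                                            maf = numeric())), 0.5),
               class = "ncd_insufficient_data")
})

test_that("appending an FD strictly increases NCD2 when below tf", {
  set.seed(13)
  for (i in 1:100) {
    w <- random_window(sample(1:15, 1), sample(0:10, 1))
    tf <- sample(c(0.3, 0.4, 0.5), 1)
    v0 <- ncd2(w, tf)$value
    if (v0 >= tf) next
    s2 <- rbind(w$sites,
                data.frame(pos = max(w$sites$pos) + 1L, kind = "FD",
                           minor_count = 0L, total_called = w$sites$total_called[1],
                           maf = 0))
    v1 <- ncd2(window_sites(s2), tf)$value
    expect_gt(v1, v0)
  }
})

test_that("tajimas_d matches the textbook oracle and sign conventions", {
  # many singletons drive D negative
  expect_lt(tajimas_d(rep(1L, 40), 20), 0)
  # oracle equality on a small configuration
  expect_equal(tajimas_d(c(1L, 2L), 4), tajd_oracle(c(1L, 2L), 4),
               tolerance = 1e-12)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    counts <- sample.int(n - 1, sample(1:25, 1), replace = TRUE)
    expect_equal(tajimas_d(counts, n), tajd_oracle(counts, n), tolerance = 1e-12)
  }
  # S = 0: undefined marker, not an error
  expect_true(is.na(tajimas_d(integer(), 10)))
  expect_error(tajimas_d(c(1L), 1), class = "ncd_config_error")
})

test_that("tajimas_d is zero when pi equals S/a1", {
  # n = 4, a1 = 11/6: 8 singletons (pi 0.5 each) + 3 doubletons (2/3 each)
  # give pi = 6 = 11 / a1, so the numerator vanishes exactly
  expect_equal(tajimas_d(c(rep(1L, 8), rep(2L, 3)), 4), 0)
})

test_that("hka_chi2 matches a contingency-table oracle and flags direction", {
  # proportions equal to background: statistic 0
  r <- hka_chi2(list(n_snps = 10, n_fds = 10),
                list(total_snps = 100, total_fds = 100))
  expect_equal(r$statistic, 0)
  expect_equal(r$direction, "none")
  # pure polymorphism excess
  r <- hka_chi2(list(n_snps = 10, n_fds = 0),
                list(total_snps = 1000, total_fds = 1000))
  expect_equal(r$direction, "polymorphism_excess")
  expect_gt(r$signed, 0)
  # oracle equality on a toy table: window (8,2) vs remainder (92,98)
  r <- hka_chi2(list(n_snps = 8, n_fds = 2),
                list(total_snps = 100, total_fds = 100))
  expect_equal(r$statistic, chi2_oracle(8, 2, 92, 98), tolerance = 1e-12)
  expect_error(hka_chi2(list(n_snps = 1, n_fds = 1),
                        list(total_snps = 0, total_fds = 0)),
               class = "ncd_config_error")
  expect_error(hka_chi2(list(n_snps = 0, n_fds = 0),
                        list(total_snps = 10, total_fds = 10)),
               class = "ncd_insufficient_data")
})

test_that("window_sites enforces site invariants", {
  expect_error(window_sites(data.frame(pos = c(1, 1), kind = "SNP",
                                       maf = c(0.1, 0.2))),
               class = "ncd_undefined_input")
  expect_error(window_sites(data.frame(pos = 1, kind = "FD", maf = 0.1)),
               class = "ncd_undefined_input")
  expect_error(window_sites(data.frame(pos = 1, kind = "SNP", maf = 0)),
               class = "ncd_undefined_input")
  w <- window_sites(data.frame(pos = c(5, 2), kind = "SNP", maf = c(0.1, 0.2)))
  expect_equal(w$sites$pos, c(2, 5))  # sorted
  expect_equal(w$is_count, 2L)
})
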