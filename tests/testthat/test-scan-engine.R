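test_that("make_windows tiles contigs with the sliding design", {
  w <- make_windows(c(c1 = 6000L))
  expect_equal(w$start, c(0L, 1500L, 3000L))
  expect_equal(w$end, c(3000L, 4500L, 6000L))
  expect_equal(nrow(make_windows(c(c1 = 2999L))), 0)
  # counting oracle: floor((L - size) / step) + 1
  for (L in c(3000L, 4499L, 10000L, 33100L)) {
    expect_equal(nrow(make_windows(c(x = L))),
                 floor((L - 3000) / 1500) + 1)
  }
  w10 <- make_windows(c(x = 10000L))
  expect_equal(nrow(w10), 5)
  expect_equal(max(w10$start), 6000L)
})

test_that("filter_windows applies inclusive boundaries and keeps a ledger", {
  win <- data.frame(chrom = "c", start = 0L, end = 3000L,
                    n_snps = c(9L, 10L, 10L, 10L), n_fds = 0L,
                    is = c(9L, 10L, 10L, 10L),
                    orth_bp = c(600L, 499L, 500L, 600L))
  fl <- filter_windows(win)
  expect_equal(nrow(fl$kept), 2)
  expect_equal(fl$kept$orth_bp, c(500L, 600L))   # 500 bp is inclusive
  expect_equal(unname(fl$ledger["low_is"]), 1L)
  expect_equal(unname(fl$ledger["orthology"]), 1L)
})

test_that("build_null bins by IS and merges sparse bins outward", {
  set.seed(41)
  vals <- list(ncd2 = runif(300, 0.3, 0.5),
               is = sample(c(10L, 11L, 12L, 30L), 300, replace = TRUE))
  null <- build_null(vals, tf = 0.5, min_count = 120)
  expect_s3_class(null, "ncd_null")
  expect_equal(null$is_values, c(10L, 11L, 12L, 30L))
  expect_true(all(null$stats$n >= 120 | null$stats$radius >= 18))
  expect_equal(null$stats$min, vapply(null$values, min, 0))
  expect_true(all(null$stats$sd > 0))
  # round-trip through the TSV container
  p <- tempfile(fileext = ".tsv")
  write_null(null, p)
  null2 <- read_null(p, min_count = 120)
  expect_equal(null2$stats, null$stats)
  unlink(p)
})

test_that("call_significant requires strictly beating the null minimum", {
  null <- build_null(list(ncd2 = seq(0.2, 0.4, length.out = 100),
                          is = rep(15L, 100)), tf = 0.5, min_count = 10)
  expect_false(call_significant(0.2, null, 15L))    # equal to min: not below
  expect_true(call_significant(0.19999, null, 15L))
  # synthetic null of 10,000 uniform draws: observed below all is significant
  set.seed(42)
  u <- runif(10000, 0.3, 0.5)
  null10k <- build_null(list(ncd2 = u, is = rep(20L, 10000)), tf = 0.5,
                        min_count = 1000)
  expect_true(call_significant(min(u) - 1e-6, null10k, 20L))
  expect_false(call_significant(min(u), null10k, 20L))
  # direct count oracle: nothing in the bin lies below the observed value
  expect_equal(sum(u < min(u) - 1e-6), 0)
})

test_that("z_standardize matches the bin moments", {
  null <- build_null(list(ncd2 = c(0.3, 0.35, 0.4), is = rep(12L, 3)),
                     tf = 0.5, min_count = 2)
  m <- mean(c(0.3, 0.35, 0.4)); s <- sd(c(0.3, 0.35, 0.4))
  expect_equal(z_standardize(m, null, 12L), 0)
  expect_equal(z_standardize(0.2, null, 12L), (0.2 - m) / s)
  # explicit arithmetic example: (0.2 - 0.35) / 0.05 = -3
  expect_equal((0.2 - 0.35) / 0.05, -3)
  # loop oracle over random bins
  set.seed(43)
  for (i in 1:20) {
    v <- runif(50, 0, 0.5); is0 <- sample(10:20, 1)
    nl <- build_null(list(ncd2 = v, is = rep(is0, 50)), tf = 0.4, min_count = 5)
    x <- runif(1, 0, 0.5)
    expect_equal(z_standardize(x, nl, is0), (x - mean(v)) / sd(v),
                 tolerance = 1e-12)
  }
})

test_that("empirical_p ranks most negative z first with deterministic ties", {
  z <- c(-3, -1, -2, NA, 0)
  p <- empirical_p(z)
  expect_equal(p, c(1, 3, 2, NA, 4) / 4)
  expect_true(all(p >= 1 / 4, na.rm = TRUE))
  # ties broken by IS descending then coordinates
  z2 <- c(-1, -1, -1)
  p2 <- empirical_p(z2, is_count = c(5L, 9L, 9L),
                    chrom = c("1", "2", "1"), start = c(10L, 5L, 5L))
  expect_equal(p2, c(3, 2, 1) / 3)
  # monotone nondecreasing in z
  set.seed(44)
  z3 <- rnorm(200)
  p3 <- empirical_p(z3)
  expect_true(all(diff(p3[order(z3)]) >= 0))
})

test_that("call_outliers takes the ceiling of the cutoff tail", {
  p <- empirical_p(seq(-5, 5, length.out = 2000))
  expect_equal(sum(call_outliers(p, cutoff = 0.0005)), 1)
  expect_equal(sum(call_outliers(p, cutoff = 0.01)), 20)
  # cutoff * N fractional: 0.0005 * 1500 = 0.75 -> 1 window
  p2 <- empirical_p(rnorm(1500))
  expect_equal(sum(call_outliers(p2, cutoff = 0.0005)), 1)
})

test_that("assign_tf minimizes empirical P with documented tie-breaks", {
  p <- rbind(c(1e-6, 1e-4, 1e-3))
  z <- rbind(c(-5, -4, -3))
  expect_equal(assign_tf(p, z, c(0.3, 0.4, 0.5)), 0.3)
  # all p equal: most negative z wins
  expect_equal(assign_tf(rbind(c(1e-3, 1e-3, 1e-3)),
                         rbind(c(-1, -4, -2)), c(0.3, 0.4, 0.5)), 0.4)
  # p and z equal: smallest tf
  expect_equal(assign_tf(rbind(c(1e-3, 1e-3, 1e-3)),
                         rbind(c(-1, -1, -1)), c(0.3, 0.4, 0.5)), 0.3)
  # argmin oracle on random rows
  set.seed(45)
  for (i in 1:50) {
    p <- matrix(runif(3), 1); z <- matrix(rnorm(3), 1)
    expect_equal(assign_tf(p, z, c(0.3, 0.4, 0.5)),
                 c(0.3, 0.4, 0.5)[which.min(p)])
  }
})

test_that("merge_candidates unions overlapping and book-ended windows", {
  w <- data.frame(chrom = "c1", start = c(0L, 1500L), end = c(3000L, 4500L))
  m <- merge_candidates(w)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 4500L)
  # disjoint windows stay disjoint; book-ended merge
  w2 <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                   start = c(0L, 3000L, 9000L, 0L),
                   end = c(3000L, 6000L, 12000L, 3000L))
  m2 <- merge_candidates(w2)
  expect_equal(nrow(m2), 3)
  expect_equal(m2$end[m2$chrom == "c1"], c(6000L, 12000L))
  # interval-union oracle: per-bp membership on random sets
  set.seed(46)
  for (i in 1:10) {
    k <- sample(2:10, 1)
    st <- sample(0:50, k, replace = TRUE)
    w3 <- data.frame(chrom = "x", start = st, end = st + sample(1:10, k, TRUE))
    m3 <- merge_candidates(w3)
    cover <- rep(FALSE, 100)
    for (j in seq_len(k)) cover[(w3$start[j] + 1):w3$end[j]] <- TRUE
    mcover <- rep(FALSE, 100)
    for (j in seq_len(nrow(m3))) mcover[(m3$start[j] + 1):m3$end[j]] <- TRUE
    expect_equal(mcover, cover)
    expect_true(all(m3$start[-1] > m3$end[-nrow(m3)]))  # disjoint, non-adjacent
  }
})

test_that("resampling_enrichment is seed-stable and near 1 for absent categories", {
  set.seed(47)
  bg <- data.frame(chrom = "c", start = seq(0L, 49500L, 1500L),
                   end = seq(0L, 49500L, 1500L) + 3000L)
  sites <- data.frame(chrom = "c", pos = sample(0:52499, 400),
                      kind = "SNP", maf = 0.1)
  cat_flag <- runif(400) < 0.3
  cand <- bg[1:5, ]
  r1 <- resampling_enrichment(cand, bg, sites, cat_flag, n_resamples = 200, seed = 7)
  r2 <- resampling_enrichment(cand, bg, sites, cat_flag, n_resamples = 200, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p >= 1 / 201 && r1$p <= 1)
  # category absent from candidates: p ~ 1
  idx <- unique(unlist(window_site_index(merge_candidates(cand), sites)))
  flag0 <- cat_flag; flag0[idx] <- FALSE
  r0 <- resampling_enrichment(cand, bg, sites, flag0, n_resamples = 100, seed = 8)
  expect_gt(r0$p, 0.5)
})

test_that("run_scan produces a rectangular per-tf table on synthetic data", {
  set.seed(48)
  model <- demographic_model("constant", N0 = 5000)
  nreps <- simulate_neutral(model, n = 20, L = 3000, n_reps = 150, seed = 61)
  nulls <- list("0.5" = build_null(nreps, tf = 0.5, min_count = 60),
                "0.4" = build_null(nreps, tf = 0.4, min_count = 60))
  # build a toy genome by concatenating further neutral replicates
  reps <- simulate_neutral(model, n = 20, L = 3000, n_reps = 40, seed = 62)
  sites <- do.call(rbind, lapply(seq_along(reps), function(i) {
    s <- replicate_sites(reps[[i]])$sites
    s$pos <- s$pos + (i - 1L) * 3000L
    s$chrom <- "g1"
    s
  }))
  res <- run_scan(sites, c(g1 = 40L * 3000L), nulls, tf_values = c(0.4, 0.5),
                  min_is = 10, min_orthologous_bp = 0)
  sc <- res$scan
  expect_true(all(c("ncd2_0.4", "z_0.4", "emp_p_0.4", "significant_0.4",
                    "outlier_0.4", "ncd2_0.5", "assigned_tf") %in% names(sc)))
  expect_true(all(sc$is >= 10))
  expect_true(all(sc$assigned_tf %in% c(0.4, 0.5)))
  # significant and testable implies z < 0
  sig <- which(sc$significant_0.5 %in% TRUE)
  expect_true(all(sc$z_0.5[sig] < 0))
  # emp_p bounded below by 1/N
  N <- sum(!is.na(sc$emp_p_0.5))
  expect_true(all(sc$emp_p_0.5 >= 1 / N, na.rm = TRUE))
})
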