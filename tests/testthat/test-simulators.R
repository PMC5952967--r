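test_that("demographic models validate their epochs", {
  m <- demographic_model("african")
  expect_equal(m$epochs$N, c(14474, 7310))
  expect_equal(m$epochs$t_start, c(0, 5920))
  e <- demographic_model("european")$epochs
  expect_true(all(diff(e$t_start) > 0))
  expect_error(demographic_model_from_epochs(
    data.frame(t_start = c(5, 0), N = c(1, 2))), class = "ncd_config_error")
  expect_error(demographic_model_from_epochs(
    data.frame(t_start = c(0, 5), N = c(100, -1))), class = "ncd_config_error")
})

test_that("neutral simulator is seed-deterministic", {
  m <- demographic_model("constant", N0 = 2000)
  a <- simulate_neutral(m, n = 8, L = 1000, n_reps = 3, seed = 99)
  b <- simulate_neutral(m, n = 8, L = 1000, n_reps = 3, seed = 99)
  expect_identical(a, b)
  c_ <- simulate_neutral(m, n = 8, L = 1000, n_reps = 3, seed = 100)
  expect_false(identical(a, c_))
})

test_that("neutral segregating sites match Watterson's expectation", {
  # constant N, no outgroup: E[S] = 4 N mu L * a_{n-1}
  N0 <- 5000; n <- 10; L <- 2000; mu <- 2.5e-8; nrep <- 400
  m <- demographic_model("constant", N0 = N0)
  reps <- simulate_neutral(m, n = n, L = L, mu = mu, rho = 1e-8,
                           outgroup_split_ma = NA, n_reps = nrep, seed = 71)
  S <- vapply(reps, function(r) length(r$positions), 0L)
  expS <- 4 * N0 * mu * L * sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(nrep)
  expect_lt(abs(mean(S) - expS), 3 * se + 1e-9)
})

test_that("fixed differences follow the molecular clock with ancestral correction", {
  # n = 2: E[FD branch] = 2 T_split + 2 * 2N_anc - E[T_mrca], E[T_mrca] = 2N*2/2...
  # two sampled lineages coalesce at mean 2N; outgroup + sample stems each add
  # T_split plus one ancestral coalescence of mean 2N.
  N0 <- 5000; n <- 2; L <- 500; mu <- 2.5e-8; nrep <- 400
  m <- demographic_model("constant", N0 = N0)
  split_gen <- 6.5e6 / 25
  reps <- simulate_neutral(m, n = n, L = L, mu = mu, rho = 0,
                           outgroup_split_ma = 6.5, n_reps = nrep, seed = 72)
  fd <- vapply(reps, function(r) replicate_sites(r)$n_fds, 0L)
  exp_branch <- 2 * split_gen + 2 * (2 * N0) - 2 * N0
  expFD <- mu * L * exp_branch
  se <- sd(fd) / sqrt(nrep)
  expect_lt(abs(mean(fd) - expFD), 3 * se + 1e-9)
})

test_that("overdominance trajectories hit the deterministic fixed point", {
  # fixed-point oracle: iterate the infinite-population recursion
  det_feq <- function(s_AA, s_aa) {
    x <- 0.5
    for (i in 1:5000) x <- ncdscan:::wf_expected_freq(x, s_AA, s_aa)
    x
  }
  expect_equal(det_feq(0.06, 0.04), 0.04 / 0.10, tolerance = 1e-8)
  expect_equal(det_feq(0.05, 0.05), 0.5, tolerance = 1e-8)
  # stochastic mean matches s_aa / (s_AA + s_aa) within 3 SE
  set.seed(73)
  xf <- wf_trajectory(N = 1000, s_AA = 0.07, s_aa = 0.03, x0 = 0.3,
                      n_gen = 2000, n_reps = 300)
  keep <- xf > 0 & xf < 1
  se <- sd(xf[keep]) / sqrt(sum(keep))
  expect_lt(abs(mean(xf[keep]) - 0.3), 3 * se)
})

test_that("neutral reduction of the forward simulator is a martingale", {
  set.seed(74)
  xf <- wf_trajectory(N = 500, s_AA = 0, s_aa = 0, x0 = 0.35,
                      n_gen = 50, n_reps = 2000)
  se <- sd(xf) / sqrt(length(xf))
  expect_lt(abs(mean(xf) - 0.35), 3 * se)
})

test_that("balancing simulator is seed-deterministic and reduces to neutral", {
  m <- demographic_model("constant", N0 = 3000)
  sel <- selection_model(f_eq = 0.5, s_total = 0.02, tbs_ma = 0.5)
  a <- simulate_balancing(m, sel, n = 10, L = 1000, n_reps = 2, seed = 75,
                          scaling = 20)
  b <- simulate_balancing(m, sel, n = 10, L = 1000, n_reps = 2, seed = 75,
                          scaling = 20)
  expect_identical(a, b)
  expect_true(attr(a, "n_redraws") >= 0)
  # zero selection returns plain neutral replicates
  s0 <- selection_model(s_AA = 0, s_aa = 0)
  n0 <- simulate_balancing(m, s0, n = 6, L = 500, n_reps = 2, seed = 76)
  n1 <- simulate_neutral(m, n = 6, L = 500, n_reps = 2, seed = 76)
  expect_identical(n0[[1]]$haplotypes, n1[[1]]$haplotypes)
})

test_that("selection model rejects unreachable equilibria", {
  expect_error(selection_model(s_AA = 0.01, s_aa = 0), class = "ncd_config_error")
  expect_error(selection_model(f_eq = 1.2), class = "ncd_config_error")
})

test_that("balancing replicates show the balancing-selection signature", {
  # relative to neutral: more SNPs per FD and folded-spectrum mass near f_eq
  m <- demographic_model("african")
  nrep <- 25
  neu <- simulate_neutral(m, n = 50, L = 3000, n_reps = nrep, seed = 77)
  sel <- simulate_balancing(m, selection_model(f_eq = 0.5, tbs_ma = 5),
                            n = 50, L = 3000, n_reps = nrep, seed = 78,
                            scaling = 20)
  ratio <- function(reps) {
    vapply(reps, function(r) {
      w <- replicate_sites(r)
      w$n_snps / (w$n_fds + 1)
    }, 0)
  }
  expect_gt(mean(ratio(sel)), mean(ratio(neu)))
  mass_near <- function(reps, tf) {
    vapply(reps, function(r) {
      m0 <- replicate_sites(r)$sites$maf
      mean(abs(m0 - tf) < 0.15)
    }, 0)
  }
  expect_gt(mean(mass_near(sel, 0.5)), mean(mass_near(neu, 0.5)))
  # NCD2 at the balanced frequency is depressed
  expect_lt(mean(vapply(sel, replicate_ncd2, 0, tf = 0.5)),
            mean(vapply(neu, replicate_ncd2, 0, tf = 0.5)))
})
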