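# Shared helpers: small in-code fixtures and independent oracles.

# naive per-site loop implementation of NCD, kept independent of ncd()
ncd_loop_oracle <- function(mafs, tf) {
  acc <- 0
  for (p in mafs) acc <- acc + (p - tf)^2
  sqrt(acc / length(mafs))
}

# textbook-constant Tajima's D oracle, written from scratch with loops
tajd_oracle <- function(counts, n) {
  S <- length(counts)
  pi_hat <- 0
  for (c in counts) pi_hat <- pi_hat + 2 * c * (n - c)
  pi_hat <- pi_hat / (n * (n - 1))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force 2x2 chi-square (expected counts from margins)
chi2_oracle <- function(a, b, c, d) {
  tot <- a + b + c + d
  obs <- c(a, b, c, d)
  rs <- c(a + b, a + b, c + d, c + d)
  cs <- c(a + c, b + d, a + c, b + d)
  e <- rs * cs / tot
  sum((obs - e)^2 / e)
}

# random window_sites with n_snp SNPs and n_fd FDs
random_window <- function(n_snp, n_fd, n_chr = 100) {
  minor <- if (n_snp > 0) sample.int(n_chr %/% 2, n_snp, replace = TRUE) else integer()
  pos <- sample.int(10000, n_snp + n_fd)
  window_sites(data.frame(
    pos = pos,
    kind = c(rep("SNP", n_snp), rep("FD", n_fd)),
    minor_count = c(minor, rep(0L, n_fd)),
    total_called = n_chr,
    maf = c(minor / n_chr, rep(0, n_fd))
  ))
}

# random replicate set for round-trip tests
random_replicates <- function(k, n = 6, L = 500) {
  lapply(seq_len(k), function(i) {
    S <- sample(0:12, 1)
    if (S == 0) return(sim_replicate(matrix(0L, n, 0), integer(), integer(), L))
    pos <- sort(sample(0:(L - 1), S))
    hap <- matrix(rbinom(n * S, 1, 0.3), n, S)
    sim_replicate(hap, pos, rbinom(S, 1, 0.2), L)
  })
}
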