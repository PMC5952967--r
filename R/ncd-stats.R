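#' Fold an allele count onto the minor-allele frequency scale
#'
#' Balancing selection is expected to hold alleles near an equilibrium
#' frequency, but with no prior on whether the ancestral or derived allele is
#' the balanced one the natural scale is the folded site frequency spectrum:
#' the minor allele frequency (MAF), which lives in \code{[0, 0.5]}.
#'
#' @param allele_count Count of one allele (either allele; the fold makes the
#'   choice irrelevant). Vectorized.
#' @param total_called Number of called chromosomes at the site (> 0).
#' @return Minor allele frequency, \code{min(c, N - c) / N}, in
#'   \code{[0, 0.5]}.
#' @examples
#' folded_maf(70, 100)  # 0.30
#' folded_maf(50, 100)  # 0.50
#' @export
folded_maf <- function(allele_count, total_called) {
  if (any(total_called <= 0)) {
    stop_undefined_input("folded_maf: total_called must be > 0")
  }
  if (any(allele_count < 0 | allele_count > total_called)) {
    stop_undefined_input("folded_maf: allele_count must be in [0, total_called]")
  }
  pmin(allele_count, total_called - allele_count) / total_called
}

#' The Non-Central Deviation (NCD) statistic
#'
#' Quantifies how far a set of folded allele frequencies lies from a target
#' frequency \code{tf}, the frequency hypothesized for a balanced
#' polymorphism:
#' \deqn{NCD(tf) = \sqrt{\sum_i (p_i - tf)^2 / n}}
#' where \eqn{p_i} is the minor allele frequency of the i-th informative site
#' and \eqn{n} the number of informative sites.  It is a standard-deviation
#' style dispersion measure taken around \code{tf} rather than around the
#' sample mean; low values support balancing selection.  Note the square
#' root: NCD is on the frequency scale, bounded by
#' \code{max(tf, 0.5 - tf)}.
#'
#' @param mafs Numeric vector of folded minor allele frequencies in
#'   \code{[0, 0.5]}; fixed differences enter as 0 (see [ncd2()]).
#' @param tf Target frequency in \code{(0, 0.5]}.  Values outside the folded
#'   range are rejected, not folded.
#' @return Nonnegative scalar in \code{[0, max(tf, 0.5 - tf)]}.
#' @examples
#' ncd(c(0.5, 0.25, 0), tf = 0.5)
#' @export
ncd <- function(mafs, tf) {
  check_tf(tf)
  if (length(mafs) == 0L) {
    stop_insufficient_data("ncd: no informative sites")
  }
  if (any(is.na(mafs)) || any(mafs < 0 | mafs > 0.5)) {
    stop_undefined_input("ncd: mafs must be in [0, 0.5]")
  }
  sqrt(sum((mafs - tf)^2) / length(mafs))
}

check_tf <- function(tf) {
  if (length(tf) != 1L || is.na(tf) || tf <= 0 || tf > 0.5) {
    stop_config("tf must be a single value in (0, 0.5], got %s",
                paste(format(tf), collapse = ","))
  }
  invisible(tf)
}

#' Bundle the informative sites of one genomic window
#'
#' Informative sites (IS) are biallelic SNPs plus fixed differences (FD)
#' relative to an outgroup.  The bundle validates site invariants (FDs carry
#' MAF 0; SNPs carry 0 < MAF <= 0.5; positions sorted and unique) and caches
#' the SNP/FD/IS counts used by the scan filters.
#'
#' @param sites A data.frame with columns \code{pos}, \code{kind}
#'   ("SNP"/"FD") and \code{maf}; optionally \code{chrom},
#'   \code{minor_count}, \code{total_called}.
#' @return An object of class \code{window_sites} with elements
#'   \code{sites}, \code{n_snps}, \code{n_fds}, \code{is_count}.
#' @export
window_sites <- function(sites) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("pos", "kind", "maf") %in% names(sites)))
  if (nrow(sites) > 0) {
    if (!all(sites$kind %in% c("SNP", "FD"))) {
      stop_undefined_input("window_sites: kind must be 'SNP' or 'FD'")
    }
    if (anyDuplicated(sites$pos)) {
      stop_undefined_input("window_sites: duplicate positions")
    }
    sites <- sites[order(sites$pos), , drop = FALSE]
    fd <- sites$kind == "FD"
    if (any(sites$maf[fd] != 0)) {
      stop_undefined_input("window_sites: FD sites must have maf 0")
    }
    if (any(sites$maf[!fd] <= 0 | sites$maf[!fd] > 0.5)) {
      stop_undefined_input("window_sites: SNP maf must be in (0, 0.5]")
    }
  }
  structure(list(
    sites    = sites,
    n_snps   = sum(sites$kind == "SNP"),
    n_fds    = sum(sites$kind == "FD"),
    is_count = nrow(sites)
  ), class = "window_sites")
}

#' @export
print.window_sites <- function(x, ...) {
  cat(sprintf("<window_sites> %d IS (%d SNPs + %d FDs)\n",
              x$is_count, x$n_snps, x$n_fds))
  invisible(x)
}

as_window_sites <- function(window) {
  if (inherits(window, "window_sites")) window else window_sites(window)
}

#' NCD1: Non-Central Deviation over polymorphic sites only
#'
#' The outgroup-free variant: only SNP minor allele frequencies enter the
#' statistic.  Use when no outgroup is available; [ncd2()] has higher power
#' when fixed differences can be called.
#'
#' @param window A \code{window_sites} object (or a site data.frame).
#' @param tf Target frequency in \code{(0, 0.5]}.
#' @return List of class \code{ncd_result}: \code{tf}, \code{value},
#'   \code{is_used}, \code{statistic = "NCD1"}.
#' @export
ncd1 <- function(window, tf) {
  window <- as_window_sites(window)
  if (window$n_snps < 1L) {
    stop_insufficient_data("ncd1: window has no SNPs (%d FDs present)",
                           window$n_fds)
  }
  mafs <- window$sites$maf[window$sites$kind == "SNP"]
  ncd_result(tf, ncd(mafs, tf), length(mafs), "NCD1")
}

#' NCD2: Non-Central Deviation over SNPs and fixed differences
#'
#' Fixed differences to the outgroup are informative about the time scale of
#' the genealogy: under long-term balancing selection linked divergence is
#' depleted relative to polymorphism.  NCD2 therefore counts each FD as an
#' informative site with minor allele frequency 0, so the greater the number
#' of FDs, the larger the NCD2 and the weaker the support for balancing
#' selection.
#'
#' @inheritParams ncd1
#' @return List of class \code{ncd_result}: \code{tf}, \code{value},
#'   \code{is_used}, \code{statistic = "NCD2"}.
#' @export
ncd2 <- function(window, tf) {
  window <- as_window_sites(window)
  if (window$is_count < 1L) {
    stop_insufficient_data("ncd2: window has no informative sites")
  }
  ncd_result(tf, ncd(window$sites$maf, tf), window$is_count, "NCD2")
}

ncd_result <- function(tf, value, is_used, statistic) {
  structure(list(tf = tf, value = value, is_used = is_used,
                 statistic = statistic),
            class = "ncd_result")
}

#' @export
print.ncd_result <- function(x, ...) {
  cat(sprintf("%s(tf = %g) = %.5f  [%d informative sites]\n",
              x$statistic, x$tf, x$value, x$is_used))
  invisible(x)
}

#' Tajima's D from per-site allele counts
#'
#' Comparator neutrality test.  D contrasts mean pairwise diversity (pi)
#' with Watterson's estimator S/a1; an excess of intermediate-frequency
#' alleles (the balancing-selection signature) drives D positive.
#'
#' @param counts Integer vector of allele counts, one per segregating site.
#'   Either derived or minor counts work since pi is fold-invariant; counts
#'   must be in \code{[1, sample_size - 1]}.
#' @param sample_size Number of sampled chromosomes (>= 2).
#' @return Scalar D, or \code{NA_real_} when there are no segregating sites
#'   (the statistic is undefined; window tables stay rectangular).
#' @references Tajima, F. (1989) Genetics 123:585-595.
#' @export
tajimas_d <- function(counts, sample_size) {
  n <- sample_size
  if (length(n) != 1L || is.na(n) || n < 2) {
    stop_config("tajimas_d: sample_size must be >= 2")
  }
  S <- length(counts)
  if (S == 0L) return(NA_real_)
  if (any(counts < 1 | counts > n - 1)) {
    stop_undefined_input("tajimas_d: counts must be in [1, sample_size - 1]")
  }
  # mean pairwise differences
  pi_hat <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Single-window HKA-type polymorphism/divergence test
#'
#' Comparator plumbing: a 2x2 chi-square contrasting a window's SNP and
#' fixed-difference counts with the genome-wide remainder.  Balancing
#' selection predicts an excess of polymorphism relative to divergence, so
#' the balancing-selection tail is \code{direction == "polymorphism_excess"}.
#'
#' @param window List or data.frame row with \code{n_snps} and \code{n_fds}
#'   (window informative-site counts).
#' @param background List with \code{total_snps}, \code{total_fds}: genome-wide
#'   totals (including the window; the remainder is formed internally).
#' @return List with \code{statistic} (chi-square, no continuity correction),
#'   \code{direction} (\code{"polymorphism_excess"},
#'   \code{"divergence_excess"} or \code{"none"}) and \code{signed}
#'   (statistic signed positive for polymorphism excess, for ROC use).
#' @export
hka_chi2 <- function(window, background) {
  ws <- window$n_snps; wf <- window$n_fds
  ts <- background$total_snps; tf_ <- background$total_fds
  if (is.null(ts) || is.null(tf_) || ts + tf_ <= 0 || ts < 0 || tf_ < 0) {
    stop_config("hka_chi2: background totals must be positive")
  }
  if (ws + wf <= 0) {
    stop_insufficient_data("hka_chi2: window has no informative sites")
  }
  rs <- ts - ws; rf <- tf_ - wf
  if (rs < 0 || rf < 0) {
    stop_config("hka_chi2: window counts exceed background totals")
  }
  tab <- matrix(c(ws, wf, rs, rf), nrow = 2, byrow = TRUE,
                dimnames = list(c("window", "rest"), c("snps", "fds")))
  # expected window SNP count under homogeneity
  exp_ws <- (ws + wf) * (ws + rs) / sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stat <- 0
  } else {
    stat <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
  }
  direction <- if (stat == 0 || ws == exp_ws) "none"
               else if (ws > exp_ws) "polymorphism_excess"
               else "divergence_excess"
  signed <- if (direction == "divergence_excess") -stat else stat
  list(statistic = stat, direction = direction, signed = signed)
}
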