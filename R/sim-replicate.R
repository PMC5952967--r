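# Container for one simulated replicate: a binary haplotype matrix plus an
# outgroup allele per site, the common currency between the simulators, the
# ms-format reader/writer and the statistics layer.

#' Construct a simulation replicate
#'
#' @param haplotypes n x S integer matrix of 0/1 alleles (rows = sampled
#'   chromosomes, columns = sites; 1 = derived).
#' @param positions Integer vector of length S, 0-based positions in
#'   \code{[0, L)}, strictly increasing.
#' @param outgroup Integer vector of length S with the outgroup allele
#'   (0 = ancestral, 1 = derived) at each site.
#' @param L Simulated sequence length in bp.
#' @return Object of class \code{sim_replicate}.
#' @export
sim_replicate <- function(haplotypes, positions, outgroup, L) {
  haplotypes <- as.matrix(haplotypes)
  S <- ncol(haplotypes)
  if (length(positions) != S || length(outgroup) != S) {
    stop_config("sim_replicate: positions/outgroup length must match site count")
  }
  if (S > 0) {
    if (is.unsorted(positions, strictly = TRUE)) {
      stop_config("sim_replicate: positions must be strictly increasing")
    }
    if (any(positions < 0 | positions >= L)) {
      stop_config("sim_replicate: positions must lie in [0, L)")
    }
    if (!all(haplotypes %in% c(0L, 1L)) || !all(outgroup %in% c(0L, 1L))) {
      stop_config("sim_replicate: alleles must be 0/1")
    }
  }
  structure(list(
    haplotypes = haplotypes,
    positions  = as.integer(positions),
    outgroup   = as.integer(outgroup),
    n = nrow(haplotypes),
    L = as.integer(L)
  ), class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("<sim_replicate> n = %d chromosomes, L = %d bp, %d sites\n",
              x$n, x$L, length(x$positions)))
  invisible(x)
}

#' Classify a replicate's sites into SNPs and fixed differences
#'
#' Applies the same classification rule as the VCF/outgroup reader: a site
#' polymorphic within the sample is a SNP (whatever the outgroup carries); a
#' site monomorphic in the sample whose single allele differs from the
#' outgroup allele is a fixed difference (FD); a site monomorphic in the
#' sample and identical to the outgroup is invisible and dropped.
#'
#' @param rep A \code{sim_replicate}.
#' @param chrom Contig label for the returned sites.
#' @return A \code{window_sites} object (FDs carry maf 0).
#' @export
replicate_sites <- function(rep, chrom = "sim") {
  stopifnot(inherits(rep, "sim_replicate"))
  S <- length(rep$positions)
  if (S == 0L) {
    return(window_sites(data.frame(chrom = character(), pos = integer(),
                                   kind = character(), minor_count = integer(),
                                   total_called = integer(), maf = numeric())))
  }
  d <- colSums(rep$haplotypes)
  n <- rep$n
  is_snp <- d > 0 & d < n
  is_fd  <- (d == 0L & rep$outgroup == 1L) | (d == n & rep$outgroup == 0L)
  keep <- is_snp | is_fd
  minor <- ifelse(is_snp, pmin(d, n - d), 0L)
  out <- data.frame(
    chrom = chrom,
    pos = rep$positions[keep],
    kind = ifelse(is_snp[keep], "SNP", "FD"),
    minor_count = as.integer(minor[keep]),
    total_called = n,
    maf = minor[keep] / n,
    stringsAsFactors = FALSE
  )
  # duplicate positions cannot arise from the simulators (collision nudging)
  window_sites(out)
}

#' NCD2 / NCD1 on a whole replicate
#'
#' Convenience wrappers treating the full simulated sequence as one window,
#' as in power analyses.
#'
#' @inheritParams replicate_sites
#' @param tf Target frequency.
#' @return The NCD value (scalar); \code{NA_real_} when the replicate has no
#'   usable sites (no IS for NCD2, no SNPs for NCD1).
#' @export
replicate_ncd2 <- function(rep, tf) {
  w <- replicate_sites(rep)
  if (w$is_count < 1L) return(NA_real_)
  ncd2(w, tf)$value
}

#' @rdname replicate_ncd2
#' @export
replicate_ncd1 <- function(rep, tf) {
  w <- replicate_sites(rep)
  if (w$n_snps < 1L) return(NA_real_)
  ncd1(w, tf)$value
}
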