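#' Sliding genomic windows
#'
#' Half-open windows \code{[k*step, k*step + size)} wholly contained in the
#' contig, the 3-kb / 1.5-kb sliding design of the genome scan.
#'
#' @param contig_lengths Named integer vector (contig -> length in bp).
#' @param size Window size in bp (default 3000).
#' @param step Step in bp (default 1500).
#' @return data.frame chrom, start, end (0-based half-open), ordered by
#'   (contig, start).
#' @export
make_windows <- function(contig_lengths, size = 3000, step = 1500) {
  if (size <= 0 || step <= 0) stop_config("make_windows: size/step must be > 0")
  out <- lapply(names(contig_lengths), function(ch) {
    L <- contig_lengths[[ch]]
    if (L < size) return(NULL)
    starts <- seq(0L, L - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  rownames(out) <- NULL
  out
}

#' Count informative sites per window
#'
#' @param windows data.frame from [make_windows()].
#' @param sites data.frame of Sites (chrom, pos 0-based, kind, maf).
#' @return \code{windows} with columns n_snps, n_fds, is appended, plus a
#'   list-column-free index: use [window_site_index()] for the site lists.
#' @export
count_window_sites <- function(windows, sites) {
  idx <- window_site_index(windows, sites)
  windows$n_snps <- vapply(idx, function(i) sum(sites$kind[i] == "SNP"), 0L)
  windows$n_fds <- vapply(idx, function(i) sum(sites$kind[i] == "FD"), 0L)
  windows$is <- windows$n_snps + windows$n_fds
  windows
}

#' Map sites to windows
#'
#' @inheritParams count_window_sites
#' @return List (one element per window row) of integer row indices into
#'   \code{sites}.
#' @export
window_site_index <- function(windows, sites) {
  if (nrow(windows) == 0L) return(list())
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end))
  if (nrow(sites) == 0L) return(rep(list(integer(0)), nrow(windows)))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  hits <- GenomicRanges::findOverlaps(wgr, sgr)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(windows))))
}

#' Filter scan windows on informative-site and orthology content
#'
#' A window is kept iff it has at least \code{min_is} informative sites and
#' at least \code{min_orthologous_bp} base pairs with outgroup orthology
#' (both boundaries inclusive).
#'
#' @param windows data.frame with columns n_snps, n_fds, is (see
#'   [count_window_sites()]) and optionally \code{orth_bp}.
#' @param min_is Minimum informative sites (default 10).
#' @param min_orthologous_bp Minimum orthologous bp (default 500); only
#'   enforced when \code{orth_bp} is present.
#' @return List with \code{kept} (filtered data.frame) and \code{ledger}
#'   (named counts of exclusions by reason: low_is, orthology).
#' @export
filter_windows <- function(windows, min_is = 10, min_orthologous_bp = 500) {
  low_is <- windows$is < min_is
  low_orth <- if ("orth_bp" %in% names(windows)) {
    windows$orth_bp < min_orthologous_bp
  } else rep(FALSE, nrow(windows))
  keep <- !low_is & !low_orth
  list(
    kept = windows[keep, , drop = FALSE],
    ledger = c(low_is = sum(low_is & !low_orth),
               orthology = sum(low_orth & !low_is),
               both = sum(low_is & low_orth),
               kept = sum(keep))
  )
}

#' Merge candidate windows into half-open regions
#'
#' Union of overlapping or book-ended windows (across tf values and/or
#' populations); used before SNP-level annotation counting so each SNP is
#' counted once.
#'
#' @param windows data.frame chrom, start, end (0-based half-open).
#' @return data.frame chrom, start, end of disjoint merged regions, ordered
#'   by (contig, start).
#' @export
merge_candidates <- function(windows) {
  if (nrow(windows) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1L, windows$end))
  m <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  m <- GenomicRanges::sort(m)
  data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
             start = GenomicRanges::start(m) - 1L,
             end = GenomicRanges::end(m),
             stringsAsFactors = FALSE)
}
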