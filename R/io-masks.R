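# BED masks and interval utilities.  Internal convention throughout the
# package: 0-based half-open coordinates (the BED convention); VCF 1-based
# positions are shifted at the reader boundary only.  Masks are held as
# GRanges (1-based closed internally to IRanges, converted at the edges).

#' Read a BED mask
#'
#' @param path BED file (first three columns chrom, start, end; 0-based
#'   half-open).  Alternatively a data.frame with those columns.
#' @param semantics \code{"include"} (positions inside pass) or
#'   \code{"exclude"}.
#' @return A \code{mask_set}: normalized (sorted, merged) GRanges with a
#'   \code{semantics} attribute.
#' @export
read_bed_mask <- function(path, semantics = c("include", "exclude")) {
  semantics <- match.arg(semantics)
  bed <- if (is.data.frame(path)) path else {
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)[, 1:3]
  }
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (any(bed$end <= bed$start)) stop_parse("read_bed_mask: end must exceed start")
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  gr <- GenomicRanges::reduce(gr)
  structure(gr, semantics = semantics, class = class(gr))
}

mask_semantics <- function(mask) {
  s <- attr(mask, "semantics")
  if (is.null(s)) "include" else s
}

# logical: which 0-based positions pass the mask
positions_pass_mask <- function(chrom, pos0, mask) {
  if (is.null(mask)) return(rep(TRUE, length(pos0)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
  inside <- IRanges::overlapsAny(q, mask)
  if (mask_semantics(mask) == "include") inside else !inside
}

# bp of [start0, end0) half-open windows covered by the include-side of mask
window_mask_bp <- function(chrom, start0, end0, mask) {
  if (is.null(mask)) return(end0 - start0)
  w <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  cov <- GenomicRanges::intersect(w, mask, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(w, cov)
  widths <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(w)[S4Vectors::queryHits(hit)],
    IRanges::ranges(cov)[S4Vectors::subjectHits(hit)]))
  out <- integer(length(w))
  agg <- tapply(widths, S4Vectors::queryHits(hit), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  if (mask_semantics(mask) == "include") out else (end0 - start0) - out
}
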