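# Population genotypes from VCF and fixed-difference classification against
# an outgroup.  VCF positions are 1-based; everything downstream is 0-based
# half-open.

#' Read biallelic SNP sites from a VCF
#'
#' Extracts genotypes for a sample subset, computes folded minor allele
#' frequencies over called chromosomes, and withholds records monomorphic in
#' the subsample for fixed-difference classification (see
#' [classify_fixed_differences()]).  Multiallelic records and non-SNP
#' variants are dropped; records with a call rate below
#' \code{min_call_rate} are excluded.
#'
#' @param vcf Path to a VCF file (plain or bgzipped).
#' @param samples Character vector of sample names to keep (\code{NULL} =
#'   all).  Unknown names raise a config error.
#' @param mask Optional \code{mask_set} from [read_bed_mask()].
#' @param min_call_rate Minimum fraction of chromosomes called at a site
#'   (default 0.9).
#' @return List with \code{sites} (data.frame of SNP Sites: chrom, pos
#'   (0-based), kind, minor_count, total_called, maf), \code{monomorphic}
#'   (data.frame chrom, pos, allele: records monomorphic in the subsample,
#'   with the single allele carried), and \code{n_skipped} (malformed or
#'   filtered records).
#' @export
read_population_sites <- function(vcf, samples = NULL, mask = NULL,
                                  min_call_rate = 0.9) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (nrow(fix) == 0L) {
    return(list(sites = empty_sites(), monomorphic = empty_mono(), n_skipped = 0L))
  }
  avail <- colnames(gt)[-1]
  if (is.null(samples)) samples <- avail
  missing_s <- setdiff(samples, avail)
  if (length(missing_s)) {
    stop_config("read_population_sites: unknown sample(s): %s",
                paste(missing_s, collapse = ", "))
  }
  gtm <- gt[, samples, drop = FALSE]

  bases <- c("A", "C", "G", "T")
  is_snp_rec <- fix$REF %in% bases & fix$ALT %in% bases
  pos0 <- as.integer(fix$POS) - 1L
  in_mask <- positions_pass_mask(fix$CHROM, pos0, mask)
  keep <- is_snp_rec & in_mask & !is.na(pos0)
  n_skipped <- sum(!is_snp_rec & in_mask, na.rm = TRUE)

  sites <- list(); mono <- list()
  for (i in which(keep)) {
    g <- sub(":.*", "", gtm[i, ])
    alleles <- unlist(strsplit(g, "[/|]"))
    called <- alleles %in% c("0", "1")
    nc <- sum(called)
    if (nc == 0L || nc / length(alleles) < min_call_rate) {
      n_skipped <- n_skipped + 1L
      next
    }
    nalt <- sum(alleles[called] == "1")
    if (nalt > 0L && nalt < nc) {
      minor <- min(nalt, nc - nalt)
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos0[i], kind = "SNP",
        minor_count = minor, total_called = nc, maf = minor / nc,
        stringsAsFactors = FALSE)
    } else {
      mono[[length(mono) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos0[i],
        allele = if (nalt == nc) fix$ALT[i] else fix$REF[i],
        stringsAsFactors = FALSE)
    }
  }
  list(
    sites = if (length(sites)) do.call(rbind, sites) else empty_sites(),
    monomorphic = if (length(mono)) do.call(rbind, mono) else empty_mono(),
    n_skipped = n_skipped
  )
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), kind = character(),
             minor_count = integer(), total_called = integer(),
             maf = numeric(), stringsAsFactors = FALSE)
}
empty_mono <- function() {
  data.frame(chrom = character(), pos = integer(), allele = character(),
             stringsAsFactors = FALSE)
}

#' Outgroup alleles from a reference-aligned FASTA or an allele table
#'
#' @param x Path to a FASTA of outgroup sequences in reference coordinates
#'   (one record per contig), a \code{Biostrings::DNAStringSet}, or a
#'   data.frame with columns chrom, pos (0-based), allele.
#' @param accept_lowercase Treat soft-masked (lowercase) bases as called
#'   (default \code{FALSE}: they are missing).
#' @return Object of class \code{outgroup_source}.
#' @export
outgroup_source <- function(x, accept_lowercase = FALSE) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos", "allele") %in% names(x)))
    return(structure(list(kind = "table", table = x),
                     class = "outgroup_source"))
  }
  if (inherits(x, "DNAStringSet")) {
    # DNAStringSet normalizes case, so soft-mask state is already gone
    chars <- lapply(as.character(x), function(s) strsplit(s, "")[[1]])
    names(chars) <- sub("\\s.*", "", names(x))
  } else {
    # read the FASTA text directly: case conveys the soft-mask state, which
    # DNAStringSet would normalize away
    lines <- readLines(x)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop_parse("outgroup_source: no FASTA headers in %s", x)
    grp <- cumsum(hdr)
    chars <- lapply(split(lines[!hdr], grp[!hdr]), function(ss) {
      strsplit(paste(ss, collapse = ""), "")[[1]]
    })
    names(chars) <- sub("\\s.*", "", sub("^>", "", lines[hdr]))
  }
  structure(list(kind = "fasta", chars = chars,
                 accept_lowercase = accept_lowercase),
            class = "outgroup_source")
}

#' Outgroup allele at given positions
#'
#' @param og An [outgroup_source()].
#' @param chrom Contig id (scalar).
#' @param pos0 Integer vector of 0-based positions.
#' @return Character vector of alleles in A/C/G/T, \code{NA} where the
#'   outgroup is missing (uncalled, soft-masked unless accepted, N, gap, or
#'   position absent).
#' @export
outgroup_allele <- function(og, chrom, pos0) {
  stopifnot(inherits(og, "outgroup_source"))
  bases <- c("A", "C", "G", "T")
  if (og$kind == "table") {
    tb <- og$table[og$table$chrom == chrom, ]
    a <- toupper(tb$allele[match(pos0, tb$pos)])
    a[!a %in% bases] <- NA
    return(a)
  }
  s <- og$chars[[chrom]]
  if (is.null(s)) return(rep(NA_character_, length(pos0)))
  raw <- rep(NA_character_, length(pos0))
  ok <- pos0 >= 0 & pos0 < length(s)
  raw[ok] <- s[pos0[ok] + 1L]
  if (og$accept_lowercase) raw <- toupper(raw)
  raw[!raw %in% bases] <- NA
  raw
}

#' Contigs covered by an outgroup source
#' @param og An [outgroup_source()].
#' @export
outgroup_contigs <- function(og) {
  if (og$kind == "table") unique(og$table$chrom) else names(og$chars)
}

#' Orthologous footprint of an outgroup source on one contig
#'
#' Positions where the outgroup allele is callable, as a 0-based half-open
#' interval data.frame; used to compute per-window orthologous bp for the
#' scan filter.
#'
#' @inheritParams outgroup_allele
#' @param contig_length Length of the contig (needed for FASTA sources
#'   shorter than the contig).
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
outgroup_footprint <- function(og, chrom, contig_length = NULL) {
  if (og$kind == "table") {
    p <- sort(unique(og$table$pos[og$table$chrom == chrom]))
    if (!length(p)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
    runs <- cumsum(c(1L, diff(p) != 1L))
    agg <- split(p, runs)
    return(data.frame(chrom = chrom,
                      start = vapply(agg, min, 0L),
                      end = vapply(agg, max, 0L) + 1L,
                      row.names = NULL))
  }
  s <- og$chars[[chrom]]
  if (is.null(s)) return(data.frame(chrom = character(), start = integer(),
                                    end = integer()))
  bases <- c("A", "C", "G", "T")
  called <- if (og$accept_lowercase) toupper(s) %in% bases else s %in% bases
  r <- rle(called)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = chrom, start = starts[r$values], end = ends[r$values],
             row.names = NULL)
}

#' Classify sample-monomorphic positions as fixed differences
#'
#' A fixed difference (FD) is emitted for a position where every called
#' chromosome in the sample carries one allele and the outgroup carries a
#' different, callable allele.  Positions with a missing outgroup allele
#' contribute nothing (they fall outside the orthologous footprint);
#' contigs absent from the outgroup are skipped with a warning.
#'
#' @param monomorphic data.frame (chrom, pos 0-based, allele) from
#'   [read_population_sites()].
#' @param outgroup An [outgroup_source()].
#' @param mask Optional \code{mask_set}.
#' @return data.frame of FD Sites (same columns as SNP sites; maf = 0,
#'   minor_count = 0).
#' @export
classify_fixed_differences <- function(monomorphic, outgroup, mask = NULL) {
  if (nrow(monomorphic) == 0L) return(empty_sites())
  out <- list()
  for (chrom in unique(monomorphic$chrom)) {
    if (!chrom %in% outgroup_contigs(outgroup)) {
      warning(sprintf("contig %s absent from outgroup; skipped for FDs", chrom))
      next
    }
    mm <- monomorphic[monomorphic$chrom == chrom, ]
    keep <- positions_pass_mask(chrom, mm$pos, mask)
    mm <- mm[keep, , drop = FALSE]
    if (!nrow(mm)) next
    og <- outgroup_allele(outgroup, chrom, mm$pos)
    fd <- !is.na(og) & og != toupper(mm$allele)
    if (any(fd)) {
      out[[chrom]] <- data.frame(
        chrom = chrom, pos = mm$pos[fd], kind = "FD",
        minor_count = 0L, total_called = NA_integer_, maf = 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_sites()
}
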