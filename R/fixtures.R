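# Test-fixture generator: writes a toy VCF + outgroup FASTA + mask BED whose
# parsed Sites exactly reproduce a site ledger.  All files are synthetic.

#' Generate a synthetic VCF / outgroup FASTA / mask BED fixture
#'
#' Writes files on a toy contig such that running
#' [read_population_sites()] + [classify_fixed_differences()] over them
#' returns exactly the sites of the ledger.  SNP ledger rows become
#' biallelic records with the requested minor-allele count; FD rows become
#' records monomorphic for an allele that differs from the outgroup base at
#' that position.
#'
#' @param ledger data.frame with columns \code{pos} (0-based, unique),
#'   \code{kind} ("SNP"/"FD") and for SNPs \code{minor_count}; optional
#'   \code{chrom} (default "chrT").
#' @param dir Output directory (created if needed).
#' @param n_dip Number of diploid samples to write (default 50, i.e. 100
#'   chromosomes).
#' @param contig_length Contig length; defaults to max(pos) + 100.
#' @param seed Seed for the random base choices and genotype shuffling.
#' @return List with paths \code{vcf}, \code{fasta}, \code{bed}, the contig
#'   length, and the ledger as written.
#' @export
fixture_vcf <- function(ledger, dir = tempfile("ncdfix"), n_dip = 50,
                        contig_length = NULL, seed = 1) {
  set.seed(seed)
  if (nrow(ledger) > 0 && anyDuplicated(ledger$pos)) {
    stop_config("fixture_vcf: ledger positions must be unique")
  }
  chrom <- if ("chrom" %in% names(ledger) && nrow(ledger)) ledger$chrom[1] else "chrT"
  if (is.null(contig_length)) {
    contig_length <- if (nrow(ledger)) max(ledger$pos) + 100L else 1000L
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, contig_length, replace = TRUE)
  outg <- ref  # identical except at FD positions

  n_chr <- 2L * n_dip
  samples <- sprintf("S%03d", seq_len(n_dip))
  rows <- character(0)
  if (nrow(ledger)) {
    ledger <- ledger[order(ledger$pos), , drop = FALSE]
    for (i in seq_len(nrow(ledger))) {
      p0 <- ledger$pos[i]
      refb <- ref[p0 + 1L]
      altb <- sample(setdiff(bases, refb), 1)
      if (ledger$kind[i] == "SNP") {
        mc <- as.integer(ledger$minor_count[i])
        if (is.na(mc) || mc < 1L || mc > n_chr %/% 2L) {
          stop_config("fixture_vcf: SNP minor_count must be in [1, n_chr/2]")
        }
        alleles <- sample(c(rep(1L, mc), rep(0L, n_chr - mc)))
      } else {
        # monomorphic ALT so the sample allele differs from the outgroup,
        # which keeps the reference base at this position
        alleles <- rep(1L, n_chr)
      }
      gts <- paste(alleles[seq(1, n_chr, 2)], alleles[seq(2, n_chr, 2)],
                   sep = "/")
      rows <- c(rows, paste(c(chrom, p0 + 1L, ".", refb, altb, ".", "PASS",
                              ".", "GT", gts), collapse = "\t"))
    }
  }
  vcf_path <- file.path(dir, "fixture.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), vcf_path)

  fasta_path <- file.path(dir, "outgroup.fa")
  writeLines(c(sprintf(">%s", chrom),
               paste(outg, collapse = "")), fasta_path)

  bed_path <- file.path(dir, "mask.bed")
  writeLines(sprintf("%s\t0\t%d", chrom, contig_length), bed_path)

  list(vcf = vcf_path, fasta = fasta_path, bed = bed_path,
       contig_length = contig_length, chrom = chrom, ledger = ledger,
       n_chr = n_chr)
}

#' Parse a fixture (or any VCF + outgroup + mask triple) into sites
#'
#' Convenience wrapper chaining [read_population_sites()] and
#' [classify_fixed_differences()].
#'
#' @param vcf,fasta,bed Paths as produced by [fixture_vcf()].
#' @param samples Optional sample subset.
#' @return data.frame of SNP and FD Sites sorted by (chrom, pos).
#' @export
read_sites <- function(vcf, fasta, bed = NULL, samples = NULL) {
  mask <- if (!is.null(bed)) read_bed_mask(bed) else NULL
  pop <- read_population_sites(vcf, samples = samples, mask = mask)
  og <- outgroup_source(fasta)
  fds <- classify_fixed_differences(pop$monomorphic, og, mask = mask)
  out <- rbind(pop$sites, fds)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
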