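# Genome-scan assembly: per-window NCD2 across tf values, Z-standardization,
# empirical P, outlier calling and assigned tf.

#' Empirical P values from Z ranks
#'
#' Ranks the windows by Z (most negative = strongest balancing-selection
#' signature = rank 1) and assigns \code{p = rank / N}.  Ties are broken
#' deterministically by (Z ascending, IS descending, chrom, start) so that
#' rank/N is reproducible.
#'
#' @param z Numeric vector of Z values (NA allowed: untestable windows get
#'   NA p and are not counted in N).
#' @param is_count,chrom,start Tie-break keys (optional; defaults keep input
#'   order among ties).
#' @return Numeric vector of empirical p in \code{[1/N, 1]}, NA where z is
#'   NA.
#' @export
empirical_p <- function(z, is_count = NULL, chrom = NULL, start = NULL) {
  n <- length(z)
  if (is.null(is_count)) is_count <- rep(0L, n)
  if (is.null(chrom)) chrom <- rep("", n)
  if (is.null(start)) start <- seq_len(n)
  ok <- !is.na(z)
  N <- sum(ok)
  p <- rep(NA_real_, n)
  if (N == 0L) return(p)
  o <- order(z[ok], -is_count[ok], chrom[ok], start[ok])
  r <- integer(N)
  r[o] <- seq_len(N)
  p[ok] <- r / N
  p
}

#' Flag outlier windows
#'
#' The most extreme windows of the empirical-P ranking: ranks
#' \code{1 .. ceiling(cutoff * N)} (the 0.05% lower tail by default).  At
#' N = 1,657,989 scanned windows this is exactly 829 windows; the boundary
#' window's p (829/N) exceeds the cutoff by 3e-9, which is why the count is
#' a ceiling rather than a floor.
#'
#' @param p Empirical p values from [empirical_p()] (NA allowed).
#' @param cutoff Empirical-P cutoff (default 0.0005).
#' @return Logical flags (NA propagates).
#' @export
call_outliers <- function(p, cutoff = 0.0005) {
  N <- sum(!is.na(p))
  k <- ceiling(cutoff * N)
  ifelse(is.na(p), NA, round(p * N) <= k)
}

#' Assigned tf per window
#'
#' The tf value minimizing the window's empirical P; ties resolved by most
#' negative Z, then smallest tf.
#'
#' @param p_mat Matrix of empirical p, one column per tf.
#' @param z_mat Matrix of Z, same shape.
#' @param tf_values Numeric vector of tf values (column order).
#' @return Numeric vector of assigned tf (NA when all columns NA).
#' @export
assign_tf <- function(p_mat, z_mat, tf_values) {
  stopifnot(ncol(p_mat) == length(tf_values), all(dim(p_mat) == dim(z_mat)))
  o_tf <- order(tf_values)   # smallest-tf preference as final tie-break
  apply_rows <- function(i) {
    p <- p_mat[i, ]; z <- z_mat[i, ]
    if (all(is.na(p))) return(NA_real_)
    cand <- which(p == min(p, na.rm = TRUE))
    if (length(cand) > 1L) {
      zc <- z[cand]
      cand <- cand[which(zc == min(zc, na.rm = TRUE))]
    }
    if (length(cand) > 1L) cand <- cand[order(match(cand, o_tf))][1]
    tf_values[cand[1]]
  }
  vapply(seq_len(nrow(p_mat)), apply_rows, 0)
}

#' Run the NCD2 genome scan
#'
#' For each filtered window computes NCD2 at each tf, the IS-matched
#' significance call and Z score against the supplied null distributions,
#' the empirical P over all scanned windows, outlier flags and the assigned
#' tf.
#'
#' @param sites data.frame of Sites (chrom, pos 0-based, kind, maf), e.g.
#'   from [read_sites()].
#' @param contig_lengths Named vector of contig lengths.
#' @param nulls Named list of \code{ncd_null} objects keyed by tf (names
#'   like "0.3"); one per requested tf.
#' @param tf_values Target frequencies (default c(0.3, 0.4, 0.5)).
#' @param size,step Window geometry (default 3000 / 1500).
#' @param min_is,min_orthologous_bp Filter thresholds (defaults 10 / 500).
#' @param orthology Optional mask_set (or BED-like data.frame) of
#'   outgroup-orthologous intervals used for the orthologous-bp filter.
#' @param outlier_cutoff Empirical-P cutoff (default 0.0005).
#' @return List with \code{scan} (data.frame: chrom, start, end, n_snps,
#'   n_fds, is, then per tf ncd2/z/emp_p/significant/outlier columns, and
#'   assigned_tf) and \code{ledger} (window exclusion counts).
#' @export
run_scan <- function(sites, contig_lengths, nulls,
                     tf_values = c(0.3, 0.4, 0.5),
                     size = 3000, step = 1500,
                     min_is = 10, min_orthologous_bp = 500,
                     orthology = NULL, outlier_cutoff = 0.0005) {
  tf_keys <- format_tf(tf_values)
  if (!all(tf_keys %in% names(nulls))) {
    stop_config("run_scan: missing null distribution for tf %s",
                paste(setdiff(tf_keys, names(nulls)), collapse = ", "))
  }
  win <- make_windows(contig_lengths, size = size, step = step)
  win <- count_window_sites(win, sites)
  if (!is.null(orthology)) {
    if (is.data.frame(orthology)) orthology <- read_bed_mask(orthology)
    win$orth_bp <- window_mask_bp(win$chrom, win$start, win$end, orthology)
  }
  fl <- filter_windows(win, min_is = min_is,
                       min_orthologous_bp = min_orthologous_bp)
  kept <- fl$kept
  idx <- window_site_index(kept, sites)
  n_win <- nrow(kept)

  for (k in seq_along(tf_values)) {
    tf <- tf_values[k]
    null <- nulls[[tf_keys[k]]]
    ncd2_v <- z_v <- rep(NA_real_, n_win)
    sig_v <- rep(NA, n_win)
    for (i in seq_len(n_win)) {
      s <- sites[idx[[i]], , drop = FALSE]
      if (nrow(s) == 0L) next
      val <- ncd(s$maf, tf)
      ncd2_v[i] <- val
      sig_v[i] <- call_significant(val, null, nrow(s))
      z_v[i] <- z_standardize(val, null, nrow(s))
    }
    p_v <- empirical_p(z_v, kept$is, kept$chrom, kept$start)
    out_v <- call_outliers(p_v, cutoff = outlier_cutoff)
    kept[[paste0("ncd2_", tf_keys[k])]] <- ncd2_v
    kept[[paste0("z_", tf_keys[k])]] <- z_v
    kept[[paste0("emp_p_", tf_keys[k])]] <- p_v
    kept[[paste0("significant_", tf_keys[k])]] <- sig_v
    kept[[paste0("outlier_", tf_keys[k])]] <- out_v
  }
  p_mat <- as.matrix(kept[paste0("emp_p_", tf_keys)])
  z_mat <- as.matrix(kept[paste0("z_", tf_keys)])
  kept$assigned_tf <- assign_tf(p_mat, z_mat, tf_values)
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  list(scan = kept, ledger = fl$ledger)
}

format_tf <- function(tf_values) {
  vapply(tf_values, function(x) format(x, trim = TRUE), "")
}

#' Write the scan table as TSV
#'
#' One row per window, deterministic (contig, start) ordering, fixed column
#' schema; a \code{# ncdscan} header line records the run configuration for
#' reproducibility.
#'
#' @param scan Scan data.frame from [run_scan()].
#' @param path Output path (".gz" suffix gzips).
#' @param config Optional named list echoed into the header comment.
#' @return \code{path}, invisibly.
#' @export
write_scan_tsv <- function(scan, path, config = NULL) {
  scan <- scan[order(scan$chrom, scan$start), , drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(paste0("# ncdscan ",
                      paste(names(config), unlist(config), sep = "=",
                            collapse = " ")), con)
  }
  utils::write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resampling enrichment of an annotation among candidate windows
#'
#' Compares the proportion of (merged, deduplicated) candidate-window SNPs
#' falling in an annotation category with the proportions obtained by
#' resampling the same number of windows from the background
#' (scanned) set.  One-tailed empirical
#' \code{p = (1 + #resamples with proportion >= observed) / (n_resamples + 1)}.
#'
#' @param candidates data.frame chrom/start/end of candidate windows.
#' @param background data.frame chrom/start/end of all scanned windows.
#' @param sites data.frame of SNP Sites (chrom, pos).
#' @param category Logical vector along \code{sites} rows: membership in
#'   the annotation category.
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Seed for the resampling.
#' @return List: \code{observed} (proportion), \code{p}, \code{n_snps}
#'   (deduplicated candidate SNPs), \code{n_resamples}.
#' @export
resampling_enrichment <- function(candidates, background, sites, category,
                                  n_resamples = 1000, seed = NULL) {
  stopifnot(length(category) == nrow(sites))
  if (!is.null(seed)) set.seed(seed)
  prop_in <- function(win) {
    merged <- merge_candidates(win)
    idx <- unique(unlist(window_site_index(merged, sites)))
    if (length(idx) == 0L) return(c(prop = NA_real_, n = 0))
    c(prop = mean(category[idx]), n = length(idx))
  }
  obs <- prop_in(candidates)
  k <- nrow(candidates)
  hits <- 0L
  for (r in seq_len(n_resamples)) {
    draw <- background[sample.int(nrow(background), k), , drop = FALSE]
    pr <- prop_in(draw)["prop"]
    if (!is.na(pr) && !is.na(obs["prop"]) && pr >= obs["prop"]) hits <- hits + 1L
  }
  list(observed = unname(obs["prop"]), p = (1 + hits) / (n_resamples + 1),
       n_snps = unname(obs["n"]), n_resamples = n_resamples)
}
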