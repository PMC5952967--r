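# Simulation-matched null distributions: per (tf, IS-count) summaries of
# NCD2 over neutral replicates.  Matching on the number of informative
# sites absorbs the higher sampling variance of the statistic in
# site-poor windows.

#' Build an informative-site-matched null distribution
#'
#' Computes NCD2(tf) on every neutral replicate (whole replicate = one
#' window) and bins the values by the replicate's IS count.  Bins holding
#' fewer than \code{min_count} values are augmented with the nearest IS
#' neighbors, expanding symmetrically until satisfied; the merge radius is
#' recorded per bin.
#'
#' @param replicates List of [sim_replicate()] (neutral), or a numeric
#'   data.frame/list with \code{ncd2} and \code{is} vectors for
#'   pre-computed values.
#' @param tf Target frequency.
#' @param min_count Minimum values per bin before neighbor merging stops
#'   (default 1000).
#' @return Object of class \code{ncd_null}: \code{tf}, \code{is_values}
#'   (sorted IS counts observed), \code{values} (list per IS bin after
#'   merging: numeric vector), \code{stats} (data.frame is, n, min, mean,
#'   sd, radius).
#' @export
build_null <- function(replicates, tf, min_count = 1000) {
  check_tf(tf)
  if (is.list(replicates) && length(replicates) &&
      inherits(replicates[[1]], "sim_replicate")) {
    ws <- lapply(replicates, replicate_sites)
    is_count <- vapply(ws, function(w) w$is_count, 0L)
    ok <- is_count >= 1L
    vals <- vapply(ws[ok], function(w) ncd2(w, tf)$value, 0)
    is_count <- is_count[ok]
  } else {
    vals <- replicates$ncd2
    is_count <- replicates$is
    stopifnot(length(vals) == length(is_count))
  }
  if (length(vals) == 0L) stop_insufficient_data("build_null: no usable replicates")
  by_is <- split(vals, is_count)
  is_values <- sort(as.integer(names(by_is)))

  merged <- vector("list", length(is_values))
  radius <- integer(length(is_values))
  for (i in seq_along(is_values)) {
    r <- 0L
    repeat {
      sel <- is_values[abs(is_values - is_values[i]) <= r]
      v <- unlist(by_is[as.character(sel)], use.names = FALSE)
      if (length(v) >= min_count || r > diff(range(is_values)) + 1L) break
      r <- r + 1L
    }
    merged[[i]] <- v
    radius[i] <- r
  }
  stats <- data.frame(
    is = is_values,
    n = vapply(merged, length, 0L),
    min = vapply(merged, min, 0),
    mean = vapply(merged, mean, 0),
    sd = vapply(merged, stats::sd, 0),
    radius = radius
  )
  if (any(is.na(stats$sd) | stats$sd <= 0)) {
    stop_insufficient_data("build_null: a bin has zero variance; add replicates")
  }
  structure(list(tf = tf, is_values = is_values, values = merged,
                 stats = stats,
                 raw = data.frame(is = is_count, value = vals)),
            class = "ncd_null")
}

#' @export
print.ncd_null <- function(x, ...) {
  cat(sprintf("<ncd_null> tf = %g, %d IS bins (IS %d..%d), %d values total\n",
              x$tf, length(x$is_values), min(x$is_values), max(x$is_values),
              sum(vapply(x$values, length, 0L)) ))
  invisible(x)
}

# nearest retained IS bin index for an observed IS count; NA when no bins
match_null_bin <- function(null, is_count) {
  if (length(null$is_values) == 0L) return(NA_integer_)
  which.min(abs(null$is_values - is_count))
}

#' Significance call against the IS-matched null
#'
#' A window is significant when its observed NCD2 is strictly lower than
#' every value in the matched null bin (with the nominal 10,000
#' simulations this is P < 0.0001).
#'
#' @param ncd2_value Observed NCD2.
#' @param null An \code{ncd_null}.
#' @param is_count The window's IS count.
#' @return Logical; \code{NA} when no bin can be matched (untestable
#'   window).
#' @export
call_significant <- function(ncd2_value, null, is_count) {
  b <- match_null_bin(null, is_count)
  if (is.na(b)) return(NA)
  ncd2_value < null$stats$min[b]
}

#' Z-standardize an observed NCD2 against the IS-matched null
#'
#' \code{Z = (NCD2 - mean(null bin)) / sd(null bin)}: the number of
#' standard deviations the window lies from the neutral expectation at its
#' IS count, comparable across windows and tf values.
#'
#' @inheritParams call_significant
#' @return Numeric Z; \code{NA} when untestable.
#' @export
z_standardize <- function(ncd2_value, null, is_count) {
  b <- match_null_bin(null, is_count)
  if (is.na(b)) return(NA_real_)
  (ncd2_value - null$stats$mean[b]) / null$stats$sd[b]
}

#' Persist / restore a null distribution as a TSV container
#'
#' Single-file plain-text container keyed by (tf, IS): one row per stored
#' value.
#'
#' @param null An \code{ncd_null} (for writing).
#' @param path File path.
#' @export
write_null <- function(null, path) {
  # the unmerged (is, value) pairs fully determine the object
  rows <- data.frame(tf = null$tf, is = null$raw$is, value = null$raw$value)
  utils::write.table(rows, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_null
#' @param min_count Bin merging threshold used on reload.
#' @export
read_null <- function(path, min_count = 1000) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t")
  tf <- unique(rows$tf)
  if (length(tf) != 1L) stop_parse("read_null: file must hold a single tf")
  build_null(list(ncd2 = rows$value, is = rows$is), tf = tf,
             min_count = min_count)
}
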