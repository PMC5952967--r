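# Power benchmarking: TPR at fixed FPR and ROC curves over paired
# neutral / selected replicate sets.

#' True positive rate at a fixed false positive rate
#'
#' The detection threshold is the empirical \code{fpr}-quantile of the
#' neutral statistic distribution, taken as the order statistic of rank
#' \code{ceiling(fpr * n)} in the selection direction; power (TPR) is the
#' fraction of selected replicates strictly beyond it (ties with the
#' threshold are not counted, a conservative choice).
#'
#' @param neutral,selected Numeric vectors of the statistic under
#'   neutrality and under selection (NAs dropped).
#' @param fpr Fixed false positive rate in (0, 1); default 0.05.
#' @param direction \code{"lower"} when selection drives the statistic
#'   down (NCD), \code{"higher"} when up (Tajima's D, HKA polymorphism
#'   excess under balancing selection).
#' @param statistic,condition Optional labels carried into the result.
#' @return List of class \code{power_result}: tpr, fpr, threshold,
#'   n_neutral, n_selected, direction, statistic, condition.
#' @export
tpr_at_fpr <- function(neutral, selected, fpr = 0.05,
                       direction = c("lower", "higher"),
                       statistic = NULL, condition = NULL) {
  direction <- match.arg(direction)
  if (length(fpr) != 1L || is.na(fpr) || fpr <= 0 || fpr >= 1) {
    stop_config("tpr_at_fpr: fpr must be in (0, 1)")
  }
  neutral <- neutral[!is.na(neutral)]
  selected <- selected[!is.na(selected)]
  if (!length(neutral) || !length(selected)) {
    stop_insufficient_data("tpr_at_fpr: empty statistic vector")
  }
  k <- ceiling(fpr * length(neutral))
  thr <- if (direction == "lower") sort(neutral)[k] else
    sort(neutral, decreasing = TRUE)[k]
  tpr <- if (direction == "lower") mean(selected < thr) else mean(selected > thr)
  structure(list(tpr = tpr, fpr = fpr, threshold = thr,
                 n_neutral = length(neutral), n_selected = length(selected),
                 direction = direction, statistic = statistic,
                 condition = condition),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result>%s TPR = %.3f at FPR = %g (threshold %.4g, %d/%d reps)\n",
              if (is.null(x$statistic)) "" else paste0(" ", x$statistic),
              x$tpr, x$fpr, x$threshold, x$n_selected, x$n_neutral))
  invisible(x)
}

#' ROC curve over paired statistic vectors
#'
#' @inheritParams tpr_at_fpr
#' @return data.frame (fpr, tpr), monotone nondecreasing in fpr, with
#'   endpoints (0, .) and (1, 1).
#' @export
roc_curve <- function(neutral, selected, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  neutral <- neutral[!is.na(neutral)]
  selected <- selected[!is.na(selected)]
  if (!length(neutral) || !length(selected)) {
    stop_insufficient_data("roc_curve: empty statistic vector")
  }
  s <- if (direction == "lower") 1 else -1
  thr <- sort(unique(c(neutral, selected) * s))
  fpr <- vapply(thr, function(t) mean(neutral * s < t), 0)
  tpr <- vapply(thr, function(t) mean(selected * s < t), 0)
  out <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  out
}

#' Power grid over simulation conditions
#'
#' End-to-end driver: simulates neutral and balancing replicate sets per
#' condition, computes the requested statistics on each whole replicate and
#' tabulates TPR at the fixed FPR.
#'
#' @param conditions data.frame with columns \code{pop} ("african" /
#'   "european"), \code{tbs_ma}, \code{f_eq}, \code{L}; optional \code{n}
#'   (chromosomes, default 100).
#' @param tf_values tf values for NCD1/NCD2 columns.
#' @param statistics Character subset of
#'   \code{c("ncd1", "ncd2", "tajd", "hka")}.
#' @param n_reps Replicates per arm.
#' @param fpr Fixed false positive rate.
#' @param seed Root seed; per-condition substreams are derived from it.
#' @param scaling Forward-simulation rescaling factor.
#' @return data.frame: one row per condition x statistic x tf with tpr,
#'   threshold and arm sizes.
#' @export
power_grid <- function(conditions, tf_values = c(0.3, 0.4, 0.5),
                       statistics = c("ncd1", "ncd2", "tajd", "hka"),
                       n_reps = 1000, fpr = 0.05, seed = 1, scaling = 10) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  rows <- list()
  neutral_cache <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    n <- if ("n" %in% names(cond)) cond$n else 100
    model <- demographic_model(as.character(cond$pop))
    nkey <- paste(cond$pop, cond$L, n, sep = "_")
    if (is.null(neutral_cache[[nkey]])) {
      neutral_cache[[nkey]] <- simulate_neutral(
        model, n = n, L = cond$L, n_reps = n_reps,
        seed = (seed + 7L * ci) %% .Machine$integer.max)
    }
    neu <- neutral_cache[[nkey]]
    sel <- simulate_balancing(
      model, selection_model(f_eq = cond$f_eq, tbs_ma = cond$tbs_ma),
      n = n, L = cond$L, n_reps = n_reps,
      seed = (seed + 7L * ci + 3L) %% .Machine$integer.max,
      scaling = scaling)
    stats_n <- replicate_stat_table(neu, tf_values)
    # HKA background from the neutral arm for both arms: each replicate is
    # one window tested against a neutral genome background
    bg <- list(total_snps = sum(stats_n$n_snps), total_fds = sum(stats_n$n_fds))
    stats_s <- replicate_stat_table(sel, tf_values, background = bg)
    for (st in statistics) {
      if (st %in% c("ncd1", "ncd2")) {
        for (tf in tf_values) {
          col <- paste0(st, "_", format_tf(tf))
          pr <- tpr_at_fpr(stats_n[[col]], stats_s[[col]], fpr = fpr,
                           direction = "lower")
          rows[[length(rows) + 1L]] <- data.frame(
            cond, statistic = st, tf = tf, tpr = pr$tpr,
            threshold = pr$threshold, n_neutral = pr$n_neutral,
            n_selected = pr$n_selected)
        }
      } else {
        dirn <- "higher"
        pr <- tpr_at_fpr(stats_n[[st]], stats_s[[st]], fpr = fpr,
                         direction = dirn)
        rows[[length(rows) + 1L]] <- data.frame(
          cond, statistic = st, tf = NA_real_, tpr = pr$tpr,
          threshold = pr$threshold, n_neutral = pr$n_neutral,
          n_selected = pr$n_selected)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-replicate statistic table used by power_grid
replicate_stat_table <- function(reps, tf_values, background = NULL) {
  ws <- lapply(reps, replicate_sites)
  n_snps <- vapply(ws, function(w) w$n_snps, 0L)
  n_fds <- vapply(ws, function(w) w$n_fds, 0L)
  out <- data.frame(n_snps = n_snps, n_fds = n_fds)
  for (tf in tf_values) {
    key <- format_tf(tf)
    out[[paste0("ncd2_", key)]] <- vapply(seq_along(ws), function(i) {
      if (ws[[i]]$is_count < 1L) NA_real_ else ncd2(ws[[i]], tf)$value
    }, 0)
    out[[paste0("ncd1_", key)]] <- vapply(seq_along(ws), function(i) {
      if (ws[[i]]$n_snps < 1L) NA_real_ else ncd1(ws[[i]], tf)$value
    }, 0)
  }
  out$tajd <- vapply(seq_along(ws), function(i) {
    s <- ws[[i]]$sites
    mc <- s$minor_count[s$kind == "SNP"]
    n <- reps[[i]]$n
    if (length(mc) == 0L) NA_real_ else tajimas_d(mc, n)
  }, 0)
  # 'background' counts exclude the tested window; when absent, use the
  # remainder of this arm
  out$hka <- vapply(seq_along(ws), function(i) {
    if (n_snps[i] + n_fds[i] == 0L) return(NA_real_)
    bg <- if (is.null(background)) {
      list(total_snps = sum(n_snps), total_fds = sum(n_fds))
    } else {
      list(total_snps = background$total_snps + n_snps[i],
           total_fds = background$total_fds + n_fds[i])
    }
    hka_chi2(list(n_snps = n_snps[i], n_fds = n_fds[i]), bg)$signed
  }, 0)
  out
}
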