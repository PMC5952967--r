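# Reader/writer for ms-format simulation output (the dialect emitted by ms
# and msms): replicate blocks introduced by "//", a "segsites:" count, a
# "positions:" line of fractions in [0, 1), then one 0/1 haplotype row per
# sampled chromosome.  The writer appends a non-standard "outgroup:" row per
# block carrying the outgroup allele at each site; the reader accepts plain
# ms files without it (outgroup then taken as ancestral everywhere).

#' Read ms-format simulation output
#'
#' @param x Path to an ms-format file, or a character vector of its lines.
#' @param L Sequence length in bp used to scale the fractional positions to
#'   integer coordinates.  Taken from a \code{-L <bp>} token on the command
#'   line header when present (the writer emits one); required otherwise.
#' @return List of [sim_replicate()] objects.  Fractional positions are
#'   scaled to \code{[0, L)} and rounded; collisions are nudged to the next
#'   free integer position.
#' @export
read_ms <- function(x, L = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  if (is.null(L) && length(lines)) {
    m <- regmatches(lines[1], regexec("-L ([0-9]+)", lines[1]))[[1]]
    if (length(m) == 2L) L <- as.integer(m[2])
  }
  if (is.null(L)) {
    stop_config("read_ms: sequence length L not given and no -L header token")
  }
  n_header <- NA_integer_
  if (length(lines)) {
    tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(tok) >= 2L && grepl("^[0-9]+$", tok[2])) {
      n_header <- as.integer(tok[2])
    }
  }
  starts <- which(trimws(lines) == "//")
  reps <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[seq(starts[k] + 1L, bounds[k + 1L] - 1L)]
    reps[[k]] <- parse_ms_block(block, k, L, n_header)
  }
  reps
}

parse_ms_block <- function(block, index, L, n_header = NA_integer_) {
  block <- block[trimws(block) != "" | seq_along(block) < 0]
  seg_line <- grep("^segsites:", trimws(block), value = TRUE)
  if (length(seg_line) == 0L) {
    stop_parse("read_ms: replicate %d lacks a segsites line", index)
  }
  S <- as.integer(sub("^segsites:\\s*", "", trimws(seg_line[1])))
  og_line <- grep("^outgroup:", trimws(block), value = TRUE)
  hap_lines <- grep("^[01]+$", trimws(block), value = TRUE)
  if (S == 0L) {
    n0 <- if (!is.na(n_header)) n_header else length(hap_lines)
    return(sim_replicate(matrix(0L, nrow = n0, ncol = 0),
                         integer(), integer(), L))
  }
  pos_line <- grep("^positions:", trimws(block), value = TRUE)
  if (length(pos_line) == 0L) {
    stop_parse("read_ms: replicate %d lacks a positions line", index)
  }
  frac <- as.numeric(strsplit(sub("^positions:\\s*", "", trimws(pos_line[1])),
                              "\\s+")[[1]])
  if (length(frac) != S || anyNA(frac)) {
    stop_parse("read_ms: replicate %d positions line malformed", index)
  }
  if (length(hap_lines) == 0L || any(nchar(hap_lines) != S)) {
    stop_parse("read_ms: replicate %d truncated (haplotype rows do not match segsites)",
               index)
  }
  if (!is.na(n_header) && length(hap_lines) != n_header) {
    stop_parse("read_ms: replicate %d truncated (%d of %d haplotype rows)",
               index, length(hap_lines), n_header)
  }
  hap <- do.call(rbind, lapply(hap_lines, function(s) {
    as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  }))
  og <- integer(S)
  if (length(og_line)) {
    og_s <- sub("^outgroup:\\s*", "", trimws(og_line[1]))
    if (nchar(og_s) != S) {
      stop_parse("read_ms: replicate %d outgroup row does not match segsites", index)
    }
    og <- as.integer(strsplit(og_s, "", fixed = TRUE)[[1]])
  }
  pos <- scale_ms_positions(frac, L)
  o <- order(pos)
  sim_replicate(hap[, o, drop = FALSE], pos[o], og[o], L)
}

# fractions of [0,1) -> distinct integer bp in [0, L)
scale_ms_positions <- function(frac, L) {
  pos <- pmin(pmax(round(frac * L), 0), L - 1)
  used <- logical(L)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i] + 1L              # 1-based index into 'used'
    while (p <= L && used[p]) p <- p + 1L
    if (p > L) {                  # wrap downward if the top is saturated
      p <- pos[i] + 1L
      while (p >= 1L && used[p]) p <- p - 1L
      if (p < 1L) stop_parse("read_ms: more sites than positions available")
    }
    used[p] <- TRUE
    out[i] <- p - 1L
  }
  out
}

#' Write replicates as ms-format text
#'
#' @param replicates List of [sim_replicate()] objects (equal \code{n} and
#'   \code{L}).
#' @param path Optional output path; when \code{NULL} the lines are returned
#'   invisibly-visible as a character vector.
#' @return Character vector of lines (invisibly when \code{path} is given).
#' @export
write_ms <- function(replicates, path = NULL) {
  if (length(replicates) == 0L) stop_config("write_ms: no replicates")
  stopifnot(all(vapply(replicates, inherits, logical(1), "sim_replicate")))
  n <- replicates[[1]]$n
  L <- replicates[[1]]$L
  out <- c(sprintf("ncdscan %d %d -L %d", n, length(replicates), L),
           "0 0 0", "")
  for (rep in replicates) {
    S <- length(rep$positions)
    out <- c(out, "//", sprintf("segsites: %d", S))
    if (S > 0) {
      out <- c(out,
        paste("positions:",
              paste(sprintf("%.10f", rep$positions / rep$L), collapse = " ")),
        apply(rep$haplotypes, 1, paste, collapse = ""),
        paste0("outgroup: ", paste(rep$outgroup, collapse = "")))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
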