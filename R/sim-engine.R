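# Ancestral-recombination-graph engine shared by the neutral and
# balancing-selection simulators.
#
# Lineages carry their ancestral material as disjoint segments on [0, L),
# each segment with the set of sampled chromosomes descending from it (the
# outgroup lineage is sample id n + 1).  Events are drawn in continuous
# time with piecewise-constant rates:
#   * coalescence within a population/allelic class at rate C(k,2) / (2N);
#   * recombination on a lineage at rate rho_bp * span;
#   * mutations are dropped as a Poisson process on total ancestral length
#     between events, each mutation inheriting the descendant set of the
#     segment it falls on (so no marginal trees are ever built).
# Material whose descendant set is complete (all samples + outgroup) has
# found its MRCA and is discarded.
#
# During an optional structured phase (a balanced polymorphism segregating
# at sel_pos, frequency trajectory x(t)), lineages live on one of two
# allelic backgrounds.  The class sizes are 2Nx and 2N(1-x); recombination
# spans include the distance to the selected site, and a breakpoint that
# separates a lineage's material from the selected site moves the material
# to a background drawn with probability x (Hudson-Kaplan background
# switching).  At the selection onset time all derived-background lineages
# coalesce into the single originating chromosome.

new_lineage <- function(segm, dsc, class) {
  len <- sum(segm[, 2] - segm[, 1])
  list(segs = segm, desc = dsc, cls = class,
       lo = segm[1, 1], hi = segm[nrow(segm), 2], len = len)
}

# Merge two lineages' segment structures; returns NULL when all material
# has reached its MRCA.
merge_lineages <- function(a, b, n_tot, class) {
  bps <- sort(unique(c(a$segs[, 1], a$segs[, 2], b$segs[, 1], b$segs[, 2])))
  lo <- bps[-length(bps)]
  hi <- bps[-1]
  mid <- (lo + hi) / 2
  ia <- findInterval(mid, a$segs[, 1])
  cov_a <- ia >= 1 & mid < a$segs[pmax(ia, 1L), 2]
  ib <- findInterval(mid, b$segs[, 1])
  cov_b <- ib >= 1 & mid < b$segs[pmax(ib, 1L), 2]
  keep <- cov_a | cov_b
  lo <- lo[keep]; hi <- hi[keep]
  ia <- ia[keep]; ib <- ib[keep]
  cov_a <- cov_a[keep]; cov_b <- cov_b[keep]
  dsc <- vector("list", length(lo))
  full <- logical(length(lo))
  for (i in seq_along(lo)) {
    d <- integer(0)
    if (cov_a[i]) d <- a$desc[[ia[i]]]
    if (cov_b[i]) d <- unique(c(d, b$desc[[ib[i]]]))
    dsc[[i]] <- d
    full[i] <- length(d) == n_tot
  }
  lo <- lo[!full]; hi <- hi[!full]; dsc <- dsc[!full]
  if (length(lo) == 0L) return(NULL)
  # fuse abutting intervals with identical descendant sets
  if (length(lo) > 1L) {
    fuse <- logical(length(lo))
    for (i in 2:length(lo)) {
      fuse[i] <- hi[i - 1] == lo[i] && identical(sort(dsc[[i - 1]]), sort(dsc[[i]]))
    }
    grp <- cumsum(!fuse)
    lo <- tapply(lo, grp, min)
    hi2 <- tapply(hi, grp, max)
    dsc <- dsc[!fuse]
    lo <- as.numeric(lo); hi <- as.numeric(hi2)
  }
  new_lineage(cbind(lo, hi), dsc, class)
}

split_lineage <- function(lin, b) {
  s <- lin$segs
  left_rows <- s[, 1] < b
  right_rows <- s[, 2] > b
  mk <- function(rows, clip_hi, clip_lo) {
    if (!any(rows)) return(NULL)
    sm <- s[rows, , drop = FALSE]
    dd <- lin$desc[rows]
    if (clip_hi) sm[nrow(sm), 2] <- min(sm[nrow(sm), 2], b)
    if (clip_lo) sm[1, 1] <- max(sm[1, 1], b)
    new_lineage(sm, dd, lin$cls)
  }
  list(left = mk(left_rows, clip_hi = TRUE, clip_lo = FALSE),
       right = mk(right_rows, clip_hi = FALSE, clip_lo = TRUE))
}

# One genealogy; returns list(pos = numeric, desc = list) of mutations.
# traj: NULL, or list(tbs = onset in generations, t_left = ascending left
# edges of the piecewise x(t) (first 0, last < tbs), x = frequency of the
# derived background per piece).  init_class: length-n vector, 1 = derived
# background, 2 = ancestral; required when traj is given.
sim_genealogy <- function(n, L, mu, rho, epochs, split_gen = Inf,
                          traj = NULL, init_class = NULL, sel_pos = L / 2) {
  has_og <- is.finite(split_gen)
  n_tot <- n + has_og
  lins <- vector("list", n_tot)
  for (i in seq_len(n)) {
    cl <- if (!is.null(traj)) init_class[i] else 2L
    lins[[i]] <- new_lineage(matrix(c(0, L), 1), list(i), cl)
  }
  if (has_og) lins[[n + 1L]] <- new_lineage(matrix(c(0, L), 1), list(n + 1L), 3L)

  tbs <- if (!is.null(traj)) traj$tbs else -1
  tb <- sort(unique(c(0, epochs$t_start,
                      if (!is.null(traj)) c(traj$t_left, tbs),
                      if (has_og) split_gen)))
  n_int <- length(tb)
  N_int <- epoch_N(epochs, tb)
  x_int <- rep(NA_real_, n_int)
  if (!is.null(traj)) {
    str_int <- tb < tbs
    x_int[str_int] <- traj$x[findInterval(tb[str_int], traj$t_left)]
  } else {
    str_int <- rep(FALSE, n_int)
  }

  mut_pos <- numeric(0)
  mut_desc <- list()
  drop_muts <- function(t0, t1) {
    if (t1 <= t0) return(invisible())
    tot <- sum(vapply(lins, function(l) l$len, 0))
    nm <- stats::rpois(1, mu * tot * (t1 - t0))
    if (nm == 0L) return(invisible())
    lens <- vapply(lins, function(l) l$len, 0)
    which_l <- sample.int(length(lins), nm, replace = TRUE, prob = lens)
    for (m in seq_len(nm)) {
      l <- lins[[which_l[m]]]
      seg_len <- l$segs[, 2] - l$segs[, 1]
      si <- if (nrow(l$segs) == 1L) 1L else
        sample.int(nrow(l$segs), 1L, prob = seg_len)
      p <- stats::runif(1, l$segs[si, 1], l$segs[si, 2])
      mut_pos[length(mut_pos) + 1L] <<- p
      mut_desc[[length(mut_desc) + 1L]] <<- l$desc[[si]]
    }
    invisible()
  }

  t <- 0
  j <- 1L
  merged_at_onset <- is.null(traj)
  og_joined <- !has_og
  guard <- 0L

  while (length(lins) >= 2L) {
    guard <- guard + 1L
    if (guard > 2e6L) stop_ncd("ncd_internal_error", "sim_genealogy: event cap exceeded")
    structured <- str_int[j]
    N <- N_int[j]
    x <- x_int[j]
    cls <- vapply(lins, function(l) l$cls, 0L)
    kA <- sum(cls == 1L)
    ka <- sum(cls == 2L)
    rateA <- if (structured) kA * (kA - 1) / 2 / (2 * N * x) else 0
    ratea <- if (structured) ka * (ka - 1) / 2 / (2 * N * (1 - x)) else
      ka * (ka - 1) / 2 / (2 * N)
    spans <- vapply(seq_along(lins), function(i) {
      l <- lins[[i]]
      if (l$cls == 3L) return(0)
      if (structured) max(l$hi, sel_pos) - min(l$lo, sel_pos) else l$hi - l$lo
    }, 0)
    rec_rates <- rho * spans
    R <- rateA + ratea + sum(rec_rates)
    t_next_b <- if (j < n_int) tb[j + 1L] else Inf
    dt <- if (R > 0) stats::rexp(1) / R else Inf
    if (t + dt >= t_next_b) {
      if (!is.finite(t_next_b)) {
        stop_ncd("ncd_internal_error", "sim_genealogy: no events possible")
      }
      drop_muts(t, t_next_b)
      t <- t_next_b
      j <- j + 1L
      if (!merged_at_onset && t >= tbs) {
        # all derived-background lineages descend from the single mutant
        idxA <- which(vapply(lins, function(l) l$cls, 0L) == 1L)
        while (length(idxA) >= 2L) {
          m <- merge_lineages(lins[[idxA[1]]], lins[[idxA[2]]], n_tot, 2L)
          lins[idxA[1]] <- list(m)
          lins[idxA[2]] <- list(NULL)
          lins <- lins[!vapply(lins, is.null, TRUE)]
          idxA <- which(vapply(lins, function(l) l$cls, 0L) == 1L)
        }
        for (i in seq_along(lins)) if (lins[[i]]$cls == 1L) lins[[i]]$cls <- 2L
        merged_at_onset <- TRUE
      }
      if (!og_joined && t >= split_gen) {
        for (i in seq_along(lins)) if (lins[[i]]$cls == 3L) lins[[i]]$cls <- 2L
        og_joined <- TRUE
      }
      next
    }
    drop_muts(t, t + dt)
    t <- t + dt
    u <- stats::runif(1, 0, R)
    if (u < rateA + ratea) {
      cc <- if (u < rateA) 1L else 2L
      idx <- which(cls == cc)
      pick <- sample(idx, 2L)
      m <- merge_lineages(lins[[pick[1]]], lins[[pick[2]]], n_tot, cc)
      lins[pick[1]] <- list(m)
      lins[pick[2]] <- list(NULL)
      lins <- lins[!vapply(lins, is.null, TRUE)]
    } else {
      u <- u - rateA - ratea
      i <- findInterval(u, cumsum(rec_rates)) + 1L
      l <- lins[[i]]
      lo_s <- if (structured) min(l$lo, sel_pos) else l$lo
      hi_s <- if (structured) max(l$hi, sel_pos) else l$hi
      b <- stats::runif(1, lo_s, hi_s)
      pieces <- split_lineage(l, b)
      if (structured) {
        sel_side <- if (b < sel_pos) "right" else "left"
        other_side <- if (sel_side == "right") "left" else "right"
        keep_piece <- pieces[[sel_side]]
        move_piece <- pieces[[other_side]]
        new_cls <- if (stats::runif(1) < x) 1L else 2L
        if (is.null(move_piece)) next          # breakpoint beyond material
        if (is.null(keep_piece)) {
          # all material detaches from the selected background
          move_piece$cls <- new_cls
          lins[[i]] <- move_piece
        } else {
          keep_piece$cls <- l$cls
          move_piece$cls <- new_cls
          lins[[i]] <- keep_piece
          lins[[length(lins) + 1L]] <- move_piece
        }
      } else {
        if (is.null(pieces$left) || is.null(pieces$right)) next
        pieces$left$cls <- l$cls
        pieces$right$cls <- l$cls
        lins[[i]] <- pieces$left
        lins[[length(lins) + 1L]] <- pieces$right
      }
    }
  }
  list(pos = mut_pos, desc = mut_desc, n_tot = n_tot)
}

# distinct integer bp in [0, L) from integer candidates (nudging collisions)
nudge_int_positions <- function(pos, L) {
  used <- logical(L)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    p <- min(max(pos[i], 0L), L - 1L) + 1L    # 1-based into 'used'
    while (p <= L && used[p]) p <- p + 1L
    if (p > L) {
      p <- min(max(pos[i], 0L), L - 1L) + 1L
      while (p >= 1L && used[p]) p <- p - 1L
      if (p < 1L) stop_config("more sites than available positions")
    }
    used[p] <- TRUE
    out[i] <- p - 1L
  }
  out
}

# genealogy output -> sim_replicate; sel_site: NULL or list(pos, carriers)
genealogy_to_replicate <- function(gen, n, L, sel_site = NULL) {
  pos <- gen$pos
  desc <- gen$desc
  o <- order(pos)
  pos <- pos[o]
  desc <- desc[o]
  carriers <- lapply(desc, function(d) d[d <= n])
  og <- vapply(desc, function(d) any(d == n + 1L), TRUE)
  visible <- vapply(seq_along(desc), function(i) {
    k <- length(carriers[[i]])
    (k > 0L && k < n) || (k == 0L && og[i]) || (k == n && !og[i])
  }, TRUE)
  pos <- pos[visible]; carriers <- carriers[visible]; og <- og[visible]
  ipos <- as.integer(floor(pos))
  if (!is.null(sel_site)) {
    ipos <- c(ipos, as.integer(sel_site$pos))
    carriers <- c(carriers, list(sel_site$carriers))
    og <- c(og, FALSE)
    o <- order(ipos)
    ipos <- ipos[o]; carriers <- carriers[o]; og <- og[o]
  }
  if (length(ipos)) ipos <- nudge_int_positions(ipos, L)
  o <- order(ipos)
  ipos <- ipos[o]; carriers <- carriers[o]; og <- og[o]
  S <- length(ipos)
  hap <- matrix(0L, nrow = n, ncol = S)
  for (jj in seq_len(S)) hap[carriers[[jj]], jj] <- 1L
  sim_replicate(hap, ipos, as.integer(og), L)
}
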