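#' Specify an overdominant balanced polymorphism
#'
#' Heterozygote advantage with genotype fitnesses
#' \code{w_AA = 1 - s_AA}, \code{w_Aa = 1}, \code{w_aa = 1 - s_aa} maintains
#' the derived allele A at the equilibrium frequency
#' \code{f_eq = s_aa / (s_AA + s_aa)}; symmetric costs give 0.5.
#'
#' @param f_eq Equilibrium frequency in (0, 1); together with
#'   \code{s_total} determines the homozygote costs
#'   \code{s_aa = f_eq * s_total}, \code{s_AA = (1 - f_eq) * s_total}.
#'   Alternatively pass \code{s_AA}/\code{s_aa} directly.
#' @param s_total Combined homozygote fitness cost \code{s_AA + s_aa};
#'   default 0.01 (strong enough that the polymorphism persists for
#'   millions of years at human effective sizes).
#' @param s_AA,s_aa Explicit homozygote costs (override \code{f_eq}).
#' @param tbs_ma Time since onset of balancing selection, in Ma.
#' @return Object of class \code{selection_model}.
#' @export
selection_model <- function(f_eq = 0.5, s_total = 0.01,
                            s_AA = NULL, s_aa = NULL, tbs_ma = 5) {
  if (is.null(s_AA) != is.null(s_aa)) {
    stop_config("selection_model: give both s_AA and s_aa, or neither")
  }
  if (is.null(s_AA)) {
    if (f_eq <= 0 || f_eq >= 1) stop_config("selection_model: f_eq must be in (0, 1)")
    s_aa <- f_eq * s_total
    s_AA <- (1 - f_eq) * s_total
  }
  if (s_AA < 0 || s_aa < 0) stop_config("selection_model: costs must be >= 0")
  if (s_AA + s_aa > 0 && (s_AA == 0 || s_aa == 0)) {
    stop_config("selection_model: f_eq unreachable with a zero homozygote cost")
  }
  f_eq <- if (s_AA + s_aa > 0) s_aa / (s_AA + s_aa) else NA_real_
  structure(list(s_AA = s_AA, s_aa = s_aa, f_eq = f_eq, tbs_ma = tbs_ma),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> s_AA = %g, s_aa = %g (f_eq = %s), onset %g Ma\n",
              x$s_AA, x$s_aa, format(x$f_eq), x$tbs_ma))
  invisible(x)
}

#' Forward Wright-Fisher allele-frequency trajectories under overdominance
#'
#' Diploid viability selection followed by binomial sampling of 2N gametes
#' per generation.  With both costs zero the process is neutral drift (a
#' martingale in the allele frequency).
#'
#' @param N Diploid population size (constant here; the balancing simulator
#'   layers the demographic model on top).
#' @param s_AA,s_aa Homozygote fitness costs (heterozygote fitness 1).
#' @param x0 Initial frequency of A.
#' @param n_gen Number of generations to iterate.
#' @param n_reps Number of independent trajectories.
#' @param record \code{"final"} returns the final frequency per replicate;
#'   \code{"full"} returns an \code{(n_gen + 1) x n_reps} matrix.
#' @return Numeric vector or matrix of allele frequencies.
#' @export
wf_trajectory <- function(N, s_AA, s_aa, x0, n_gen, n_reps = 1,
                          record = c("final", "full")) {
  record <- match.arg(record)
  if (N < 1 || n_gen < 0) stop_config("wf_trajectory: bad N or n_gen")
  x <- rep(x0, n_reps)
  full <- if (record == "full") matrix(NA_real_, n_gen + 1, n_reps) else NULL
  if (!is.null(full)) full[1, ] <- x
  for (g in seq_len(n_gen)) {
    x <- stats::rbinom(n_reps, 2 * N, wf_expected_freq(x, s_AA, s_aa)) / (2 * N)
    if (!is.null(full)) full[g + 1, ] <- x
  }
  if (record == "full") full else x
}

# deterministic one-generation map under overdominant viability selection
wf_expected_freq <- function(x, s_AA, s_aa) {
  w_AA <- 1 - s_AA
  w_aa <- 1 - s_aa
  wbar <- x^2 * w_AA + 2 * x * (1 - x) + (1 - x)^2 * w_aa
  (x^2 * w_AA + x * (1 - x)) / wbar
}

# Batch of conditioned trajectories over the selected phase, rescaled.
# Returns chunk means of x (forward order), final frequencies and the
# number of discarded (lost/fixed) trajectories.
balancing_trajectories <- function(model, sel, scaling, n_reps,
                                   n_chunks = 200L, max_tries = 60L) {
  gt <- model$generation_time
  tbs_gen <- sel$tbs_ma * 1e6 / gt
  G <- max(2L, as.integer(round(tbs_gen / scaling)))
  chunk <- ceiling(G / n_chunks)
  n_chunks <- as.integer(ceiling(G / chunk))
  s_AA <- sel$s_AA * scaling
  s_aa <- sel$s_aa * scaling
  if (s_AA >= 1 || s_aa >= 1) {
    stop_config("balancing_trajectories: scaled costs must stay below 1; lower scaling")
  }
  # scaled diploid size per scaled generation (forward: g = 1 is the onset)
  t_ago <- (G - seq_len(G)) * scaling
  Ns <- pmax(2L, as.integer(round(epoch_N(model$epochs, t_ago) / scaling)))
  x0 <- 1 / (2 * Ns[1])

  got <- 0L
  n_redraws <- 0L
  chunk_x <- matrix(NA_real_, n_chunks, n_reps)
  x_final <- numeric(n_reps)
  tries <- 0L
  while (got < n_reps) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_config("balancing_trajectories: conditioning failed after %d batches", tries)
    }
    m <- min(20000L, max(2L * (n_reps - got), 100L))
    x <- rep(x0, m)
    cs <- matrix(0, n_chunks, m)
    alive <- rep(TRUE, m)
    for (g in seq_len(G)) {
      ia <- which(alive)
      if (length(ia) == 0L) break
      p <- wf_expected_freq(x[ia], s_AA, s_aa)
      x[ia] <- stats::rbinom(length(ia), 2 * Ns[g], p) / (2 * Ns[g])
      ci <- ((g - 1L) %/% chunk) + 1L
      cs[ci, ia] <- cs[ci, ia] + x[ia]
      alive[ia] <- x[ia] > 0 & x[ia] < 1
    }
    ok <- which(alive)
    n_redraws <- n_redraws + (m - length(ok))
    if (length(ok) == 0L) next
    take <- ok[seq_len(min(length(ok), n_reps - got))]
    # per-chunk generation counts (last chunk may be short)
    gl <- rep(chunk, n_chunks)
    gl[n_chunks] <- G - chunk * (n_chunks - 1L)
    cols <- got + seq_along(take)
    chunk_x[, cols] <- cs[, take, drop = FALSE] / gl
    x_final[cols] <- x[take]
    got <- got + length(take)
  }
  # clamp: a surviving trajectory never sits exactly at 0 or 1 on average
  chunk_x[chunk_x <= 0] <- x0 / 2
  chunk_x[chunk_x >= 1] <- 1 - x0 / 2
  list(chunk_x = chunk_x, x_final = x_final, n_redraws = n_redraws,
       tbs_gen = tbs_gen, chunk_gen = chunk * scaling, G = G,
       n_chunks = n_chunks)
}

#' Simulate replicates with an overdominant balanced polymorphism
#'
#' Two-stage design.  (1) The frequency of the balanced allele is simulated
#' forward in time from its origin (one copy at the onset time) with a
#' rescaled Wright-Fisher model (population size and time divided by
#' \code{scaling}, selection coefficients multiplied), conditioned on the
#' polymorphism surviving to sampling; lost or fixed trajectories are
#' redrawn and counted.  (2) Linked neutral variation is generated on the
#' structured genealogy implied by the trajectory: backward in time,
#' lineages live on the derived or ancestral background (class sizes
#' \code{2Nx(t)} and \code{2N(1-x(t))}) and switch backgrounds by
#' recombination at a rate proportional to their distance from the selected
#' site; at the onset all derived-background lineages coalesce into the
#' originating chromosome, and the process continues as the neutral
#' coalescent (including the outgroup lineage).  The balanced site itself
#' is placed at the sequence midpoint.
#'
#' @inheritParams simulate_neutral
#' @param sel A [selection_model()].
#' @param scaling Rescaling factor (>= 1) for the forward stage.
#' @return List of [sim_replicate()] objects with attribute
#'   \code{n_redraws} (discarded trajectories during conditioning).
#' @export
simulate_balancing <- function(model, sel, n = 100, L = 3000, mu = 2.5e-8,
                               rho = 1e-8, outgroup_split_ma = 6.5,
                               n_reps = 1, seed = NULL, scaling = 10) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(sel, "selection_model"))
  if (scaling < 1) stop_config("simulate_balancing: scaling must be >= 1")
  if (sel$s_AA + sel$s_aa <= 0) {
    # neutral reduction: no balanced site, plain neutral replicates
    return(simulate_neutral(model, n, L, mu, rho, outgroup_split_ma,
                            n_reps, seed))
  }
  if (!is.null(seed)) set.seed(seed)
  gt <- model$generation_time
  split_gen <- if (is.na(outgroup_split_ma)) Inf else
    outgroup_split_ma * 1e6 / gt
  tbs_gen <- sel$tbs_ma * 1e6 / gt
  if (tbs_gen >= split_gen) {
    stop_config("simulate_balancing: selection onset must postdate the outgroup split")
  }
  tr <- balancing_trajectories(model, sel, scaling, n_reps)
  sel_pos <- L / 2
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    # backward-time piecewise x(t): reverse the forward chunk means
    xb <- rev(tr$chunk_x[, i])
    t_left <- (seq_along(xb) - 1L) * tr$chunk_gen
    nA <- stats::rbinom(1, n, tr$x_final[i])
    init_class <- rep(2L, n)
    if (nA > 0) init_class[seq_len(nA)] <- 1L
    traj <- list(tbs = tr$tbs_gen, t_left = t_left, x = xb)
    gen <- sim_genealogy(n, L, mu, rho, model$epochs, split_gen = split_gen,
                         traj = traj, init_class = init_class,
                         sel_pos = sel_pos)
    sel_site <- if (nA > 0) list(pos = floor(sel_pos), carriers = seq_len(nA))
                else NULL
    reps[[i]] <- genealogy_to_replicate(gen, n, L, sel_site = sel_site)
  }
  attr(reps, "n_redraws") <- tr$n_redraws
  reps
}
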