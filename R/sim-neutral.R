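#' Simulate neutral replicates with an outgroup lineage
#'
#' Coalescent with recombination under a piecewise demographic model, with a
#' single outgroup lineage that joins the ancestral population at the
#' human-chimp split.  Mutations are dropped as a Poisson process on the
#' ancestral-recombination-graph branches; each replicate's sites are
#' classified into sample SNPs and fixed differences exactly as the VCF /
#' outgroup reader would classify them.
#'
#' @param model A [demographic_model()].
#' @param n Number of sampled chromosomes (>= 2).
#' @param L Sequence length in bp.
#' @param mu Mutation rate per site per generation.
#' @param rho Recombination rate per site per generation.
#' @param outgroup_split_ma Human-chimp split in Ma (converted with the
#'   model's generation time); \code{NA} drops the outgroup lineage (no
#'   fixed differences; NCD1-only simulations).
#' @param n_reps Number of replicates.
#' @param seed Integer seed; the replicate set is bit-identical for a fixed
#'   seed.
#' @return List of [sim_replicate()] objects.
#' @export
simulate_neutral <- function(model, n = 100, L = 3000, mu = 2.5e-8,
                             rho = 1e-8, outgroup_split_ma = 6.5,
                             n_reps = 1, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (n < 2) stop_config("simulate_neutral: n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  split_gen <- if (is.na(outgroup_split_ma)) Inf else
    outgroup_split_ma * 1e6 / model$generation_time
  lapply(seq_len(n_reps), function(i) {
    gen <- sim_genealogy(n, L, mu, rho, model$epochs, split_gen = split_gen)
    genealogy_to_replicate(gen, n, L)
  })
}
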