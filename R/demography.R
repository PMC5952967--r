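#' Piecewise demographic models for the coalescent simulator
#'
#' Single-population piecewise-constant effective-size histories.  The
#' shipped \code{"african"} and \code{"european"} models follow the Gravel
#' et al. (2011) inference for human populations with a generation time of
#' 25 years: an ancestral size of 7,310 diploids, African expansion to
#' 14,474 at 148 kya, and for Europe an out-of-Africa bottleneck (1,861
#' diploids at 51 kya) followed by a second bottleneck to 1,032 at 23 kya
#' with exponential growth at 0.38% per generation to the present.  Growth
#' epochs are discretized into piecewise-constant steps
#' (\code{growth_steps}); continental migration is not modeled.
#'
#' @param population One of \code{"african"}, \code{"european"},
#'   \code{"constant"}.
#' @param N0 Diploid size for the \code{"constant"} model.
#' @param generation_time Years per generation (used to convert Ma to
#'   generations downstream).
#' @param growth_steps Number of piecewise-constant steps used to
#'   approximate an exponential-growth epoch.
#' @return Object of class \code{demographic_model} with an \code{epochs}
#'   data.frame (\code{t_start} in generations ago, ascending from 0;
#'   \code{N} diploid size).
#' @export
demographic_model <- function(population = c("african", "european", "constant"),
                              N0 = 10000, generation_time = 25,
                              growth_steps = 24) {
  population <- match.arg(population)
  kya <- function(y) y * 1000 / generation_time
  epochs <- switch(population,
    constant = data.frame(t_start = 0, N = N0),
    african = data.frame(t_start = c(0, kya(148)), N = c(14474, 7310)),
    european = {
      t_growth <- kya(23)            # 920 generations
      r <- 0.0038                    # per-generation growth rate
      n_eu0 <- 1032                  # size at onset of growth (23 kya)
      # discretize N(t) = n_eu0 * exp(r * (t_growth - t)) over [0, t_growth)
      edges <- seq(0, t_growth, length.out = growth_steps + 1)
      mids <- (edges[-1] + edges[-length(edges)]) / 2
      rbind(
        data.frame(t_start = edges[-length(edges)],
                   N = n_eu0 * exp(r * (t_growth - mids))),
        data.frame(t_start = c(t_growth, kya(51), kya(148)),
                   N = c(1861, 14474, 7310))
      )
    })
  validate_epochs(epochs)
  structure(list(label = population, epochs = epochs,
                 generation_time = generation_time),
            class = "demographic_model")
}

validate_epochs <- function(epochs) {
  if (!is.data.frame(epochs) || !all(c("t_start", "N") %in% names(epochs))) {
    stop_config("epochs must be a data.frame with t_start and N")
  }
  if (epochs$t_start[1] != 0 || is.unsorted(epochs$t_start, strictly = TRUE)) {
    stop_config("epoch t_start must start at 0 and be strictly increasing")
  }
  if (any(epochs$N <= 0)) stop_config("epoch sizes must be positive")
  invisible(epochs)
}

#' Build a demographic model from explicit epochs
#'
#' @param epochs data.frame with \code{t_start} (generations ago, first row
#'   0, strictly increasing) and \code{N} (diploid size).
#' @param label Model label.
#' @inheritParams demographic_model
#' @export
demographic_model_from_epochs <- function(epochs, label = "custom",
                                          generation_time = 25) {
  validate_epochs(epochs)
  structure(list(label = label, epochs = epochs,
                 generation_time = generation_time),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s (%d epochs, generation time %g y)\n",
              x$label, nrow(x$epochs), x$generation_time))
  invisible(x)
}

# diploid size at time t (generations ago)
epoch_N <- function(epochs, t) {
  epochs$N[findInterval(t, epochs$t_start)]
}
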