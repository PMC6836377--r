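#' Parameters of the fission-growth model
#'
#' A discrete weekly branching process emulating asexual planarian culture:
#' each week every individual independently survives with probability
#' \code{1 - death_p}, and each survivor fissions into two with probability
#' \code{fission_p}, so the expected weekly growth factor is
#' \code{(1 - death_p) * (1 + fission_p)}. Defaults match the standard
#' breeding test: 10 starting animals followed for 6 weeks in 3 independent
#' batches.
#'
#' @param n0 starting individuals per batch (> 0 integer).
#' @param fission_p per-individual per-week fission probability in [0, 1].
#' @param death_p per-individual per-week death probability in [0, 1].
#' @param weeks number of weeks followed (>= 1).
#' @param n_batches number of independent batches (>= 1).
#' @return an object of class \code{growth_params}.
#' @export
growth_params <- function(n0 = 10, fission_p = 0.2, death_p = 0,
                          weeks = 6, n_batches = 3) {
  stopifnot(n0 >= 1, n0 == round(n0),
            fission_p >= 0, fission_p <= 1, death_p >= 0, death_p <= 1,
            weeks >= 1, weeks == round(weeks),
            n_batches >= 1, n_batches == round(n_batches))
  structure(list(n0 = as.integer(n0), fission_p = fission_p,
                 death_p = death_p, weeks = as.integer(weeks),
                 n_batches = as.integer(n_batches)),
            class = "growth_params")
}

#' Simulate weekly population counts under fission growth
#'
#' @param params a \code{\link{growth_params}}.
#' @param seed integer seed.
#' @return a data.frame with columns \code{batch}, \code{week} (0 ..
#'   \code{weeks}; week 0 holds \code{n0}) and \code{count} (non-negative
#'   integers). Reproducible from \code{seed}.
#' @examples
#' counts <- simulate_population(growth_params(fission_p = 0.5), seed = 1)
#' @export
simulate_population <- function(params, seed) {
  stopifnot(inherits(params, "growth_params"))
  set.seed(as.integer(seed))
  out <- vector("list", params$n_batches)
  for (b in seq_len(params$n_batches)) {
    n <- integer(params$weeks + 1L)
    n[1L] <- params$n0
    for (w in seq_len(params$weeks)) {
      surv <- stats::rbinom(1L, n[w], 1 - params$death_p)
      fiss <- stats::rbinom(1L, surv, params$fission_p)
      n[w + 1L] <- surv + fiss
    }
    out[[b]] <- data.frame(batch = b, week = 0:params$weeks, count = n)
  }
  do.call(rbind, out)
}
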