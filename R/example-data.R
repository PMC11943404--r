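#' Synthetic alternate-uses fluency dataset
#'
#' Generates a dataset shaped like a typical three-task alternate-uses
#' fluency study: 202 persons, 3 items, one person (the last) observed
#' on a single item only, equal slopes of 0.34 and easiness values
#' around 2 on the log-count scale (so expected counts near 6-8 ideas at
#' average ability and observed scores spanning roughly 1-23). The true
#' generating parameters are returned alongside the data.
#'
#' @param seed integer seed.
#' @param n_persons number of persons (default 202).
#' @param easiness per-item easiness (default `c(2.06, 1.74, 2.07)`).
#' @param slope per-item slopes (default all 0.34; equal slopes make the
#'   RPCM the generating model even when fit as a 2PPCM).
#' @return A list with `data` (a [count_data] with `3 * (n_persons - 1)
#'   + 1` records), `theta` (true abilities), and `params` (the true
#'   [item_params]).
#' @export
#' @examples
#' ex <- simulate_example_dataset(seed = 1)
#' ex$data
simulate_example_dataset <- function(seed = 1, n_persons = 202,
                                     easiness = c(2.06, 1.74, 2.07),
                                     slope = c(0.34, 0.34, 0.34)) {
  ip <- item_params(c("I1", "I2", "I3"), easiness, slope,
                    model_kind = if (length(unique(slope)) == 1L)
                      "RPCM" else "2PPCM")
  miss <- cbind(person = c(n_persons, n_persons), item = c(2L, 3L))
  sim <- simulate_dataset(sim_config(n_persons, ip,
                                     missing_pattern = miss,
                                     seed = seed))
  c(sim, list(params = ip))
}
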