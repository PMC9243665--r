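#' Encode the conditioned stimulus on the mossy fibers
#'
#' One independent 40-Hz Poisson realization per mossy fiber over the CS
#' support `[cs_onset, cs_onset + cs_duration)`; trains differ across fibers
#' and across trials (non-recurrent patterns, maximizing granule-layer
#' pattern diversity).
#'
#' @param n_mf Number of mossy fibers, >= 1.
#' @param cfg A [protocol_config()].
#' @return List of `n_mf` sorted spike-time vectors (ms).
#' @export
encode_cs <- function(n_mf, cfg = protocol_config()) {
  stopifnot(n_mf >= 1)
  dur <- cfg$cs_duration
  lapply(seq_len(n_mf), function(i) {
    n <- rpois(1, cfg$cs_rate * dur / 1000)
    sort(cfg$cs_onset + runif(n) * dur)
  })
}

#' Encode the unconditioned stimulus on the inferior olive
#'
#' A deterministic regular burst at `us_rate` over
#' `[us_onset, us_onset + us_duration)`, identical for every IO cell
#' (shared teaching signal co-terminating with the CS).
#'
#' @param n_io Number of IO cells, >= 1.
#' @param cfg A [protocol_config()].
#' @return List of `n_io` identical spike-time vectors (ms).
#' @export
encode_us <- function(n_io, cfg = protocol_config()) {
  stopifnot(n_io >= 1)
  isi <- 1000 / cfg$us_rate
  train <- seq(cfg$us_onset, cfg$us_onset + cfg$us_duration - isi / 2, by = isi)
  lapply(seq_len(n_io), function(i) train)
}

#' Build the per-trial stimulus sets of one session
#'
#' Draws a fresh CS realization for every trial from the session's CS stream
#' and attaches the (deterministic) US burst when `paired` is `TRUE`.
#'
#' @param connectome A `connectome` (supplies mossy-fiber and IO counts).
#' @param cfg A [protocol_config()].
#' @param seed Seed of the CS stream.
#' @param paired If `FALSE` the US is omitted (CS-alone trials).
#' @return List of `n_trials` elements, each with `cs` (list of mf trains)
#'   and `us` (list of IO trains, empty vectors when unpaired).
#' @export
make_session_stimuli <- function(connectome, cfg = protocol_config(),
                                 seed = 1, paired = TRUE) {
  n_mf <- pop_size(connectome, "mf")
  n_io <- pop_size(connectome, "IO")
  us <- if (paired) encode_us(n_io, cfg)
        else lapply(seq_len(n_io), function(i) numeric(0))
  with_seed(derive_seed(seed, "cs"), {
    lapply(seq_len(cfg$n_trials), function(trial)
      list(cs = encode_cs(n_mf, cfg), us = us))
  })
}
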