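#' Instantaneous conductance-based synaptic current
#'
#' @param g Conductance (nS), >= 0.
#' @param V Postsynaptic membrane potential (mV).
#' @param E_rev Reversal potential (mV).
#' @return Current in pA: `g * (E_rev - V)`.
#' @export
synaptic_current <- function(g, V, E_rev) {
  if (!all(is.finite(c(g, V, E_rev)))) stop("non-finite input")
  stopifnot(all(g >= 0))
  g * (E_rev - V)
}

#' Conductance time course after presynaptic spikes
#'
#' Exponential decay between spikes; each presynaptic spike (after its
#' transmission delay) increments the conductance by the synaptic weight.
#'
#' @param t Evaluation times (ms).
#' @param spike_times Presynaptic spike times (ms).
#' @param weight Weight (nS).
#' @param tau_syn Decay constant (ms), > 0.
#' @param delay Transmission delay (ms), > 0.
#' @return Conductance (nS) at `t`.
#' @export
conductance_trace <- function(t, spike_times, weight, tau_syn, delay = 1) {
  stopifnot(tau_syn > 0, delay > 0)
  g <- numeric(length(t))
  for (ts in spike_times + delay) {
    on <- t >= ts
    g[on] <- g[on] + weight * exp(-(t[on] - ts) / tau_syn)
  }
  g
}

#' Supervised spike-timing plasticity at pf-PC synapses
#'
#' Batch update driven by the inferior-olive teaching signal: every
#' parallel-fiber spike that falls within `teaching_window` ms before (or
#' exactly at) a spike of the target Purkinje cell's climbing-fiber source is
#' depressed by `ltd_step`; every other parallel-fiber spike is potentiated
#' by `ltp_step`. Results are clipped to `[w_min, w_max]`. Purkinje cells
#' without a climbing-fiber source (e.g. after a lesion) receive LTP only.
#'
#' @param pf_spikes List (one element per synapse) of sorted presynaptic
#'   spike times (ms).
#' @param io_spikes List (one element per Purkinje cell) of sorted teaching
#'   spike times; an empty vector means no teaching signal.
#' @param target Integer vector mapping each synapse to its Purkinje cell
#'   (index into `io_spikes`).
#' @param weights Numeric vector of current weights, one per synapse.
#' @param params A [plasticity_config()].
#' @return Updated weight vector.
#' @export
apply_pf_pc_plasticity <- function(pf_spikes, io_spikes, target, weights,
                                   params = plasticity_config()) {
  if (length(pf_spikes) != length(weights) ||
      length(target) != length(weights))
    stop("pf_spikes, target and weights must have one entry per synapse")
  if (any(target < 1 | target > length(io_spikes)))
    stop("target indices outside io_spikes range")
  W <- params$teaching_window
  new_w <- weights
  for (i in seq_along(weights)) {
    tp <- pf_spikes[[i]]
    if (!length(tp)) next
    ios <- io_spikes[[target[i]]]
    if (length(ios)) {
      # first teaching spike at or after each pf spike
      j <- findInterval(tp, ios, left.open = TRUE) + 1L
      ltd <- j <= length(ios) & (ios[pmin(j, length(ios))] - tp) <= W
      n_ltd <- sum(ltd)
    } else n_ltd <- 0L
    n_ltp <- length(tp) - n_ltd
    new_w[i] <- new_w[i] + params$ltp_step * n_ltp - params$ltd_step * n_ltd
  }
  pmin(params$w_max, pmax(params$w_min, new_w))
}
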