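# Small network configuration used by simulation-heavy unit tests: granular
# and molecular layers at one fifth of the default size (PC count stays 99).
small_config <- function(...) {
  ebcc_config(network = default_network_config(scale = 0.2), ...)
}

small_connectome <- function(seed = 1) {
  build_connectome(default_network_config(scale = 0.2), seed = seed)
}

# two-population toy: one spike-source "mf" feeding one LIF-like cell wired
# as a minimal connectome (used by engine unit tests)
toy_config <- function(weight = 50, delay = 2, sign = +1) {
  list(
    populations = list(mf = list(size = 1), DCN = list(size = 1)),
    connections = list(
      `mf-DCN` = list(source = "mf", target = "DCN", convergence = 1,
                      weight = weight, delay = delay, sign = sign,
                      plastic = FALSE)
    ),
    scale = 1
  )
}

toy_neuron_params <- function(I_e = 0) {
  list(DCN = list(Cm = 100, tau_m = 20, E_rest = -60, V_th = -50,
                  V_reset = -70, t_ref = 2, I_e = I_e, k_adap = 0, k1 = 0,
                  k2 = 0, A1 = 0, A2 = 0, tau_exc = 2, tau_inh = 5,
                  E_exc = 0, E_inh = -80, rest_rate = 0, I_e_jitter = 0))
}

# brute-force reference: per-pair double loop over pf and teaching spikes
brute_force_plasticity <- function(pf_spikes, io_spikes, target, weights, p,
                                   efficacy = rep(1, length(io_spikes))) {
  out <- weights
  for (i in seq_along(weights)) {
    ios <- io_spikes[[target[i]]]
    for (tp in pf_spikes[[i]]) {
      ltd <- FALSE
      for (s in ios) if (s >= tp && s - tp <= p$teaching_window) {
        ltd <- TRUE; break
      }
      out[i] <- out[i] + if (ltd) -p$ltd_step * efficacy[target[i]]
                         else p$ltp_step
    }
  }
  pmin(p$w_max, pmax(p$w_min, out))
}

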