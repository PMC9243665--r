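#' E-GLIF parameter set
#'
#' Validated constructor for the extended generalized leaky
#' integrate-and-fire parameters of one population.
#'
#' @param Cm Membrane capacitance (pF), > 0.
#' @param tau_m Membrane time constant (ms), > 0.
#' @param E_rest Resting potential (mV).
#' @param V_th Spike threshold (mV).
#' @param V_reset Reset potential (mV), must not exceed `V_th`.
#' @param t_ref Absolute refractory period (ms), > 0.
#' @param I_e Constant endogenous current (pA).
#' @param k_adap Adaptation coupling (pA/(mV*ms)), >= 0.
#' @param k1 Decay rate of the spike-triggered depolarizing current (1/ms).
#' @param k2 Decay rate of the adaptation current (1/ms).
#' @param A1 Spike-triggered depolarizing current increment (pA).
#' @param A2 Spike-triggered adaptation current increment (pA).
#' @return List of class `eglif_params`.
#' @export
eglif_params <- function(Cm, tau_m, E_rest, V_th, V_reset, t_ref, I_e = 0,
                         k_adap = 0, k1 = 0, k2 = 0, A1 = 0, A2 = 0) {
  stopifnot(Cm > 0, tau_m > 0, t_ref > 0, k1 >= 0, k2 >= 0,
            V_reset <= V_th)
  structure(list(Cm = Cm, tau_m = tau_m, E_rest = E_rest, V_th = V_th,
                 V_reset = V_reset, t_ref = t_ref, I_e = I_e,
                 k_adap = k_adap, k1 = k1, k2 = k2, A1 = A1, A2 = A2),
            class = "eglif_params")
}

#' Initial neuron state
#'
#' @param params An `eglif_params` (or plain list with the same fields).
#' @param V Membrane potential (mV), default resting.
#' @return List with `V`, `I_adap`, `I_dep` (pA) and `refractory` (ms).
#' @export
neuron_state <- function(params, V = params$E_rest) {
  list(V = V, I_adap = 0, I_dep = 0, refractory = 0)
}

param_vector <- function(p) {
  c(p$Cm, p$tau_m, p$E_rest, p$V_th, p$V_reset, p$t_ref, p$I_e,
    p$k_adap, p$k1, p$k2, p$A1, p$A2)
}

#' Advance one E-GLIF neuron by one time step
#'
#' Exponential-Euler update of the linear three-state dynamics
#' \deqn{dV/dt = -(V - E_{rest})/\tau_m + (I_e + I_{dep} - I_{adap} + I_{syn})/C_m}
#' \deqn{dI_{adap}/dt = k_{adap}(V - E_{rest}) - k_2 I_{adap}, \quad
#'       dI_{dep}/dt = -k_1 I_{dep}}
#' with the coupling terms frozen over the step. The spike test is applied at
#' the step end; on a spike V is reset, `A1`/`A2` are added to the
#' depolarizing/adaptation currents and the absolute refractory period
#' starts, during which V stays clamped at the reset value.
#'
#' @param state Neuron state, see [neuron_state()].
#' @param params An `eglif_params`.
#' @param I_syn Total synaptic current over the step (pA).
#' @param dt Step (ms), in (0, 0.5].
#' @return List `state` (updated) and `spiked` (logical).
#' @export
step_neuron <- function(state, params, I_syn = 0, dt = 0.1) {
  stopifnot(dt > 0, dt <= 0.5)
  if (!all(is.finite(c(state$V, state$I_adap, state$I_dep, I_syn))))
    stop("non-finite neuron state or input")
  p <- params
  e2 <- exp(-p$k2 * dt)
  cad <- if (p$k2 > 0) (p$k_adap / p$k2) * (1 - e2) else p$k_adap * dt
  ia <- state$I_adap * e2 + cad * (state$V - p$E_rest)
  id <- state$I_dep * exp(-p$k1 * dt)
  if (state$refractory > 0) {
    return(list(state = list(V = p$V_reset, I_adap = ia, I_dep = id,
                             refractory = max(0, state$refractory - dt)),
                spiked = FALSE))
  }
  vinf <- p$E_rest + p$tau_m * (p$I_e + id - ia + I_syn) / p$Cm
  v <- vinf + (state$V - vinf) * exp(-dt / p$tau_m)
  if (v >= p$V_th) {
    list(state = list(V = p$V_reset, I_adap = ia + p$A2, I_dep = id + p$A1,
                      refractory = p$t_ref),
         spiked = TRUE)
  } else {
    list(state = list(V = v, I_adap = ia, I_dep = id, refractory = 0),
         spiked = FALSE)
  }
}

#' Simulate one isolated E-GLIF neuron
#'
#' @param params An `eglif_params` (or per-population entry of
#'   [default_neuron_params()]).
#' @param duration Simulated time (ms).
#' @param dt Step (ms).
#' @param I_in Extra constant input current (pA), added to `I_e`.
#' @param spikes_in Optional presynaptic spike times (ms) driving a
#'   conductance-based synapse.
#' @param w_in,tau_syn,E_rev Synapse weight (nS), decay (ms) and reversal
#'   potential (mV) for `spikes_in`.
#' @param record_v Record the voltage trace?
#' @param V0 Initial membrane potential (mV).
#' @return List with `spikes` (times, ms), `V` (trace if recorded), `rate`
#'   (Hz) and final `state`.
#' @export
simulate_neuron <- function(params, duration, dt = 0.1, I_in = 0,
                            spikes_in = numeric(0), w_in = 1, tau_syn = 2,
                            E_rev = 0, record_v = FALSE,
                            V0 = params$E_rest) {
  n_steps <- round(duration / dt)
  res <- cpp_simulate_neuron(param_vector(params), dt, n_steps, I_in,
                             as.numeric(spikes_in), w_in, tau_syn, E_rev,
                             record_v, V0, 0, 0)
  res$rate <- length(res$spikes) / (duration / 1000)
  res
}

#' Tune the endogenous current to a target resting rate
#'
#' Monotone bisection on `I_e` so that the isolated neuron fires within 5%
#' of `target_rate` over 10 s of simulated time (firing rate is
#' non-decreasing in the endogenous current).
#'
#' @param params An `eglif_params`.
#' @param target_rate Target rate (Hz), >= 0.
#' @param dt Step (ms).
#' @param duration Simulated time used per evaluation (ms).
#' @param bounds Search interval for `I_e` (pA).
#' @return The tuned `I_e` (pA).
#' @export
tune_endogenous_current <- function(params, target_rate, dt = 0.1,
                                    duration = 10000, bounds = c(0, 5000)) {
  stopifnot(target_rate >= 0)
  rate_at <- function(ie) {
    p <- params; p$I_e <- ie
    simulate_neuron(p, duration, dt = dt)$rate
  }
  if (target_rate == 0) {
    # largest current keeping the neuron silent: just return a subthreshold one
    return(0)
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (rate_at(hi) < target_rate)
    stop("target rate unreachable within current bounds")
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) <= 0.05 * target_rate) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
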