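#' Default E-GLIF parameters per population
#'
#' Per-population parameters of the extended generalized leaky
#' integrate-and-fire neuron (membrane constants, threshold/reset, endogenous
#' current, adaptation and spike-triggered depolarizing currents) together
#' with receptor time constants / reversal potentials and the resting-rate
#' target used to tune the endogenous current. Values are calibrated defaults
#' chosen to satisfy physiological resting rates of the cerebellar populations
#' and the Purkinje-cell burst-pause response to climbing-fiber input; they
#' are configuration, not measurements.
#'
#' @return Named list (one entry per spiking population) of parameter lists.
#'   Fields: `Cm` (pF), `tau_m` (ms), `E_rest`, `V_th`, `V_reset` (mV),
#'   `t_ref` (ms), `I_e` (pA), `k_adap` (pA/(mV*ms)), `k1`, `k2` (1/ms),
#'   `A1`, `A2` (pA), `tau_exc`, `tau_inh` (ms), `E_exc`, `E_inh` (mV),
#'   `rest_rate` (Hz, resting-rate target of the population) and
#'   `I_e_jitter` (pA, half-width of the uniform per-cell spread of the
#'   endogenous current emulating intrinsic-excitability heterogeneity).
#' @export
default_neuron_params <- function() {
  p <- function(Cm, tau_m, E_rest, V_th, V_reset, t_ref, I_e,
                k_adap, k1, k2, A1, A2, tau_exc, tau_inh, rest_rate,
                I_e_jitter) {
    list(Cm = Cm, tau_m = tau_m, E_rest = E_rest, V_th = V_th,
         V_reset = V_reset, t_ref = t_ref, I_e = I_e, k_adap = k_adap,
         k1 = k1, k2 = k2, A1 = A1, A2 = A2,
         tau_exc = tau_exc, tau_inh = tau_inh, E_exc = 0, E_inh = -80,
         rest_rate = rest_rate, I_e_jitter = I_e_jitter)
  }
  list(
    GrC      = p(7,   25, -62, -41, -70, 1.5,   0,   0.02, 0.3, 0.04,   5,   2, 1.9, 4.5,  0,   0),
    GoC      = p(145, 44, -62, -55, -75, 2.0, 28.1,  0.01, 0.2, 0.05,   0,  10, 5.0, 5.0,  8,   1),
    PC       = p(334, 47, -59, -43, -69, 0.8, 937.5, 0.50, 0.2, 0.05, 100, 300, 1.1, 2.8, 60,  20),
    MLI      = p(14.6,10, -68, -53, -78, 1.6, 23.5,  0.01, 0.3, 0.10,   0,   2, 120, 2.0, 20,   1),
    DCN      = p(142, 33, -45, -36, -55, 1.5,  47,   0.00, 0.1, 0.02,   0,   0, 2.0, 5.0, 15,   2),
    DCN_GABA = p(56,  50, -50, -39, -55, 3.0, 14.7,  0.01, 0.1, 0.05,  10,  10, 3.0, 5.0,  5,   1),
    IO       = p(189, 11, -45, -35, -45, 1.0, 266,   0.50, 0.1, 0.05,   0,  50, 1.0, 10.0, 1.5, 3)
  )
}

#' Default network configuration
#'
#' Population sizes and per-group wiring (mean inbound convergence per target
#' cell, weight, delay, sign) of the olivocerebellar microcircuit. The
#' Purkinje population is fixed at 99 cells; granular/molecular-layer sizes
#' are reduced-scale defaults, and `scale` multiplies them (and the
#' convergences of groups whose source is scaled) for faster experiments.
#' The per-target convergences of excitatory (`pf`, `aa`, climbing-fiber) and
#' inhibitory (MLI) inputs to Purkinje cells are calibrated so the structural
#' excitatory/inhibitory synapse ratio onto PCs equals 62.3 at scale 1.
#'
#' @param scale Multiplier (> 0) for mossy-fiber, granule, Golgi and
#'   molecular-layer interneuron counts.
#' @return A list with `populations`, `connections` and `scale`, accepted by
#'   [build_connectome()].
#' @export
default_network_config <- function(scale = 1) {
  g <- function(source, target, convergence, weight, delay, sign, plastic = FALSE) {
    list(source = source, target = target, convergence = convergence,
         weight = weight, delay = delay, sign = sign, plastic = plastic)
  }
  list(
    populations = list(
      mf = list(size = 100), GrC = list(size = 2000), GoC = list(size = 16),
      PC = list(size = 99), MLI = list(size = 120), DCN = list(size = 16),
      DCN_GABA = list(size = 16), IO = list(size = 16)
    ),
    connections = list(
      `mf-GrC`      = g("mf",  "GrC", 4,   0.8,  1, +1),
      `mf-GoC`      = g("mf",  "GoC", 20,  0.3,  1, +1),
      `GrC-GoC`     = g("GrC", "GoC", 100, 0.1,  2, +1),
      `GoC-GrC`     = g("GoC", "GrC", 2,   0.6,  2, -1),
      `aa-PC`       = g("GrC", "PC",  22,  0.4,  1, +1),
      `pf-PC`       = g("GrC", "PC",  600, 0.9,  2, +1, plastic = TRUE),
      `GrC-MLI`     = g("GrC", "MLI", 80,  0.008, 2, +1),
      `MLI-PC`      = g("MLI", "PC",  10,  2.5,  1, -1),
      `PC-DCN`      = g("PC",  "DCN", 8,   0.09, 1, -1),
      `mf-DCN`      = g("mf",  "DCN", 30,  0.01, 1, +1),
      `IO-PC`       = g("IO",  "PC",  1,   60,   4, +1),
      `IO-DCN`      = g("IO",  "DCN", 2,   1.0,  4, +1),
      `IO-DCN_GABA` = g("IO",  "DCN_GABA", 2, 1.0, 4, +1),
      `DCN_GABA-IO` = g("DCN_GABA", "IO", 4, 0.5, 4, -1)
    ),
    scale = scale
  )
}

#' Default EBCC protocol configuration
#'
#' Conditioned stimulus: independent 40-Hz Poisson trains on every mossy
#' fiber for 280 ms from trial onset. Unconditioned stimulus: a regular
#' 500-Hz burst on all inferior-olive cells for 30 ms, co-terminating with
#' the CS (onset 250 ms). 100 trials of 1000 ms, in blocks of 10.
#'
#' @param ... Overrides for individual fields.
#' @return List with fields `cs_rate`, `cs_duration`, `cs_onset`, `us_rate`,
#'   `us_duration`, `us_onset`, `trial_duration`, `n_trials`, `block_size`
#'   (ms/Hz/counts), plus stimulus coupling weights `us_weight` (nS, drive of
#'   the US train onto IO cells).
#' @export
protocol_config <- function(...) {
  cfg <- list(cs_rate = 40, cs_duration = 280, cs_onset = 0,
              us_rate = 500, us_duration = 30, us_onset = 250,
              trial_duration = 1000, n_trials = 100, block_size = 10,
              us_weight = 80)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$us_onset + cfg$us_duration == cfg$cs_onset + cfg$cs_duration,
            cfg$trial_duration > cfg$cs_duration)
  cfg
}

#' Default plasticity configuration for the pf-PC synapse
#'
#' Supervised spike-timing rule: a parallel-fiber spike falling within
#' `teaching_window` ms before (or at) a spike of the target Purkinje cell's
#' climbing-fiber source is depressed by `ltd_step`; every other
#' parallel-fiber spike is potentiated by `ltp_step`. Weights are clipped to
#' `[w_min, w_max]` and updated in a batch at each trial boundary.
#' Step magnitudes are calibrated so that the control learning curve reaches
#' about 70% conditioned responses in the sixth block of ten trials.
#'
#' @param ... Overrides for individual fields.
#' @return List with `ltp_step`, `ltd_step` (nS), `teaching_window` (ms),
#'   `w_min`, `w_max` (nS) and `enabled`.
#' @export
plasticity_config <- function(...) {
  cfg <- list(ltp_step = 0.00065, ltd_step = 0.0065, teaching_window = 100,
              w_min = 0, w_max = 1.2, enabled = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$ltp_step >= 0, cfg$ltd_step >= 0, cfg$teaching_window > 0,
            cfg$w_min >= 0, cfg$w_min < cfg$w_max)
  cfg
}

#' Default analysis configuration for the behavioral readout
#'
#' @param ... Overrides for individual fields.
#' @return List with spike-density kernel widths `sdf_sigma_pc`,
#'   `sdf_sigma_dcn` (ms), motor moving-average window `ma_window` (ms),
#'   conditioned-response threshold `cr_threshold` (Hz), CR window
#'   `cr_window` (ms from CS onset), `baseline_window` (ms, trial 1),
#'   Tukey fence factor `iqr_factor`, significance level `alpha`, and the
#'   analysis grid step `grid_dt` (ms).
#' @export
analysis_config <- function(...) {
  cfg <- list(sdf_sigma_pc = 20, sdf_sigma_dcn = 10, ma_window = 100,
              cr_threshold = 4, cr_window = c(100, 280),
              baseline_window = c(280, 1000), iqr_factor = 1.5, alpha = 0.01,
              grid_dt = 1)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$sdf_sigma_pc > 0, cfg$sdf_sigma_dcn > 0, cfg$cr_threshold > 0,
            diff(cfg$cr_window) > 0)
  cfg
}

#' Aggregate simulation configuration
#'
#' Bundles network, protocol, plasticity and analysis blocks (the unit
#' understood by the pipeline functions). Any block can be overridden.
#'
#' @param network,protocol,plasticity,analysis Configuration blocks.
#' @param neuron_params Per-population E-GLIF parameters.
#' @param dt Integration step (ms), at most 0.5.
#' @return List of class `ebcc_config`.
#' @export
ebcc_config <- function(network = default_network_config(),
                        protocol = protocol_config(),
                        plasticity = plasticity_config(),
                        analysis = analysis_config(),
                        neuron_params = default_neuron_params(),
                        dt = 0.1) {
  stopifnot(dt > 0, dt <= 0.5)
  structure(list(network = network, protocol = protocol,
                 plasticity = plasticity, analysis = analysis,
                 neuron_params = neuron_params, dt = dt),
            class = "ebcc_config")
}
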