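# Simulation loop wrappers around the compiled clock-driven core.

dynamic_pops <- function(connectome) {
  setdiff(connectome$populations$name, "mf")
}

# global 0-based offsets of the dynamic (non-source) populations
pop_offsets <- function(connectome) {
  dyn <- dynamic_pops(connectome)
  sizes <- connectome$populations$size[match(dyn, connectome$populations$name)]
  stats::setNames(c(0, cumsum(sizes))[seq_along(dyn)], dyn)
}

# parameter/receptor matrices, engine-form groups, teacher map
build_sim <- function(connectome, dt, ie_scale = NULL) {
  dyn <- dynamic_pops(connectome)
  off <- pop_offsets(connectome)
  sizes <- stats::setNames(connectome$populations$size,
                           connectome$populations$name)
  N <- sum(sizes[dyn])
  par <- matrix(0, N, 12)
  recpar <- matrix(0, N, 4)
  for (pop in dyn) {
    p <- connectome$neuron_params[[pop]]
    if (is.null(p)) stop("no neuron parameters for population ", pop)
    ie <- p$I_e * (ie_scale[[pop]] %||% 1)
    rows <- off[[pop]] + seq_len(sizes[[pop]])
    par[rows, ] <- matrix(c(p$Cm, p$tau_m, p$E_rest, p$V_th, p$V_reset,
                            p$t_ref, ie, p$k_adap, p$k1, p$k2, p$A1, p$A2),
                          length(rows), 12, byrow = TRUE)
    offs <- connectome$ie_offsets[[pop]]
    if (!is.null(offs)) par[rows, 7] <- par[rows, 7] + offs
    recpar[rows, ] <- matrix(c(p$tau_exc, p$tau_inh, p$E_exc, p$E_inh),
                             length(rows), 4, byrow = TRUE)
  }
  groups <- lapply(connectome$groups, function(g) {
    src_kind <- if (g$source == "mf") 0L else 1L
    pre0 <- if (src_kind == 0L) g$pre - 1L else off[[g$source]] + g$pre - 1L
    list(src_kind = src_kind, pre = as.integer(pre0),
         post = as.integer(off[[g$target]] + g$post - 1L),
         w = as.numeric(g$weight),
         delay_steps = max(1L, as.integer(round(g$delay / dt))),
         sign = as.integer(g$sign))
  })
  teacher <- rep(-1L, N)
  efficacy <- rep(1, N)
  if ("IO-PC" %in% names(connectome$groups)) {
    g <- connectome$groups[["IO-PC"]]
    teacher[off[["PC"]] + g$post] <- off[["IO"]] + g$pre - 1L
    # complex-spike LTD triggering is all-or-none from below (a weakened
    # climbing fiber still triggers depression), while an increased
    # climbing-fiber synaptic density scales the depression up
    ref_w <- g$ref_weight %||% connectome$config$connections[["IO-PC"]]$weight
    if (!is.null(ref_w) && ref_w > 0)
      efficacy[off[["PC"]] + g$post] <- pmax(1, g$weight / ref_w)
  }
  plastic_idx <- which(vapply(connectome$groups, function(g)
    isTRUE(g$plastic), TRUE))
  list(par = par, recpar = recpar, groups = groups, teacher = teacher,
       efficacy = efficacy,
       plastic = if (length(plastic_idx)) plastic_idx[1] - 1L else -1L,
       offsets = off, sizes = sizes, N = N, dyn = dyn)
}

# desynchronized initial states: V uniform between reset and threshold
initial_states <- function(connectome, seed) {
  sim <- build_sim(connectome, dt = 0.1)
  with_seed(derive_seed(seed, "init"), {
    V <- runif(sim$N, sim$par[, 5], sim$par[, 4] - 1e-6)
    cbind(V, 0, 0, 0)
  })
}

# stimuli (cs/us lists of per-cell trains) -> engine event lists for one trial
stim_to_events <- function(stim, sim, us_weight, overlay_trial = NULL,
                           trial_duration = Inf) {
  cs_id <- rep.int(seq_along(stim$cs) - 1L,
                   vapply(stim$cs, length, 0L))
  cs_t <- unlist(stim$cs, use.names = FALSE) %||% numeric(0)
  if (length(cs_t) && (min(cs_t) < 0 || max(cs_t) >= trial_duration))
    stop("stimulus time outside trial")
  o <- order(cs_t)
  mf <- list(id = as.integer(cs_id[o]), t = as.numeric(cs_t[o]))

  io_off <- if ("IO" %in% names(sim$offsets)) sim$offsets[["IO"]] else NULL
  if (is.null(io_off) && sum(lengths(stim$us)) > 0)
    stop("unknown population: US requires an IO population")
  us_id <- if (is.null(io_off)) integer(0)
           else rep.int(io_off + seq_along(stim$us) - 1L,
                        vapply(stim$us, length, 0L))
  us_t <- if (is.null(io_off)) numeric(0)
          else unlist(stim$us, use.names = FALSE) %||% numeric(0)
  tgt <- us_id; tt <- us_t
  ww <- rep(us_weight, length(us_t)); rr <- rep(0L, length(us_t))
  if (!is.null(overlay_trial)) {
    ov_off <- sim$offsets[[overlay_trial$pop]]
    ov_id <- rep.int(ov_off + seq_along(overlay_trial$trains) - 1L,
                     vapply(overlay_trial$trains, length, 0L))
    ov_t <- unlist(overlay_trial$trains, use.names = FALSE) %||% numeric(0)
    tgt <- c(tgt, ov_id); tt <- c(tt, ov_t)
    ww <- c(ww, rep(overlay_trial$weight, length(ov_t)))
    rr <- c(rr, rep(0L, length(ov_t)))
  }
  if (length(tt) && (min(tt) < 0 || max(tt) >= trial_duration))
    stop("stimulus time outside trial")
  o <- order(tt)
  inj <- list(target = as.integer(tgt[o]), t = as.numeric(tt[o]),
              w = as.numeric(ww[o]), rec = as.integer(rr[o]))
  list(mf = mf, inj = inj)
}

raw_to_recording <- function(ids, ts, sim, trial, duration) {
  pop <- rep(NA_character_, length(ids))
  id_local <- integer(length(ids))
  for (p in sim$dyn) {
    lo <- sim$offsets[[p]]
    sel <- ids >= lo & ids < lo + sim$sizes[[p]]
    pop[sel] <- p
    id_local[sel] <- ids[sel] - lo + 1L
  }
  structure(list(trial = trial,
                 spikes = data.frame(population = pop, id = id_local,
                                     time = ts, stringsAsFactors = FALSE),
                 duration = duration),
            class = "trial_recording")
}

#' Run a full EBCC session
#'
#' Runs `n_trials` consecutive trials (neuron state, synaptic conductances
#' and plastic weights all carry over between trials), injecting a fresh CS
#' realization per trial plus the shared US burst, applying the batched
#' pf-PC plasticity update at every trial boundary, and recording all spikes
#' per trial. Deterministic given `(connectome, protocol, seed)`.
#'
#' @param connectome A `connectome` (possibly lesioned).
#' @param protocol A [protocol_config()].
#' @param seed Master seed; CS realizations and initial states use derived
#'   streams.
#' @param plasticity A [plasticity_config()]; set `enabled = FALSE` to
#'   freeze weights.
#' @param dt Integration step (ms).
#' @param paired If `FALSE`, CS-alone trials (no US).
#' @param overlay Optional whole-session stimulation overlay as produced by
#'   [apply_burst_lesion()].
#' @param ie_scale Optional named list scaling the endogenous current of
#'   given populations (e.g. `list(PC = 0.5)`).
#' @param stimuli Optional pre-built stimulus sets (from
#'   [make_session_stimuli()]); by default they are generated internally.
#' @param warmup_ms Settling period (ms) simulated before the first trial
#'   without stimulation, recording or plasticity, so that the pacemaking
#'   populations reach their tonic equilibrium before trial 1.
#' @param rehearsal When `TRUE` (default for paired sessions) one
#'   unrecorded habituation trial (a CS+US presentation with frozen
#'   weights, using its own CS realization) precedes trial 1, so every
#'   recorded trial starts from the stereotyped post-stimulus network
#'   state.
#' @return Object of class `ebcc_session`: `recordings` (list of
#'   `trial_recording`), final `weights` per group, `mean_w` (mean pf-PC
#'   weight after each trial), `snapshots` (pf-PC weights at each block end),
#'   and the inputs used.
#' @export
run_session <- function(connectome, protocol = protocol_config(), seed = 1,
                        plasticity = plasticity_config(), dt = 0.1,
                        paired = TRUE, overlay = NULL, ie_scale = NULL,
                        stimuli = NULL, warmup_ms = 1000,
                        rehearsal = paired) {
  sim <- build_sim(connectome, dt, ie_scale = ie_scale)
  if (is.null(stimuli))
    stimuli <- make_session_stimuli(connectome, protocol, seed, paired)
  n_trials <- length(stimuli)
  if (!is.null(overlay) && length(overlay$trains) != n_trials)
    stop("overlay does not cover the session")
  n_skip <- if (isTRUE(rehearsal)) 1L else 0L
  if (n_skip) {
    n_mf <- pop_size(connectome, "mf")
    rehearsal_cs <- with_seed(derive_seed(seed, "cs-rehearsal"),
                              encode_cs(n_mf, protocol))
    rehearsal_stim <- list(cs = rehearsal_cs,
                           us = encode_us(pop_size(connectome, "IO"),
                                          protocol))
    stimuli <- c(list(rehearsal_stim), stimuli)
  }
  n_all <- n_trials + n_skip
  mf_trains <- vector("list", n_all)
  inj_trains <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    ev <- stim_to_events(stimuli[[i]], sim, protocol$us_weight,
                         overlay_trial = if (!is.null(overlay) && i > n_skip)
                           list(pop = overlay$pop, weight = overlay$weight,
                                trains = overlay$trains[[i - n_skip]]),
                         trial_duration = protocol$trial_duration)
    mf_trains[[i]] <- ev$mf; inj_trains[[i]] <- ev$inj
  }
  init <- initial_states(connectome, seed)
  plast <- list(enabled = isTRUE(plasticity$enabled), group = sim$plastic,
                ltp = plasticity$ltp_step, ltd = plasticity$ltd_step,
                window = plasticity$teaching_window,
                wmin = plasticity$w_min, wmax = plasticity$w_max,
                teacher = sim$teacher, efficacy = sim$efficacy,
                skip_trials = n_skip)
  raw <- cpp_run_session(sim$par, sim$recpar, init, unname(sim$groups),
                         mf_trains, inj_trains, n_all,
                         protocol$trial_duration, dt, plast,
                         protocol$block_size %||% 0L,
                         as.integer(round(warmup_ms / dt)))
  recordings <- lapply(seq_len(n_trials), function(i)
    raw_to_recording(raw$spike_id[[i + n_skip]], raw$spike_t[[i + n_skip]],
                     sim, i, protocol$trial_duration))
  out_conn <- connectome
  for (g in seq_along(out_conn$groups))
    out_conn$groups[[g]]$weight <- raw$weights[[g]]
  structure(list(recordings = recordings, connectome = out_conn,
                 protocol = protocol, plasticity = plasticity, dt = dt,
                 seed = seed,
                 mean_w = raw$mean_w[n_skip + seq_len(n_trials)],
                 snapshots = raw$snapshots,
                 state = raw$state, sim = sim),
            class = "ebcc_session")
}

#' @export
print.ebcc_session <- function(x, ...) {
  n_sp <- sum(vapply(x$recordings, function(r) nrow(r$spikes), 0))
  cat("EBCC session:", length(x$recordings), "trials,", n_sp, "spikes,",
      "seed", x$seed, "\n")
  invisible(x)
}

#' Run a single trial
#'
#' One trial of the clock-driven loop, starting from the supplied (or fresh)
#' neuron states, with optional plasticity at the trial end.
#'
#' @param connectome A `connectome`.
#' @param stimuli List with `cs` (per-mf spike trains) and `us` (per-IO
#'   trains); see [make_session_stimuli()].
#' @param duration Trial duration (ms).
#' @param states Optional N x 4 state matrix (V, I_adap, I_dep, refractory)
#'   from a previous call; fresh desynchronized states otherwise.
#' @param plasticity A [plasticity_config()] or `NULL`/disabled for frozen
#'   weights.
#' @param seed Seed for fresh initial states.
#' @param dt Integration step (ms).
#' @param us_weight Conductance (nS) of each US stimulus spike onto IO.
#' @return List with `recording` (a `trial_recording`), updated `connectome`
#'   (weights) and `states`.
#' @export
run_trial <- function(connectome, stimuli, duration = 1000, states = NULL,
                      plasticity = plasticity_config(enabled = FALSE),
                      seed = 1, dt = 0.1, us_weight = 80) {
  sim <- build_sim(connectome, dt)
  ev <- stim_to_events(stimuli, sim, us_weight, trial_duration = duration)
  if (is.null(states)) states <- initial_states(connectome, seed)
  plast <- list(enabled = isTRUE(plasticity$enabled), group = sim$plastic,
                ltp = plasticity$ltp_step, ltd = plasticity$ltd_step,
                window = plasticity$teaching_window,
                wmin = plasticity$w_min, wmax = plasticity$w_max,
                teacher = sim$teacher, efficacy = sim$efficacy,
                skip_trials = 0L)
  raw <- cpp_run_session(sim$par, sim$recpar, states, unname(sim$groups),
                         list(ev$mf), list(ev$inj), 1L, duration, dt,
                         plast, 0L, 0L)
  out_conn <- connectome
  for (g in seq_along(out_conn$groups))
    out_conn$groups[[g]]$weight <- raw$weights[[g]]
  list(recording = raw_to_recording(raw$spike_id[[1]], raw$spike_t[[1]],
                                    sim, 1L, duration),
       connectome = out_conn, states = raw$state)
}

#' Spikes of one population as per-cell time lists
#'
#' @param recording A `trial_recording`.
#' @param pop Population name.
#' @param n_cells Population size (number of list entries).
#' @return List of `n_cells` sorted spike-time vectors (ms).
#' @export
population_spikes <- function(recording, pop, n_cells) {
  sp <- recording$spikes
  sel <- sp$population == pop
  split(sp$time[sel], factor(sp$id[sel], levels = seq_len(n_cells)))
}

#' Write spikes in GDF style (two columns: neuron id, time)
#'
#' Times are session times (trial index unrolled). One file per population:
#' `<prefix><pop>.gdf`.
#'
#' @param session An `ebcc_session`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_gdf <- function(session, dir, prefix = "spikes_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- session_spikes(session)
  df$time_global <- (df$trial - 1) * session$protocol$trial_duration + df$time
  paths <- character(0)
  for (p in unique(df$population)) {
    path <- file.path(dir, paste0(prefix, p, ".gdf"))
    sub <- df[df$population == p, c("id", "time_global")]
    write.table(sub[order(sub$time_global), ], path, row.names = FALSE,
                col.names = FALSE, sep = "\t")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a GDF spike file
#'
#' @param path Two-column whitespace-separated text file (id, time).
#' @return data.frame with `id` and `time`.
#' @export
read_gdf <- function(path) {
  df <- read.table(path, col.names = c("id", "time"))
  df$id <- as.integer(df$id)
  df
}

#' All spikes of a session as one data frame
#'
#' @param session An `ebcc_session`.
#' @return data.frame with `trial`, `population`, `id`, `time` (ms within
#'   trial).
#' @export
session_spikes <- function(session) {
  do.call(rbind, lapply(session$recordings, function(r)
    cbind(trial = r$trial, r$spikes)))
}
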