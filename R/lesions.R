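#' Lesion specifications
#'
#' Tagged descriptions of the three dystonia-like alterations applied to the
#' control model: reduced olivocerebellar input, aberrant Purkinje-cell burst
#' firing (intrinsic or IO-induced), and imbalanced synaptic densities on
#' Purkinje cells.
#'
#' @param fraction Severity of the reduced-IO lesion, in `[0, 1]` (the study
#'   levels are 0.25, 0.5, 0.75): that fraction of Purkinje cells loses its
#'   climbing-fiber source and all surviving IO-PC weights are scaled by
#'   `1 - fraction`.
#' @param train_on Duration (ms) of each injected spike-train phase.
#' @param pauses Candidate pause durations (ms) between trains, drawn
#'   equiprobably per gap (intrinsic burst lesion).
#' @param pause Fixed pause duration (ms) (IO-induced burst lesion).
#' @param ie_factor Multiplier on the Purkinje endogenous current (intrinsic
#'   burst lesion reduces intrinsic pacemaking).
#' @param stim_rate Spike rate (Hz) inside each injected train phase.
#' @param weight Conductance (nS) of each injected overlay spike.
#' @param level `"mild"` or `"severe"` synaptic-imbalance level:
#'   mild removes 14% of pf-PC and 39% of MLI-PC synapses and scales IO-PC
#'   weights by +32%; severe removes 25% / 71% and scales by +57%.
#' @return List of class `lesion_spec` with a `kind` field.
#' @name lesion_spec
NULL

#' @rdname lesion_spec
#' @export
lesion_reduced_io <- function(fraction) {
  stopifnot(length(fraction) == 1, fraction >= 0, fraction <= 1)
  structure(list(kind = "reduced_io", fraction = fraction),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @export
lesion_intrinsic_burst <- function(train_on = 20, pauses = c(20, 30),
                                   ie_factor = 0.8, stim_rate = 500,
                                   weight = 45) {
  structure(list(kind = "intrinsic_burst", train_on = train_on,
                 pauses = pauses, ie_factor = ie_factor,
                 stim_rate = stim_rate, weight = weight),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @export
lesion_io_burst <- function(train_on = 40, pause = 40, stim_rate = 500,
                            weight = 80) {
  structure(list(kind = "io_burst", train_on = train_on, pause = pause,
                 stim_rate = stim_rate, weight = weight),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @export
lesion_synaptic_imbalance <- function(level = c("mild", "severe")) {
  level <- match.arg(level)
  structure(list(kind = "synaptic_imbalance", level = level),
            class = "lesion_spec")
}

#' Reduce the olivocerebellar input
#'
#' Disconnects the climbing-fiber (teaching) source from
#' `round(fraction * |PC|)` Purkinje cells, drawn from the lesion stream, and
#' scales all surviving IO-PC weights by `1 - fraction` (both factors applied
#' simultaneously).
#'
#' @param connectome Control `connectome`.
#' @param fraction Damage level in `[0, 1]`.
#' @param seed Seed of the lesion stream.
#' @return Lesioned `connectome`.
#' @export
apply_reduced_io <- function(connectome, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(connectome)
  n_pc <- pop_size(connectome, "PC")
  n_cut <- round(fraction * n_pc)
  cut <- with_seed(derive_seed(seed, "lesion"),
                   sample.int(n_pc, n_cut, replace = FALSE))
  g <- connectome$groups[["IO-PC"]]
  keep <- !(g$post %in% cut)
  g$pre <- g$pre[keep]; g$post <- g$post[keep]
  g$weight <- g$weight[keep] * (1 - fraction)
  connectome$groups[["IO-PC"]] <- g
  connectome
}

#' Imbalance the synaptic densities on Purkinje cells
#'
#' Randomly removes the study proportions of pf-PC and MLI-PC synapses
#' (counts rounded to the nearest integer) and scales IO-PC weights up by
#' the corresponding proportion (the one-climbing-fiber rule is preserved:
#' the increased climbing-fiber synapse density acts multiplicatively on the
#' existing connection).
#'
#' @param connectome Control `connectome`.
#' @param level `"mild"` (pf -14%, MLI -39%, IO +32%) or `"severe"`
#'   (pf -25%, MLI -71%, IO +57%).
#' @param seed Seed of the lesion stream.
#' @return Lesioned `connectome`.
#' @export
apply_synaptic_imbalance <- function(connectome, level = c("mild", "severe"),
                                     seed = 1) {
  level <- match.arg(level)
  frac <- switch(level,
                 mild = c(pf = 0.14, mli = 0.39, io = 0.32),
                 severe = c(pf = 0.25, mli = 0.71, io = 0.57))
  drop_edges <- function(g, p, stream) {
    n <- length(g$pre)
    n_drop <- round(p * n)
    if (n_drop > 0) {
      drop <- with_seed(stream, sample.int(n, n_drop, replace = FALSE))
      g$pre <- g$pre[-drop]; g$post <- g$post[-drop]
      g$weight <- g$weight[-drop]
    }
    g
  }
  connectome$groups[["pf-PC"]] <-
    drop_edges(connectome$groups[["pf-PC"]], frac[["pf"]],
               derive_seed(seed, "lesion-pf"))
  connectome$groups[["MLI-PC"]] <-
    drop_edges(connectome$groups[["MLI-PC"]], frac[["mli"]],
               derive_seed(seed, "lesion-mli"))
  g <- connectome$groups[["IO-PC"]]
  g$weight <- g$weight * (1 + frac[["io"]])
  connectome$groups[["IO-PC"]] <- g
  connectome
}

# intermittent on/off spike-train pattern covering one session,
# split per trial; regular spikes at stim_rate inside on-phases
burst_pattern <- function(session_ms, trial_ms, train_on, pause_fun,
                          stim_rate) {
  isi <- 1000 / stim_rate
  t <- 0
  times <- list(); k <- 0
  while (t < session_ms) {
    on_end <- min(t + train_on, session_ms)
    k <- k + 1
    times[[k]] <- seq(t, on_end - isi / 2, by = isi)
    t <- on_end + pause_fun()
  }
  all_t <- unlist(times)
  n_trials <- ceiling(session_ms / trial_ms)
  lapply(seq_len(n_trials), function(i) {
    sel <- all_t >= (i - 1) * trial_ms & all_t < i * trial_ms
    all_t[sel] - (i - 1) * trial_ms
  })
}

#' Build a burst-firing lesion overlay
#'
#' Whole-session intermittent stimulation injected through a dedicated
#' strong excitatory synapse: for the intrinsic Purkinje burst lesion,
#' 20-ms spike trains separated by pauses drawn equiprobably from 20 or
#' 30 ms onto every PC (each cell gets an independent pattern), combined
#' with a reduced PC endogenous current; for the IO-induced lesion, 40-ms
#' trains with fixed 40-ms pauses onto every IO cell (shared pattern, on top
#' of the US).
#'
#' @param spec A `lesion_spec` of kind `intrinsic_burst` or `io_burst`.
#' @param protocol A [protocol_config()].
#' @param n_cells Number of target cells (PC or IO population size).
#' @param seed Seed of the lesion stream (pause draws).
#' @return Overlay list: `pop`, `weight`, per-trial list of per-cell spike
#'   trains, and `ie_scale` (named list of endogenous-current multipliers,
#'   possibly empty).
#' @export
apply_burst_lesion <- function(spec, protocol = protocol_config(), n_cells,
                               seed = 1) {
  stopifnot(inherits(spec, "lesion_spec"),
            spec$kind %in% c("intrinsic_burst", "io_burst"))
  session_ms <- protocol$n_trials * protocol$trial_duration
  if (spec$kind == "intrinsic_burst") {
    pattern <- with_seed(derive_seed(seed, "lesion-burst"),
      burst_pattern(session_ms, protocol$trial_duration, spec$train_on,
                    function() sample(spec$pauses, 1), spec$stim_rate))
    trains <- lapply(seq_len(protocol$n_trials), function(tr)
      rep(list(pattern[[tr]]), n_cells))
    list(pop = "PC", weight = spec$weight, trains = trains,
         ie_scale = list(PC = spec$ie_factor))
  } else {
    pattern <- burst_pattern(session_ms, protocol$trial_duration,
                             spec$train_on, function() spec$pause,
                             spec$stim_rate)
    trains <- lapply(seq_len(protocol$n_trials), function(tr)
      rep(list(pattern[[tr]]), n_cells))
    list(pop = "IO", weight = spec$weight, trains = trains,
         ie_scale = list())
  }
}

#' Apply any lesion to a control setup
#'
#' Dispatch helper returning the lesioned connectome plus session overlay
#' and endogenous-current overrides, ready for [run_session()].
#'
#' @param connectome Control `connectome`.
#' @param spec A `lesion_spec`, or `NULL` for the control condition.
#' @param protocol A [protocol_config()].
#' @param seed Seed of the lesion stream.
#' @return List with `connectome`, `overlay` (or `NULL`) and `ie_scale`.
#' @export
apply_lesion <- function(connectome, spec, protocol = protocol_config(),
                         seed = 1) {
  if (is.null(spec))
    return(list(connectome = connectome, overlay = NULL, ie_scale = NULL))
  stopifnot(inherits(spec, "lesion_spec"))
  switch(spec$kind,
    reduced_io = list(
      connectome = apply_reduced_io(connectome, spec$fraction, seed),
      overlay = NULL, ie_scale = NULL),
    synaptic_imbalance = list(
      connectome = apply_synaptic_imbalance(connectome, spec$level, seed),
      overlay = NULL, ie_scale = NULL),
    intrinsic_burst = ,
    io_burst = {
      pop <- if (spec$kind == "intrinsic_burst") "PC" else "IO"
      ov <- apply_burst_lesion(spec, protocol, pop_size(connectome, pop),
                               seed)
      list(connectome = connectome, overlay = ov, ie_scale = ov$ie_scale)
    },
    stop("unknown lesion kind: ", spec$kind))
}
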