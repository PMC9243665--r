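#' Spike density function of a cell group
#'
#' Convolution of each cell's spike train with a Gaussian kernel (truncated
#' at four standard deviations, no edge renormalization), in Hz, on a
#' regular time grid; the population SDF is the mean over cells.
#'
#' @param spikes List of per-cell spike-time vectors (ms).
#' @param sigma Kernel standard deviation (ms), > 0.
#' @param t_max Trial duration (ms); the grid spans `[0, t_max)`.
#' @param grid_dt Grid step (ms).
#' @return List of class `sdf_trace`: `time` (ms), `cells`
#'   (cells x time matrix, Hz), `pop` (population-mean SDF, Hz).
#' @export
compute_sdf <- function(spikes, sigma, t_max, grid_dt = 1) {
  stopifnot(sigma > 0, t_max > 0, grid_dt > 0)
  time <- seq(0, t_max - grid_dt, by = grid_dt)
  if (!length(time)) stop("empty analysis grid")
  half <- ceiling(4 * sigma / grid_dt)
  kt <- seq(-half, half) * grid_dt
  kern <- dnorm(kt, sd = sigma) * 1000          # spikes/ms -> Hz
  n <- length(time)
  cells <- matrix(0, length(spikes), n)
  for (i in seq_along(spikes)) {
    sp <- spikes[[i]]
    if (!length(sp)) next
    counts <- tabulate(pmin(n, pmax(1L, floor(sp / grid_dt) + 1L)), nbins = n)
    full <- c(numeric(half), counts, numeric(half))
    cells[i, ] <- stats::filter(full, kern, sides = 2)[half + seq_len(n)]
  }
  structure(list(time = time, cells = cells, pop = colMeans(cells),
                 sigma = sigma, grid_dt = grid_dt),
            class = "sdf_trace")
}

#' Motor output: moving-average filtered DCN population SDF
#'
#' Trailing (causal) moving average with edge shrinkage: the value at `t`
#' averages the input over the preceding `ma_window` ms (less near the trial
#' start). The filtered eyelid-closure signal is read from this trace.
#'
#' @param x Numeric input trace (Hz) or an `sdf_trace` (its population mean
#'   is used).
#' @param ma_window Window length (ms).
#' @param grid_dt Grid step of `x` (ms).
#' @return Filtered trace, same length as the input.
#' @export
motor_output <- function(x, ma_window = 100, grid_dt = 1) {
  if (inherits(x, "sdf_trace")) { grid_dt <- x$grid_dt; x <- x$pop }
  w <- max(1L, round(ma_window / grid_dt))
  if (w > length(x)) stop("window exceeds trace length")
  cs <- cumsum(x)
  n <- length(x)
  lag <- c(numeric(w), cs[seq_len(n - w)])
  (cs - lag) / pmin(seq_len(n), w)
}

# supremum of thresholds at which the trial is a CR. Because the motor
# output is a trailing moving average, its value at US onset already
# summarizes the response sustained over the preceding window, so the
# detectable-threshold supremum is the motor value at US onset (the last
# in-window sample): at any lower threshold the trace has reached the
# threshold within the window and is (still) at or above it at the US.
# Improperly timed responses — traces that never drop below the threshold
# during the first 100 ms, i.e. whose exceedance pre-dates the CR window —
# are not CRs; trials whose pre-window minimum is at or above the US-onset
# level can therefore never be detected at any threshold.
cr_strength_trace <- function(x, time, win_start, us_onset) {
  idx <- which(time >= win_start & time <= us_onset)
  if (!length(idx)) return(-Inf)
  level <- x[max(idx)]
  early <- x[time < win_start]
  if (length(early) && min(early) >= level) return(-Inf)
  level
}

#' Detect a conditioned response in a motor-output trace
#'
#' A CR is flagged when the filtered motor output reaches the threshold
#' inside the CR window and remains at or above it at US onset. Because the
#' motor output is a trailing moving average, being at threshold at the US
#' implies a sustained elevation over the preceding window. Improperly
#' timed responses — traces already at or above the threshold throughout
#' the first 100 ms from CS onset (the exceedance pre-dates the window) —
#' are not counted as CRs. The CR onset is the start of the monotonic rise
#' preceding the first in-window reach (the last sample at which the
#' discrete derivative turns positive and stays positive up to the reach),
#' not earlier than the CR-window start, reported as advance (ms) relative
#' to US onset. For anticipatory traces (below threshold before the
#' window) the flag is monotone in the threshold.
#'
#' @param motor Filtered motor-output trace (Hz), see [motor_output()].
#' @param cfg An [analysis_config()] (threshold, CR window).
#' @param us_onset US onset time (ms).
#' @param grid_dt Grid step of `motor` (ms).
#' @param threshold Optional threshold override (Hz).
#' @return List: `cr` (logical), `onset` (ms before US, `NA` if no CR) and
#'   `strength` (supremum of thresholds at which the trial would be a CR).
#' @export
detect_cr <- function(motor, cfg = analysis_config(), us_onset = 250,
                      grid_dt = 1, threshold = NULL) {
  th <- threshold %||% cfg$cr_threshold
  time <- seq(0, by = grid_dt, length.out = length(motor))
  win_start <- cfg$cr_window[1]
  if (max(time) < us_onset) stop("trace does not cover the CR window")
  cand <- which(time >= win_start & time <= us_onset)
  iu <- max(cand)
  strength <- cr_strength_trace(motor, time, win_start, us_onset)
  early <- motor[time < win_start]
  pre_existing <- length(early) && min(early) >= th
  if (strength < th || pre_existing)
    return(list(cr = FALSE, onset = NA_real_, strength = strength))
  i_reach <- cand[motor[cand] >= th][1]
  d <- diff(motor)
  i0 <- i_reach
  while (i0 > 2 && d[i0 - 1] > 0) i0 <- i0 - 1
  onset_time <- max(time[i0], win_start)
  list(cr = TRUE, onset = us_onset - onset_time, strength = strength)
}

#' Calibrate the CR threshold on a reference block
#'
#' Places the detection threshold so that the reference block (the sixth by
#' default) yields the target proportion of conditioned responses — the
#' calibration criterion used for the control condition. The threshold is
#' the midpoint between the k-th and (k+1)-th largest per-trial CR strengths
#' of the block, `k = target * block size`.
#'
#' @param strengths Per-trial CR strengths of the session (in trial order).
#' @param block Reference block index.
#' @param block_size Trials per block.
#' @param target Target CR proportion in the reference block.
#' @param fallback Threshold returned when the block cannot reach the target
#'   (fewer than `k` positive strengths).
#' @return Threshold (Hz).
#' @export
calibrate_cr_threshold <- function(strengths, block = 6, block_size = 10,
                                   target = 0.7, fallback = 4) {
  idx <- ((block - 1) * block_size + 1):(block * block_size)
  s <- sort(strengths[idx], decreasing = TRUE)
  k <- round(target * block_size)
  if (!is.finite(s[k]) || s[k] <= 0) return(fallback)
  lo <- if (k < length(s) && is.finite(s[k + 1])) max(0, s[k + 1]) else 0
  (s[k] + lo) / 2
}

#' Learning index: SDF change in the CR window over the last block
#'
#' Per cell, mean over the last-block trials of the SDF time-integral in the
#' CR window minus the mean SDF over the first 100 ms after CS onset times
#' the CR-window duration. Negative values indicate suppression (Purkinje
#' cells), positive values facilitation (nuclei). Units: spikes.
#'
#' @param traces List of `sdf_trace` objects, exactly the last-block trials.
#' @param cfg An [analysis_config()].
#' @return Numeric vector, one change index per cell.
#' @export
sdf_change <- function(traces, cfg = analysis_config()) {
  per_trial <- lapply(traces, function(tr) {
    dt_s <- tr$grid_dt / 1000
    in_win <- tr$time >= cfg$cr_window[1] & tr$time < cfg$cr_window[2]
    in_ref <- tr$time >= 0 & tr$time < 100
    win_dur <- (cfg$cr_window[2] - cfg$cr_window[1]) / 1000
    rowSums(tr$cells[, in_win, drop = FALSE]) * dt_s -
      rowMeans(tr$cells[, in_ref, drop = FALSE]) * win_dur
  })
  Reduce(`+`, per_trial) / length(per_trial)
}

#' Baseline firing statistics in the first trial
#'
#' Firing rate and inter-spike-interval coefficient of variation per cell in
#' the baseline window (end of CS to end of trial). Cells with fewer than
#' three spikes in the window get an undefined CV.
#'
#' @param spikes List of per-cell spike times (ms) of trial 1.
#' @param window Baseline window (ms).
#' @return data.frame with `rate` (Hz) and `cv_isi` per cell.
#' @export
baseline_stats <- function(spikes, window = c(280, 1000)) {
  stopifnot(diff(window) > 0)
  dur_s <- diff(window) / 1000
  res <- t(vapply(spikes, function(sp) {
    inw <- sp[sp >= window[1] & sp <= window[2]]
    rate <- length(inw) / dur_s
    cv <- if (length(inw) >= 3) {
      isi <- diff(inw)
      sd(isi) / mean(isi)
    } else NA_real_
    c(rate, cv)
  }, c(0, 0)))
  data.frame(rate = res[, 1], cv_isi = res[, 2])
}

#' Tukey-fence outlier exclusion
#'
#' Keeps the values inside `[Q1 - f*IQR, Q3 + f*IQR]` with
#' linear-interpolation quartiles (type 7); input order is preserved.
#'
#' @param values Numeric vector with at least 4 values (`NA`s dropped).
#' @param iqr_factor Fence factor `f`.
#' @return The retained values.
#' @export
exclude_outliers <- function(values, iqr_factor = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - iqr_factor * iqr &
         values <= q[2] + iqr_factor * iqr]
}

#' Behavioral analysis of a full session
#'
#' Computes, per trial, the DCN population SDF, the filtered motor output
#' and the CR flag/onset/strength; per block, the %CR; plus the last-block
#' SDF-change indices for PC and DCN, and trial-1 baseline statistics.
#'
#' @param session An `ebcc_session`.
#' @param cfg An [analysis_config()].
#' @param threshold CR threshold (Hz); defaults to `cfg$cr_threshold`. Use
#'   [calibrate_cr_threshold()] on `strength` to re-derive it from the data.
#' @return Object of class `ebcc_behavior`: `trials` (data.frame: trial,
#'   cr, onset, strength), `blocks` (block, pct_cr), `total_crs`,
#'   `onset_mean`, `onset_sd`, `sdf_change_pc`, `sdf_change_dcn`,
#'   `baseline_pc`, `baseline_dcn`, `motor` (trials x time matrix),
#'   `pc_sdf`, `dcn_sdf` (population-mean matrices), `threshold`.
#' @export
analyze_session <- function(session, cfg = analysis_config(),
                            threshold = NULL) {
  th <- threshold %||% cfg$cr_threshold
  proto <- session$protocol
  n_pc <- pop_size(session$connectome, "PC")
  n_dcn <- pop_size(session$connectome, "DCN")
  n_trials <- length(session$recordings)
  t_max <- proto$trial_duration
  grid_n <- length(seq(0, t_max - cfg$grid_dt, by = cfg$grid_dt))
  motor <- matrix(0, n_trials, grid_n)
  pc_pop <- matrix(0, n_trials, grid_n)
  dcn_pop <- matrix(0, n_trials, grid_n)
  block_size <- proto$block_size
  last_block <- (n_trials - block_size + 1):n_trials
  pc_last <- vector("list", length(last_block))
  dcn_last <- vector("list", length(last_block))
  for (i in seq_len(n_trials)) {
    rec <- session$recordings[[i]]
    pc_sdf <- compute_sdf(population_spikes(rec, "PC", n_pc),
                          cfg$sdf_sigma_pc, t_max, cfg$grid_dt)
    dcn_sdf <- compute_sdf(population_spikes(rec, "DCN", n_dcn),
                           cfg$sdf_sigma_dcn, t_max, cfg$grid_dt)
    pc_pop[i, ] <- pc_sdf$pop
    dcn_pop[i, ] <- dcn_sdf$pop
    motor[i, ] <- motor_output(dcn_sdf$pop, cfg$ma_window, cfg$grid_dt)
    if (i %in% last_block) {
      k <- i - min(last_block) + 1
      pc_last[[k]] <- pc_sdf; dcn_last[[k]] <- dcn_sdf
    }
  }
  det <- lapply(seq_len(n_trials), function(i)
    detect_cr(motor[i, ], cfg, proto$us_onset, cfg$grid_dt, threshold = th))
  trials <- data.frame(
    trial = seq_len(n_trials),
    cr = vapply(det, `[[`, TRUE, "cr"),
    onset = vapply(det, `[[`, 0, "onset"),
    strength = vapply(det, `[[`, 0, "strength"))
  blocks <- data.frame(
    block = seq_len(n_trials %/% block_size),
    pct_cr = vapply(split(trials$cr, (trials$trial - 1) %/% block_size),
                    function(x) 100 * mean(x), 0, USE.NAMES = FALSE))
  onsets <- trials$onset[trials$cr]
  rec1 <- session$recordings[[1]]
  structure(list(
    trials = trials, blocks = blocks, total_crs = sum(trials$cr),
    onset_mean = if (length(onsets)) mean(onsets) else NA_real_,
    onset_sd = if (length(onsets) > 1) sd(onsets) else NA_real_,
    sdf_change_pc = sdf_change(pc_last, cfg),
    sdf_change_dcn = sdf_change(dcn_last, cfg),
    baseline_pc = baseline_stats(population_spikes(rec1, "PC", n_pc),
                                 cfg$baseline_window),
    baseline_dcn = baseline_stats(population_spikes(rec1, "DCN", n_dcn),
                                  cfg$baseline_window),
    motor = motor, pc_sdf = pc_pop, dcn_sdf = dcn_pop,
    threshold = th, config = cfg),
    class = "ebcc_behavior")
}

#' Re-detect conditioned responses at a new threshold
#'
#' Cheap re-analysis of an existing [analyze_session()] result (no
#' re-simulation): re-runs the detector on the stored motor traces.
#'
#' @param behavior An `ebcc_behavior`.
#' @param threshold New threshold (Hz).
#' @param us_onset US onset (ms).
#' @return Updated `ebcc_behavior`.
#' @export
redetect <- function(behavior, threshold, us_onset = 250) {
  cfg <- behavior$config
  det <- lapply(seq_len(nrow(behavior$motor)), function(i)
    detect_cr(behavior$motor[i, ], cfg, us_onset, cfg$grid_dt,
              threshold = threshold))
  behavior$trials$cr <- vapply(det, `[[`, TRUE, "cr")
  behavior$trials$onset <- vapply(det, `[[`, 0, "onset")
  n <- nrow(behavior$trials)
  bs <- n / nrow(behavior$blocks)
  behavior$blocks$pct_cr <- vapply(
    split(behavior$trials$cr, (behavior$trials$trial - 1) %/% bs),
    function(x) 100 * mean(x), 0, USE.NAMES = FALSE)
  behavior$total_crs <- sum(behavior$trials$cr)
  onsets <- behavior$trials$onset[behavior$trials$cr]
  behavior$onset_mean <- if (length(onsets)) mean(onsets) else NA_real_
  behavior$onset_sd <- if (length(onsets) > 1) sd(onsets) else NA_real_
  behavior$threshold <- threshold
  behavior
}

#' @export
print.ebcc_behavior <- function(x, ...) {
  cat("EBCC behavior: ", x$total_crs, " CRs / ", nrow(x$trials),
      " trials (threshold ", signif(x$threshold, 3), " Hz)\n", sep = "")
  cat(" %CR per block:", paste(round(x$blocks$pct_cr), collapse = " "), "\n")
  if (is.finite(x$onset_mean))
    cat(sprintf(" CR onset: %.0f +/- %.0f ms before US\n",
                x$onset_mean, x$onset_sd %||% NA))
  invisible(x)
}
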