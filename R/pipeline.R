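#' Run one experimental condition
#'
#' Full pipeline for one condition: build the control connectome, apply the
#' lesion (if any), generate stimuli, run the 100-trial session and analyze
#' behavior — once per seed. The CR detection threshold is either fixed, or
#' (for the control condition with `calibrate = TRUE`) placed per seed so
#' that the sixth block yields 70% CRs, the calibration criterion of the
#' physiological condition.
#'
#' @param condition `NULL`/`"control"` or a `lesion_spec`.
#' @param seeds Integer vector of master seeds (one session per seed).
#' @param config An [ebcc_config()].
#' @param threshold CR threshold (Hz) or per-seed numeric vector; `NULL`
#'   with `calibrate = TRUE` derives it from each session's sixth block.
#' @param calibrate Calibrate the threshold on block 6 (70% criterion)?
#' @param label Condition label; derived from the lesion kind by default.
#' @return Object of class `ebcc_experiment`: `label`, `seeds`, `behaviors`
#'   (per seed), `sessions` (per seed), pooled summary fields from the first
#'   seed (`total_crs`, `blocks`, `onset_mean`, `onset_sd`, `threshold`).
#' @export
run_experiment <- function(condition = NULL, seeds = 1, config = ebcc_config(),
                           threshold = NULL, calibrate = is.null(threshold),
                           label = NULL) {
  if (identical(condition, "control")) condition <- NULL
  if (!is.null(condition) && !inherits(condition, "lesion_spec"))
    stop("condition must be NULL, \"control\" or a lesion_spec")
  label <- label %||% if (is.null(condition)) "control" else
    paste0(condition$kind,
           if (condition$kind == "reduced_io") paste0("_", condition$fraction)
           else if (condition$kind == "synaptic_imbalance")
             paste0("_", condition$level) else "")
  behaviors <- list(); sessions <- list()
  thr <- rep_len(threshold %||% NA_real_, length(seeds))
  for (k in seq_along(seeds)) {
    seed <- seeds[k]
    conn <- build_connectome(config$network, derive_seed(seed, "connectome"),
                             config$neuron_params)
    les <- apply_lesion(conn, condition, config$protocol, seed)
    ses <- run_session(les$connectome, config$protocol, seed,
                       config$plasticity, dt = config$dt,
                       overlay = les$overlay,
                       ie_scale = les$ie_scale)
    beh <- analyze_session(ses, config$analysis)
    if (is.na(thr[k])) {
      thr[k] <- if (calibrate)
        calibrate_cr_threshold(beh$trials$strength,
                               block_size = config$protocol$block_size,
                               fallback = config$analysis$cr_threshold)
      else config$analysis$cr_threshold
    }
    beh <- redetect(beh, thr[k], config$protocol$us_onset)
    behaviors[[k]] <- beh; sessions[[k]] <- ses
  }
  b1 <- behaviors[[1]]
  structure(list(label = label, seeds = seeds, condition = condition,
                 behaviors = behaviors, sessions = sessions,
                 total_crs = b1$total_crs, blocks = b1$blocks,
                 onset_mean = b1$onset_mean, onset_sd = b1$onset_sd,
                 threshold = thr),
            class = "ebcc_experiment")
}

#' @export
print.ebcc_experiment <- function(x, ...) {
  cat("condition:", x$label, "(", length(x$seeds), "seed(s) )\n")
  print(x$behaviors[[1]])
  invisible(x)
}

# exact (binomial) McNemar below 25 discordant pairs, chi-square with
# continuity correction otherwise
mcnemar_paired <- function(a, b) {
  n01 <- sum(!a & b); n10 <- sum(a & !b)
  nd <- n01 + n10
  if (nd == 0) return(1)
  if (nd < 25) binom.test(n10, nd, 0.5)$p.value
  else {
    stat <- (abs(n10 - n01) - 1)^2 / nd
    pchisq(stat, 1, lower.tail = FALSE)
  }
}

#' Compare two conditions
#'
#' Wilcoxon rank tests on CR-onset, SDF-change and baseline distributions
#' (outliers excluded by Tukey fences for the distribution-valued indices,
#' as in the reference analysis), and McNemar's test on the per-trial CR
#' flags paired by trial index. Distributions that are empty on either side
#' are skipped and flagged.
#'
#' @param a,b `ebcc_experiment` objects (first seed compared), or
#'   `ebcc_behavior` objects.
#' @param alpha Significance level.
#' @return data.frame with one row per test: `measure`, `p`, `significant`,
#'   `skipped`.
#' @export
compare_conditions <- function(a, b, alpha = 0.01) {
  ba <- if (inherits(a, "ebcc_experiment")) a$behaviors[[1]] else a
  bb <- if (inherits(b, "ebcc_experiment")) b$behaviors[[1]] else b
  if (nrow(ba$trials) != nrow(bb$trials))
    stop("conditions ran different protocol lengths")
  wt <- function(x, y, trim = TRUE) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (!length(x) || !length(y))
      return(c(p = NA_real_, skipped = 1))
    if (trim && length(x) >= 4) x <- exclude_outliers(x)
    if (trim && length(y) >= 4) y <- exclude_outliers(y)
    c(p = suppressWarnings(wilcox.test(x, y)$p.value), skipped = 0)
  }
  rows <- rbind(
    onset = wt(ba$trials$onset[ba$trials$cr], bb$trials$onset[bb$trials$cr],
               trim = FALSE),
    sdf_change_pc = wt(ba$sdf_change_pc, bb$sdf_change_pc),
    sdf_change_dcn = wt(ba$sdf_change_dcn, bb$sdf_change_dcn),
    baseline_rate_pc = wt(ba$baseline_pc$rate, bb$baseline_pc$rate),
    baseline_cv_pc = wt(ba$baseline_pc$cv_isi, bb$baseline_pc$cv_isi),
    baseline_rate_dcn = wt(ba$baseline_dcn$rate, bb$baseline_dcn$rate),
    baseline_cv_dcn = wt(ba$baseline_dcn$cv_isi, bb$baseline_dcn$cv_isi),
    pct_cr = c(p = mcnemar_paired(ba$trials$cr, bb$trials$cr), skipped = 0))
  data.frame(measure = rownames(rows), p = rows[, "p"],
             significant = !is.na(rows[, "p"]) & rows[, "p"] < alpha,
             skipped = rows[, "skipped"] == 1, row.names = NULL)
}

#' Dose-response regression of CR counts on damage level
#'
#' Ordinary least squares of the total CR counts on the damage fractions,
#' with the coefficient of determination and the slope test p-value.
#'
#' @param damage Damage levels (>= 3 distinct values).
#' @param crs Total CR counts, same length.
#' @return List with `r2`, `p`, `slope`, `intercept`.
#' @export
dose_response_regression <- function(damage, crs) {
  stopifnot(length(damage) == length(crs), length(damage) >= 3)
  if (length(unique(damage)) < 2) stop("degenerate damage levels")
  if (stats::var(crs) == 0)
    return(list(r2 = 0, p = NA_real_, slope = 0, intercept = crs[1]))
  fit <- lm(crs ~ damage)
  s <- summary(fit)
  list(r2 = s$r.squared,
       p = if (nrow(s$coefficients) > 1) s$coefficients[2, 4] else NA_real_,
       slope = coef(fit)[[2]], intercept = coef(fit)[[1]])
}

#' Run the full condition matrix
#'
#' The eight conditions of the study: control, reduced olivocerebellar
#' input at 25/50/75%, intrinsic and IO-induced Purkinje burst firing, and
#' mild/severe synaptic imbalance. The CR threshold is calibrated on the
#' control session (70% CRs in block 6) and reused, fixed, for every
#' lesioned condition run with the matched seed.
#'
#' @param seed Master seed (matched across conditions).
#' @param config An [ebcc_config()].
#' @param conditions Optional named list of `lesion_spec`s to run instead of
#'   the default matrix (control is always run first).
#' @return Named list of `ebcc_experiment` objects, plus attribute
#'   `threshold` (the calibrated CR threshold).
#' @export
run_condition_matrix <- function(seed = 1, config = ebcc_config(),
                                 conditions = NULL) {
  if (is.null(conditions))
    conditions <- list(
      reduced_io_0.25 = lesion_reduced_io(0.25),
      reduced_io_0.5 = lesion_reduced_io(0.5),
      reduced_io_0.75 = lesion_reduced_io(0.75),
      intrinsic_burst = lesion_intrinsic_burst(),
      io_burst = lesion_io_burst(),
      imbalance_mild = lesion_synaptic_imbalance("mild"),
      imbalance_severe = lesion_synaptic_imbalance("severe"))
  control <- run_experiment(NULL, seed, config, calibrate = TRUE)
  thr <- control$threshold[1]
  out <- c(list(control = control),
           lapply(conditions, function(spec)
             run_experiment(spec, seed, config, threshold = thr)))
  attr(out, "threshold") <- thr
  out
}
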