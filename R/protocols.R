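#' Classify the outcome of a defibrillation attempt
#'
#' The activity metric is the fraction of excitable nodes above -50 mV
#' (recorded every sample by [simulate_tissue()]). The arrhythmia is deemed
#' terminated at the last time the metric reaches `threshold`, provided the
#' tissue then stays quiet for at least `quiet_ms` and through the end of
#' the success window (`window` ms after light offset — the protocol's
#' monitoring period for resumption of stable reentry). Termination at or
#' before light offset is a `success_during_light`; termination after
#' offset but early enough that the remaining window confirms quiescence is
#' a `success_indirect` (spontaneous termination after illumination ends
#' due to light-induced destabilization); anything else is a `failure`.
#' Recordings that stopped early because the tissue went quiescent count as
#' quiet through the window (quiescent tissue cannot restart without a
#' stimulus).
#'
#' @param recording A [simulate_tissue()] recording without electrical
#'   stimuli after light onset.
#' @param light_off Light offset time, ms.
#' @param window Success window after light offset, ms (default 800).
#' @param threshold Active-fraction threshold (default 0.005).
#' @param quiet_ms Minimum quiet tail, ms (default 200).
#' @return An object of class `defib_outcome`: list with `outcome`
#'   (`"success_during_light"`, `"success_indirect"` or `"failure"`) and
#'   `termination_ms` (NA for failures).
#' @export
detect_termination <- function(recording, light_off, window = 800,
                               threshold = 0.005, quiet_ms = 200) {
  stopifnot(inherits(recording, "tissue_recording"))
  t <- recording$t_ms; a <- recording$activity
  t_end_needed <- light_off + window
  if (!recording$stopped_early && max(t) < t_end_needed)
    stop(sprintf(
      "recording ends at %.0f ms; must extend to %.0f ms past light offset",
      max(t), t_end_needed))
  active_t <- t[a >= threshold]
  if (length(active_t) == 0) {
    out <- list(outcome = "success_during_light", termination_ms = min(t))
  } else {
    t_last <- max(active_t)
    if (t_last > t_end_needed - quiet_ms && !recording$stopped_early) {
      out <- list(outcome = "failure", termination_ms = NA_real_)
    } else if (t_last <= light_off) {
      out <- list(outcome = "success_during_light", termination_ms = t_last)
    } else {
      out <- list(outcome = "success_indirect", termination_ms = t_last)
    }
  }
  structure(out, class = "defib_outcome")
}

#' @export
print.defib_outcome <- function(x, ...) {
  cat(sprintf("<defib_outcome> %s%s\n", x$outcome,
              if (!is.na(x$termination_ms))
                sprintf(" (termination at %.0f ms)", x$termination_ms)
              else ""))
  invisible(x)
}

wavelength_color <- function(nm) {
  if (nm >= 600) "red" else if (nm >= 500) "green" else "blue"
}

#' Irradiance x onset x opsin defibrillation sweep
#'
#' Runs one simulation per (opsin, irradiance, onset-time) combination,
#' each starting from the identical induced reentrant state, with a
#' `light_ms`-long endocardial illumination pulse and a `window`-ms
#' post-illumination success window. Light onsets are measured relative to
#' the predicted next activation of the induction reference probe, so the
#' onset set spans the reentrant cycle. The same diffuse expression map is
#' reused for every opsin; per-wavelength attenuation fields are computed
#' once. Per-cell simulation errors are recorded in the outcome table, not
#' raised.
#'
#' @param tissue A [make_tissue()] result.
#' @param induced An `induction_result` with `inducible = TRUE`.
#' @param opsins Character vector of opsin presets (default all three).
#' @param irradiances Surface irradiances, mW/mm^2. The protocol grids are
#'   decade-spanning: atrial 0.001-1, ventricular 0.001-10.
#' @param onsets Light onset offsets, ms, relative to the reference
#'   activation (atrial protocol: 0, 70, 140; ventricular: 0, 100, 200).
#' @param expression An [build_expression_map()] map (default: 58.2%
#'   diffuse expression with the tissue seed).
#' @param light_ms Illumination duration, ms (default 1000).
#' @param window Post-light success window, ms (default 800).
#' @param dt Time step, ms (desk protocol default 0.05).
#' @param plateau_ms Length of the end-of-light interval over which the
#'   illuminated-endocardium mean voltage is summarized.
#' @param verbose Print one line per attempt.
#' @return An object of class `sweep_table`: list with `counts` (matrix
#'   irradiance x opsin of successes out of `length(onsets)`), `attempts`
#'   (data frame with one row per attempt: opsin, irradiance, onset,
#'   outcome, termination time, endo/epi plateau voltages), `onsets`,
#'   `light_ms`, `window` and `meta`.
#' @export
run_defib_sweep <- function(tissue, induced,
                            opsins = c("GtACR1", "ChR2-RED", "ChR2"),
                            irradiances = c(0.05, 0.5, 5),
                            onsets = c(0, 100, 200),
                            expression = NULL, light_ms = 1000,
                            window = 800, dt = 0.05, plateau_ms = 200,
                            verbose = FALSE) {
  stopifnot(inherits(tissue, "tissue_model"))
  if (!isTRUE(induced$inducible))
    stop("induced state is not reentrant")
  if (is.null(expression))
    expression <- build_expression_map(tissue, seed = tissue$spec$seed)
  A <- assemble_diffusion(tissue)
  # reference activation: predicted next firing of the induction probe
  acts <- induced$probe_activations
  cl <- induced$cycle_length_ms
  t_ref <- max(acts) + cl - induced$end_ms
  if (t_ref < 0) t_ref <- t_ref %% cl

  expr_endo <- intersect(tissue$surfaces_active$endo, which(expression))
  groups <- list(endo_expr = expr_endo, epi = tissue$surfaces_active$epi)

  fields <- list()
  rows <- list()
  counts <- matrix(0L, length(irradiances), length(opsins),
                   dimnames = list(as.character(irradiances), opsins))
  for (op_name in opsins) {
    op <- opsin_params(op_name)
    col <- wavelength_color(op$peak_wavelength)
    if (is.null(fields[[col]]))
      fields[[col]] <- solve_attenuation(tissue, light_preset(col), "endo")
    for (ee in irradiances) {
      for (on in onsets) {
        light_on <- t_ref + on
        light_off <- light_on + light_ms
        res <- tryCatch({
          rec <- simulate_tissue(
            tissue, duration = light_off + window + 10, dt = dt,
            state = induced$state,
            light = list(light_pulse(light_on, light_ms, ee)),
            opsin = op, expression = expression,
            attenuation = fields[[col]], groups = groups,
            early_exit = TRUE, early_after = light_off, A = A)
          outc <- detect_termination(rec, light_off, window)
          sel <- rec$t_ms >= light_off - plateau_ms & rec$t_ms <= light_off
          list(outcome = outc$outcome, term = outc$termination_ms,
               endo_plateau = mean(rec$group_V["endo_expr", sel]),
               epi_plateau = mean(rec$group_V["epi", sel]))
        }, error = function(e)
          list(outcome = paste("error:", conditionMessage(e)),
               term = NA_real_, endo_plateau = NA_real_,
               epi_plateau = NA_real_))
        ok <- res$outcome %in% c("success_during_light", "success_indirect")
        if (ok)
          counts[as.character(ee), op_name] <-
            counts[as.character(ee), op_name] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          opsin = op_name, irradiance = ee, onset = on,
          light_on = light_on, outcome = res$outcome,
          termination_ms = res$term, endo_plateau_mV = res$endo_plateau,
          epi_plateau_mV = res$epi_plateau)
        if (verbose)
          message(sprintf("%8s E=%g on=+%g -> %s", op_name, ee, on,
                          res$outcome))
      }
    }
  }
  structure(
    list(counts = counts, attempts = do.call(rbind, rows), onsets = onsets,
         light_ms = light_ms, window = window,
         meta = list(irradiances = irradiances, opsins = opsins,
                     expression_fraction = attr(expression, "fraction"),
                     expression_seed = attr(expression, "seed"),
                     t_ref = t_ref, dt = dt)),
    class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf(
    "<sweep_table> successes out of %d onsets (%g ms light, %g ms window)\n",
    length(x$onsets), x$light_ms, x$window))
  tab <- x$counts
  cat("  irradiance (mW/mm^2):\n")
  print(tab)
  invisible(x)
}

#' Minimal fully-successful irradiance per opsin
#'
#' The smallest irradiance in the sweep grid at which every onset time
#' succeeded (`n/n`); `Inf` if none.
#'
#' @param sweep A [run_defib_sweep()] table.
#' @return Named numeric vector, one entry per opsin.
#' @export
min_full_success <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_table"))
  n_on <- length(sweep$onsets)
  ir <- as.numeric(rownames(sweep$counts))
  vapply(colnames(sweep$counts), function(op) {
    full <- ir[sweep$counts[, op] == n_on]
    if (length(full)) min(full) else Inf
  }, 0)
}

#' Single-cell action-potential suppression experiment
#'
#' Applies two identical electrical stimuli, one before light onset and one
#' during illumination, to a single opsin-expressing myocyte. The verdict
#' is `TRUE` (suppression) when the first stimulus elicits an action
#' potential (post-stimulus peak above 0 mV) and the second does not
#' (membrane stays below -20 mV once the stimulus artifact has dissipated,
#' `artifact_ms` after stimulus offset). With GtACR1 under green light the
#' membrane is instead forced to a plateau near the -40 mV chloride
#' reversal.
#'
#' @param membrane `"ventricular"` or `"atrial"`.
#' @param opsin [opsin_params()] (default GtACR1).
#' @param e_e Irradiance, mW/mm^2 (protocol value 1.00).
#' @param stim_before,stim_during Stimulus onsets, ms.
#' @param light_on,light_ms Illumination onset and duration, ms.
#' @param amplitude,pulse_ms Stimulus strength (pA/pF) and duration (ms).
#' @param artifact_ms Settling margin after stimulus offset before the
#'   response window opens, ms.
#' @param duration Total simulated time, ms.
#' @return List with `suppressed` (logical verdict), `peak_before`,
#'   `peak_during` (post-stimulus response peaks, mV), `plateau`
#'   (mean voltage over the last 100 ms of light) and `trace`.
#' @export
run_single_cell_suppression <- function(membrane = "ventricular",
                                        opsin = opsin_params("GtACR1"),
                                        e_e = 1.0, stim_before = 100,
                                        stim_during = 1000, light_on = 500,
                                        light_ms = 1000, amplitude = 30,
                                        pulse_ms = 5, artifact_ms = 3,
                                        duration = 3600) {
  tr <- simulate_cell(
    membrane, duration = duration,
    stimuli = data.frame(start = c(stim_before, stim_during),
                         duration = pulse_ms, amplitude = amplitude),
    light = data.frame(start = light_on, duration = light_ms,
                       irradiance = e_e),
    opsin = opsin)
  resp_peak <- function(t0) {
    sel <- tr$time_ms >= t0 + pulse_ms + artifact_ms &
      tr$time_ms <= t0 + pulse_ms + 100
    max(tr$V_mV[sel])
  }
  pb <- resp_peak(stim_before)
  pd <- resp_peak(stim_during)
  plateau_sel <- tr$time_ms >= light_on + light_ms - 100 &
    tr$time_ms <= light_on + light_ms
  list(suppressed = pb > 0 && pd < -20, peak_before = pb, peak_during = pd,
       plateau = mean(tr$V_mV[plateau_sel]), trace = tr)
}
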