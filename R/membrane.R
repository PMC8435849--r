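#' Region kinds of diseased cardiac tissue
#'
#' Tissue nodes carry one of five labels: `atrial_normal` and
#' `atrial_fibrotic` for atrial-like tissue, `ventricular_normal` and
#' `ventricular_BZ` (peri-infarct border zone) for ventricular-like tissue,
#' and `scar`. Scar is non-excitable: no ionic model is evaluated there and
#' scar nodes carry no conductive coupling.
#'
#' @return Character vector of the recognized region kinds.
#' @export
region_kinds <- function() {
  c("atrial_normal", "atrial_fibrotic", "ventricular_normal",
    "ventricular_BZ", "scar")
}

model_id <- function(membrane) {
  switch(membrane, ventricular = 0L, atrial = 1L,
         stop("unknown membrane kind: ", membrane))
}

#' Ionic remodeling for diseased-tissue regions
#'
#' Returns the conductance multipliers applied to the baseline myocyte model
#' in remodeled regions. The multipliers act on the currents that dominate
#' conduction and repolarization: for ventricular border zone, sodium
#' (x0.38), L-type calcium (x0.69) and the rapid/slow delayed rectifiers
#' (x0.30 / x0.20); for fibrosis-remodeled atrial tissue, sodium (x0.6),
#' L-type calcium (x0.5) and the inward rectifier (x0.5). These values are
#' conventions from the infarct- and fibrosis-modeling literature, exposed
#' here as configuration (they are not measurements of any particular
#' cohort); atrial fibrotic tissue additionally carries reduced tissue-level
#' conductivity (see [geometry_spec()]).
#'
#' @param region One of [region_kinds()] (not `"scar"`).
#' @param overrides Optional named list overriding individual multipliers
#'   (`g_Na`, `g_CaL`, `g_Kr`, `g_Ks`, `g_K1`).
#' @return Named numeric vector of multipliers, in the slot order used by
#'   the solver: ventricular `(g_Na, g_CaL, g_Kr, g_Ks)`, atrial
#'   `(g_Na, g_CaL, g_K1, unused)`.
#' @export
apply_region_remodeling <- function(region, overrides = NULL) {
  region <- match.arg(region, region_kinds())
  if (region == "scar") stop("scar carries no ionic model")
  sc <- switch(region,
    atrial_normal = c(g_Na = 1, g_CaL = 1, g_K1 = 1, unused = 1),
    atrial_fibrotic = c(g_Na = 0.6, g_CaL = 0.5, g_K1 = 0.5, unused = 1),
    ventricular_normal = c(g_Na = 1, g_CaL = 1, g_Kr = 1, g_Ks = 1),
    ventricular_BZ = c(g_Na = 0.38, g_CaL = 0.69, g_Kr = 0.30, g_Ks = 0.20))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(sc))
    if (length(bad)) stop("unknown remodeling multiplier(s): ",
                          paste(bad, collapse = ", "))
    sc[names(overrides)] <- unlist(overrides)
  }
  sc
}

# scale matrix (4 x 2) used by the solvers: column 1 = normal, column 2 =
# remodeled (fibrotic / BZ)
region_scale_matrix <- function(membrane, overrides = NULL) {
  if (membrane == "ventricular")
    cbind(apply_region_remodeling("ventricular_normal"),
          apply_region_remodeling("ventricular_BZ", overrides))
  else
    cbind(apply_region_remodeling("atrial_normal"),
          apply_region_remodeling("atrial_fibrotic", overrides))
}

# memoised resting-state cache
.rest_cache <- new.env(parent = emptyenv())

#' Stabilized resting state of a myocyte model
#'
#' Returns the quiescent steady state of the chosen ionic model (human
#' atrial, Courtemanche-type, or human ventricular, epicardial ten
#' Tusscher-type), obtained by integrating the published initial conditions
#' without stimulation for `equilibrate_ms` (default 10 s) and cached per
#' (model, region). The result is stationary: |dV/dt| < 0.01 mV/ms.
#'
#' @param membrane `"ventricular"` or `"atrial"`.
#' @param region Region kind (default the normal region for the model).
#'   Remodeled regions equilibrate to their own resting state.
#' @param equilibrate_ms Unpaced equilibration time, ms.
#' @param dt Integration step, ms.
#' @return Numeric state vector (V first; see [simulate_cell()] for use).
#' @export
init_resting <- function(membrane = c("ventricular", "atrial"),
                         region = NULL, equilibrate_ms = 10000, dt = 0.025) {
  membrane <- match.arg(membrane)
  if (is.null(region))
    region <- paste0(membrane, ifelse(membrane == "atrial", "_normal",
                                      "_normal"))
  region <- match.arg(region, region_kinds())
  if (region == "scar") stop("scar has no ionic state")
  if (!startsWith(region, substr(membrane, 1, 4)))
    stop(sprintf("region '%s' is incompatible with %s membrane",
                 region, membrane))
  key <- paste(membrane, region, equilibrate_ms, dt, sep = "|")
  if (!is.null(.rest_cache[[key]])) return(.rest_cache[[key]])
  sc <- apply_region_remodeling(region)
  y0 <- cell_initial_state_cpp(model_id(membrane))
  nothing <- matrix(numeric(0), 0, 3)
  r <- cell_run_cpp(model_id(membrane), y0, dt,
                    as.integer(round(equilibrate_ms / dt)), 0L, nothing,
                    nothing, 0L, numeric(0), numeric(0), unname(sc))
  .rest_cache[[key]] <- r$state
  r$state
}

opsin_id <- function(params) {
  if (is.null(params)) 0L else if (params$kind == "GtACR1") 1L else 2L
}

opsin_par_vector <- function(params) {
  if (is.null(params)) return(numeric(0))
  unlist(params[vapply(params, is.numeric, logical(1))])
}

#' Simulate a single myocyte with electrical stimuli and illumination
#'
#' Integrates one cell of the chosen ionic model (Rush-Larsen updates for
#' the gating variables, forward Euler for voltage and concentrations),
#' optionally coupled to a light-gated opsin current at full single-cell
#' expression. Direct (unattenuated) irradiance is applied during light
#' pulses.
#'
#' @param membrane `"ventricular"` or `"atrial"`.
#' @param duration Simulated time, ms.
#' @param dt Time step, ms (must be <= 0.05).
#' @param stimuli Data frame / matrix with columns `start`, `duration`,
#'   `amplitude` (ms, ms, pA/pF); positive amplitude depolarizes.
#' @param light Data frame / matrix with columns `start`, `duration`,
#'   `irradiance` (ms, ms, mW/mm^2).
#' @param opsin Optional [opsin_params()] set.
#' @param region Region kind for remodeling (default normal).
#' @param state Initial state; default [init_resting()].
#' @param sample_ms Recording interval, ms.
#' @return An object of class `cell_trace`: data.frame with `time_ms`,
#'   `V_mV`, `I_opsin`, `Ee`, plus attributes `state` and `opsin_state`
#'   holding the final states.
#' @export
simulate_cell <- function(membrane = c("ventricular", "atrial"),
                          duration = 1000, dt = 0.025, stimuli = NULL,
                          light = NULL, opsin = NULL, region = NULL,
                          state = NULL, sample_ms = 0.5) {
  membrane <- match.arg(membrane)
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  if (is.null(region)) region <- paste0(membrane, "_normal")
  if (is.null(state)) state <- init_resting(membrane, region)
  sc <- unname(apply_region_remodeling(region))
  stim_m <- protocol_matrix(stimuli, c("start", "duration", "amplitude"))
  light_m <- protocol_matrix(light, c("start", "duration", "irradiance"))
  op_id <- opsin_id(opsin)
  op0 <- if (op_id == 0L) numeric(0) else unname(opsin_init(opsin))
  r <- cell_run_cpp(model_id(membrane), state, dt,
                    as.integer(round(duration / dt)),
                    max(1L, as.integer(round(sample_ms / dt))), stim_m,
                    light_m, op_id, opsin_par_vector(opsin), op0, sc)
  out <- data.frame(time_ms = r$time_ms, V_mV = r$V_mV,
                    I_opsin = r$I_opsin, Ee = r$Ee)
  structure(out, class = c("cell_trace", "data.frame"),
            state = r$state, opsin_state = r$opsin_state,
            membrane = membrane, region = region)
}

#' @export
plot.cell_trace <- function(x, ...) {
  graphics::plot(x$time_ms, x$V_mV, type = "l", xlab = "time (ms)",
                 ylab = "Vm (mV)", ...)
  lit <- range(x$time_ms[x$Ee > 0])
  if (is.finite(lit[1]))
    graphics::rect(lit[1], graphics::par("usr")[3], lit[2],
                   graphics::par("usr")[4], border = NA,
                   col = grDevices::adjustcolor("forestgreen", 0.15))
  invisible(x)
}

protocol_matrix <- function(x, cols) {
  if (is.null(x) || NROW(x) == 0L) return(matrix(numeric(0), 0, 3))
  m <- as.matrix(as.data.frame(x)[, cols])
  storage.mode(m) <- "double"
  unname(m)
}

#' Advance a single myocyte state by one integration step
#'
#' Low-level single-step interface: Rush-Larsen update of the gates and
#' forward-Euler update of voltage and concentrations under an applied
#' current. Mainly useful for oracle-style tests; production runs use
#' [simulate_cell()] and [simulate_tissue()], which keep the loop compiled.
#'
#' @param state Numeric state vector (see [init_resting()]).
#' @param i_applied Depolarizing applied current, pA/pF.
#' @param dt Time step, ms (<= 0.05).
#' @param membrane `"ventricular"` or `"atrial"`.
#' @param region Region kind.
#' @return Updated state vector.
#' @export
ionic_step <- function(state, i_applied = 0, dt = 0.025,
                       membrane = c("ventricular", "atrial"),
                       region = NULL) {
  membrane <- match.arg(membrane)
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  if (is.null(region)) region <- paste0(membrane, "_normal")
  sc <- unname(apply_region_remodeling(region))
  stim <- matrix(c(0, dt, i_applied), 1, 3)
  nothing <- matrix(numeric(0), 0, 3)
  r <- cell_run_cpp(model_id(membrane), state, dt, 1L, 0L, stim, nothing,
                    0L, numeric(0), numeric(0), sc)
  r$state
}
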