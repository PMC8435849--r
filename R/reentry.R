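#' Desk-scale synthetic tissue presets
#'
#' Named [geometry_spec()] configurations used by the defibrillation
#' protocols at bench scale:
#'
#' * `"ventricular-desk"` — a 23 x 23 x 2 mm ventricular-like slab at
#'   0.5 mm spacing carrying a transmural infarct scar (radius 6.5 mm) with
#'   a 1 mm border-zone rim; tissue beyond 11 mm radius is also scar, so
#'   the excitable myocardium forms an annular channel around the infarct —
#'   the synthetic analogue of a reentrant VT circuit circling a scar.
#' * `"ventricular-protected"` — a 22 x 22 x 5 mm slab with a central
#'   transmural scar (radius 5.5 mm), a border-zone rim and, in addition,
#'   an endocardial scar cap over the channel (from the endo surface down
#'   to 1 mm below the epicardium, radius 10.5 mm), creating an
#'   epicardial-side reentry path that is several green penetration depths
#'   away from the illuminated endocardium and electrotonically insulated
#'   from it — a protected epicardial circuit. Tissue beyond the cap
#'   radius remains excitable at full thickness.
#' * `"ventricular-unprotected"` — the same 5 mm slab without the cap
#'   (the control for the protected-circuit comparison).
#' * `"atrial-desk"` — a 20 x 20 x 2.5 mm homogeneous atrial-like slab.
#'
#' The ventricular desk presets reduce the monodomain diffusivities to
#' 35% of the organ-scale defaults and accelerate repolarization
#' (delayed-rectifier conductances x3), shrinking the reentrant wavelength
#' so that a sustained circuit fits a bench-sized slab; cycle lengths
#' remain in the clinical VT range. These are deliberate desk-scale study
#' conditions (see the methods vignette) — patient-specific thresholds are
#' not claimed.
#'
#' @param name Preset name.
#' @param seed Seed recorded in the spec.
#' @return A [geometry_spec()].
#' @export
slab_preset <- function(name = c("ventricular-desk", "ventricular-protected",
                                 "ventricular-unprotected", "atrial-desk"),
                        seed = 1L) {
  name <- match.arg(name)
  desk_cond <- c(0.13, 0.0325) * 0.35
  desk_scale <- list(normal = c(g_Kr = 3, g_Ks = 3))
  switch(name,
    "ventricular-desk" = geometry_spec(
      "ventricular", lateral = 23, thickness = 2.0, spacing = 0.5,
      disease = disease_scar(scar_radius = 6.5, bz_width = 1,
                             outer_radius = 11),
      cond = desk_cond, ionic_scale = desk_scale, seed = seed),
    "ventricular-protected" = geometry_spec(
      "ventricular", lateral = 22, thickness = 5, spacing = 0.5,
      disease = disease_scar(scar_radius = 5.5, bz_width = 1,
                             protect = TRUE, cap_radius = 10.5,
                             cap_depth = 4),
      cond = desk_cond, ionic_scale = desk_scale, seed = seed),
    "ventricular-unprotected" = geometry_spec(
      "ventricular", lateral = 22, thickness = 5, spacing = 0.5,
      disease = disease_scar(scar_radius = 5.5, bz_width = 1),
      cond = desk_cond, ionic_scale = desk_scale, seed = seed),
    "atrial-desk" = geometry_spec(
      "atrial", lateral = 20, thickness = 2.5, spacing = 0.45, seed = seed))
}

#' Induce reentry in a tissue slab
#'
#' Two induction methods are provided. `cross_field` (default at desk
#' scale) delivers an S1 pulse along a radial line on the west side of the
#' slab, followed by an S2 pulse covering the southern half at a coupling
#' interval chosen from `s2_scan`; inside the vulnerable window the S2
#' wavefront is blocked on its refractory (east) side and escapes across
#' the recovered S1 line, leaving a single wave circulating around the
#' central obstacle (or a functional core). `rapid_pacing` implements the
#' clinical-style induction trains: atrial — twelve 5 ms pulses starting
#' at a 300 ms coupling interval, decremented by 20 ms to 200 ms and then
#' held there; ventricular — eight 5 ms pulses at 600 ms followed by two
#' extrastimuli at the coupling intervals in `extra_ci`.
#'
#' Each candidate is verified by simulating at least `verify_ms` beyond
#' the last stimulus and requiring ongoing activity plus at least four
#' activations at a reference probe; the dominant cycle length is measured
#' from the probe's activation intervals. Failure to induce after the
#' configured scan is reported (`inducible = FALSE`), not an error.
#'
#' @param tissue A [make_tissue()] result.
#' @param method `"cross_field"` or `"rapid_pacing"`.
#' @param s2_scan Candidate S1-S2 coupling intervals, ms (cross-field).
#' @param extra_ci Extrastimulus coupling intervals, ms (ventricular
#'   rapid pacing).
#' @param verify_ms Stimulus-free persistence required to call the state
#'   reentrant, ms (>= 2000 recommended).
#' @param amplitude,pulse_ms Stimulus strength (pA/pF) and duration (ms).
#' @param dt Time step, ms (defaults to the desk protocol step, 0.05).
#' @param A Optional precomputed diffusion operator.
#' @return An object of class `induction_result`: list with `inducible`,
#'   `state` (the induced state matrix at the end of verification),
#'   `cycle_length_ms`, `s2_used`, `probe` (reference probe active index),
#'   `probe_activations`, `end_ms` and `recording`.
#' @export
induce_reentry <- function(tissue, method = c("cross_field", "rapid_pacing"),
                           s2_scan = seq(220, 320, by = 15),
                           extra_ci = c(320, 280), verify_ms = 2200,
                           amplitude = 40, pulse_ms = 5, dt = 0.05,
                           A = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(tissue, "tissue_model"))
  if (is.null(A)) A <- assemble_diffusion(tissue)
  nd <- tissue_nodes(tissue)
  ctr <- (tissue$dims[1:2] - 1) * tissue$spacing / 2
  h <- tissue$spacing
  west_line <- nd$active[abs(nd$y - ctr[2]) <= h / 2 & nd$x <= ctr[1]]
  south <- nd$active[nd$y < ctr[2] - h / 4]
  # reference probe: easternmost excitable mid-depth node
  midz <- nd[nd$iz == ceiling(tissue$dims[3] / 2), ]
  probe <- midz$active[which.max(midz$x)]
  rest <- resting_state_matrix(tissue)

  # two-stage verification: a short screening run that exits as soon as the
  # tissue goes quiescent, then a stimulus-free continuation to verify_ms
  verify <- function(state0, t0, stims, screen_ms = 700) {
    rec1 <- simulate_tissue(
      tissue, duration = t0 + screen_ms, dt = dt, state = state0,
      stimuli = stims, probes = probe, record_activations = TRUE,
      A = A, sample_ms = 1, early_exit = TRUE, early_after = t0 + 50)
    acts1 <- rec1$activations[[probe]]
    acts1 <- acts1[acts1 > t0 + 100]
    if (rec1$stopped_early || rec1$activity[length(rec1$activity)] == 0)
      return(list(ok = FALSE))
    off <- rec1$end_ms
    rec2 <- simulate_tissue(
      tissue, duration = t0 + verify_ms - off, dt = dt,
      state = rec1$final_state, probes = probe, record_activations = TRUE,
      A = A, sample_ms = 1, early_exit = TRUE, early_after = 0)
    acts <- c(acts1, rec2$activations[[probe]] + off)
    ok <- !rec2$stopped_early && length(acts) >= 4 &&
      rec2$activity[length(rec2$activity)] > 0 &&
      (off + rec2$end_ms - max(acts)) < 1.5 * stats::median(diff(acts))
    list(ok = isTRUE(ok), rec = rec2,
         cl = if (length(acts) >= 3) stats::median(diff(acts)) else NA_real_,
         acts = acts, end_ms = off + rec2$end_ms)
  }

  if (method == "cross_field") {
    for (s2 in s2_scan) {
      stims <- list(stim_pulse(5, pulse_ms, amplitude, west_line),
                    stim_pulse(5 + s2, pulse_ms, amplitude, south))
      v <- verify(rest, 5 + s2 + pulse_ms, stims)
      if (v$ok)
        return(structure(
          list(inducible = TRUE, state = v$rec$final_state,
               cycle_length_ms = v$cl, s2_used = s2, probe = probe,
               probe_activations = v$acts, end_ms = v$end_ms,
               method = method, recording = v$rec),
          class = "induction_result"))
    }
    return(structure(list(inducible = FALSE, method = method,
                          s2_scan = s2_scan),
                     class = "induction_result"))
  }

  # rapid pacing from the west line
  if (tissue$membrane == "atrial") {
    cis <- c(300, 280, 260, 240, 220, 200, rep(200, 6))
  } else {
    cis <- c(rep(600, 8), extra_ci)
  }
  onsets <- 5 + cumsum(c(0, cis[-length(cis)]))
  stims <- lapply(onsets, function(t0)
    stim_pulse(t0, pulse_ms, amplitude, west_line))
  v <- verify(rest, max(onsets) + pulse_ms, stims)
  if (v$ok)
    structure(list(inducible = TRUE, state = v$rec$final_state,
                   cycle_length_ms = v$cl, s2_used = NA_real_, probe = probe,
                   probe_activations = v$acts, end_ms = v$end_ms,
                   method = method, recording = v$rec),
              class = "induction_result")
  else
    structure(list(inducible = FALSE, method = method),
              class = "induction_result")
}

#' @export
print.induction_result <- function(x, ...) {
  if (isTRUE(x$inducible))
    cat(sprintf(
      "<induction_result> reentry induced (%s%s), cycle length %.0f ms\n",
      x$method,
      if (!is.na(x$s2_used)) sprintf(", S2 = %g ms", x$s2_used) else "",
      x$cycle_length_ms))
  else
    cat("<induction_result> non-inducible with the configured scan\n")
  invisible(x)
}
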