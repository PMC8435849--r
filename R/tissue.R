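#' Assemble the anisotropic monodomain diffusion operator
#'
#' Builds the finite-difference discretization of `div(D grad V)` over the
#' excitable (non-scar) nodes of a tissue model, in units of 1/ms (the
#' diffusivity tensor `D = D_T I + (D_L - D_T) f f^T` already folds the
#' conductivity, surface-to-volume ratio and membrane capacitance). Fibers
#' lie in the wall plane and rotate linearly across the wall, so within
#' each transmural layer the tensor is constant; in-plane cross-derivative
#' terms use the standard four-corner stencil. Boundary and scar interfaces
#' are zero-flux: couplings simply vanish there and the diagonal is set so
#' every row sums to zero (a constant field diffuses to nothing, and total
#' charge is conserved). Node-level conductivity multipliers (fibrosis)
#' enter as the geometric mean over each edge. The operator is symmetric.
#'
#' @param tissue A [make_tissue()] result.
#' @return A `dgCMatrix` of dimension n_active x n_active.
#' @export
assemble_diffusion <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  nx <- tissue$dims[1]; ny <- tissue$dims[2]; nz <- tissue$dims[3]
  ng <- nx * ny * nz
  h2 <- tissue$spacing^2
  act <- tissue$act_of_grid
  na_ <- length(tissue$active)
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  DL <- tissue$cond[1]; DT <- tissue$cond[2]
  th <- tissue$theta
  Dxx <- DT + (DL - DT) * cos(th)^2
  Dyy <- DT + (DL - DT) * sin(th)^2
  Dxy <- (DL - DT) * sin(th) * cos(th)
  s <- numeric(ng)
  s[tissue$active] <- tissue$cond_scale

  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  add_dir <- function(di, dj, dk, wt_by_layer) {
    ok <- (ix + di >= 1L) & (ix + di <= nx) &
          (iy + dj >= 1L) & (iy + dj <= ny) &
          (iz + dk >= 1L) & (iz + dk <= nz) & !is.na(act)
    g1 <- which(ok)
    g2 <- g1 + di + dj * nx + dk * (nx * ny)
    keep <- !is.na(act[g2])
    g1 <- g1[keep]; g2 <- g2[keep]
    w <- wt_by_layer[iz[g1]] * sqrt(s[g1] * s[g2]) / h2
    ii <<- c(ii, act[g1]); jj <<- c(jj, act[g2]); ww <<- c(ww, w)
  }
  add_dir(+1L, 0L, 0L, Dxx); add_dir(-1L, 0L, 0L, Dxx)
  add_dir(0L, +1L, 0L, Dyy); add_dir(0L, -1L, 0L, Dyy)
  add_dir(0L, 0L, +1L, rep(DT, nz)); add_dir(0L, 0L, -1L, rep(DT, nz))
  add_dir(+1L, +1L, 0L, Dxy / 2); add_dir(-1L, -1L, 0L, Dxy / 2)
  add_dir(+1L, -1L, 0L, -Dxy / 2); add_dir(-1L, +1L, 0L, -Dxy / 2)

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(na_, na_))
  A <- (A + Matrix::t(A)) / 2
  Matrix::diag(A) <- 0
  Matrix::diag(A) <- -Matrix::rowSums(A)
  methods::as(A, "generalMatrix")
}

#' Electrical stimulus pulse for tissue simulations
#'
#' @param start Onset, ms.
#' @param duration Pulse duration, ms (> 0).
#' @param amplitude Depolarizing current density, pA/pF.
#' @param nodes Active-node indices receiving the pulse.
#' @return A `stim_pulse` list.
#' @export
stim_pulse <- function(start, duration, amplitude, nodes) {
  stopifnot(duration > 0, is.finite(amplitude), length(nodes) >= 1)
  structure(list(start = start, duration = duration, amplitude = amplitude,
                 nodes = as.integer(nodes)), class = "stim_pulse")
}

#' Illumination pulse for tissue simulations
#'
#' @param start Onset, ms.
#' @param duration Pulse duration, ms (default 1000, the protocol length).
#' @param irradiance Surface irradiance, mW/mm^2.
#' @return A `light_pulse` list.
#' @export
light_pulse <- function(start, duration = 1000, irradiance) {
  stopifnot(duration > 0, irradiance >= 0)
  structure(list(start = start, duration = duration,
                 irradiance = irradiance), class = "light_pulse")
}

default_dt <- function(membrane) if (membrane == "atrial") 0.05 else 0.025

# initial state matrix (NSTATE x n_active) from per-region resting states
resting_state_matrix <- function(tissue, equilibrate_ms = 10000) {
  memb <- tissue$membrane
  base <- init_resting(memb, paste0(memb, "_normal"),
                       equilibrate_ms = equilibrate_ms)
  ns <- length(base)
  st <- matrix(base, ns, length(tissue$active))
  if (any(tissue$region == 1L)) {
    rem <- init_resting(memb,
                        if (memb == "atrial") "atrial_fibrotic"
                        else "ventricular_BZ",
                        equilibrate_ms = equilibrate_ms)
    st[, tissue$region == 1L] <- rem
  }
  st
}

#' Run an opsin-coupled monodomain tissue simulation
#'
#' The workhorse simulation loop: per-node membrane kinetics (Rush-Larsen
#' gating, forward-Euler concentrations and voltage) with the opsin
#' photocurrent added at expressing nodes using each node's attenuated
#' local irradiance, operator-split against a Crank-Nicolson diffusion
#' solve (Jacobi-preconditioned conjugate gradients on the constant system
#' matrix). Deterministic given its inputs.
#'
#' @param tissue A [make_tissue()] result.
#' @param duration Simulated time, ms.
#' @param dt Ionic time step, ms; defaults to 0.025 (ventricular) /
#'   0.05 (atrial).
#' @param state Initial state matrix (`NSTATE x n_active`), e.g. the
#'   `final_state` of a previous recording; default: regional resting
#'   states.
#' @param stimuli List of [stim_pulse()] objects.
#' @param light List of [light_pulse()] objects (requires `opsin`,
#'   `expression` and `attenuation`).
#' @param opsin [opsin_params()] of the expressed opsin, or `NULL`.
#' @param expression [build_expression_map()] result, or `NULL` for no
#'   expression.
#' @param attenuation [solve_attenuation()] field; its wavelength must
#'   match the opsin's peak wavelength (configuration error otherwise).
#' @param opsin_state Initial opsin state matrix (5 x n_active), default
#'   dark-adapted.
#' @param probes Active-node indices whose voltage is recorded every
#'   `sample_ms`.
#' @param groups Named list of active-node index vectors; the mean voltage
#'   of each group is recorded every `sample_ms`.
#' @param sample_ms Sampling interval for probes/activity, ms.
#' @param snap_ms Voltage snapshot interval, ms (0 = none).
#' @param record_activations Record per-node activation times (upward
#'   crossings of -20 mV with a 50 ms lockout).
#' @param diff_every Number of ionic steps per diffusion solve.
#' @param early_exit If `TRUE`, the run stops once every node has been
#'   below `early_vmax` for `early_quiet_ms` after `early_after` ms
#'   (quiescent tissue cannot re-initiate reentry without a stimulus).
#' @param early_after,early_vmax,early_quiet_ms Early-exit parameters.
#' @param A Optional precomputed [assemble_diffusion()] operator.
#' @param cg_tol,cg_maxit Conjugate-gradient tolerance and iteration cap.
#' @return An object of class `tissue_recording`: list with `t_ms`,
#'   `activity` (fraction of excitable nodes above -50 mV), `probe_V`,
#'   `group_V`, `activations`, `snap_t`/`snapshots`, `final_state`,
#'   `final_opsin`, `end_ms`, `stopped_early` and `meta`.
#' @export
simulate_tissue <- function(tissue, duration, dt = NULL, state = NULL,
                            stimuli = list(), light = list(), opsin = NULL,
                            expression = NULL, attenuation = NULL,
                            opsin_state = NULL, probes = integer(0),
                            groups = list(), sample_ms = 1, snap_ms = 0,
                            record_activations = FALSE, diff_every = 2L,
                            early_exit = FALSE, early_after = NULL,
                            early_vmax = -60, early_quiet_ms = 100,
                            A = NULL, cg_tol = 1e-8, cg_maxit = 200L) {
  stopifnot(inherits(tissue, "tissue_model"))
  if (is.null(dt)) dt <- default_dt(tissue$membrane)
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  n <- length(tissue$active)
  if (inherits(stimuli, "stim_pulse")) stimuli <- list(stimuli)
  if (inherits(light, "light_pulse")) light <- list(light)

  # light configuration must be mutually consistent before any stepping
  if (length(light) > 0) {
    if (is.null(opsin) || is.null(expression) || is.null(attenuation))
      stop("light pulses require opsin, expression and attenuation")
    if (!isTRUE(all.equal(attenuation$wavelength, opsin$peak_wavelength)))
      stop(sprintf(
        "attenuation field wavelength (%g nm) does not match opsin '%s' (%g nm)",
        attenuation$wavelength, opsin$kind, opsin$peak_wavelength))
    if (length(expression) != n)
      stop("expression map does not match tissue")
  }
  if (is.null(state)) state <- resting_state_matrix(tissue)
  if (ncol(state) != n) stop("state matrix does not match tissue")

  if (is.null(A)) A <- assemble_diffusion(tissue)
  atten_act <- if (!is.null(attenuation)) {
    if (!identical(dim_field(attenuation), tissue$dims))
      stop("attenuation field does not match tissue grid")
    attenuation$factor[tissue$active]
  } else rep(0, n)
  expr_vec <- if (!is.null(expression)) as.logical(expression) else
    rep(FALSE, n)

  stim_times <- if (length(stimuli))
    do.call(rbind, lapply(stimuli, function(s)
      c(s$start, s$duration, s$amplitude))) else matrix(numeric(0), 0, 3)
  stim_nodes <- lapply(stimuli, function(s) as.integer(s$nodes - 1L))
  light_times <- if (length(light))
    do.call(rbind, lapply(light, function(l)
      c(l$start, l$duration, l$irradiance))) else matrix(numeric(0), 0, 3)

  op_id <- if (length(light) > 0) opsin_id(opsin) else 0L
  op0 <- matrix(0, 5, n)
  if (op_id > 0 && !is.null(opsin_state)) op0 <- opsin_state
  else if (op_id > 0) op0[1, ] <- if (op_id == 2L) 1 else 0

  if (is.null(early_after))
    early_after <- if (length(light))
      max(vapply(light, function(l) l$start + l$duration, 0)) else 0
  scales <- region_scale_matrix(tissue$membrane)
  isc <- tissue$spec$ionic_scale
  if (!is.null(isc)) {
    for (nm in names(isc)) {
      col <- match(nm, c("normal", "remodeled"))
      if (is.na(col)) stop("ionic_scale names must be 'normal'/'remodeled'")
      v <- isc[[nm]]
      idx <- match(names(v), rownames(scales))
      if (anyNA(idx)) stop("unknown ionic_scale entries")
      scales[idx, col] <- scales[idx, col] * v
    }
  }

  res <- tissue_run_cpp(
    model_id(tissue$membrane), state, as.integer(tissue$region),
    unname(scales), dt, as.integer(round(duration / dt)),
    as.integer(diff_every), A, stim_times, stim_nodes, light_times,
    atten_act, op_id, opsin_par_vector(opsin), expr_vec, op0,
    as.integer(probes - 1L),
    lapply(unname(as.list(groups)), function(g) as.integer(g - 1L)),
    sample_ms, snap_ms, -50, 50, record_activations, 0.005, early_exit,
    early_after, early_vmax, early_quiet_ms, cg_tol, as.integer(cg_maxit))

  probe_V <- res$probe_V
  if (length(probes)) rownames(probe_V) <- paste0("node", probes)
  group_V <- res$group_V
  if (length(groups)) rownames(group_V) <- names(groups)
  structure(
    list(t_ms = res$t_ms, activity = res$activity, probe_V = probe_V,
         group_V = group_V,
         activations = if (record_activations) res$activations else NULL,
         snap_t = res$snap_t, snapshots = res$snapshots,
         final_state = res$state, final_opsin = res$opsin_state,
         end_ms = res$end_ms, stopped_early = res$stopped_early,
         cg_iterations = res$cg_iterations,
         meta = list(membrane = tissue$membrane, dt = dt,
                     diff_every = diff_every, n_nodes = n,
                     opsin = if (op_id > 0) opsin$kind else "none",
                     light = light_times, sample_ms = sample_ms)),
    class = "tissue_recording")
}

dim_field <- function(field) field$dims

#' @export
print.tissue_recording <- function(x, ...) {
  cat(sprintf(
    "<tissue_recording> %s, %d nodes, %.0f ms simulated%s (dt %g ms, opsin %s)\n",
    x$meta$membrane, x$meta$n_nodes, x$end_ms,
    if (x$stopped_early) " [stopped early: quiescent]" else "",
    x$meta$dt, x$meta$opsin))
  cat(sprintf("  final activity: %.3f; probes: %d; snapshots: %d\n",
              x$activity[length(x$activity)], nrow(x$probe_V),
              length(x$snap_t)))
  invisible(x)
}

#' @export
plot.tissue_recording <- function(x, what = c("probes", "activity"), ...) {
  what <- match.arg(what)
  if (what == "activity" || nrow(x$probe_V) == 0) {
    graphics::plot(x$t_ms, x$activity, type = "l", xlab = "time (ms)",
                   ylab = "active fraction (V > -50 mV)", ...)
  } else {
    graphics::matplot(x$t_ms, t(x$probe_V), type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "Vm (mV)", ...)
    graphics::legend("topright", legend = rownames(x$probe_V),
                     col = seq_len(nrow(x$probe_V)), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Advance a monodomain state by a fixed number of steps
#'
#' Thin wrapper over the compiled operator-split loop (reaction step, then
#' Crank-Nicolson diffusion) without recording; useful for convergence
#' tests and custom protocols.
#'
#' @inheritParams simulate_tissue
#' @param n_steps Number of ionic steps.
#' @return The updated state matrix.
#' @export
step_monodomain <- function(tissue, state, dt = NULL, n_steps = 1L,
                            A = NULL, stimuli = list(), diff_every = 2L) {
  if (is.null(dt)) dt <- default_dt(tissue$membrane)
  rec <- simulate_tissue(tissue, duration = n_steps * dt, dt = dt,
                         state = state, stimuli = stimuli, A = A,
                         diff_every = diff_every, sample_ms = n_steps * dt)
  rec$final_state
}

#' Conduction velocity of a planar wave
#'
#' Paces a planar wave from one face of a (typically disease-free) slab
#' and measures conduction velocity by linear regression of activation
#' time on distance along the propagation axis, using the middle half of
#' the track to avoid stimulus and boundary effects.
#'
#' @param tissue A [make_tissue()] result.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param dt Time step, ms.
#' @param amplitude,stim_ms Stimulus strength (pA/pF) and duration (ms).
#' @param diff_every Ionic steps per diffusion solve.
#' @return Conduction velocity, mm/ms.
#' @export
measure_cv <- function(tissue, axis = "x", dt = NULL, amplitude = 40,
                       stim_ms = 2, diff_every = 2L) {
  nd <- tissue_nodes(tissue)
  coord <- nd[[axis]]
  span <- max(coord)
  stim_nodes <- nd$active[coord <= max(2 * tissue$spacing, 0.41)]
  rec <- simulate_tissue(
    tissue, duration = span / 0.1 + 50, dt = dt,
    stimuli = list(stim_pulse(5, stim_ms, amplitude, stim_nodes)),
    record_activations = TRUE, diff_every = diff_every)
  at <- vapply(rec$activations, function(a) if (length(a)) a[1] else NA_real_,
               0)
  sel <- !is.na(at) & coord >= 0.25 * span & coord <= 0.75 * span
  if (sum(sel) < 10) stop("planar wave failed to propagate")
  fit <- stats::lm(at[sel] ~ coord[sel])
  1 / unname(stats::coef(fit)[2])
}
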