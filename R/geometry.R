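#' Specification of a synthetic cardiac tissue slab
#'
#' Describes a structured 3-D wall of myocardium standing in for a
#' patient-derived chamber: a box with an illuminated endocardial face
#' (z = 0) and an opposing epicardial face, linear transmural fiber
#' rotation, and an optional disease pattern. All randomness used by the
#' generator derives from `seed`.
#'
#' @param chamber `"ventricular"` (ten Tusscher-type kinetics; default wall
#'   thickness 8 mm, spacing 0.40 mm) or `"atrial"` (Courtemanche-type;
#'   default thickness 2.5 mm, spacing 0.45 mm). The atrial wall is thin
#'   relative to the ~0.52 mm green-light penetration depth, the
#'   ventricular wall much thicker — the anatomic contrast that drives the
#'   difference in optogenetic defibrillation behavior between chambers.
#' @param lateral Lateral extent, mm (length 1 or 2).
#' @param thickness Wall thickness, mm (>= 3 spacings).
#' @param spacing Node spacing, mm.
#' @param fiber_rotation Total endo-to-epi fiber rotation, degrees
#'   (linear; default 120).
#' @param disease Disease descriptor: `disease_none()`,
#'   [disease_fibrosis()], or [disease_scar()].
#' @param cond Monodomain diffusivities `c(longitudinal, transverse)` in
#'   mm^2/ms (conductivity over surface-to-volume ratio times membrane
#'   capacitance). Defaults target a longitudinal conduction velocity of
#'   ~0.6 mm/ms (ventricular) / ~0.7 mm/ms (atrial) with a 4:1
#'   conductivity anisotropy.
#' @param fibrosis_cond_scale Conductivity multiplier inside fibrotic
#'   regions (atrial), default 0.5.
#' @param ionic_scale Optional named list of extra conductance multipliers
#'   applied on top of the regional remodeling, with elements `normal`
#'   and/or `remodeled` (named vectors as in [apply_region_remodeling()]).
#'   Used by the desk-scale presets to accelerate repolarization so that a
#'   reentrant wavelength fits a bench-sized slab.
#' @param seed Integer seed for all generator randomness.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(chamber = c("ventricular", "atrial"),
                          lateral = 30, thickness = NULL, spacing = NULL,
                          fiber_rotation = 120, disease = disease_none(),
                          cond = NULL, fibrosis_cond_scale = 0.5,
                          ionic_scale = NULL, seed = 1L) {
  chamber <- match.arg(chamber)
  if (is.null(thickness)) thickness <- if (chamber == "atrial") 2.5 else 8
  if (is.null(spacing)) spacing <- if (chamber == "atrial") 0.45 else 0.40
  if (is.null(cond))
    cond <- if (chamber == "atrial") c(0.243, 0.0607) else c(0.13, 0.0325)
  if (length(lateral) == 1L) lateral <- c(lateral, lateral)
  if (thickness < 3 * spacing)
    stop("wall thickness must be at least 3 node spacings")
  stopifnot(length(cond) == 2L, all(cond > 0))
  structure(
    list(chamber = chamber, lateral = lateral, thickness = thickness,
         spacing = spacing, fiber_rotation = fiber_rotation,
         disease = disease, cond = cond,
         fibrosis_cond_scale = fibrosis_cond_scale,
         ionic_scale = ionic_scale,
         seed = as.integer(seed)),
    class = "geometry_spec")
}

#' @rdname disease_scar
#' @export
disease_none <- function() list(type = "none")

#' Disease patterns for synthetic tissue
#'
#' `disease_fibrosis()` scatters roughly spherical fibrotic patches
#' (remodeled ionic currents plus reduced conductivity) until the requested
#' node fraction is reached, emulating diffuse fibrosis in the atrial
#' fibrillation substrate. `disease_scar()` carves a non-excitable
#' transmural scar cylinder surrounded by a border-zone (BZ) annulus,
#' emulating the infarct substrate of ischemic cardiomyopathy; options:
#'
#' * `outer_radius` — if set, everything outside this radius is also scar,
#'   leaving an annular excitable channel around the central scar that can
#'   host anatomical reentry (the synthetic analogue of a reentrant VT
#'   circuit circling an infarct).
#' * `protect` — if `TRUE`, an additional scar cap is placed on the
#'   endocardial side above the channel (from the endo surface down to
#'   `cap_depth`, out to `cap_radius`), so the surviving epicardial-side
#'   channel is shielded from endocardial illumination both optically
#'   (several green penetration depths away) and electrotonically (the cap
#'   insulates it from optogenetically forced tissue) — a protected
#'   epicardial circuit.
#'
#' @param density Fibrotic node fraction in `[0, 1]`.
#' @param patch_mm Approximate fibrotic patch diameter, mm.
#' @param center Scar center in the lateral plane, mm (default mid-slab).
#' @param scar_radius Radius of the transmural scar cylinder, mm.
#' @param bz_width Width of the BZ annulus around the scar, mm.
#' @param outer_radius Optional outer radius of the excitable channel, mm.
#' @param protect Logical; add the endocardial protecting cap.
#' @param cap_radius Radius of the protecting cap, mm (default
#'   `outer_radius`, or `scar_radius + bz_width + 4` if unset).
#' @param cap_depth Depth of the protecting cap from the endocardial
#'   surface, mm.
#' @return A disease descriptor list for [geometry_spec()].
#' @export
disease_fibrosis <- function(density = 0.3, patch_mm = 1.5) {
  stopifnot(density >= 0, density <= 1)
  list(type = "diffuse_fibrosis", density = density, patch_mm = patch_mm)
}

#' @rdname disease_fibrosis
#' @export
disease_scar <- function(center = NULL, scar_radius = 4.5, bz_width = 1.5,
                         outer_radius = NULL, protect = FALSE,
                         cap_radius = NULL, cap_depth = NULL) {
  list(type = "scar_with_bz", center = center, scar_radius = scar_radius,
       bz_width = bz_width, outer_radius = outer_radius, protect = protect,
       cap_radius = cap_radius, cap_depth = cap_depth)
}

#' Build a synthetic tissue model from a specification
#'
#' Realizes a [geometry_spec()] as a structured grid: assigns region labels
#' (normal / remodeled / scar) according to the disease descriptor, linear
#' transmural fiber rotation, endo/epi surface labels, and the node sets
#' used by the solver (scar nodes are excluded from the electrical state).
#' The same spec always produces the identical tissue.
#'
#' @param spec A [geometry_spec()].
#' @return An object of class `tissue_model` with fields `dims`, `spacing`,
#'   `membrane`, `theta` (fiber angle per transmural layer, radians),
#'   `region_grid` (0 normal, 1 remodeled, 2 scar over the full grid),
#'   `active` (grid indices of non-scar nodes), `region` (per active node),
#'   `surfaces` (grid indices: `endo`, `epi`), `surfaces_active`
#'   (active-node indices of the excitable surface nodes), `cond`,
#'   `cond_scale` (per active node) and `spec`.
#' @export
make_tissue <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  h <- spec$spacing
  nx <- round(spec$lateral[1] / h) + 1L
  ny <- round(spec$lateral[2] / h) + 1L
  nz <- round(spec$thickness / h) + 1L
  n <- nx * ny * nz
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  x <- (ix - 1L) * h; y <- (iy - 1L) * h; z <- (iz - 1L) * h

  region <- integer(n)  # 0 normal
  cond_scale <- rep(1, n)
  d <- spec$disease
  if (d$type == "diffuse_fibrosis" && d$density > 0) {
    target <- round(d$density * n)
    lab <- with_seed(spec$seed, {
      lab <- logical(n)
      r_patch <- max(d$patch_mm / 2, h / 2)
      guard <- 0L
      while (sum(lab) < target && guard < 100000L) {
        cx <- stats::runif(1, 0, spec$lateral[1])
        cy <- stats::runif(1, 0, spec$lateral[2])
        cz <- stats::runif(1, 0, spec$thickness)
        sel <- (x - cx)^2 + (y - cy)^2 + (z - cz)^2 <= r_patch^2
        lab <- lab | sel
        guard <- guard + 1L
      }
      over <- sum(lab) - target
      if (over > 0) lab[sample(which(lab), over)] <- FALSE
      lab
    })
    region[lab] <- 1L
    cond_scale[lab] <- spec$fibrosis_cond_scale
  } else if (d$type == "scar_with_bz") {
    ctr <- if (is.null(d$center)) spec$lateral / 2 else d$center
    rr <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    region[rr <= d$scar_radius] <- 2L
    region[rr > d$scar_radius & rr <= d$scar_radius + d$bz_width] <- 1L
    if (!is.null(d$outer_radius)) region[rr > d$outer_radius] <- 2L
    if (isTRUE(d$protect)) {
      cap_r <- if (!is.null(d$cap_radius)) d$cap_radius else
        if (!is.null(d$outer_radius)) d$outer_radius else
          d$scar_radius + d$bz_width + 4
      cap_z <- if (!is.null(d$cap_depth)) d$cap_depth else
        spec$thickness - 3 * h
      region[rr <= cap_r & z <= cap_z] <- 2L
    }
  }
  if (spec$chamber == "atrial" && any(region == 1L))
    cond_scale[region == 1L] <- spec$fibrosis_cond_scale

  active <- which(region != 2L)
  if (length(active) == 0L) stop("disease pattern leaves no excitable tissue")
  act_of_grid <- rep(NA_integer_, n)
  act_of_grid[active] <- seq_along(active)

  theta <- (spec$fiber_rotation * pi / 180) *
    ((seq_len(nz) - 1) / max(nz - 1, 1) - 0.5)

  endo <- which(iz == 1L)
  epi <- which(iz == nz)
  structure(
    list(dims = c(nx, ny, nz), spacing = h,
         membrane = spec$chamber, theta = theta,
         region_grid = region, active = active, act_of_grid = act_of_grid,
         region = region[active], cond_scale = cond_scale[active],
         surfaces = list(endo = endo, epi = epi),
         surfaces_active = list(endo = act_of_grid[endo][!is.na(act_of_grid[endo])],
                                epi = act_of_grid[epi][!is.na(act_of_grid[epi])]),
         cond = spec$cond, spec = spec),
    class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model> %s slab %g x %g x %g mm @ %g mm (%d x %d x %d nodes)\n",
    x$membrane, (x$dims[1] - 1) * x$spacing, (x$dims[2] - 1) * x$spacing,
    (x$dims[3] - 1) * x$spacing, x$spacing, x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("  excitable nodes: %d (%.1f%%); remodeled: %d; scar: %d\n",
              length(x$active),
              100 * length(x$active) / prod(x$dims),
              sum(x$region == 1L), sum(x$region_grid == 2L)))
  cat(sprintf("  disease: %s; fiber rotation %g deg; D = (%g, %g) mm^2/ms\n",
              x$spec$disease$type, x$spec$fiber_rotation, x$cond[1], x$cond[2]))
  invisible(x)
}

#' Per-node coordinate/label table of a tissue model
#'
#' @param tissue A [make_tissue()] result.
#' @param what `"active"` (default; excitable nodes only, with their
#'   solver index) or `"grid"` (all grid nodes).
#' @return Data frame with grid index, active index (NA for scar), integer
#'   lattice coordinates, physical coordinates (mm), region code and
#'   surface flags.
#' @export
tissue_nodes <- function(tissue, what = c("active", "grid")) {
  what <- match.arg(what)
  nx <- tissue$dims[1]; ny <- tissue$dims[2]; nz <- tissue$dims[3]
  n <- nx * ny * nz
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  df <- data.frame(
    grid = seq_len(n), active = tissue$act_of_grid,
    ix = ix, iy = iy, iz = iz,
    x = (ix - 1) * tissue$spacing, y = (iy - 1) * tissue$spacing,
    z = (iz - 1) * tissue$spacing,
    region = tissue$region_grid,
    endo = iz == 1L, epi = iz == nz)
  if (what == "active") df[!is.na(df$active), ] else df
}

#' Diffuse opsin expression map
#'
#' Selects the requested fraction of excitable (non-scar) nodes uniformly
#' at random without replacement — the diffuse expression pattern expected
#' after systemic viral gene delivery. The achieved fraction is exact to
#' within one node; the same `(tissue, fraction, seed)` always gives the
#' identical map, and one map is reused across opsins for a given geometry.
#'
#' @param tissue A [make_tissue()] result.
#' @param fraction Target expressing fraction among excitable nodes
#'   (default 0.582, the transduction level reported in mouse hearts one
#'   year after systemic AAV delivery).
#' @param seed Integer seed.
#' @return An object of class `expression_map`: logical vector over active
#'   nodes with attributes `fraction` (achieved) and `seed`.
#' @export
build_expression_map <- function(tissue, fraction = 0.582, seed = 1L) {
  stopifnot(inherits(tissue, "tissue_model"),
            fraction >= 0, fraction <= 1)
  n <- length(tissue$active)
  k <- round(fraction * n)
  expr <- logical(n)
  if (k > 0)
    expr[with_seed(seed, sample.int(n, k))] <- TRUE
  structure(expr, class = "expression_map", fraction = k / n,
            seed = as.integer(seed))
}

#' @export
print.expression_map <- function(x, ...) {
  cat(sprintf("<expression_map> %d / %d nodes expressing (%.1f%%), seed %d\n",
              sum(x), length(x), 100 * attr(x, "fraction"), attr(x, "seed")))
  invisible(x)
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
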