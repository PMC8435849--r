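# Configuration schema: section -> key -> c(type, default or NA)
config_schema <- function() {
  list(
    geometry = list(
      preset = "character", chamber = "character", lateral = "numeric",
      thickness = "numeric", spacing = "numeric", fiber_rotation = "numeric",
      cond = "numeric", seed = "numeric"),
    opsin = list(
      preset = "character", g_max = "numeric", E_rev = "numeric",
      tau_on = "numeric", tau_off = "numeric"),
    optics = list(
      color = "character", mu_a = "numeric", mu_s_prime = "numeric",
      g_anisotropy = "numeric", D = "numeric", wavelength = "numeric"),
    expression = list(fraction = "numeric", seed = "numeric"),
    protocol = list(
      irradiances = "numeric", onsets = "numeric", light_ms = "numeric",
      window = "numeric", s2_scan = "numeric", method = "character"),
    simulation = list(
      dt = "numeric", diff_every = "numeric", sample_ms = "numeric",
      duration = "numeric"))
}

config_defaults <- function() {
  list(
    geometry = list(preset = "ventricular-desk", seed = 1),
    opsin = list(preset = "GtACR1"),
    optics = list(color = "green"),
    expression = list(fraction = 0.582, seed = 1),
    protocol = list(irradiances = c(0.05, 0.5, 5), onsets = c(0, 100, 200),
                    light_ms = 1000, window = 800,
                    method = "cross_field"),
    simulation = list(dt = 0.05, diff_every = 2, sample_ms = 1))
}

#' Load and validate a structured run configuration
#'
#' Reads a YAML configuration describing geometry, opsin, optics,
#' expression, protocol and simulation settings; validates every key
#' against the schema (unknown keys are rejected by name, type mismatches
#' reported with the expected type) and fills documented defaults for
#' anything omitted. A minimal configuration naming only a geometry preset
#' and an opsin is therefore complete.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return Validated configuration list with attribute `"filled"` naming
#'   defaulted keys.
#' @seealso [save_config()] for the round-trip inverse.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  schema <- config_schema()
  bad_sec <- setdiff(names(cfg), names(schema))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(schema[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key '%s' in section '%s'", bad[1], sec))
    for (k in names(cfg[[sec]])) {
      want <- schema[[sec]][[k]]
      v <- cfg[[sec]][[k]]
      ok <- switch(want, numeric = is.numeric(v),
                   character = is.character(v), TRUE)
      if (!ok)
        stop(sprintf("key '%s.%s' must be %s", sec, k, want))
    }
  }
  filled <- character(0)
  defs <- config_defaults()
  for (sec in names(defs)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
    for (k in names(defs[[sec]])) {
      if (is.null(cfg[[sec]][[k]])) {
        cfg[[sec]][[k]] <- defs[[sec]][[k]]
        filled <- c(filled, paste(sec, k, sep = "."))
      }
    }
  }
  structure(cfg, filled = filled)
}

#' @rdname load_config
#' @param cfg Configuration list.
#' @param path Output file path.
#' @export
save_config <- function(cfg, path) {
  attr(cfg, "filled") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a per-node field as a legacy VTK structured-points file
#'
#' Writes an ASCII VTK file viewable in ParaView/VisIt with one or more
#' point-data arrays on the structured grid of a tissue model. For
#' attenuation fields both the linear factor and its log10 are written
#' (illumination figures conventionally use the log10 scale).
#'
#' @param x An `attenuation_field`, or a numeric vector over grid nodes,
#'   or a named list of such vectors.
#' @param tissue The [make_tissue()] model defining the grid.
#' @param path Output `.vtk` path.
#' @param name Array name used for a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, tissue, path, name = "field") {
  dims <- tissue$dims
  n <- prod(dims)
  arrays <- if (inherits(x, "attenuation_field")) {
    list(attenuation = x$factor,
         attenuation_log10 = log10(pmax(x$factor, 1e-300)))
  } else if (is.list(x)) x else stats::setNames(list(x), name)
  for (a in arrays) if (length(a) != n)
    stop("array length does not match the grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "optodefib field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", tissue$spacing, tissue$spacing,
                       tissue$spacing),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(arrays)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(arrays[[nm]], digits = 10, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(path)
}

#' Export simulation artifacts to standard formats
#'
#' Dispatches on the object class: clamp traces and probe traces go to CSV
#' (columns `time_ms`, `Ee_mW_mm2`, `V_mV`, `I_pA_pF` for clamp traces),
#' sweep tables to a success-rate CSV (one row per irradiance, one column
#' per opsin, cells `n/k`), attenuation fields to VTK (requires `tissue`),
#' and whole recordings to RDS (a lossless hierarchical container).
#'
#' @param x Object to write.
#' @param path Output path.
#' @param format One of `"csv"`, `"vtk"`, `"rds"`; default inferred from
#'   the object class.
#' @param tissue Tissue model (needed for VTK output).
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, format = NULL, tissue = NULL) {
  if (is.null(format)) {
    format <- if (inherits(x, "attenuation_field")) "vtk"
      else if (inherits(x, "tissue_recording")) "rds"
      else "csv"
  }
  switch(format,
    csv = {
      if (inherits(x, "sweep_table")) {
        tab <- as.data.frame(x$counts)
        tab[] <- lapply(tab, function(cnt)
          sprintf("%d/%d", cnt, length(x$onsets)))
        tab <- cbind(irradiance_mW_mm2 = rownames(x$counts), tab)
        write.csv(tab, path, row.names = FALSE)
      } else if (inherits(x, "tissue_recording")) {
        df <- data.frame(time_ms = x$t_ms, activity = x$activity)
        if (nrow(x$probe_V))
          df <- cbind(df, as.data.frame(t(x$probe_V)))
        write.csv(df, path, row.names = FALSE)
      } else write.csv(as.data.frame(x), path, row.names = FALSE)
    },
    vtk = {
      if (is.null(tissue)) stop("VTK output requires the tissue model")
      write_vtk(x, tissue, path)
    },
    rds = saveRDS(x, path),
    stop("unsupported format '", format,
         "'; supported: csv, vtk, rds"))
  invisible(path)
}

#' Run manifest
#'
#' Machine-readable record of a pipeline run: configuration snapshot,
#' seeds, package version, content hashes of every artifact in the run
#' directory, and wall time. Reruns with identical inputs produce
#' identical content hashes for deterministic stages.
#'
#' @param dir Run directory.
#' @param config Configuration list used for the run.
#' @param seeds Named list/vector of seeds.
#' @param started `proc.time()` captured at run start (for the wall-time
#'   entry).
#' @return The manifest list, invisibly; written as `manifest.json` in
#'   `dir`.
#' @export
write_manifest <- function(dir, config = NULL, seeds = NULL,
                           started = NULL) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  man <- list(
    package = "optodefib",
    version = as.character(packageVersion("optodefib")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds, config = config, artifacts = hashes,
    wall_time_s = if (!is.null(started))
      unname((proc.time() - started)["elapsed"]) else NA)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Write a defibrillation report bundle
#'
#' Writes the success-rate table (one row per irradiance, one column per
#' opsin), the per-attempt outcome table, optional probe-trace plots and
#' activation maps for supplied recordings, and a machine-readable JSON
#' summary with seeds; finishes with a content-hash manifest. Rerunning
#' with the same inputs reproduces the bundle byte-for-byte (PNGs aside).
#'
#' @param sweep A [run_defib_sweep()] result.
#' @param dir Output directory (created if needed).
#' @param recordings Optional named list of `tissue_recording` objects to
#'   plot.
#' @param tissue Optional tissue model (enables activation-map images).
#' @param config Optional configuration snapshot for the manifest.
#' @return `dir`, invisibly.
#' @export
report <- function(sweep, dir, recordings = NULL, tissue = NULL,
                   config = NULL) {
  stopifnot(inherits(sweep, "sweep_table"))
  started <- proc.time()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_outputs(sweep, file.path(dir, "success_rates.csv"), "csv")
  write.csv(sweep$attempts, file.path(dir, "attempts.csv"),
            row.names = FALSE)
  summary <- list(
    counts = as.data.frame(as.table(sweep$counts)),
    onsets = sweep$onsets, light_ms = sweep$light_ms,
    window = sweep$window, min_full_success = as.list(min_full_success(sweep)),
    meta = sweep$meta)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    grDevices::png(file.path(dir, paste0("trace_", nm, ".png")),
                   width = 900, height = 500)
    plot(rec, if (nrow(rec$probe_V)) "probes" else "activity")
    grDevices::dev.off()
    if (!is.null(tissue) && !is.null(rec$activations)) {
      at <- vapply(rec$activations,
                   function(a) if (length(a)) a[length(a)] else NA_real_, 0)
      grDevices::png(file.path(dir, paste0("activation_", nm, ".png")),
                     width = 700, height = 650)
      nd <- tissue_nodes(tissue)
      endo <- nd[nd$iz == 1, ]
      graphics::plot(endo$x, endo$y, col = grDevices::hcl.colors(64)[
        cut(at[endo$active], 64, labels = FALSE)], pch = 15, cex = 1.2,
        xlab = "x (mm)", ylab = "y (mm)",
        main = paste("last activation time,", nm))
      grDevices::dev.off()
    }
  }
  write_manifest(dir, config = config,
                 seeds = list(expression = sweep$meta$expression_seed),
                 started = started)
  invisible(dir)
}
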