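# Configuration files and structured outputs.  Model configurations are
# YAML with sections `species`, `baths`, `geometry`, `charges`, `run`; all
# lengths in nm, charges in e, concentrations in mol/L, voltages in mV.

#' Load and validate a model configuration
#'
#' Reads a YAML configuration describing the electrolyte, the pore and the
#' run settings, applies defaults, and validates every physical invariant
#' of the domain types (positive radii and diffusion coefficients,
#' electroneutral baths, geometry consistency).  All offending keys are
#' reported together.
#'
#' @param path Path to a YAML file.
#' @return A list with `electrolyte`, `system`, `pattern` (or `NULL`),
#'   `grid`, `run_spec`, `raw` (the parsed file with defaults injected).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  need(!is.null(cfg$species), "missing section: species")
  need(!is.null(cfg$baths), "missing section: baths")
  need(!is.null(cfg$geometry), "missing section: geometry")
  if (length(problems)) stop("invalid config:\n  ",
                             paste(problems, collapse = "\n  "))

  species <- lapply(cfg$species, function(s) {
    for (f in c("name", "valence", "radius", "d_bulk")) {
      need(!is.null(s[[f]]), paste0("species entry missing `", f, "`"))
    }
    s
  })
  if (length(problems)) stop("invalid config:\n  ",
                             paste(problems, collapse = "\n  "))
  sp <- lapply(species, function(s) {
    ion_species(s$name, s$valence, s$radius, s$d_bulk,
                s$d_pore %||% s$d_bulk)
  })
  cl <- unlist(cfg$baths$left)
  cr <- unlist(cfg$baths$right %||% cfg$baths$left)
  el <- tryCatch(
    electrolyte(sp, cl, cr,
                dielectric = cfg$baths$dielectric %||% 78.45,
                temperature = cfg$baths$temperature %||% 298.15),
    error = function(e) {
      stop("invalid config: bath definition rejected: ",
           conditionMessage(e))
    })

  g <- cfg$geometry
  voltage <- cfg$run$voltage_mV %||% 0
  ch <- cfg$charges
  pattern <- NULL
  if (!is.null(ch) && !is.null(ch$type) && ch$type != "none") {
    pattern <- charge_pattern(
      sigma_left = ch$sigma_left %||% 0,
      sigma_right = ch$sigma_right %||% 0,
      sigma_ref = ch$sigma_ref %||% .sigma0,
      x_left = ch$x_left %||% 0.5,
      pore_radius = g$pore_radius %||% 0.97,
      pore_length = g$pore_length %||% 6.4,
      grid_dz = ch$grid_dz %||% 0.2)
    builder <- switch(ch$type,
                      regions = build_region_charge_pore,
                      localized = build_localized_charge_pore,
                      stop("invalid config: unknown charges.type `",
                           ch$type, "` (regions, localized, none)"))
    sys <- builder(pattern,
                   cell_radius = g$cell_radius %||%
                     (pattern$pore_radius + 2),
                   cell_half_length = g$cell_half_length %||%
                     (pattern$pore_length / 2 + 2),
                   applied_voltage = voltage)
  } else if (!is.null(g$pore_radius)) {
    H <- g$pore_length %||% 6.4
    sys <- pore_system(g$cell_radius %||% (g$pore_radius + 2),
                       g$cell_half_length %||% (H / 2 + 2),
                       membrane = c(-H / 2, H / 2),
                       wall_profile = g$pore_radius,
                       applied_voltage = voltage)
  } else {
    sys <- pore_system(g$cell_radius %||% 3, g$cell_half_length %||% 3,
                       applied_voltage = voltage)
  }
  run <- cfg$run %||% list()
  grid <- build_subvolume_grid(sys, nz = run$nz %||% 16,
                               nr = run$nr %||% 4)
  run_spec <- lemc_run_spec(
    sweeps = run$sweeps %||% 2000,
    equilibration = run$equilibration %||% ((run$sweeps %||% 2000) %/% 4))
  cfg$run <- utils::modifyList(
    list(voltage_mV = voltage, nz = grid$nz, nr = grid$nr,
         sweeps = run_spec$sweeps,
         equilibration = run_spec$equilibration), run)
  list(electrolyte = el, system = sys, pattern = pattern, grid = grid,
       run_spec = run_spec, raw = cfg)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()] at the level of the raw configuration list:
#' `load_config(dump_config(cfg, f))` reproduces the same model.
#'
#' @param raw The `raw` element of a [load_config()] result (or a
#'   compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(raw, path) {
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record attached to every output set: configuration digest,
#' seed, package version, tolerances and convergence flags.
#'
#' @param seed Integer seed of the run.
#' @param config Optional raw configuration list (digested into the
#'   manifest).
#' @param extra Named list of additional fields (tolerances, flags).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(seed, config = NULL, extra = list()) {
  digest <- if (!is.null(config)) {
    # small order-independent content digest, no external dependencies
    s <- paste(deparse(config[order(names(config))]), collapse = "")
    sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 257)) %%
              .Machine$integer.max)
  } else NA_character_
  structure(
    c(list(package = "nplemc",
           version = as.character(utils::packageVersion("nplemc")),
           seed = seed, config_digest = digest,
           timestamp = format(Sys.time(), tz = "UTC",
                              "%Y-%m-%dT%H:%M:%SZ")),
      extra),
    class = "run_manifest"
  )
}

#' Write the structured outputs of a run
#'
#' Writes the axial profiles, the full (z, r) concentration table, the
#' device summary and the manifest to a directory:
#' `profiles_axial.csv`, `profiles_zr.csv`, `device.json`,
#' `convergence.json`, `manifest.json`.  Column order is fixed; rerunning
#' with the same seed reproduces the CSV bodies byte for byte.
#'
#' @param result An `npl_result`, or `NULL` to write a manifest only.
#' @param directory Output directory (created if needed).
#' @param manifest A [run_manifest()].
#' @param device Optional `device_result` to include.
#' @param electrolyte The [electrolyte()] of the run (for species names).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, directory, manifest,
                          device = NULL, electrolyte = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(x, f) {
    p <- file.path(directory, f)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <<- c(written, p)
  }
  if (!is.null(result)) {
    grid <- result$grid
    prof <- axial_profile(result$fieldset)
    p1 <- file.path(directory, "profiles_axial.csv")
    utils::write.csv(prof, p1, row.names = FALSE, quote = FALSE)
    written <- c(written, p1)
    iz <- rep(seq_len(grid$nz), grid$nr)
    ir <- rep(seq_len(grid$nr), each = grid$nz)
    zr <- data.frame(species = rep(result$species,
                                   each = grid$nz * grid$nr),
                     iz = rep(iz, length(result$species)),
                     ir = rep(ir, length(result$species)),
                     z_nm = rep(grid$z_center[iz], length(result$species)),
                     r_nm = rep(grid$r_center[cbind(iz, ir)],
                                length(result$species)),
                     conc_M = as.vector(t(result$fieldset$conc)),
                     conc_se_M = as.vector(t(result$fieldset$conc_se)))
    p2 <- file.path(directory, "profiles_zr.csv")
    utils::write.csv(zr, p2, row.names = FALSE, quote = FALSE)
    written <- c(written, p2)
    put(list(manifest_digest = manifest$config_digest,
             voltage_mV = result$voltage_mV,
             currents = result$currents,
             total_current_pA = result$total_current_pA,
             converged = result$converged,
             device = if (!is.null(device)) unclass(device) else NULL),
        "device.json")
    put(list(manifest_digest = manifest$config_digest,
             iterations = result$iterations,
             converged = result$converged,
             history_pA = as.data.frame(result$history)),
        "convergence.json")
  }
  put(unclass(manifest), "manifest.json")
  invisible(written)
}
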