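# Configuration, file output and the command-line entry point.
#
# Config files are YAML with explicit unit suffixes in key names (the mix
# of mN/m, nm/s and um makes implicit units dangerous); units are converted
# once at parse time into the internal um/s/pN system.

.scenario_keys <- c(
  preset = NA, name = NA,
  stimulus_scale = "stimulus_scale",
  contact_protrusion_scale = "contact_protrusion_scale",
  attraction_on = "attraction_on",
  tension_rest_mN_per_m = "tension_rest",
  tension_plateau_mN_per_m = "tension_plateau",
  ramp_onset_s = "ramp_onset",
  ramp_duration_s = "ramp_duration",
  viscosity_ramp_factor = "viscosity_ramp_factor",
  t_end_s = "t_end",
  resolution = "resolution",
  cell_radius_um = "cell_radius",
  target_radius_um = "target_radius",
  seed = "seed"
)

.param_keys <- c(
  mu_solvent_pN_s_per_um2 = "mu_solvent",
  mu_network_0_pN_s_per_um2 = "mu_network_0",
  drag_coeff_pN_s_per_um4 = "drag_coeff",
  k_poly_per_au_s = "k_poly",
  k_depoly_per_s = "k_depoly",
  theta_base = "theta_base",
  theta_max = "theta_max",
  D_m_um2_per_s = "D_m",
  k_decay_per_s = "k_decay",
  source_strength_au_um_per_s = "source_strength",
  sigma_protrude_pN_per_um2 = "sigma_protrude",
  sigma_attract_pN_per_um2 = "sigma_attract",
  attract_range_um = "attract_range",
  contact_zone_gap_um = "contact_zone_gap",
  bending_stab_pN_per_um = "bending_stab",
  zip_speed_um_per_s = "zip_speed",
  zip_speed_attract_um_per_s = "zip_speed_attract",
  zip_stiffness_pN_s_per_um = "zip_stiffness",
  zip_wrap_boost = "zip_wrap_boost",
  zip_bead_coupling = "zip_bead_coupling",
  tau_transient_s = "tau_transient",
  leading_edge_width_nodes = "leading_edge_width"
)

#' Load a scenario + parameter configuration file
#'
#' YAML with two optional sections, `scenario` and `params`. The scenario
#' section may name a `preset` (see [make_scenario()]) whose fields are then
#' overridden key by key. Unknown keys are rejected by name; all values are
#' validated against the type invariants.
#'
#' @param path config file path.
#' @return list with `scenario` (`phago_scenario`) and `params`
#'   (`phago_params`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  raw <- yaml::read_yaml(path)
  sec_unknown <- setdiff(names(raw), c("scenario", "params"))
  if (length(sec_unknown))
    stop("configuration error: unknown section(s): ",
         paste(sec_unknown, collapse = ", "))

  sraw <- raw$scenario
  sc <- if (!is.null(sraw$preset)) make_scenario(sraw$preset) else make_scenario("antibody")
  if (!is.null(sraw)) {
    unknown <- setdiff(names(sraw), names(.scenario_keys))
    if (length(unknown))
      stop("configuration error: unknown scenario key(s): ",
           paste(unknown, collapse = ", "))
    for (k in setdiff(names(sraw), c("preset"))) {
      field <- .scenario_keys[[k]]
      if (is.na(field)) { sc$name <- sraw[[k]]; next }
      sc[[field]] <- sraw[[k]]
    }
  }
  sc <- validate_scenario(sc)

  praw <- raw$params
  pl <- as.list(default_params())
  if (!is.null(praw)) {
    unknown <- setdiff(names(praw), names(.param_keys))
    if (length(unknown))
      stop("configuration error: unknown parameter key(s): ",
           paste(unknown, collapse = ", "))
    for (k in names(praw)) pl[[.param_keys[[k]]]] <- praw[[k]]
  }
  pr <- tryCatch(do.call(default_params, pl),
                 error = function(e) stop("configuration error: ",
                                          conditionMessage(e)))
  list(scenario = sc, params = pr)
}

#' Write a scenario (and optionally parameters) as an editable config file
#'
#' @param scenario `phago_scenario`.
#' @param path output path.
#' @param params optional `phago_params` to include.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path, params = NULL) {
  inv <- names(.scenario_keys)[!is.na(.scenario_keys)]
  sout <- stats::setNames(
    lapply(inv, function(k) scenario[[.scenario_keys[[k]]]]), inv)
  sout <- c(list(name = scenario$name), sout)
  out <- list(scenario = sout)
  if (!is.null(params)) {
    pout <- stats::setNames(
      lapply(names(.param_keys), function(k) params[[.param_keys[[k]]]]),
      names(.param_keys))
    out$params <- pout
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a trajectory as CSV (lossless round trip)
#'
#' Columns `time_s, position_um, tension_mN_per_m, engulfed_fraction`,
#' written with 17 significant digits (binary-lossless for doubles) and a
#' C-locale decimal point.
#'
#' @param traj `phago_trajectory` (or benchmark trace).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  pos <- if (!is.null(traj$target_position)) traj$target_position else traj$position
  df <- list(time_s = traj$time, position_um = pos,
             tension_mN_per_m = traj$tension,
             engulfed_fraction = traj$engulfed_fraction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (length(traj$time)) {
    rows <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                             sep = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path CSV path.
#' @return a trajectory-like list usable by the observables functions.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(time = df$time_s, target_position = df$position_um,
                 tension = df$tension_mN_per_m,
                 engulfed_fraction = df$engulfed_fraction),
            class = "phago_trajectory")
}

#' Write a legacy ASCII VTK snapshot of the mesh and fields
#'
#' Unstructured-grid file with the cross-section quads: cell data carries
#' the network fraction theta, the element-averaged messenger and the
#' network viscosity; point data carries both phase velocities and the
#' pressure. Readable by standard VTK viewers.
#'
#' @param mesh `phago_mesh`.
#' @param state `phago_fields`.
#' @param path output path (.vtk).
#' @param params `phago_params` (for the viscosity field).
#' @param stimulation_factor viscosity multiplier used for the snapshot.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(mesh, state, path, params = default_params(),
                               stimulation_factor = 1) {
  if (!inherits(mesh, "phago_mesh")) stop("contract violation: not a phago_mesh")
  N <- nrow(mesh$coords); E <- nrow(mesh$quads)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("phagoflow axisymmetric cross-section snapshot (x=r, y=z)")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", N)
  writeLines(sprintf("%.9g %.9g 0", mesh$coords[, 1L], mesh$coords[, 2L]), con)
  w("CELLS %d %d", E, 5L * E)
  writeLines(sprintf("4 %d %d %d %d", mesh$quads[, 1L] - 1L,
                     mesh$quads[, 2L] - 1L, mesh$quads[, 3L] - 1L,
                     mesh$quads[, 4L] - 1L), con)
  w("CELL_TYPES %d", E)
  writeLines(rep("9", E), con)
  w("CELL_DATA %d", E)
  w("SCALARS theta double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", state$theta), con)
  w("SCALARS messenger double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", .nodal_to_elem(mesh, state$messenger)), con)
  w("SCALARS viscosity double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g",
                     viscosity_of(state$theta, stimulation_factor, params)), con)
  w("POINT_DATA %d", N)
  w("VECTORS v_network double")
  writeLines(sprintf("%.9g %.9g 0", state$v_network[, 1L],
                     state$v_network[, 2L]), con)
  w("VECTORS v_solvent double")
  writeLines(sprintf("%.9g %.9g 0", state$v_solvent[, 1L],
                     state$v_solvent[, 2L]), con)
  w("SCALARS pressure double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", state$pressure), con)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON sidecar written before a run starts: config hash, package version,
#' scenario name, resolution, seed, output paths and wall-clock start.
#'
#' @param scenario `phago_scenario`.
#' @param params `phago_params`.
#' @param out_paths character vector of files the run will produce.
#' @param path manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(scenario, params, out_paths, path) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario_config(scenario, tmp, params)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    code_version = as.character(utils::packageVersion("phagoflow")),
    scenario = scenario$name,
    resolution = scenario$resolution,
    seed = scenario$seed,
    outputs = as.list(out_paths),
    wall_start = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## ---- command-line interface ----

.cli_usage <- paste(
  "usage: phagoflow <command> [options]",
  "",
  "commands:",
  "  simulate  --scenario NAME | --config FILE  [--resolution X] [--out DIR]",
  "            [--snapshots-every S] [--verbose]",
  "  benchmark --scenario NAME --n N --seed S [--out DIR]",
  "  metrics   --traj FILE [--out FILE]",
  "  compare   --sim FILE --bench FILE [--out FILE]",
  "  calibrate --scenario NAME [--mu-scale X] [--resolution X]",
  sep = "\n")

.cli_parse <- function(args) {
  opts <- list()
  flags <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 2L
      } else {
        flags <- c(flags, key)
        i <- i + 1L
      }
    } else stop("usage error: unexpected argument: ", a)
  }
  list(opts = opts, flags = flags)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `benchmark`, `metrics`, `compare`, `calibrate`.
#' A thin Rscript wrapper is installed at `inst/scripts/phagoflow`.
#'
#' @param argv character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 ok, 1 usage, 2 configuration,
#'   3 numerical failure.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { message(.cli_usage); return(1L) }
  cmd <- argv[[1L]]
  parsed <- tryCatch(.cli_parse(argv[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) { message(conditionMessage(parsed)); return(1L) }
  o <- parsed$opts; fl <- parsed$flags
  code <- tryCatch({
    switch(cmd,
      simulate = {
        if (!is.null(o$config)) {
          cfg <- load_config(o$config)
          sc <- cfg$scenario; pr <- cfg$params
        } else if (!is.null(o$scenario)) {
          sc <- make_scenario(o$scenario); pr <- default_params()
        } else stop("usage error: simulate needs --scenario or --config")
        if (!is.null(o$resolution)) sc$resolution <- as.numeric(o$resolution)
        sc <- validate_scenario(sc)
        outdir <- if (!is.null(o$out)) o$out else "."
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        traj_path <- file.path(outdir, paste0(sc$name, "_trajectory.csv"))
        man_path <- file.path(outdir, paste0(sc$name, "_manifest.json"))
        write_manifest(sc, pr, traj_path, man_path)
        snap <- if (!is.null(o[["snapshots-every"]]))
          as.numeric(o[["snapshots-every"]]) else NULL
        traj <- run_simulation(sc, pr,
                               verbose = if ("verbose" %in% fl) 20L else 0L,
                               snapshot_every = snap, snapshot_dir = outdir)
        write_trajectory_csv(traj, traj_path)
        s <- summarize_trajectory(traj)
        message(sprintf("push-out %.3f um; engulfment %.1f s; max inward speed %.1f nm/s",
                        s$push_out_distance, s$engulfment_time, s$max_inward_speed))
        0L
      },
      benchmark = {
        if (is.null(o$scenario) || is.null(o$n) || is.null(o$seed))
          stop("usage error: benchmark needs --scenario, --n, --seed")
        outdir <- if (!is.null(o$out)) o$out else "."
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        co <- gen_cohort(o$scenario, as.integer(o$n), as.integer(o$seed))
        for (i in seq_along(co$traces)) {
          tr <- co$traces[[i]]
          write_trajectory_csv(tr, file.path(outdir,
            sprintf("%s_bench_%04d.csv", o$scenario, i)))
          jsonlite::write_json(tr$true_params, file.path(outdir,
            sprintf("%s_bench_%04d.json", o$scenario, i)), auto_unbox = TRUE)
        }
        utils::write.csv(co$summary,
                         file.path(outdir, paste0(o$scenario, "_cohort_summary.csv")),
                         row.names = FALSE)
        0L
      },
      metrics = {
        if (is.null(o$traj)) stop("usage error: metrics needs --traj")
        tr <- read_trajectory_csv(o$traj)
        s <- summarize_trajectory(tr)
        out <- if (!is.null(o$out)) o$out else stdout()
        jsonlite::write_json(s, out, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
        0L
      },
      compare = {
        if (is.null(o$sim) || is.null(o$bench))
          stop("usage error: compare needs --sim and --bench")
        cmpr <- compare_trace(read_trajectory_csv(o$sim),
                              read_trajectory_csv(o$bench))
        out <- if (!is.null(o$out)) o$out else stdout()
        jsonlite::write_json(cmpr, out, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
        0L
      },
      calibrate = {
        if (is.null(o$scenario)) stop("usage error: calibrate needs --scenario")
        sc <- make_scenario(o$scenario)
        if (!is.null(o$resolution)) sc$resolution <- as.numeric(o$resolution)
        sc <- validate_scenario(sc)
        pr <- as.list(default_params())
        if (!is.null(o[["mu-scale"]]))
          pr$mu_network_0 <- pr$mu_network_0 * as.numeric(o[["mu-scale"]])
        traj <- run_simulation(sc, do.call(default_params, pr))
        s <- summarize_trajectory(traj)
        message(sprintf("mu_network_0=%.0f: push-out %.3f um; engulfment %.1f s; speed %.1f nm/s",
                        pr$mu_network_0, s$push_out_distance,
                        s$engulfment_time, s$max_inward_speed))
        0L
      },
      { message(.cli_usage); 1L }
    )
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("usage error", msg)) 1L
    else if (grepl("configuration error|unknown scenario|should be one of|arg", msg)) 2L
    else 3L
  })
  code
}
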