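# Scenario presets (the mechanoeffector switchboard of the two target-
# specific models and their counterfactual variants) and the simulation
# driver that advances the five-step computational cycle.

#' Scenario presets for the target-specific models
#'
#' Returns the effector switchboard of the named variant:
#' \describe{
#'   \item{zymosan}{75% stimulus, 50% contact-zone protrusion, no
#'     membrane-cytoskeleton attraction, tension 0.025 -> 0.3 mN/m,
#'     five-fold whole-cell viscosity rise concurrent with the tension.}
#'   \item{antibody}{100% stimulus, no contact-zone protrusion, attraction
#'     on, tension 0.025 -> 0.15 mN/m, constant viscosity.}
#'   \item{fcgamma_no_attraction}{the antibody model with the attraction
#'     switched off (insufficient-push-out counterfactual).}
#'   \item{zymosan_full_contact_protrusion}{the zymosan model with
#'     full-strength contact-zone protrusion (overshoot counterfactual).}
#' }
#'
#' @param name one of the four preset names above.
#' @return object of class `phago_scenario`.
#' @export
make_scenario <- function(name = c("zymosan", "antibody",
                                   "fcgamma_no_attraction",
                                   "zymosan_full_contact_protrusion")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    stimulus_scale = 1,
    contact_protrusion_scale = 0,
    attraction_on = TRUE,
    tension_rest = 0.025,       # mN/m
    tension_plateau = 0.15,     # mN/m
    ramp_onset = 10,            # s after first contact
    ramp_duration = 60,         # s
    viscosity_ramp_factor = 1,
    t_end = 150,                # s
    resolution = 1,
    cell_radius = 4.25,         # um
    target_radius = 1.6,        # um
    seed = 1L                   # reserved; the core is deterministic
  )
  sc <- switch(name,
    antibody = base,
    zymosan = utils::modifyList(base, list(
      stimulus_scale = 0.75, contact_protrusion_scale = 0.5,
      attraction_on = FALSE, tension_plateau = 0.3,
      viscosity_ramp_factor = 5, t_end = 300)),
    fcgamma_no_attraction = utils::modifyList(base, list(
      attraction_on = FALSE)),
    zymosan_full_contact_protrusion = utils::modifyList(base, list(
      stimulus_scale = 0.75, contact_protrusion_scale = 1,
      attraction_on = FALSE, tension_plateau = 0.3,
      viscosity_ramp_factor = 5, t_end = 300))
  )
  validate_scenario(sc)
}

#' Validate a scenario configuration
#' @param sc a named list of scenario settings.
#' @return the list with class `phago_scenario`, or an error naming the
#'   offending field.
#' @export
validate_scenario <- function(sc) {
  chk <- function(cond, msg) if (!cond) stop("configuration error: ", msg)
  chk(sc$stimulus_scale >= 0 && sc$stimulus_scale <= 1, "stimulus_scale must be in [0, 1]")
  chk(sc$contact_protrusion_scale >= 0 && sc$contact_protrusion_scale <= 1,
      "contact_protrusion_scale must be in [0, 1]")
  chk(is.logical(sc$attraction_on), "attraction_on must be logical")
  chk(sc$viscosity_ramp_factor >= 1, "viscosity_ramp_factor must be >= 1")
  chk(sc$tension_plateau >= sc$tension_rest, "tension_plateau must be >= tension_rest")
  chk(sc$tension_rest >= 0, "tension_rest must be >= 0")
  chk(sc$ramp_duration > 0, "ramp_duration must be > 0")
  chk(sc$t_end > 0, "t_end must be > 0")
  chk(sc$resolution > 0, "resolution must be > 0")
  chk(sc$cell_radius > sc$target_radius, "cell_radius must exceed target_radius")
  structure(sc, class = "phago_scenario")
}

## polar-angle completion threshold: 175 degrees of adhered arc counts as
## engulfment (exact membrane fusion is not modelled)
.completion_phi <- 175 * pi / 180
.completion_fraction <- .completion_phi / pi

#' Engulfment completion threshold (fraction of polar angle)
#'
#' The adhered arc extent at which a run is considered complete,
#' as a fraction of the full polar angle: 175/180.
#' @export
completion_fraction <- function() .completion_fraction

#' Run a full phagocytosis simulation
#'
#' Advances the computational cycle (Courant timestep; boundary advection
#' with the network flow + node repositioning; conservative field remap;
#' implicit messenger reaction-diffusion; constitutive update; momentum
#' solve with rigid-target coupling; phase interconversion; adhesion
#' growth; target force balance) until `t_end` or 20 s past engulfment
#' completion. Deterministic for fixed inputs.
#'
#' @param config `phago_scenario` from [make_scenario()] or
#'   [validate_scenario()].
#' @param params `phago_params`.
#' @param verbose print one diagnostic line every `verbose` steps (0 = quiet).
#' @param snapshot_every write a VTK snapshot every this many seconds
#'   (NULL = none).
#' @param snapshot_dir directory for snapshots.
#' @return object of class `phago_trajectory`: time series of target
#'   position (relative to the rear cell edge), cortical tension (mN/m) and
#'   engulfed fraction, plus run diagnostics.
#' @export
run_simulation <- function(config, params = default_params(), verbose = 0L,
                           snapshot_every = NULL, snapshot_dir = ".") {
  stopifnot(inherits(config, "phago_scenario"))
  res <- config$resolution
  target <- target_sphere(config$target_radius)
  mesh <- build_initial_mesh(cell_radius = config$cell_radius,
                             target = target, initial_contact_angle = 0,
                             resolution = res)
  target <- attr(mesh, "target")
  fields <- init_fields(mesh, params)
  V0 <- mesh_volume(mesh)
  dt_max <- 0.5 / res

  t <- 0
  contact_time <- NA_real_
  completed_at <- NA_real_
  cap <- 4096L
  tt <- numeric(cap); pos <- numeric(cap); ten <- numeric(cap); ef <- numeric(cap)
  nrec <- 0L
  max_vol_drift <- 0
  max_step_drift <- 0
  theta_rng <- NULL
  m_min <- Inf
  max_divres <- 0
  phi_series_ok <- TRUE
  aborted <- NULL
  last_phi <- 0
  next_snap <- if (is.null(snapshot_every)) Inf else 0
  snap_id <- 0L

  rear_node <- mesh$bmer[1L]

  record <- function(gamma) {
    nrec <<- nrec + 1L
    if (nrec > length(tt)) {
      tt <<- c(tt, numeric(cap)); pos <<- c(pos, numeric(cap))
      ten <<- c(ten, numeric(cap)); ef <<- c(ef, numeric(cap))
    }
    tt[nrec] <<- t
    pos[nrec] <<- target$center_z - mesh$coords[rear_node, 2L]
    ten[nrec] <<- gamma / 1000
    ef[nrec] <<- target$phi_max / pi
  }

  repeat {
    ## adhesion growth (irreversible, contiguous from the pole)
    upd <- update_adhesion(mesh, target)
    mesh <- upd$mesh; target <- upd$target
    if (is.na(contact_time) && any(mesh$contact)) contact_time <- t
    if (target$phi_max < last_phi - 1e-12) phi_series_ok <- FALSE
    last_phi <- target$phi_max

    tc <- if (is.na(contact_time)) 0 else t - contact_time
    gamma <- if (is.na(contact_time)) 1000 * config$tension_rest else
      cortical_tension(tc, config)
    stim <- if (is.na(contact_time)) 1 else .stimulation_factor(tc, config)

    if (nrec == 0L) record(gamma)

    ## momentum solve (rigid-target axial velocity solved monolithically)
    bst <- .effector_stresses(mesh, fields, config, params, target, gamma)
    sol <- solve_momentum(mesh, fields, params, gamma,
                          boundary_stresses = bst,
                          target = target, stimulation_factor = stim)
    fields$v_network <- sol$v_network
    fields$v_solvent <- sol$v_solvent
    fields$pressure <- sol$pressure
    max_divres <- max(max_divres, sol$div_residual)

    ## explicit boundary motion under surface tension is stable only below
    ## the capillary time scale mu h / gamma of the finest feature
    dt_cap <- 0.3 * (params$mu_network_0 * params$theta_base * stim +
                       params$mu_solvent) * .min_edge(mesh) / max(gamma, 1e-6)
    dt <- courant_timestep(mesh, sol$v_network, cfl = 0.5,
                           dt_max = min(dt_max, dt_cap))

    ## Lagrangian advection of the whole mesh with the network flow;
    ## if the move inverts an element, try a smoothing rescue, then halve
    ## dt (up to 6 times)
    Vold_e <- element_volumes(mesh)
    ok <- FALSE
    for (try in 1:7) {
      tg_try <- target
      tg_try$center_z <- tg_try$center_z + sol$W * dt
      mesh_adv <- advect_boundary(mesh, sol$v_network, dt, move_interior = TRUE)
      mesh_adv <- .clip_outside_target(mesh_adv, tg_try, 0)
      if (min(corner_jacobians(mesh_adv)) > 0) { ok <- TRUE; break }
      unt <- .untangle(mesh_adv)
      if (min(corner_jacobians(unt)) > 0) { mesh_adv <- unt; ok <- TRUE; break }
      resc <- tryCatch(reposition_interior(unt, target = tg_try,
                                           sweeps = 10L, redistribute = FALSE),
                       error = function(e) NULL)
      if (!is.null(resc) && min(corner_jacobians(resc)) > 0) {
        mesh_adv <- resc; ok <- TRUE; break
      }
      dt <- dt / 2
    }
    if (!ok) {
      aborted <- paste0("remesh failure: advection kept inverting elements at t = ",
                        signif(t, 5))
      warning(aborted, "; returning the trajectory up to this point",
              call. = FALSE)
      break
    }
    ## network mass is Lagrangian-conserved: theta scales with volume
    Vadv_e <- element_volumes(mesh_adv)
    fields$theta <- pmin(pmax(fields$theta * Vold_e / Vadv_e, 0), params$theta_max)
    target$center_z <- target$center_z + sol$W * dt

    ## reposition + conservative remap
    mesh_new <- reposition_interior(mesh_adv, target = target, sweeps = 40L)
    fields <- remap_fields(mesh_adv, mesh_new, fields)
    mesh <- mesh_new

    ## messenger reaction-diffusion with leading-edge source
    flux <- messenger_source(mesh, config, params)
    fields$messenger <- step_messenger(mesh, fields$messenger, params$D_m,
                                       params$k_decay, flux, dt)

    ## phase interconversion
    m_e <- .nodal_to_elem(mesh, fields$messenger)
    fields$theta <- interconvert_phases(fields$theta, m_e, params, dt)

    mesh$patch_age[mesh$contact] <- mesh$patch_age[mesh$contact] + dt
    t <- t + dt

    ## volume bookkeeping: correct the time-integration drift by a uniform
    ## normal displacement of the free membrane
    V <- mesh_volume(mesh)
    max_step_drift <- max(max_step_drift, abs(V - V0) / V0)
    mesh <- .volume_correct(mesh, V0, V)
    V <- mesh_volume(mesh)
    max_vol_drift <- max(max_vol_drift, abs(V - V0) / V0)
    theta_rng <- range(theta_rng, fields$theta)
    m_min <- min(m_min, fields$messenger)

    record(gamma)

    if (!is.null(snapshot_every) && t >= next_snap) {
      write_vtk_snapshot(mesh, fields,
                         file.path(snapshot_dir,
                                   sprintf("%s_%05.0fs.vtk", config$name, t)))
      next_snap <- next_snap + snapshot_every
      snap_id <- snap_id + 1L
    }
    if (verbose > 0L && nrec %% verbose == 0L)
      message(sprintf("t=%7.2f dt=%5.3f phi=%6.1fdeg pos=%7.3f W=%+8.5f V/V0=%.5f",
                      t, dt, target$phi_max * 180 / pi,
                      pos[nrec], sol$W, V / V0))

    if (abs(sol$W) > 0.15 || dt < 1e-3 || nrec > 20 * config$t_end / dt_max) {
      aborted <- paste0("numerical breakdown at t = ", signif(t, 5),
                        " (target velocity ", signif(sol$W, 3),
                        " um/s, dt ", signif(dt, 3), ")")
      warning(aborted, "; returning the trajectory up to this point",
              call. = FALSE)
      break
    }

    if (is.na(completed_at) && target$phi_max >= .completion_phi)
      completed_at <- t
    if (!is.na(completed_at) && t >= completed_at + 20) break
    if (t >= config$t_end) break
  }

  idx <- seq_len(nrec)
  if (!is.null(aborted)) {
    ## drop the records laid down while the breakdown was developing
    keep_t <- tt[nrec] - 15
    idx <- idx[tt[idx] <= keep_t]
    if (!length(idx)) idx <- seq_len(nrec)
  }
  structure(list(
    time = tt[idx],
    target_position = pos[idx],
    tension = ten[idx],
    engulfed_fraction = ef[idx],
    contact_time = contact_time,
    completed = !is.na(completed_at),
    completion_time = completed_at,
    scenario = config,
    n_elements = nrow(mesh$quads),
    diagnostics = list(aborted = aborted,
                       max_volume_drift = max_vol_drift,
                       max_step_volume_drift = max_step_drift,
                       theta_range = theta_rng,
                       messenger_min = m_min,
                       max_div_residual = max_divres,
                       adhered_arc_monotone = phi_series_ok,
                       final_phi_max = target$phi_max)
  ), class = "phago_trajectory")
}

## keep every node outside the (translated) target sphere, and snap the
## adhered patch nodes exactly onto its surface (captures admit a gap
## tolerance; leaving that jitter in place would give the patch polyline
## spurious concave wiggles)
.clip_outside_target <- function(mesh, target, dz_target) {
  cz <- target$center_z + dz_target
  Rt <- target$radius
  d <- sqrt(mesh$coords[, 1L]^2 + (mesh$coords[, 2L] - cz)^2)
  inside <- which(d < Rt & d > 1e-12)
  if (length(inside)) {
    sc <- Rt / d[inside]
    mesh$coords[inside, 1L] <- mesh$coords[inside, 1L] * sc
    mesh$coords[inside, 2L] <- cz + (mesh$coords[inside, 2L] - cz) * sc
  }
  ct <- mesh$bmer[mesh$contact]
  if (length(ct)) {
    dc <- sqrt(mesh$coords[ct, 1L]^2 + (mesh$coords[ct, 2L] - cz)^2)
    ok <- dc > 1e-12
    sc <- Rt / dc[ok]
    mesh$coords[ct[ok], 1L] <- mesh$coords[ct[ok], 1L] * sc
    mesh$coords[ct[ok], 2L] <- cz + (mesh$coords[ct[ok], 2L] - cz) * sc
  }
  ## re-pin axis radii possibly perturbed by the radial projection
  axn <- mesh$nid[, 1L]
  mesh$coords[axn, 1L] <- 0
  mesh
}

## uniform normal displacement of the free membrane restoring the enclosed
## volume (corrects O(dt^2) time-integration drift, not the solve itself)
.volume_correct <- function(mesh, V0, V) {
  err <- V0 - V
  A <- membrane_area(mesh)
  if (A <= 0) return(mesh)
  delta <- err / A
  delta <- sign(delta) * min(abs(delta), 0.01)
  bid <- mesh$bmer
  nb <- length(bid)
  freei <- which(!mesh$contact)
  freei <- setdiff(freei, c(1L, nb, .rear_hold_slots(mesh)))
  if (!length(freei)) return(mesh)
  nrm <- .meridian_normals(mesh)
  old <- mesh$coords
  mesh$coords[bid[freei], ] <- mesh$coords[bid[freei], , drop = FALSE] +
    delta * nrm[freei, , drop = FALSE]
  mesh$coords[bid[freei], 1L] <- pmax(mesh$coords[bid[freei], 1L], 0)
  if (min(corner_jacobians(mesh)) <= 0) mesh$coords <- old
  mesh
}

#' @export
print.phago_trajectory <- function(x, ...) {
  cat("phagocytosis trajectory:", x$scenario$name, "\n")
  cat(sprintf("  %d samples over %.1f s; %d elements\n",
              length(x$time), max(x$time), x$n_elements))
  cat(sprintf("  engulfed fraction reached %.3f (%s)\n",
              max(x$engulfed_fraction),
              if (x$completed) sprintf("completed at %.1f s", x$completion_time)
              else "incomplete"))
  invisible(x)
}

#' @export
as.data.frame.phago_trajectory <- function(x, ...) {
  data.frame(time_s = x$time, position_um = x$target_position,
             tension_mN_per_m = x$tension,
             engulfed_fraction = x$engulfed_fraction)
}
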