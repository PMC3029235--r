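# Cell-target interface mechanics: irreversible adhesion, leading-edge
# signaling, zone- and scenario-dependent disjoining/attraction stresses,
# the prescribed cortical-tension timeline, and rigid-target kinematics.

## gap tolerance for contact detection, as a fraction of the target radius
.gap_tol_frac <- 0.02

#' Update the adhesion state of the membrane against the target
#'
#' Free-membrane meridian nodes within the gap tolerance (2% of the target
#' radius) of the sphere surface and contiguous with the existing patch
#' (patches grow from the contact pole; if no patch exists yet, the node
#' nearest the sphere's proximal pole seeds it) acquire the contact tag,
#' are projected onto the sphere, and start a patch-age clock. Adhesion is
#' irreversible: nodes never lose the tag and the adhered arc
#' `target$phi_max` is non-decreasing.
#'
#' @param mesh `phago_mesh`.
#' @param target `phago_target`.
#' @return list `mesh`, `target` with updated adhesion state.
#' @export
update_adhesion <- function(mesh, target) {
  Rt <- target$radius; cz <- target$center_z
  tol <- .gap_tol_frac * Rt
  bid <- mesh$bmer
  nb <- length(bid)
  repeat {
    xy <- mesh$coords[bid, , drop = FALSE]
    d <- sqrt(xy[, 1L]^2 + (xy[, 2L] - cz)^2) - Rt
    near <- d <= tol & !mesh$contact
    if (!any(near)) break
    if (any(mesh$contact)) {
      ## contiguity: only nodes adjacent (along the meridian) to the patch
      adj <- c(FALSE, mesh$contact[-nb]) | c(mesh$contact[-1L], FALSE)
      cand <- which(near & adj)
    } else {
      ## seed at the node closest to the sphere's proximal pole
      cand <- which(near)
      pole <- c(0, cz - Rt)
      dp <- sqrt((xy[cand, 1L] - pole[1L])^2 + (xy[cand, 2L] - pole[2L])^2)
      cand <- cand[which.min(dp)]
    }
    if (!length(cand)) break
    for (s in cand) {
      p <- mesh$coords[bid[s], ]
      v <- p - c(0, cz)
      nv <- sqrt(sum(v * v))
      if (nv < 1e-12) next
      proj <- c(0, cz) + v * (Rt / nv)
      if (mesh$mer_ij[s, 1L] %in% c(0L, mesh$m) && mesh$mer_ij[s, 2L] == 0L) {
        ## pole node stays on the axis: project along the axis
        proj <- c(0, cz - Rt * sign(cz - p[2L]))
      }
      mesh$coords[bid[s], ] <- proj
      mesh$contact[s] <- TRUE
      mesh$patch_age[s] <- 0
      cphi <- max(min(-(proj[2L] - cz) / Rt, 1), -1)
      mesh$phi[s] <- acos(cphi)
    }
  }
  target$phi_max <- max(target$phi_max, mesh$phi[mesh$contact], 0, na.rm = TRUE)
  list(mesh = mesh, target = target)
}

#' Messenger production flux at the leading edge of the adherent patch
#'
#' The leading edge of fresh contact stimulates transient messenger
#' production: the flux equals `stimulus_scale * source_strength` on
#' meridian nodes that adhered less than `tau_transient` seconds ago, plus
#' a one-element-wide annulus of free membrane immediately ahead of the
#' patch rim. Once the target is fully engulfed (no free leading edge and
#' no fresh patch) the total flux is zero.
#'
#' @param mesh `phago_mesh`.
#' @param scenario `phago_scenario` (supplies `stimulus_scale`).
#' @param params `phago_params`.
#' @param annulus_nodes width of the free-membrane annulus, in nodes;
#'   defaults to the `leading_edge_width` parameter.
#' @return per-meridian-node influx vector (a.u. um/s).
#' @export
messenger_source <- function(mesh, scenario, params,
                             annulus_nodes = params$leading_edge_width) {
  nb <- length(mesh$bmer)
  flux <- numeric(nb)
  if (!any(mesh$contact)) return(flux)
  fresh <- which(mesh$contact & mesh$patch_age < params$tau_transient)
  flux[fresh] <- 1
  rim <- min(which(mesh$contact))    # patch grows from the front pole upward
  if (rim > 1L) {
    ahead <- max(1L, rim - annulus_nodes):(rim - 1L)
    flux[ahead] <- 1
  }
  flux * scenario$stimulus_scale * params$source_strength
}

#' Disjoining (protrusive) membrane stress
#'
#' The polymerized network exerts a repulsive stress on the membrane,
#' sigma = zone_scale * sigma_protrude * theta, applied outward on the
#' membrane with the equal-and-opposite reaction on the adjacent network.
#' The zone scale is 1 on free membrane in every scenario; on the
#' cell-target contact region it is the scenario's
#' `contact_protrusion_scale` (0 for antibody-coated beads, 0.5 for
#' zymosan).
#'
#' @param theta_at_membrane network fraction sampled on membrane-adjacent
#'   elements.
#' @param zone `"free"` or `"contact"`.
#' @param scenario `phago_scenario`.
#' @param params `phago_params`.
#' @return outward normal stress (pN/um^2), same length as
#'   `theta_at_membrane`.
#' @export
protrusive_stress <- function(theta_at_membrane, zone, scenario,
                              params = default_params()) {
  zs <- switch(zone,
               free = 1,
               contact = scenario$contact_protrusion_scale,
               stop("contract violation: unknown zone '", zone, "'"))
  zs * params$sigma_protrude * theta_at_membrane
}

#' Membrane-cytoskeleton attraction stress at the adherent patch
#'
#' In the antibody program the membrane adherent to the bead attracts the
#' cytoskeleton over a short range, flattening the cell onto the target; it
#' is absent for zymosan and on free membrane.
#'
#' @param zone `"free"` or `"contact"`.
#' @param scenario `phago_scenario`.
#' @param gap_normal_distance membrane-network gap (um); the stress acts
#'   within `params$attract_range`.
#' @param params `phago_params`.
#' @return inward normal stress magnitude (pN/um^2).
#' @export
attraction_stress <- function(zone, scenario, gap_normal_distance = 0,
                              params = default_params()) {
  if (!(zone %in% c("free", "contact")))
    stop("contract violation: unknown zone '", zone, "'")
  if (zone != "contact" || !isTRUE(scenario$attraction_on)) return(
    0 * gap_normal_distance)
  params$sigma_attract * as.numeric(gap_normal_distance <= params$attract_range)
}

#' Prescribed cortical-tension timeline
#'
#' Piecewise-linear tension law measured in micropipette experiments and
#' imposed on the model: resting value until ramp onset (first contact plus
#' the configured delay), linear rise over the ramp duration, then plateau
#' (0.15 mN/m for antibody-coated beads, 0.3 mN/m for zymosan).
#'
#' @param t time since first contact (s), vectorized.
#' @param scenario `phago_scenario`.
#' @return cortical tension in pN/um (1 mN/m = 1000 pN/um).
#' @export
cortical_tension <- function(t, scenario) {
  stopifnot(all(t >= 0))
  frac <- pmin(pmax((t - scenario$ramp_onset) / scenario$ramp_duration, 0), 1)
  1000 * (scenario$tension_rest +
            frac * (scenario$tension_plateau - scenario$tension_rest))
}

## stimulation factor for the whole-cell viscosity, ramping in lockstep
## with the tension (1 -> viscosity_ramp_factor)
.stimulation_factor <- function(t, scenario) {
  frac <- pmin(pmax((t - scenario$ramp_onset) / scenario$ramp_duration, 0), 1)
  1 + frac * (scenario$viscosity_ramp_factor - 1)
}

#' Advance the rigid target by its quasi-static force balance
#'
#' The target is rigid, massless and adhered irreversibly, so each step it
#' moves at the axial velocity `W` for which the net axial force vanishes.
#' That balance is solved monolithically inside [solve_momentum()] (the
#' contact-patch nodes are condensed onto the single unknown `W`); this
#' helper advances the target position and reports it relative to the rear
#' (pipette-held) edge of the cell body.
#'
#' @param target `phago_target`.
#' @param W axial target velocity from the momentum solve (um/s).
#' @param dt timestep (s).
#' @param rear_z axial position of the rear-hold edge (um).
#' @return list `target` (moved) and `position` (center relative to the
#'   rear edge, um).
#' @export
target_force_balance <- function(target, W, dt, rear_z) {
  target$center_z <- target$center_z + W * dt
  list(target = target, position = target$center_z - rear_z)
}

## assemble the per-meridian-node outward membrane stress for a scenario.
## The cell-target contact REGION comprises the adhered patch plus the free
## membrane within the contact-zone gap of the sphere surface (pushing that
## annulus along its normal presses directly against the target, which is
## exactly the effect the contact-region protrusion scale controls);
## elsewhere the membrane is free. Attraction acts on the adherent patch.
.effector_stresses <- function(mesh, state, scenario, params, target = NULL,
                               tension = NULL) {
  nb <- length(mesh$bmer)
  theta_n <- .elem_to_nodal(mesh, state$theta)
  th_mem <- theta_n[mesh$bmer]
  ## zone weight: 0 on the adhered patch and at zero gap, rising linearly
  ## to 1 (free membrane) across the contact-zone gap -- a smooth blend,
  ## since a sharp zone edge couples the protrusion discontinuously to
  ## target motion and can destabilize the force balance
  wfree <- rep(1, nb)
  if (!is.null(target)) {
    xy <- mesh$coords[mesh$bmer, , drop = FALSE]
    gap <- sqrt(xy[, 1L]^2 + (xy[, 2L] - target$center_z)^2) - target$radius
    wfree <- pmin(pmax(gap / params$contact_zone_gap, 0), 1)
  }
  wfree[mesh$contact] <- 0
  sig_free <- protrusive_stress(th_mem, "free", scenario, params)
  sig_ct <- protrusive_stress(th_mem, "contact", scenario, params)
  sig <- wfree * sig_free + (1 - wfree) * sig_ct
  if (any(mesh$contact))
    sig[mesh$contact] <- sig[mesh$contact] -
      attraction_stress("contact", scenario, 0, params)

  ## Contact-line zipper: new adhesion forms AT the rim of the patch, so
  ## cup advance is modelled as a driven dashpot pulling the leading free
  ## node onto the target surface (reaction on the target). The drive
  ## speed is limited by the local polymerization state (bond formation
  ## follows the protruding network), so the 75% zymosan stimulus slows
  ## the cup, and in the antibody program the membrane-cytoskeleton
  ## attraction adds a constant apposition force ("flattening onto the
  ## bead").
  zipper <- NULL
  if (!is.null(target) && any(mesh$contact)) {
    rim <- min(which(mesh$contact))
    if (rim > 1L) {
      lead <- rim - 1L
      xy <- mesh$coords[mesh$bmer[lead], ]
      dvec <- c(-xy[1L], target$center_z - xy[2L])
      dn <- sqrt(sum(dvec^2))
      gap <- dn - target$radius
      if (gap > 0) {
        sat <- (th_mem[lead] - params$theta_base) /
          (0.5 * (params$theta_max - params$theta_base))
        sat <- min(max(sat, 0), 1)
        ## drive speed: polymerization-limited, faster when the
        ## attraction flattens the membrane onto the bead, and
        ## accelerating with wrap angle (the sub-equator configuration is
        ## mechanically unstable against tension-driven expulsion, so the
        ## cup must cross it briskly once committed)
        vdr <- (params$zip_speed * sat +
          (if (isTRUE(scenario$attraction_on)) params$zip_speed_attract else 0)) *
          (1 + params$zip_wrap_boost * target$phi_max / pi)
        ## force capacity scales with the instantaneous cortical tension:
        ## both the wrapping resistance and what the membrane can
        ## transmit without necking off the pipette are tension-set
        gfac <- if (is.null(tension)) 1 else
          tension / (1000 * scenario$tension_plateau)
        ## dashpot stiffness is a stress scale times the lead node's
        ## membrane area (so the force it can transmit shrinks with the
        ## local element size near the poles), times the tension factor
        ar <- .meridian_node_areas(mesh)
        prt <- .meridian_partners(mesh)
        pslots <- unique(pmax(lead - 0L:2L, 2L))
        pnodes <- prt[pslots]
        pw <- c(0.5, 0.3, 0.2)[seq_along(pnodes)]
        pw <- pw / sum(pw)
        zipper <- list(
          slot = lead,
          partners = pnodes,
          pweights = pw,
          dhat = dvec / dn,
          k = params$zip_stiffness * ar[lead] * gfac,
          vdrive = vdr,
          beta = params$zip_bead_coupling,
          f0 = 0
        )
      }
    }
  }
  list(outward = sig, zipper = zipper)
}
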