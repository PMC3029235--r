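# Two-phase (cytoskeletal network + cytosolic solvent) quasi-static flow
# solver on the axisymmetric quad mesh.
#
# The network phase is a viscous fluid with viscosity proportional to its
# volume fraction theta; the solvent is a low-viscosity filler whose
# momentum balance reduces to Darcy drag against the network,
#   (1 - theta) grad p = -H (v_s - v_n),
# so the solvent velocity is eliminated analytically and recovered after
# the solve. The remaining system in (v_n, p) is a Stokes-like saddle
# problem with a pressure-Laplacian (Darcy) term that also stabilizes the
# equal-order Q1-Q1 discretization:
#   -div(2 mu(theta) D(v_n)) + grad p = f
#    div(v_n) - div(kappa grad p)     = 0,   kappa = (1-theta)^2 / H
# Units: um, s, pN; stresses pN/um^2 (= Pa), tensions pN/um.

#' Constitutive and signaling parameters
#'
#' Bundles the material, kinetic and interfacial parameters of the model.
#' Magnitudes are calibrated (see the methods vignette): the base viscosity
#' is fixed so that the antibody scenario completes engulfment in roughly a
#' minute, and all other scenarios reuse the same base values.
#'
#' @param mu_solvent solvent viscosity (pN s/um^2).
#' @param mu_network_0 network viscosity per unit theta (pN s/um^2).
#' @param drag_coeff interphase friction H (pN s/um^4).
#' @param k_poly polymerization rate per messenger unit (1/(a.u. s)).
#' @param k_depoly depolymerization rate (1/s).
#' @param theta_base resting network volume fraction.
#' @param theta_max maximum network volume fraction (< 1).
#' @param D_m messenger diffusivity (um^2/s).
#' @param k_decay messenger decay rate (1/s).
#' @param source_strength messenger production flux at the leading edge
#'   (a.u. um/s).
#' @param sigma_protrude disjoining (protrusive) stress scale per unit
#'   theta (pN/um^2).
#' @param sigma_attract membrane-cytoskeleton attraction stress at the
#'   adherent patch (pN/um^2).
#' @param attract_range interaction range of the attraction (um).
#' @param contact_zone_gap membrane within this normal distance of the
#'   target surface counts as cell-target contact region for the
#'   protrusion zone scaling (um).
#' @param bending_stab spring constant (pN/um) of the discrete curvature
#'   regularization of the free membrane, standing in for bending
#'   rigidity of the membrane/cortex composite at the element scale.
#' @param zip_speed maximum approach speed of the contact-line zipper
#'   (um/s), attained when the leading edge is fully polymerized.
#' @param zip_speed_attract additional zipper drive speed contributed by
#'   the membrane-cytoskeleton attraction (antibody program) (um/s).
#' @param zip_stiffness dashpot stiffness coupling the leading node to the
#'   target (pN s/um).
#' @param zip_wrap_boost dimensionless acceleration of the zipper drive
#'   with wrap angle (drive is multiplied by 1 + boost * phi_max / pi).
#' @param zip_bead_coupling fraction of the zipper reaction that reels the
#'   target toward the membrane; the remainder recoils on the adjacent
#'   interior network.
#' @param tau_transient duration of messenger production after a membrane
#'   patch adheres (s).
#' @param leading_edge_width width (in boundary nodes) of the free-membrane
#'   annulus ahead of the patch rim that also produces messenger.
#' @return object of class `phago_params`.
#' @export
default_params <- function(mu_solvent = 1,
                           mu_network_0 = 30000,
                           drag_coeff = 1000,
                           k_poly = 1.2,
                           k_depoly = 0.12,
                           theta_base = 0.05,
                           theta_max = 0.5,
                           D_m = 0.8,
                           k_decay = 3,
                           source_strength = 1,
                           sigma_protrude = 2000,
                           sigma_attract = 120,
                           attract_range = 0.3,
                           contact_zone_gap = 0.45,
                           bending_stab = 0,
                           zip_speed = 0.25,
                           zip_speed_attract = 0.1,
                           zip_stiffness = 80000,
                           zip_wrap_boost = 0,
                           zip_bead_coupling = 1,
                           tau_transient = 10,
                           leading_edge_width = 2) {
  p <- list(mu_solvent = mu_solvent, mu_network_0 = mu_network_0,
            drag_coeff = drag_coeff, k_poly = k_poly, k_depoly = k_depoly,
            theta_base = theta_base, theta_max = theta_max, D_m = D_m,
            k_decay = k_decay, source_strength = source_strength,
            sigma_protrude = sigma_protrude, sigma_attract = sigma_attract,
            attract_range = attract_range, contact_zone_gap = contact_zone_gap,
            bending_stab = bending_stab,
            zip_speed = zip_speed, zip_speed_attract = zip_speed_attract,
            zip_stiffness = zip_stiffness,
            zip_wrap_boost = zip_wrap_boost,
            zip_bead_coupling = zip_bead_coupling,
            tau_transient = tau_transient,
            leading_edge_width = leading_edge_width)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && x >= 0, TRUE)]
  if (length(bad)) stop("invalid parameter(s): ", paste(bad, collapse = ", "))
  if (!(theta_base < theta_max && theta_max < 1))
    stop("need theta_base < theta_max < 1")
  if (!(mu_solvent < mu_network_0 * theta_base))
    stop("solvent viscosity must be small against the network (mu_solvent << mu_network_0 * theta_base)")
  structure(p, class = "phago_params")
}

#' Initialize the field state on a mesh
#'
#' @param mesh a `phago_mesh`.
#' @param params a `phago_params`.
#' @return `phago_fields`: `theta` per element, `messenger`, `pressure`
#'   nodal, `v_network`, `v_solvent` N x 2 nodal velocities.
#' @export
init_fields <- function(mesh, params = default_params()) {
  N <- nrow(mesh$coords); E <- nrow(mesh$quads)
  structure(list(
    theta = rep(params$theta_base, E),
    messenger = numeric(N),
    pressure = numeric(N),
    v_network = matrix(0, N, 2L),
    v_solvent = matrix(0, N, 2L)
  ), class = "phago_fields")
}

#' Network viscosity from the network volume fraction
#'
#' The network constitutive law is purely viscous with viscosity linear in
#' theta, scaled by the whole-cell stimulation factor (the five-fold
#' viscosity rise of the zymosan program enters here).
#'
#' @param theta network volume fraction (element field or scalar).
#' @param stimulation_factor global viscosity multiplier (>= 1).
#' @param params a `phago_params`.
#' @return network viscosity, pN s/um^2 (the solvent contribution
#'   `mu_solvent` is carried separately by the momentum assembly).
#' @export
viscosity_of <- function(theta, stimulation_factor = 1, params = default_params()) {
  if (any(theta < 0)) stop("contract violation: negative theta")
  if (any(stimulation_factor < 1)) stop("stimulation_factor must be >= 1")
  stimulation_factor * params$mu_network_0 * theta
}

## bilinear shape functions on the reference square, local CCW node order
.bilin_shape <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}

## ---- quadrature tables (2x2 Gauss on the reference square) ----
.gauss <- local({
  g <- 1 / sqrt(3)
  pts <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  Nsh <- t(apply(pts, 1L, function(p) .bilin_shape(p[1L], p[2L])))
  dNxi <- t(apply(pts, 1L, function(p)
    c(-(1 - p[2L]), (1 - p[2L]), (1 + p[2L]), -(1 + p[2L])) / 4))
  dNeta <- t(apply(pts, 1L, function(p)
    c(-(1 - p[1L]), -(1 + p[1L]), (1 + p[1L]), (1 - p[1L])) / 4))
  list(Nsh = Nsh, dNxi = dNxi, dNeta = dNeta)
})

## per-quadrature-point geometry for all elements: returns a list per qp of
## detJ, dN/dr, dN/dz (E x 4), r at qp (E)
.elem_geom <- function(mesh) {
  q <- mesh$quads
  Xr <- matrix(mesh$coords[q, 1L], nrow(q), 4L)
  Xz <- matrix(mesh$coords[q, 2L], nrow(q), 4L)
  out <- vector("list", 4L)
  for (k in 1L:4L) {
    dxi <- .gauss$dNxi[k, ]; deta <- .gauss$dNeta[k, ]
    J11 <- Xr %*% dxi; J12 <- Xz %*% dxi
    J21 <- Xr %*% deta; J22 <- Xz %*% deta
    det <- as.numeric(J11 * J22 - J12 * J21)
    dNr <- matrix(0, nrow(q), 4L); dNz <- matrix(0, nrow(q), 4L)
    for (a in 1L:4L) {
      dNr[, a] <- (as.numeric(J22) * dxi[a] - as.numeric(J12) * deta[a]) / det
      dNz[, a] <- (-as.numeric(J21) * dxi[a] + as.numeric(J11) * deta[a]) / det
    }
    rq <- as.numeric(Xr %*% .gauss$Nsh[k, ])
    out[[k]] <- list(det = det, dNr = dNr, dNz = dNz, r = rq,
                     Nsh = .gauss$Nsh[k, ])
  }
  out
}

#' Element volumes (integral of r over each element, 2*pi dropped)
#' @param mesh a `phago_mesh`.
#' @return numeric vector of length E.
#' @export
element_volumes <- function(mesh) {
  geom <- .elem_geom(mesh)
  v <- 0
  for (k in 1L:4L) v <- v + geom[[k]]$det * geom[[k]]$r
  v
}

## lumped nodal volumes: integral of N_a r over the domain
.lumped_volumes <- function(mesh) {
  geom <- .elem_geom(mesh)
  N <- nrow(mesh$coords)
  out <- numeric(N)
  q <- mesh$quads
  for (k in 1L:4L) {
    w <- geom[[k]]$det * geom[[k]]$r
    for (a in 1L:4L)
      out <- out + .accum(N, q[, a], w * geom[[k]]$Nsh[a])
  }
  out
}

.accum <- function(N, idx, vals) {
  out <- numeric(N)
  o <- rowsum.default(vals, idx)
  out[as.integer(rownames(o))] <- o
  out
}

## membrane curvature regularization: a small spring pulling each free
## meridian node toward the midpoint of its neighbours, standing in for
## the bending rigidity of the membrane/cortex composite at the element
## scale (suppresses sub-element waists and kinks; held and adhered nodes
## are exempt)
.bending_forces <- function(mesh, k_bend) {
  bid <- mesh$bmer
  nb <- length(bid)
  xy <- mesh$coords[bid, , drop = FALSE]
  g <- matrix(0, nb, 2L)
  if (k_bend <= 0) return(g)
  inner <- 2L:(nb - 1L)
  mid <- (xy[inner - 1L, , drop = FALSE] + xy[inner + 1L, , drop = FALSE]) / 2
  g[inner, ] <- k_bend * (mid - xy[inner, , drop = FALSE])
  ## high-pass: subtract the 5-point moving average so the force vanishes
  ## on smoothly curved arcs (a raw midpoint spring acts like extra
  ## tension and would bias the Laplace balance) and responds only to
  ## element-scale kinks
  for (comp in 1L:2L) {
    sm <- stats::filter(g[, comp], rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    g[, comp] <- g[, comp] - as.numeric(sm)
  }
  g[.rear_hold_slots(mesh), ] <- 0
  g[mesh$contact, ] <- 0
  g
}

## variational cortical-tension nodal forces: -gamma * d(membrane area)/dx.
## Exact gradient of sum(rbar * seglen) over the meridian polyline; passing
## it as a boundary load makes the discrete Laplace law variationally
## consistent (static sphere -> p = 2 gamma / R).
.tension_forces <- function(mesh, gamma) {
  bid <- mesh$bmer
  xy <- mesh$coords[bid, , drop = FALSE]
  nb <- nrow(xy)
  g <- matrix(0, nb, 2L)
  for (s in seq_len(nb - 1L)) {
    pa <- xy[s, ]; pb <- xy[s + 1L, ]
    d <- pb - pa
    l <- sqrt(sum(d * d))
    if (l < 1e-300) next
    rbar <- (pa[1L] + pb[1L]) / 2
    ## dA = d(rbar)*l + rbar*dl
    g[s, 1L] <- g[s, 1L] + l / 2 + rbar * (-d[1L] / l)
    g[s, 2L] <- g[s, 2L] + rbar * (-d[2L] / l)
    g[s + 1L, 1L] <- g[s + 1L, 1L] + l / 2 + rbar * (d[1L] / l)
    g[s + 1L, 2L] <- g[s + 1L, 2L] + rbar * (d[2L] / l)
  }
  -gamma * g
}

#' Solve the quasi-static two-phase momentum balance
#'
#' Assembles and solves the Galerkin system for the network velocity,
#' nodal pressure and (when a target is adhered) the rigid-target axial
#' velocity, then recovers the solvent velocity from the Darcy drag
#' balance. Boundary conditions: variational cortical tension plus applied
#' normal membrane stresses on the meridian (with equal-and-opposite
#' reactions on the membrane-adjacent network ring), no-slip on the
#' rear-hold band, symmetry on the axis, and rigid coupling of
#' contact-patch nodes to the target's axial velocity.
#'
#' @param mesh `phago_mesh`.
#' @param state `phago_fields`.
#' @param params `phago_params`.
#' @param tension cortical tension (pN/um).
#' @param boundary_stresses optional list with per-meridian-node numeric
#'   vectors `outward` (signed outward normal stress applied to the
#'   membrane, pN/um^2, reaction applied inward to the adjacent network
#'   ring), `fvec` (nb x 2 direct nodal membrane forces, pN) and/or
#'   `target_extra` (extra axial force on the target, pN).
#' @param target optional `phago_target`; contact-patch nodes move rigidly
#'   with it.
#' @param stimulation_factor whole-cell viscosity multiplier (>= 1).
#' @return list with `v_network`, `v_solvent` (N x 2), `pressure` (N),
#'   `W` (target axial velocity, um/s; 0 when no contact), and
#'   `div_residual` (L2 norm of the discrete mixture divergence).
#' @export
solve_momentum <- function(mesh, state, params, tension,
                           boundary_stresses = NULL, target = NULL,
                           stimulation_factor = 1) {
  N <- nrow(mesh$coords); E <- nrow(mesh$quads)
  q <- mesh$quads
  theta_e <- state$theta
  mu_e <- viscosity_of(theta_e, stimulation_factor, params) + params$mu_solvent
  kappa_e <- (1 - theta_e)^2 / params$drag_coeff
  geom <- .elem_geom(mesh)

  ## element size^2 for the Brezzi-Pitkaranta stabilization
  area_e <- 0
  for (k in 1L:4L) area_e <- area_e + geom[[k]]$det
  stab_e <- 0.1 * area_e / mu_e

  trip_i <- vector("list", 4L * 16L * 9L)
  trip_j <- vector("list", 4L * 16L * 9L)
  trip_x <- vector("list", 4L * 16L * 9L)
  tn <- 0L
  push <- function(i, j, x) {
    tn <<- tn + 1L
    trip_i[[tn]] <<- i; trip_j[[tn]] <<- j; trip_x[[tn]] <<- x
  }
  idr <- function(a) a            # v_r dofs
  idz <- function(a) N + a        # v_z dofs
  idp <- function(a) 2L * N + a   # pressure dofs

  for (k in 1L:4L) {
    gk <- geom[[k]]
    w <- gk$det * gk$r
    for (a in 1L:4L) {
      na <- q[, a]
      for (b in 1L:4L) {
        nb_ <- q[, b]
        dra <- gk$dNr[, a]; dza <- gk$dNz[, a]
        drb <- gk$dNr[, b]; dzb <- gk$dNz[, b]
        Na <- gk$Nsh[a]; Nb <- gk$Nsh[b]
        co <- 2 * mu_e * w
        push(idr(na), idr(nb_), co * (dra * drb + (Na * Nb) / gk$r^2 + 0.5 * dza * dzb))
        push(idr(na), idz(nb_), co * (0.5 * dza * drb))
        push(idz(na), idr(nb_), co * (0.5 * dra * dzb))
        push(idz(na), idz(nb_), co * (dza * dzb + 0.5 * dra * drb))
        ## pressure coupling: -int p div(w) r dA  (p basis Nb)
        push(idr(na), idp(nb_), -w * Nb * (dra + Na / gk$r))
        push(idz(na), idp(nb_), -w * Nb * dza)
        ## continuity (transpose) and Darcy + stabilization
        push(idp(na), idr(nb_), -w * Na * (drb + Nb / gk$r))
        push(idp(na), idz(nb_), -w * Na * dzb)
        push(idp(na), idp(nb_), -(kappa_e + stab_e) * w * (dra * drb + dza * dzb))
      }
    }
  }

  ndof <- 3L * N + 1L   # + target axial velocity W

  ## RHS: membrane loads
  f <- numeric(ndof)
  bid <- mesh$bmer
  tf <- .tension_forces(mesh, tension) +
    .bending_forces(mesh, params$bending_stab)
  f[idr(bid)] <- f[idr(bid)] + tf[, 1L]
  f[idz(bid)] <- f[idz(bid)] + tf[, 2L]

  if (!is.null(boundary_stresses) && !is.null(boundary_stresses$outward)) {
    sig <- boundary_stresses$outward
    nrm <- .meridian_normals(mesh)
    ar <- .meridian_node_areas(mesh)
    partners <- .meridian_partners(mesh)
    Fr <- sig * ar * nrm[, 1L]; Fz <- sig * ar * nrm[, 2L]
    f[idr(bid)] <- f[idr(bid)] + Fr
    f[idz(bid)] <- f[idz(bid)] + Fz
    f[idr(partners)] <- f[idr(partners)] - Fr
    f[idz(partners)] <- f[idz(partners)] - Fz
  }
  if (!is.null(boundary_stresses) && !is.null(boundary_stresses$fvec)) {
    fv <- boundary_stresses$fvec      # nb x 2 nodal forces on the membrane
    f[idr(bid)] <- f[idr(bid)] + fv[, 1L]
    f[idz(bid)] <- f[idz(bid)] + fv[, 2L]
  }
  if (!is.null(boundary_stresses) && !is.null(boundary_stresses$target_extra))
    f[ndof] <- f[ndof] + boundary_stresses$target_extra

  ## contact-line zipper: a dashpot of stiffness k between the leading
  ## free membrane node and the target, driven at approach speed vdrive
  ## toward the target along dhat, plus a constant apposition force f0.
  ## The reaction is split: a fraction beta reels the target toward the
  ## membrane, the rest recoils on the adjacent interior network (the
  ## lamella pushes itself forward off the cell body).
  zp <- if (is.null(boundary_stresses)) NULL else boundary_stresses$zipper
  if (!is.null(zp)) {
    nd <- bid[zp$slot]
    k <- zp$k; dr <- zp$dhat[1L]; dz <- zp$dhat[2L]
    beta <- zp$beta
    drv <- k * zp$vdrive + zp$f0
    ## force on the lead node: F = [k (vdrive - dhat.(v_n - W z)) + f0] dhat
    push(idr(nd), idr(nd), k * dr * dr)
    push(idr(nd), idz(nd), k * dr * dz)
    push(idz(nd), idr(nd), k * dz * dr)
    push(idz(nd), idz(nd), k * dz * dz)
    push(idr(nd), ndof, -k * dr * dz)
    push(idz(nd), ndof, -k * dz * dz)
    f[idr(nd)] <- f[idr(nd)] + drv * dr
    f[idz(nd)] <- f[idz(nd)] + drv * dz
    ## reaction -beta F on the target's axial dof
    push(ndof, idr(nd), -beta * k * dz * dr)
    push(ndof, idz(nd), -beta * k * dz * dz)
    push(ndof, ndof, beta * k * dz * dz)
    f[ndof] <- f[ndof] - beta * drv * dz
    ## reaction -(1 - beta) F recoils into the lamella interior nodes
    for (qq in seq_along(zp$partners)) {
      pn <- zp$partners[qq]
      bR <- (1 - beta) * zp$pweights[qq] * k
      push(idr(pn), idr(nd), bR * dr * dr)
      push(idr(pn), idz(nd), bR * dr * dz)
      push(idz(pn), idr(nd), bR * dz * dr)
      push(idz(pn), idz(nd), bR * dz * dz)
      push(idr(pn), ndof, -bR * dr * dz)
      push(idz(pn), ndof, -bR * dz * dz)
      f[idr(pn)] <- f[idr(pn)] - (1 - beta) * zp$pweights[qq] * drv * dr
      f[idz(pn)] <- f[idz(pn)] - (1 - beta) * zp$pweights[qq] * drv * dz
    }
  }

  M <- Matrix::sparseMatrix(i = unlist(trip_i[seq_len(tn)]),
                            j = unlist(trip_j[seq_len(tn)]),
                            x = unlist(trip_x[seq_len(tn)]),
                            dims = c(ndof, ndof))

  ## constraints -------------------------------------------------------
  axis_nodes <- which(mesh$coords[, 1L] <= 0)
  rh_nodes <- bid[.rear_hold_slots(mesh)]
  contact_nodes <- if (any(mesh$contact)) bid[mesh$contact] else integer(0)
  has_target <- !is.null(target) && length(contact_nodes) > 0L

  zero_dofs <- unique(c(idr(axis_nodes), idr(rh_nodes), idz(rh_nodes),
                        idr(contact_nodes)))
  wdof <- ndof
  keep <- setdiff(seq_len(ndof), c(zero_dofs, idz(contact_nodes), wdof))
  nred <- length(keep) + if (has_target) 1L else 0L
  Ti <- seq_along(keep); Tj <- keep
  if (has_target) {
    wred <- length(keep) + 1L
    Ti <- c(Ti, rep(wred, length(contact_nodes) + 1L))
    Tj <- c(Tj, idz(contact_nodes), wdof)
  }
  Tr <- Matrix::sparseMatrix(i = Ti, j = Tj, x = 1, dims = c(nred, ndof))
  Mr <- Tr %*% M %*% Matrix::t(Tr)
  fr <- as.numeric(Tr %*% f)
  if (!has_target) {
    ## nothing references W; Mr already excludes it
  }
  sol <- tryCatch(
    as.numeric(Matrix::solve(Mr, fr)),
    error = function(e) stop("solver error: momentum system singular or ill-conditioned: ",
                             conditionMessage(e))
  )
  u <- as.numeric(Matrix::t(Tr) %*% sol)
  W <- if (has_target) sol[length(sol)] else 0
  if (has_target) u[idz(contact_nodes)] <- W

  v <- cbind(u[idr(seq_len(N))], u[idz(seq_len(N))])
  p <- u[idp(seq_len(N))]

  ## solvent recovery from Darcy drag balance
  gp <- .nodal_gradient(mesh, p, geom)
  theta_n <- .elem_to_nodal(mesh, theta_e)
  vs <- v - (1 - theta_n) / params$drag_coeff * gp
  vs[axis_nodes, 1L] <- 0

  ## discrete mixture divergence residual (pressure-equation rows)
  res_full <- as.numeric(M %*% u)
  divres <- sqrt(sum(res_full[idp(seq_len(N))]^2))

  list(v_network = v, v_solvent = vs, pressure = p, W = W,
       div_residual = divres)
}

## volume-weighted element-to-node averaging
.elem_to_nodal <- function(mesh, fe) {
  q <- mesh$quads
  N <- nrow(mesh$coords)
  Ve <- element_volumes(mesh)
  num <- numeric(N); den <- numeric(N)
  for (a in 1L:4L) {
    num <- num + .accum(N, q[, a], Ve * fe)
    den <- den + .accum(N, q[, a], Ve)
  }
  num / pmax(den, 1e-300)
}

## nodal-to-element: mean of the four corners
.nodal_to_elem <- function(mesh, fn) {
  q <- mesh$quads
  (fn[q[, 1L]] + fn[q[, 2L]] + fn[q[, 3L]] + fn[q[, 4L]]) / 4
}

#' Backward-Euler messenger reaction-diffusion step
#'
#' Implicit Galerkin update of dm/dt = D_m lap(m) - k_decay m with a Neumann
#' influx on designated membrane segments. The lumped mass matrix keeps the
#' scheme positivity-preserving and makes pure decay match the closed form
#' m0 / (1 + k dt) per step exactly.
#'
#' @param mesh `phago_mesh`.
#' @param m nodal messenger concentration (a.u.), non-negative.
#' @param D_m diffusivity (um^2/s).
#' @param k_decay decay rate (1/s).
#' @param boundary_source per-meridian-node influx (a.u. um/s), or NULL.
#' @param dt timestep (s).
#' @return updated nodal messenger field.
#' @export
step_messenger <- function(mesh, m, D_m, k_decay, boundary_source, dt) {
  stopifnot(dt > 0)
  if (any(m < -1e-12)) stop("contract violation: negative messenger")
  if (!is.null(boundary_source) && any(boundary_source < 0))
    stop("contract violation: negative source")
  N <- nrow(mesh$coords)
  q <- mesh$quads
  geom <- .elem_geom(mesh)
  Ml <- .lumped_volumes(mesh)

  ti <- vector("list", 64L); tj <- vector("list", 64L); tx <- vector("list", 64L)
  tn <- 0L
  for (k in 1L:4L) {
    gk <- geom[[k]]
    w <- gk$det * gk$r
    for (a in 1L:4L) for (b in 1L:4L) {
      tn <- tn + 1L
      ti[[tn]] <- q[, a]; tj[[tn]] <- q[, b]
      tx[[tn]] <- D_m * w * (gk$dNr[, a] * gk$dNr[, b] + gk$dNz[, a] * gk$dNz[, b])
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N))
  A <- K + Matrix::Diagonal(N, Ml * (1 / dt + k_decay))
  b <- Ml * m / dt
  if (!is.null(boundary_source)) {
    bid <- mesh$bmer
    xy <- mesh$coords[bid, , drop = FALSE]
    nb <- nrow(xy)
    dl <- sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nb, , drop = FALSE])^2))
    rbar <- (xy[-1L, 1L] + xy[-nb, 1L]) / 2
    qseg <- (boundary_source[-nb] + boundary_source[-1L]) / 2
    w <- qseg * rbar * dl / 2
    b[bid[-nb]] <- b[bid[-nb]] + w
    b[bid[-1L]] <- b[bid[-1L]] + w
  }
  out <- as.numeric(Matrix::solve(A, b))
  pmax(out, 0)
}

#' Interconvert the cytosolic and network phases
#'
#' Polymerization driven by the messenger against first-order
#' depolymerization back to the resting fraction:
#' d theta/dt = k_poly m (theta_max - theta) - k_depoly (theta - theta_base),
#' advanced with an unconditionally stable, bounds-preserving implicit
#' update whose fixed point is the algebraic equilibrium
#' theta* = (k_poly m theta_max + k_depoly theta_base) /
#'          (k_poly m + k_depoly).
#'
#' @param theta element network fraction.
#' @param m messenger at elements (same length as theta).
#' @param params `phago_params`.
#' @param dt timestep (s).
#' @return updated theta in `[0, theta_max]`.
#' @export
interconvert_phases <- function(theta, m, params, dt) {
  stopifnot(dt > 0, length(m) == length(theta))
  a <- params$k_poly * pmax(m, 0)
  th <- (theta + dt * (a * params$theta_max + params$k_depoly * params$theta_base)) /
    (1 + dt * (a + params$k_depoly))
  pmin(pmax(th, 0), params$theta_max)
}
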