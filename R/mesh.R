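# Axisymmetric structured quadrilateral mesh of the cell cross-section.
#
# Coordinates are cylindrical (r, z): z along the symmetry (pipette) axis,
# r >= 0. All lengths are in micrometres. The meridian cross-section of the
# cell is meshed with a single logical block of (m x n) bilinear quads:
# logical row j = 0 lies on the symmetry axis, and the membrane meridian
# (rear pole -> left column -> top row -> right column -> front pole) carries
# the boundary tags. Azimuthal factors of 2*pi are dropped consistently in
# all volume/area quadratures.

#' Rigid spherical phagocytic target
#'
#' The target is a rigid sphere centred on the symmetry axis. The default
#' radius of 1.6 um corresponds to the 3.2 um-diameter particles used as
#' model zymosan and antibody-coated targets.
#'
#' @param radius sphere radius (um).
#' @param center_z axial position of the sphere centre (um); `NULL` means
#'   "to be placed touching the cell front pole" by [build_initial_mesh()].
#' @return an object of class `phago_target` with fields `radius`,
#'   `center_z` and `phi_max` (polar-angle extent of the adhered arc,
#'   radians; 0 when nothing is adhered).
#' @export
target_sphere <- function(radius = 1.6, center_z = NULL) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  structure(list(radius = radius, center_z = center_z, phi_max = 0),
            class = "phago_target")
}

## logical node index matrix: (m+1) x (n+1), column-major over j
.nid_matrix <- function(m, n) {
  matrix(seq_len((m + 1L) * (n + 1L)), nrow = m + 1L, ncol = n + 1L)
}

## ordered meridian slots: (i, j) logical coords of the membrane polyline
.meridian_ij <- function(m, n) {
  rbind(
    cbind(0L, 0L:n),                 # left column, rear pole upward
    cbind(1L:(m - 1L), n),           # top row
    cbind(m, n:0L)                   # right column, down to front pole
  )
}

## per-segment arclength weights along the meridian (free part). The
## logical corner (m, n) lies on the smooth membrane, where a corner
## quad's Jacobian is proportional to the local polyline turn angle
## (h * curvature); keeping the boundary spacing locally coarse there
## keeps that element healthy. (The other corner, (0, n), is the pipette
## lip: a genuine geometric kink on the held band, no weighting needed.)
.segment_weights <- function(m, n) {
  nb <- m + 2L * n + 1L
  k <- seq_len(nb - 1L) + 0.5       # segment midpoints in slot units
  c2 <- n + m + 1L                  # logical corner (m, n)
  1 + 2.5 * exp(-(k - c2)^2 / 6)
}

#' Build the initial cell mesh touching a spherical target
#'
#' Constructs a near-spherical cell whose front pole touches (or, for a
#' positive `initial_contact_angle`, wraps slightly onto) the target sphere
#' on the symmetry axis. A short band of boundary at the rear pole is tagged
#' `rear_hold` and represents the holding micropipette (zero velocity).
#'
#' @param cell_radius cell radius (um); must exceed the target radius.
#' @param target a [target_sphere()]; if its `center_z` is `NULL` it is
#'   placed touching the cell front pole.
#' @param initial_contact_angle polar-angle extent (radians) of the initial
#'   adhered patch; 0 gives an empty contact patch.
#' @param resolution element-count scale factor; 1 gives a 30 x 26 block
#'   (780 elements), and at least 8 elements must span the cell radius.
#' @param rear_hold_len arclength (um) of the rear boundary band held by the
#'   pipette stand-in (the aspirated flat cap).
#' @param polish run the repositioning smoother on the freshly built mesh
#'   (disable only for diagnostic inspection of the raw layout).
#' @return a list of class `phago_mesh`; see Details.
#' @details The mesh carries `coords` (N x 2 matrix of (r, z)), `quads`
#'   (E x 4 counter-clockwise node indices), the ordered meridian node list
#'   `bmer` with per-node adhesion state (`contact`, `patch_age`, `phi`),
#'   per-segment boundary tags via [boundary_segments()], and a remesh
#'   `generation` counter.
#' @export
build_initial_mesh <- function(cell_radius = 4.25,
                               target = target_sphere(),
                               initial_contact_angle = 0,
                               resolution = 1,
                               rear_hold_len = 1.2,
                               polish = TRUE) {
  if (!inherits(target, "phago_target")) stop("target must be a phago_target")
  if (!(cell_radius > target$radius && target$radius > 0))
    stop("geometry error: need cell_radius > target radius > 0")
  ## the right logical column must outlast the fully wrapped patch (the
  ## block corner cannot sit on the concave adhered arc), so the radial
  ## direction carries more nodes than the ~22 the 175-degree patch
  ## consumes at default spacing
  n <- as.integer(round(26 * resolution))
  m <- as.integer(round(30 * resolution))
  if (n < 8L) stop("configuration error: resolution too low (need >= 8 elements across the cell radius)")
  if (!is.null(target$center_z) && target$center_z < cell_radius)
    stop("geometry error: target overlaps the cell centre")

  nid <- .nid_matrix(m, n)
  N <- (m + 1L) * (n + 1L)
  coords <- matrix(0, N, 2L)
  mer <- .meridian_ij(m, n)
  nb <- nrow(mer)

  ## membrane nodes: polar angle psi from rear pole (psi = 0) to front
  ## pole (psi = pi) on a circle of radius cell_radius centred at 0.
  ## The whole left logical column is the pipette-held band; the rest of
  ## the meridian is spaced by the corner-aware weights.
  psi_band <- rear_hold_len / cell_radius
  wseg <- .segment_weights(m, n)[(n + 1L):(nb - 1L)]
  psi <- c(rep(psi_band, n + 1L),
           psi_band + (pi - psi_band) * cumsum(wseg) / sum(wseg))
  bid <- nid[cbind(mer[, 1L] + 1L, mer[, 2L] + 1L)]
  coords[bid, 1L] <- cell_radius * sin(psi)
  coords[bid, 2L] <- -cell_radius * cos(psi)
  ## the held band is the flat cap aspirated against the pipette mouth: a
  ## disk at the lip plane, so the pipette lip is a convex corner
  coords[bid[1L:(n + 1L)], 1L] <- (0L:n) / n * cell_radius * sin(psi_band)
  coords[bid[1L:(n + 1L)], 2L] <- -cell_radius * cos(psi_band)
  coords[bid[c(1L, nb)], 1L] <- 0   # poles exactly on axis

  ## axis row j = 0: align each column base with its top-row node's z
  ## (horizontal-slice initial layout), then fill the interior with the
  ## boundary-layer-corrected column proposal
  for (i in 1L:(m - 1L)) {
    top <- nid[i + 1L, n + 1L]
    coords[nid[i + 1L, 1L], ] <- c(0, coords[top, 2L])
  }
  ids0 <- nid[2L:m, 2L:n]
  coords[as.vector(ids0), ] <- .interior_proposal(m, n, nid, coords)

  quads <- matrix(0L, m * n, 4L)
  e <- 0L
  for (j in 0L:(n - 1L)) {
    for (i in 0L:(m - 1L)) {
      e <- e + 1L
      quads[e, ] <- c(nid[i + 1L, j + 1L], nid[i + 1L, j + 2L],
                      nid[i + 2L, j + 2L], nid[i + 2L, j + 1L])
    }
  }

  if (is.null(target$center_z)) target$center_z <- cell_radius + target$radius

  mesh <- structure(list(
    m = m, n = n, nid = nid, coords = coords, quads = quads,
    bmer = bid, mer_ij = mer,
    contact = logical(nb), patch_age = rep(NA_real_, nb),
    phi = rep(NA_real_, nb),
    rear_hold_len = rear_hold_len,
    cell_radius = cell_radius,
    generation = 0L
  ), class = "phago_mesh")

  ## adhere an initial arc, if requested
  if (initial_contact_angle > 0) {
    stop_phi <- initial_contact_angle
    cz <- target$center_z
    Rt <- target$radius
    ## wrap front meridian nodes onto the sphere up to stop_phi
    arc <- Rt * stop_phi
    ds <- cell_radius * pi / (nb - 1)        # typical meridian spacing
    k <- max(1L, ceiling(arc / ds))
    for (q in 0L:k) {
      slot <- nb - q
      phi_q <- stop_phi * q / k
      mesh$coords[bid[slot], ] <- c(Rt * sin(phi_q), cz - Rt * cos(phi_q))
      mesh$contact[slot] <- TRUE
      mesh$patch_age[slot] <- 0
      mesh$phi[slot] <- phi_q
    }
    target$phi_max <- stop_phi
  }

  if (polish) {
    mesh <- reposition_interior(mesh, target = target, sweeps = 500L,
                                redistribute = FALSE)
    jac <- corner_jacobians(mesh)
    if (min(jac) <= 0) stop("remesh failure: initial mesh has non-positive Jacobians")
  }
  attr(mesh, "target") <- target
  mesh
}

#' Boundary segments of the closed cross-section polyline
#'
#' Returns the closed boundary polyline of the meshed cross-section as a
#' data frame of directed segments with tags: the membrane meridian
#' (`rear_hold`, `free_membrane` or `contact_patch`) followed by the
#' symmetry-axis closure (`axis`).
#'
#' @param mesh a `phago_mesh`.
#' @return data.frame with columns `a`, `b` (node indices) and `tag`.
#' @export
boundary_segments <- function(mesh) {
  bid <- mesh$bmer
  nb <- length(bid)
  ## arclength from rear pole along the meridian
  tag <- rep("free_membrane", nb - 1L)
  tag[seq_len(mesh$n)] <- "rear_hold"       # the held left logical column
  ct <- mesh$contact
  both <- ct[-nb] & ct[-1L]
  tag[both] <- "contact_patch"
  ax <- mesh$nid[, 1L]               # j = 0 row: front pole back to rear pole
  ax <- rev(ax)
  data.frame(
    a = c(bid[-nb], ax[-length(ax)]),
    b = c(bid[-1L], ax[-1L]),
    tag = c(tag, rep("axis", length(ax) - 1L)),
    stringsAsFactors = FALSE
  )
}

## meridian slots of the pipette-held band: the whole left logical column
## (rear pole up to and including the pipette lip at the corner (0, n))
.rear_hold_slots <- function(mesh) {
  seq_len(mesh$n + 1L)
}

#' Enclosed cell volume by Pappus quadrature
#'
#' Integrates r^2/2 dz around the closed boundary polyline (the azimuthal
#' 2*pi is dropped, consistently with all other quadratures in the package).
#'
#' @param mesh a `phago_mesh`.
#' @return enclosed volume (um^3, modulo 2*pi).
#' @export
mesh_volume <- function(mesh) {
  segs <- boundary_segments(mesh)
  ra <- mesh$coords[segs$a, 1L]; rb <- mesh$coords[segs$b, 1L]
  za <- mesh$coords[segs$a, 2L]; zb <- mesh$coords[segs$b, 2L]
  v <- sum((ra * ra + ra * rb + rb * rb) / 6 * (za - zb))
  abs(v)
}

#' Membrane area (meridian arclength weighted by radius)
#'
#' Surface area of the membrane of revolution, modulo 2*pi: sum over
#' meridian segments of mean radius times segment length.
#' @param mesh a `phago_mesh`.
#' @return membrane area (um^2, modulo 2*pi).
#' @export
membrane_area <- function(mesh) {
  bid <- mesh$bmer
  xy <- mesh$coords[bid, , drop = FALSE]
  nb <- nrow(xy)
  dl <- sqrt(rowSums((xy[-1L, ] - xy[-nb, ])^2))
  rbar <- (xy[-1L, 1L] + xy[-nb, 1L]) / 2
  sum(rbar * dl)
}

## corner Jacobian determinants of every quad, E x 4 (in the (r, z) plane)
#' @export
corner_jacobians <- function(mesh) {
  q <- mesh$quads
  r <- matrix(mesh$coords[q, 1L], nrow(q), 4L)
  z <- matrix(mesh$coords[q, 2L], nrow(q), 4L)
  jac <- matrix(0, nrow(q), 4L)
  nxt <- c(2L, 3L, 4L, 1L); prv <- c(4L, 1L, 2L, 3L)
  for (k in 1L:4L) {
    e1r <- r[, nxt[k]] - r[, k]; e1z <- z[, nxt[k]] - z[, k]
    e2r <- r[, prv[k]] - r[, k]; e2z <- z[, prv[k]] - z[, k]
    jac[, k] <- e1r * e2z - e1z * e2r
  }
  jac
}

#' Minimum scaled-Jacobian element quality
#'
#' Corner Jacobian normalized by the product of the adjacent edge lengths
#' (1 for a rectangle corner, 0 for a degenerate one, negative if inverted).
#' @param mesh a `phago_mesh`.
#' @return the minimum over all corners of all elements.
#' @export
mesh_quality <- function(mesh) {
  q <- mesh$quads
  r <- matrix(mesh$coords[q, 1L], nrow(q), 4L)
  z <- matrix(mesh$coords[q, 2L], nrow(q), 4L)
  sj <- matrix(0, nrow(q), 4L)
  nxt <- c(2L, 3L, 4L, 1L); prv <- c(4L, 1L, 2L, 3L)
  for (k in 1L:4L) {
    e1r <- r[, nxt[k]] - r[, k]; e1z <- z[, nxt[k]] - z[, k]
    e2r <- r[, prv[k]] - r[, k]; e2z <- z[, prv[k]] - z[, k]
    l1 <- sqrt(e1r^2 + e1z^2); l2 <- sqrt(e2r^2 + e2z^2)
    sj[, k] <- (e1r * e2z - e1z * e2r) / pmax(l1 * l2, .Machine$double.eps)
  }
  min(sj)
}

#' Courant timestep bound
#'
#' Returns `min(dt_max, cfl * min_e(h_e / max speed in e))` over all
#' elements, where `h_e` is the shortest element edge.
#'
#' @param mesh a `phago_mesh`.
#' @param v_network N x 2 nodal velocity matrix (um/s).
#' @param cfl Courant number in (0, 1].
#' @param dt_max accuracy-limited maximum step (s).
#' @return a strictly positive timestep (s).
#' @export
courant_timestep <- function(mesh, v_network, cfl = 0.5, dt_max = 1) {
  stopifnot(cfl > 0, cfl <= 1, dt_max > 0)
  if (!all(is.finite(v_network))) stop("numerical-state error: non-finite velocities")
  q <- mesh$quads
  r <- matrix(mesh$coords[q, 1L], nrow(q), 4L)
  z <- matrix(mesh$coords[q, 2L], nrow(q), 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  hmin <- rep(Inf, nrow(q))
  for (k in 1L:4L) {
    el <- sqrt((r[, nxt[k]] - r[, k])^2 + (z[, nxt[k]] - z[, k])^2)
    hmin <- pmin(hmin, el)
  }
  sp <- sqrt(v_network[, 1L]^2 + v_network[, 2L]^2)
  smax <- matrix(sp[q], nrow(q), 4L)
  smax <- pmax(smax[, 1L], smax[, 2L], smax[, 3L], smax[, 4L])
  dt <- suppressWarnings(min(hmin / pmax(smax, .Machine$double.xmin)))
  max(min(dt_max, cfl * dt), .Machine$double.xmin)
}

#' Advect the mesh boundary with the network flow
#'
#' Displaces membrane meridian nodes by `dt * v_network`; axis nodes keep
#' r = 0 exactly and rear-hold nodes do not move. Interior nodes are left to
#' [reposition_interior()].
#'
#' @param mesh a `phago_mesh`.
#' @param v_network N x 2 nodal velocities (um/s).
#' @param dt timestep (s), normally from [courant_timestep()].
#' @param move_interior also move interior and axis nodes materially
#'   (used by the simulation cycle so that the subsequent remap is purely
#'   a repositioning correction).
#' @return the advected mesh.
#' @export
advect_boundary <- function(mesh, v_network, dt, move_interior = FALSE) {
  rh <- mesh$bmer[.rear_hold_slots(mesh)]
  rh_old <- mesh$coords[rh, , drop = FALSE]
  if (move_interior) {
    mesh$coords <- mesh$coords + dt * v_network
  } else {
    bid <- mesh$bmer
    mesh$coords[bid, ] <- mesh$coords[bid, , drop = FALSE] +
      dt * v_network[bid, , drop = FALSE]
  }
  mesh$coords[rh, ] <- rh_old                 # pipette band does not move
  ## axis pinning: the j = 0 row (and both poles) stay at r = 0 exactly
  ax <- mesh$nid[, 1L]
  mesh$coords[ax, 1L] <- 0
  mesh$coords[mesh$bmer[c(1L, length(mesh$bmer))], 1L] <- 0
  jac <- corner_jacobians(mesh)
  if (min(jac) <= 0 && !move_interior)
    stop("remesh failure: boundary advection inverted an element (reduce dt)")
  mesh
}

## interior layout proposal: straight columns from each axis node to its
## top-row node, with fast-decaying boundary-layer corrections so the
## first columns follow the shape of the side boundary curves (the held
## band on the left, the free/patch column on the right). Returns an
## (m-1)(n-1) x 2 matrix in the order of as.vector(nid[2:m, 2:n]).
.interior_proposal <- function(m, n, nid, coords) {
  v <- (1L:(n - 1L)) / n
  out <- matrix(0, (m - 1L) * (n - 1L), 2L)
  wl <- pmax(0, 1 - (1L:(m - 1L)) / 6)       # decay from the left side
  wr <- pmax(0, 1 - ((m - 1L):1L) / 6)       # decay from the right side
  for (comp in 1L:2L) {
    Acv <- coords[nid[, 1L], comp]
    Tcv <- coords[nid[, n + 1L], comp]
    Lin <- Acv[2L:m] %o% (1 - v) + Tcv[2L:m] %o% v
    Lin0 <- Acv[1L] * (1 - v) + Tcv[1L] * v
    Linm <- Acv[m + 1L] * (1 - v) + Tcv[m + 1L] * v
    Lcv <- coords[nid[1L, 2L:n], comp]       # left (band) curve
    Rcv <- coords[nid[m + 1L, 2L:n], comp]   # right boundary curve
    corr <- wl %o% (Lcv - Lin0) + wr %o% (Rcv - Linm)
    out[, comp] <- as.vector(Lin + corr)
  }
  out
}

#' Reposition mesh nodes for resolution while preserving topology and tags
#'
#' Interior nodes are smoothed toward the centroid of their four logical
#' neighbours (damped Jacobi sweeps); axis nodes slide along the axis only;
#' free-membrane boundary nodes are redistributed to equal arclength along
#' the existing polyline (geometry and tags preserved); contact-patch,
#' rear-hold and pole nodes are fixed; every node is kept outside the
#' target sphere. The combined move is applied with a backtracking blend
#' factor so that the global minimum scaled-Jacobian quality never
#' decreases (the blend falls back to the identity if necessary).
#'
#' @param mesh a `phago_mesh`.
#' @param target optional [target_sphere()]; nodes are kept outside it.
#' @param sweeps number of Jacobi sweeps.
#' @param redistribute redistribute free-membrane boundary nodes.
#' @return the repositioned mesh (generation counter incremented).
#' @export
reposition_interior <- function(mesh, target = NULL, sweeps = 10L,
                                redistribute = TRUE) {
  m <- mesh$m; n <- mesh$n; nid <- mesh$nid
  coords0 <- mesh$coords
  coords <- coords0
  qual0 <- mesh_quality(mesh)

  Rt <- if (!is.null(target)) target$radius else NA_real_
  cz <- if (!is.null(target)) target$center_z else NA_real_
  keep_out <- function(xy) {
    if (is.null(target)) return(xy)
    d <- sqrt(xy[, 1L]^2 + (xy[, 2L] - cz)^2)
    bad <- which(d < Rt & d > 1e-12)
    if (length(bad)) {
      sc <- Rt / d[bad]
      xy[bad, 1L] <- xy[bad, 1L] * sc
      xy[bad, 2L] <- cz + (xy[bad, 2L] - cz) * sc
    }
    xy
  }

  ## free-membrane boundary smoothing between fixed anchors: nodes slide
  ## ALONG the polyline (geometry preserved) toward a blend of (a) their
  ## weighted equal-arclength position and (b) the arclength of the
  ## projection of their interior partner node, which keeps the boundary
  ## parametrization aligned with the interior columns as membrane slides
  ## toward the cup
  if (redistribute) {
    bid <- mesh$bmer; nb <- length(bid)
    fixed <- logical(nb)
    fixed[c(1L, nb)] <- TRUE
    fixed[.rear_hold_slots(mesh)] <- TRUE
    fixed[mesh$contact] <- TRUE
    ## the leading free node is the zipper's handle: sliding it back along
    ## the polyline would erase the apposition progress, so anchor it
    if (any(mesh$contact)) {
      rim <- min(which(mesh$contact))
      if (rim > 1L) fixed[rim - 1L] <- TRUE
    }
    anchors <- which(fixed)
    wseg_all <- .segment_weights(m, n)
    xy <- coords[bid, , drop = FALSE]
    for (k in seq_len(length(anchors) - 1L)) {
      a <- anchors[k]; b <- anchors[k + 1L]
      if (b - a < 2L) next
      idx <- a:b
      seg <- xy[idx, , drop = FALSE]
      dl <- sqrt(rowSums((seg[-1L, , drop = FALSE] - seg[-nrow(seg), , drop = FALSE])^2))
      s <- c(0, cumsum(dl))
      stot <- s[length(s)]
      if (stot <= 0) next
      wk <- wseg_all[a:(b - 1L)]
      s_unif <- stot * c(0, cumsum(wk)) / sum(wk)
      inner <- 2L:(length(idx) - 1L)
      ## bounded move toward the weighted equal-arclength position
      cap <- 0.3 * stot / length(idx)
      s_new <- s
      s_new[inner] <- s[inner] +
        pmin(pmax(s_unif[inner] - s[inner], -cap), cap)
      gmin <- 0.05 * stot / length(idx)
      for (q in inner) s_new[q] <- max(s_new[q], s_new[q - 1L] + gmin)
      rr <- stats::approx(s, seg[, 1L], xout = pmin(s_new[inner], stot))$y
      zz <- stats::approx(s, seg[, 2L], xout = pmin(s_new[inner], stot))$y
      coords[bid[idx[inner]], 1L] <- rr
      coords[bid[idx[inner]], 2L] <- zz
    }
    coords[bid, ] <- keep_out(coords[bid, , drop = FALSE])
  }

  ## axis nodes slide along the axis in concert with the meridian: each
  ## interior axis node takes the fraction of the axis chord given by the
  ## (monotonized) polar angle of its column's top boundary node about the
  ## cell centroid, so columns stay radial as membrane slides forward
  iax <- nid[2L:m, 1L]
  topn <- nid[2L:m, n + 1L]
  z_rear <- coords[nid[1L, 1L], 2L]
  z_front <- coords[nid[m + 1L, 1L], 2L]
  ## horizontal-slice correspondence: each interior axis node tracks its
  ## top-row node's axial position (monotonized and clamped between the
  ## poles; wrapped cup-lip columns compress toward the front pole)
  zprop <- cummax(coords[topn, 2L])
  zprop <- pmin(pmax(zprop, z_rear + 0.02), z_front - 0.02)
  dz_ax <- zprop - coords[iax, 2L]
  cap_ax <- 0.3 * (z_front - z_rear) / m
  coords[iax, 2L] <- coords[iax, 2L] + sign(dz_ax) * pmin(abs(dz_ax), cap_ax)
  ## keep the axis ordering strictly monotone between the poles
  zz <- coords[nid[, 1L], 2L]
  hmin <- (z_front - z_rear) / (4 * m)
  for (i in 2L:m) zz[i] <- min(max(zz[i], zz[i - 1L] + hmin),
                               z_front - (m + 1L - i) * hmin)
  coords[nid[2L:m, 1L], 2L] <- zz[2L:m]

  ## interior proposal: per-column interpolation from each axis node to
  ## its top-row boundary node anchors the low-frequency layout to the
  ## boundary correspondence (incomplete Jacobi relaxation alone lets the
  ## interior drift cumulatively); Jacobi sweeps then relax local wrinkles
  ids <- nid[2L:m, 2L:n]

  ## smoothing can misplace nodes where the cross-section is concave (the
  ## wrapped cup); locally revert the nodes of folded elements to their
  ## pre-proposal positions before polishing
  for (pass in 1L:3L) {
    tm <- mesh; tm$coords <- coords
    jac <- corner_jacobians(tm)
    bad <- which(apply(jac, 1L, min) <= 0)
    if (!length(bad)) break
    bad_nodes <- setdiff(unique(as.vector(mesh$quads[bad, ])),
                         c(mesh$bmer, nid[, 1L]))
    if (!length(bad_nodes)) break
    coords[bad_nodes, ] <- coords0[bad_nodes, ]
  }

  ## red-black SOR on the Winslow (inverse-harmonic) stencil: unlike
  ## plain Laplacian smoothing, Winslow grids do not fold at concave
  ## boundary sections (the engulfment cup, the waist above the pipette)
  E <- nid[3L:(m + 1L), 2L:n]; W <- nid[1L:(m - 1L), 2L:n]
  Nn <- nid[2L:m, 3L:(n + 1L)]; Ss <- nid[2L:m, 1L:(n - 1L)]
  NE <- nid[3L:(m + 1L), 3L:(n + 1L)]; NW <- nid[1L:(m - 1L), 3L:(n + 1L)]
  SE <- nid[3L:(m + 1L), 1L:(n - 1L)]; SW <- nid[1L:(m - 1L), 1L:(n - 1L)]
  ii_g <- matrix(1L:(m - 1L), m - 1L, n - 1L)
  jj_g <- matrix(1L:(n - 1L), m - 1L, n - 1L, byrow = TRUE)
  red <- ((ii_g + jj_g) %% 2L) == 0L
  omega <- 1.4
  for (s in seq_len(sweeps)) {
    for (phase in c(TRUE, FALSE)) {
      sel <- if (phase) red else !red
      xe <- coords[E[sel], , drop = FALSE]; xw <- coords[W[sel], , drop = FALSE]
      xn <- coords[Nn[sel], , drop = FALSE]; xs <- coords[Ss[sel], , drop = FALSE]
      xne <- coords[NE[sel], , drop = FALSE]; xnw <- coords[NW[sel], , drop = FALSE]
      xse <- coords[SE[sel], , drop = FALSE]; xsw <- coords[SW[sel], , drop = FALSE]
      xxi <- (xe - xw) / 2
      xeta <- (xn - xs) / 2
      al <- rowSums(xeta * xeta)
      ga <- rowSums(xxi * xxi)
      be <- rowSums(xxi * xeta)
      den <- 2 * (al + ga)
      den[den < 1e-300] <- 1e-300
      tgt <- (al * (xe + xw) + ga * (xn + xs) -
                0.5 * be * (xne - xnw - xse + xsw)) / den
      cur <- coords[ids[sel], , drop = FALSE]
      coords[ids[sel], ] <- keep_out(cur + omega * (tgt - cur))
    }
  }

  ## backtracking blend: never decrease global minimum quality
  trial_mesh <- mesh
  f <- 1
  repeat {
    trial <- coords0 + f * (coords - coords0)
    trial[nid[, 1L], 1L] <- 0                       # axis pinned exactly
    trial <- keep_out(trial)
    trial[nid[, 1L], 1L] <- 0
    trial_mesh$coords <- trial
    qt <- mesh_quality(trial_mesh)
    ## accept when quality is healthy or within a small slack of the input
    ## quality (the global minimum often sits at a logical corner element
    ## that smoothing cannot touch), but never let it collapse
    ok <- qt > 0 && qt >= min(qual0, 0.02) &&
      (qt >= qual0 - 0.005 || qt >= 0.12)
    if (ok || f < 1e-3) break
    f <- f / 2
  }
  if (f < 1e-3) trial_mesh$coords <- coords0        # identity fallback
  trial_mesh$repos_blend <- if (f < 1e-3) 0 else f
  trial_mesh$generation <- mesh$generation + 1L
  if (mesh_quality(trial_mesh) <= 0)
    stop("remesh failure: repositioning could not maintain positive Jacobians")
  trial_mesh
}

## ---- conservative field remap (old mesh -> new mesh, same topology) ----

## signed r-weighted volume of the quad swept by edge (a, b) moving from
## old coords to new coords; positive when the sweep is toward the +normal
## side of the directed old edge a->b (normal = rotate(tangent, -90deg))
.swept_volumes <- function(old_xy, new_xy, a, b) {
  r <- cbind(old_xy[a, 1L], old_xy[b, 1L], new_xy[b, 1L], new_xy[a, 1L])
  z <- cbind(old_xy[a, 2L], old_xy[b, 2L], new_xy[b, 2L], new_xy[a, 2L])
  v <- numeric(length(a))
  for (k in 1L:4L) {
    k2 <- if (k == 4L) 1L else k + 1L
    v <- v + (r[, k]^2 + r[, k] * r[, k2] + r[, k2]^2) / 6 * (z[, k2] - z[, k])
  }
  ## polygon (a_old, b_old, b_new, a_new) is CCW (positive integral) when the
  ## edge sweeps to the left of a->b; flip so positive = toward rotate(t,-90)
  ## orientation check is delegated to the caller via consistent edge order
  v
}

#' Remap fields between two meshes of identical topology
#'
#' Conservative arbitrary-Lagrangian-Eulerian remap for the repositioning
#' part of the computational cycle. Element fields (`theta`) are remapped by
#' upwind swept-face volume exchange (exactly conservative, monotone for the
#' small node movements produced by repositioning); nodal fields
#' (`messenger`, velocities, pressure) are re-interpolated at the new node
#' positions, and the messenger additionally receives a bounded conservative
#' mass fix.
#'
#' @param old_mesh,new_mesh `phago_mesh` objects sharing `quads`.
#' @param fields a `phago_fields` list (see [init_fields()]).
#' @return the remapped `phago_fields`.
#' @export
remap_fields <- function(old_mesh, new_mesh, fields) {
  if (!identical(old_mesh$quads, new_mesh$quads) ||
      old_mesh$m != new_mesh$m || old_mesh$n != new_mesh$n)
    stop("contract violation: meshes do not share topology")
  if (identical(old_mesh$coords, new_mesh$coords)) return(fields)

  m <- old_mesh$m; n <- old_mesh$n; nid <- old_mesh$nid
  Vold <- element_volumes(old_mesh)
  Vnew <- element_volumes(new_mesh)
  theta <- fields$theta
  mass <- theta * Vold

  oxy <- old_mesh$coords; nxy <- new_mesh$coords
  eid <- function(i, j) i + j * m + 1L

  ## Sweep sign convention: .swept_volumes is positive when the shared edge
  ## sweeps toward the LEFT of its direction a->b. Because every quad is
  ## counter-clockwise, the element whose CCW boundary traverses a->b has
  ## its interior on the left; a positive sweep eats into that element, so
  ## it is the donor and the opposite element gains the swept mass.

  ## vertical interior faces between e(i-1, j) and e(i, j), i = 1..m-1:
  ## shared edge (i, j) -> (i, j+1) is CCW-traversed by e(i, j) (right side)
  E <- length(Vold)
  ii <- rep(1L:(m - 1L), n); jj <- rep(0L:(n - 1L), each = m - 1L)
  aN <- nid[cbind(ii + 1L, jj + 1L)]; bN <- nid[cbind(ii + 1L, jj + 2L)]
  sv <- .swept_volumes(oxy, nxy, aN, bN)
  eL <- eid(ii - 1L, jj); eR <- eid(ii, jj)
  dm <- ifelse(sv > 0, sv * theta[eR], sv * theta[eL])
  mass_d <- .accum(E, eL, dm) - .accum(E, eR, dm)

  ## horizontal interior faces between e(i, j-1) and e(i, j), j = 1..n-1:
  ## shared edge (i, j) -> (i+1, j) is CCW-traversed by e(i, j-1) (below)
  ii <- rep(0L:(m - 1L), n - 1L); jj <- rep(1L:(n - 1L), each = m)
  aN <- nid[cbind(ii + 1L, jj + 1L)]; bN <- nid[cbind(ii + 2L, jj + 1L)]
  sv <- .swept_volumes(oxy, nxy, aN, bN)
  eB <- eid(ii, jj - 1L); eT <- eid(ii, jj)
  dm2 <- ifelse(sv > 0, sv * theta[eB], sv * theta[eT])
  mass_d <- mass_d + .accum(E, eT, dm2) - .accum(E, eB, dm2)

  ## boundary faces: self-transfer (material slides along the boundary);
  ## keeps a uniform field exactly uniform
  bmass <- (Vnew - Vold) - .volume_change_from_interior(m, n, nid, oxy, nxy)
  mass_new <- mass + mass_d + bmass * theta
  theta_new <- mass_new / pmax(Vnew, .Machine$double.eps)
  lo <- min(theta); hi <- max(theta)
  fields$theta <- pmin(pmax(theta_new, lo), hi)

  ## nodal fields: first-order update f(x_new) ~ f(x_old) + dx . grad f,
  ## clipped to the old global bounds (no new extrema), with a bounded
  ## conservative mass fix for the messenger
  dx <- nxy - oxy
  geom_o <- .elem_geom(old_mesh)
  m_tot_before <- if (is.null(fields$messenger)) NULL else
    sum(.lumped_volumes(old_mesh) * fields$messenger)
  m_old_max <- if (is.null(fields$messenger)) NULL else max(fields$messenger)
  for (nm in c("messenger", "pressure")) {
    f <- fields[[nm]]
    if (is.null(f)) next
    g <- .nodal_gradient(old_mesh, f, geom_o)
    fnew <- f + dx[, 1L] * g[, 1L] + dx[, 2L] * g[, 2L]
    fields[[nm]] <- pmin(pmax(fnew, min(f)), max(f))
  }
  if (!is.null(fields$messenger)) {
    tot_n <- sum(.lumped_volumes(new_mesh) * fields$messenger)
    mx <- max(fields$messenger)
    if (tot_n > 0 && mx > 0) {
      ## bounded conservative fix that never manufactures a new maximum
      sc <- min(max(m_tot_before / tot_n, 0.98), 1.02, m_old_max / mx)
      fields$messenger <- fields$messenger * sc
    }
  }
  fields
}

## volume-weighted nodal gradient of a Q1 nodal field
.nodal_gradient <- function(mesh, f, geom = NULL) {
  if (is.null(geom)) geom <- .elem_geom(mesh)
  q <- mesh$quads
  N <- nrow(mesh$coords)
  num_r <- numeric(N); num_z <- numeric(N); den <- numeric(N)
  for (k in 1L:4L) {
    gk <- geom[[k]]
    w <- gk$det * gk$r
    fr <- numeric(nrow(q)); fz <- numeric(nrow(q))
    for (b in 1L:4L) {
      fr <- fr + gk$dNr[, b] * f[q[, b]]
      fz <- fz + gk$dNz[, b] * f[q[, b]]
    }
    for (a in 1L:4L) {
      wa <- w * gk$Nsh[a]
      num_r <- num_r + .accum(N, q[, a], wa * fr)
      num_z <- num_z + .accum(N, q[, a], wa * fz)
      den <- den + .accum(N, q[, a], wa)
    }
  }
  cbind(num_r / pmax(den, 1e-300), num_z / pmax(den, 1e-300))
}

## per-element volume change attributable to interior+boundary node motion
## through interior faces only (same sweep bookkeeping as remap_fields)
.volume_change_from_interior <- function(m, n, nid, oxy, nxy) {
  eid <- function(i, j) i + j * m + 1L
  dv <- numeric(m * n)
  ii <- rep(1L:(m - 1L), n); jj <- rep(0L:(n - 1L), each = m - 1L)
  aN <- nid[cbind(ii + 1L, jj + 1L)]; bN <- nid[cbind(ii + 1L, jj + 2L)]
  sv <- .swept_volumes(oxy, nxy, aN, bN)
  eL <- eid(ii - 1L, jj); eR <- eid(ii, jj)
  for (k in seq_along(sv)) {
    dv[eL[k]] <- dv[eL[k]] + sv[k]
    dv[eR[k]] <- dv[eR[k]] - sv[k]
  }
  ii <- rep(0L:(m - 1L), n - 1L); jj <- rep(1L:(n - 1L), each = m)
  aN <- nid[cbind(ii + 1L, jj + 1L)]; bN <- nid[cbind(ii + 2L, jj + 1L)]
  sv <- .swept_volumes(oxy, nxy, aN, bN)
  eB <- eid(ii, jj - 1L); eT <- eid(ii, jj)
  for (k in seq_along(sv)) {
    dv[eT[k]] <- dv[eT[k]] + sv[k]
    dv[eB[k]] <- dv[eB[k]] - sv[k]
  }
  dv
}

## shortest element edge in the mesh (for the capillary timestep bound)
.min_edge <- function(mesh) {
  q <- mesh$quads
  r <- matrix(mesh$coords[q, 1L], nrow(q), 4L)
  z <- matrix(mesh$coords[q, 2L], nrow(q), 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  hmin <- Inf
  for (k in 1L:4L)
    hmin <- min(hmin, sqrt((r[, nxt[k]] - r[, k])^2 + (z[, nxt[k]] - z[, k])^2))
  hmin
}

## local untangler: iteratively pull the interior nodes of folded elements
## toward the centroid of their logical neighbours until all corner
## Jacobians are positive (or the iteration budget is exhausted)
.untangle <- function(mesh, max_iter = 80L) {
  m <- mesh$m; n <- mesh$n; nid <- mesh$nid
  fixed <- c(mesh$bmer, nid[, 1L])
  for (it in seq_len(max_iter)) {
    jac <- corner_jacobians(mesh)
    bad <- which(apply(jac, 1L, min) <= 0)
    if (!length(bad)) return(mesh)
    nodes <- setdiff(unique(as.vector(mesh$quads[bad, ])), fixed)
    if (!length(nodes)) return(mesh)
    for (nd in nodes) {
      ij <- which(nid == nd, arr.ind = TRUE)
      i <- ij[1L]; j <- ij[2L]
      nbrs <- c(nid[i - 1L, j], nid[i + 1L, j], nid[i, j - 1L], nid[i, j + 1L])
      ctr <- colMeans(mesh$coords[nbrs, , drop = FALSE])
      mesh$coords[nd, ] <- mesh$coords[nd, ] + 0.5 * (ctr - mesh$coords[nd, ])
    }
  }
  mesh
}

## outward unit normals of the meridian nodes (away from the cell interior)
.meridian_normals <- function(mesh) {
  bid <- mesh$bmer
  xy <- mesh$coords[bid, , drop = FALSE]
  nb <- nrow(xy)
  tan_prev <- rbind(xy[2L, ] - xy[1L, ],
                    xy[-1L, , drop = FALSE] - xy[-nb, , drop = FALSE])
  tan_next <- rbind(xy[-1L, , drop = FALSE] - xy[-nb, , drop = FALSE],
                    xy[nb, ] - xy[nb - 1L, ])
  tn <- tan_prev + tan_next
  ln <- sqrt(rowSums(tn^2))
  tn <- tn / pmax(ln, 1e-300)
  nrm <- cbind(tn[, 2L], -tn[, 1L])   # rotate tangent by -90 deg
  ## orient away from the cell centroid
  ctr <- colMeans(mesh$coords)
  dot <- rowSums(nrm * (xy - matrix(ctr, nb, 2L, byrow = TRUE)))
  flip <- dot < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  nrm
}

## nodal membrane area weights: half the r-weighted length of the adjacent
## meridian segments
.meridian_node_areas <- function(mesh) {
  bid <- mesh$bmer
  xy <- mesh$coords[bid, , drop = FALSE]
  nb <- nrow(xy)
  dl <- sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nb, , drop = FALSE])^2))
  rbar <- (xy[-1L, 1L] + xy[-nb, 1L]) / 2
  w <- rbar * dl
  a <- numeric(nb)
  a[-nb] <- a[-nb] + w / 2
  a[-1L] <- a[-1L] + w / 2
  a
}

## interior "partner" node (one logical ring inside) for each meridian slot
.meridian_partners <- function(mesh) {
  m <- mesh$m; n <- mesh$n; nid <- mesh$nid
  mer <- mesh$mer_ij
  nb <- nrow(mer)
  out <- integer(nb)
  for (k in seq_len(nb)) {
    i <- mer[k, 1L]; j <- mer[k, 2L]
    pi_ <- i; pj <- j
    if (i == 0L) pi_ <- 1L
    if (i == m) pi_ <- m - 1L
    if (j == n) pj <- n - 1L
    if (j == 0L) pj <- 1L                     # poles
    out[k] <- nid[pi_ + 1L, pj + 1L]
  }
  out
}
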