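# Mesh engine: construction, geometry, timestep, advection, repositioning
# and conservative remap.

test_that("initial mesh satisfies the geometric invariants", {
  mesh <- build_initial_mesh(cell_radius = 4.25, target = target_sphere(1.6),
                             resolution = 1)
  expect_true(all(mesh$coords[, 1L] >= 0))
  expect_identical(mesh$coords[mesh$nid[, 1L], 1L],
                   rep(0, nrow(mesh$nid)))           # axis exactly at r = 0
  expect_gt(min(corner_jacobians(mesh)), 0)

  segs <- boundary_segments(mesh)
  ## the boundary forms one closed polyline: consecutive segments chain and
  ## the last closes onto the first
  expect_equal(segs$a[-1L], segs$b[-nrow(segs)])
  expect_equal(segs$b[nrow(segs)], segs$a[1L])
  expect_setequal(unique(segs$tag), c("rear_hold", "free_membrane", "axis"))

  tg <- attr(mesh, "target")
  expect_equal(tg$radius, 1.6)                       # 3.2 um diameter target
})

test_that("initial contact angle controls the adhered patch", {
  m0 <- build_initial_mesh(initial_contact_angle = 0)
  expect_false(any(m0$contact))
  expect_false(any(boundary_segments(m0)$tag == "contact_patch"))

  m1 <- build_initial_mesh(initial_contact_angle = 0.3)
  expect_true(any(m1$contact))
  expect_equal(attr(m1, "target")$phi_max, 0.3)
  ## adhered nodes lie on the sphere
  tg <- attr(m1, "target")
  xy <- m1$coords[m1$bmer[m1$contact], , drop = FALSE]
  expect_lt(max(abs(sqrt(xy[, 1L]^2 + (xy[, 2L] - tg$center_z)^2) - tg$radius)),
            1e-8)
})

test_that("degenerate geometry and resolution inputs are rejected", {
  expect_error(build_initial_mesh(cell_radius = 1, target = target_sphere(1.6)),
               "geometry")
  expect_error(build_initial_mesh(resolution = 0.2), "resolution")
  expect_error(build_initial_mesh(target = target_sphere(1.6, center_z = 2)),
               "overlap")
})

test_that("doubling resolution quadruples elements and preserves volume", {
  m1 <- build_initial_mesh(resolution = 1)
  m2 <- build_initial_mesh(resolution = 2)
  expect_equal(nrow(m2$quads) / nrow(m1$quads), 4, tolerance = 0.05)
  v1 <- mesh_volume(m1); v2 <- mesh_volume(m2)
  expect_lt(abs(v2 - v1) / v1, 0.01)
  ## both agree with the analytic sphere volume (2/3 R^3 modulo 2 pi)
  expect_lt(abs(v1 - 2 / 3 * 4.25^3) / (2 / 3 * 4.25^3), 0.01)
})

test_that("courant timestep matches a brute-force per-element bound", {
  mesh <- build_initial_mesh()
  N <- nrow(mesh$coords)
  ## zero velocity: the accuracy cap rules
  expect_equal(courant_timestep(mesh, matrix(0, N, 2L), cfl = 0.5, dt_max = 2), 2)
  set.seed(7)
  v <- matrix(rnorm(2 * N, sd = 0.05), N, 2L)
  got <- courant_timestep(mesh, v, cfl = 0.4, dt_max = 100)
  ## brute force: loop every element, shortest edge / fastest corner
  q <- mesh$quads
  best <- Inf
  for (e in seq_len(nrow(q))) {
    xy <- mesh$coords[q[e, ], ]
    h <- min(sqrt(rowSums((xy - xy[c(2, 3, 4, 1), ])^2)))
    sp <- max(sqrt(rowSums(v[q[e, ], ]^2)))
    best <- min(best, h / sp)
  }
  expect_equal(got, 0.4 * best, tolerance = 1e-12)
  expect_error(courant_timestep(mesh, v * NA, 0.5, 1), "non-finite")
})

test_that("boundary advection translates, pins the axis and conserves flux", {
  mesh <- build_initial_mesh()
  N <- nrow(mesh$coords)
  ## zero velocity: identity
  m0 <- advect_boundary(mesh, matrix(0, N, 2L), dt = 0.5)
  expect_equal(m0$coords, mesh$coords)

  ## uniform axial velocity with the rear band held: free boundary
  ## translates by w dt, rear-hold nodes unmoved
  w <- 0.02; dt <- 0.5
  v <- cbind(rep(0, N), rep(w, N))
  m1 <- advect_boundary(mesh, v, dt)
  segs <- boundary_segments(mesh)
  rh_nodes <- unique(c(segs$a[segs$tag == "rear_hold"],
                       segs$b[segs$tag == "rear_hold"]))
  free_nodes <- setdiff(unique(c(segs$a[segs$tag == "free_membrane"],
                                 segs$b[segs$tag == "free_membrane"])),
                        rh_nodes)
  expect_equal(m1$coords[free_nodes, 2L], mesh$coords[free_nodes, 2L] + w * dt)
  expect_equal(m1$coords[rh_nodes, ], mesh$coords[rh_nodes, ])
  expect_identical(m1$coords[mesh$nid[, 1L], 1L], rep(0, nrow(mesh$nid)))

  ## radial inflow: volume change equals the boundary flux integral x dt
  ## (quadrature over the meridian) within 1%
  eps <- 0.01
  vin <- -eps * mesh$coords                 # v = -eps * x (radial, toward 0)
  m2 <- advect_boundary(mesh, vin, dt)
  dV <- mesh_volume(m2) - mesh_volume(mesh)
  bid <- mesh$bmer
  xy <- mesh$coords[bid, ]
  nb <- nrow(xy)
  mid <- (xy[-1L, ] + xy[-nb, ]) / 2
  tangent <- xy[-1L, ] - xy[-nb, ]
  ## outward normal of the meridian (rotate tangent, orient outward)
  nrm <- cbind(tangent[, 2L], -tangent[, 1L])
  flip <- rowSums(nrm * mid) < 0
  nrm[flip, ] <- -nrm[flip, ]
  vmid <- -eps * mid
  rbar <- mid[, 1L]
  flux <- sum(rowSums(vmid * nrm) * rbar)   # |tangent| folded into nrm
  ## rear-hold band does not move; exclude its segments from the flux
  segl <- cumsum(sqrt(rowSums(tangent^2)))
  held <- segl <= mesh$rear_hold_len
  flux <- flux - sum((rowSums(vmid * nrm) * rbar)[held])
  expect_equal(dV, flux * dt, tolerance = 0.01 * abs(flux * dt) / abs(flux * dt) + 0.01)
  expect_lt(abs(dV - flux * dt) / abs(dV), 0.01)
})

test_that("repositioning preserves boundary geometry and improves sheared meshes", {
  mesh <- build_initial_mesh()
  ## near-fixed point: an already smoothed mesh barely moves
  m1 <- reposition_interior(mesh, sweeps = 2L)
  h <- sqrt(mean(element_volumes(mesh)))
  expect_lt(max(abs(m1$coords - mesh$coords)), 0.15 * h)
  expect_equal(m1$generation, mesh$generation + 1L)
  ## boundary polyline geometry is preserved (nodes may slide along it):
  ## total meridian length and enclosed volume unchanged
  expect_equal(mesh_volume(m1), mesh_volume(mesh), tolerance = 1e-3)

  ## single perturbed interior node is restored toward its neighbours
  m2 <- mesh
  node <- m2$nid[15, 7]
  before <- m2$coords[node, ]
  m2$coords[node, ] <- before + c(0.08, -0.06)
  m3 <- reposition_interior(m2, sweeps = 4L, redistribute = FALSE)
  expect_lt(sum((m3$coords[node, ] - before)^2),
            sum((m2$coords[node, ] - before)^2))

  ## sheared mesh: minimum scaled-Jacobian quality does not decrease
  m4 <- mesh
  ids <- m4$nid[2:m4$m, 2:m4$n]
  m4$coords[as.vector(ids), 2L] <- m4$coords[as.vector(ids), 2L] +
    0.25 * m4$coords[as.vector(ids), 1L] * 0.2
  q_before <- mesh_quality(m4)
  m5 <- reposition_interior(m4, sweeps = 6L, redistribute = FALSE)
  expect_gte(mesh_quality(m5), q_before - 1e-12)
})

test_that("remap conserves mass, preserves uniform fields and is monotone", {
  mesh <- build_initial_mesh()
  params <- test_params()
  f <- init_fields(mesh, params)

  ## identity remap
  expect_equal(remap_fields(mesh, mesh, f), f)

  ## perturbed mesh: interior nodes shifted by ~half an element
  set.seed(11)
  m2 <- mesh
  ## perturb interior nodes away from the finely meshed pipette band so
  ## the perturbed mesh stays valid
  ids <- as.vector(m2$nid[8:(m2$m - 4), 3:(m2$n - 4)])
  h <- 0.03
  m2$coords[ids, ] <- m2$coords[ids, ] +
    matrix(runif(2 * length(ids), -h, h), ncol = 2L)
  stopifnot(min(corner_jacobians(m2)) > 0)

  ## uniform element field stays exactly uniform
  f$theta <- rep(0.2, nrow(mesh$quads))
  g <- remap_fields(mesh, m2, f)
  expect_equal(g$theta, f$theta, tolerance = 1e-12)

  ## Gaussian messenger blob: total mass conserved within 0.5%, no new
  ## extrema, non-uniform theta conserved exactly (flux-form remap)
  ctr <- c(1.2, 0.5)
  f$messenger <- exp(-rowSums((sweep(mesh$coords, 2L, ctr))^2) / (2 * 0.8^2))
  ev <- element_volumes(mesh)
  th <- 0.05 + 0.3 * exp(-seq_len(nrow(mesh$quads)) / 100)
  f$theta <- th
  g <- remap_fields(mesh, m2, f)
  lump <- function(mm, x) sum(phagoflow:::.lumped_volumes(mm) * x)
  expect_lt(abs(lump(m2, g$messenger) - lump(mesh, f$messenger)) /
              lump(mesh, f$messenger), 0.005)
  expect_lte(max(g$messenger), max(f$messenger) * (1 + 1e-9))
  expect_gte(min(g$messenger), min(f$messenger) - 1e-12)
  expect_equal(sum(g$theta * element_volumes(m2)), sum(th * ev),
               tolerance = 1e-10)
  expect_lte(max(g$theta), max(th) + 1e-12)

  ## topology mismatch is a contract violation
  m3 <- build_initial_mesh(resolution = 2)
  expect_error(remap_fields(mesh, m3, f), "topology")
})
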