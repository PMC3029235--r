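# Two-phase momentum solve, messenger reaction-diffusion and phase
# interconversion.

test_that("static sphere satisfies the Laplace law and stays at rest", {
  mesh <- build_initial_mesh()
  params <- test_params()
  f <- init_fields(mesh, params)
  R <- 4.25
  for (gam in c(25, 150)) {
    sol <- solve_momentum(mesh, f, params, tension = gam)
    p_exp <- 2 * gam / R
    expect_lt(abs(mean(sol$pressure) - p_exp) / p_exp, 0.02)
    ## residual velocities correspond to a shape-change rate well under
    ## 1% of R per viscous relaxation time mu R / gamma
    tau <- params$mu_network_0 * params$theta_base * R / gam
    vmax <- max(sqrt(rowSums(sol$v_network^2)))
    expect_lt(vmax * tau / R, 0.01)
    expect_equal(sol$W, 0)
  }
})

test_that("zero tension and zero stresses give zero flow and uniform pressure", {
  mesh <- build_initial_mesh()
  params <- test_params()
  f <- init_fields(mesh, params)
  sol <- solve_momentum(mesh, f, params, tension = 0)
  expect_lt(max(abs(sol$v_network)), 1e-10)
  expect_lt(diff(range(sol$pressure)), 1e-8)
})

test_that("network viscosity is linear in theta and the stimulation factor", {
  params <- test_params()
  th <- c(0, 0.1, 0.3)
  expect_equal(viscosity_of(th, 1, params), params$mu_network_0 * th)
  ## five-fold stimulation multiplies the viscosity five-fold
  expect_equal(viscosity_of(0.2, 5, params), 5 * viscosity_of(0.2, 1, params))
  expect_error(viscosity_of(-0.1, 1, params), "negative")
  expect_error(viscosity_of(0.1, 0.5, params), ">= 1")
})

test_that("backward-Euler messenger decay matches the closed form exactly", {
  mesh <- build_initial_mesh()
  k <- 0.35; dt <- 0.7
  m <- rep(2.5, nrow(mesh$coords))
  for (i in 1:5) m <- step_messenger(mesh, m, D_m = 0, k_decay = k,
                                     boundary_source = NULL, dt = dt)
  expect_equal(m, rep(2.5 / (1 + k * dt)^5, length(m)), tolerance = 1e-12)
})

test_that("messenger mass balances source over decay at steady state", {
  mesh <- build_initial_mesh()
  k <- 0.5; q <- 0.8
  nb <- length(mesh$bmer)
  src <- rep(q, nb)
  m <- numeric(nrow(mesh$coords))
  for (i in 1:60) m <- step_messenger(mesh, m, D_m = 1, k_decay = k,
                                      boundary_source = src, dt = 2)
  total_mass <- sum(phagoflow:::.lumped_volumes(mesh) * m)
  influx <- q * membrane_area(mesh)
  expect_equal(total_mass, influx / k, tolerance = 0.01)
  expect_true(all(m >= 0))
})

test_that("axial diffusion matches the analytic cosine-mode solution", {
  mesh <- make_box_mesh(mi = 30L, nj = 8L, R = 2, L = 6)
  D <- 1.2; L <- 6
  z <- mesh$coords[, 2L]
  m0 <- 1 + cos(pi * z / L)
  tend <- L^2 / (10 * D)
  nstep <- 80L
  m <- m0
  for (i in seq_len(nstep)) m <- step_messenger(mesh, m, D_m = D, k_decay = 0,
                                                boundary_source = NULL,
                                                dt = tend / nstep)
  exact <- 1 + cos(pi * z / L) * exp(-D * (pi / L)^2 * tend)
  rel_l2 <- sqrt(sum((m - exact)^2) / sum(exact^2))
  expect_lt(rel_l2, 0.03)
})

test_that("phase interconversion has the algebraic equilibrium and bounds", {
  params <- test_params()
  ## m = 0 at the resting fraction: fixed point
  th <- rep(params$theta_base, 5)
  expect_equal(interconvert_phases(th, rep(0, 5), params, 0.5), th)

  ## m = 0 above rest: exponential-like relaxation to theta_base at k_depoly
  th0 <- 0.3
  dt <- 0.02
  th <- th0
  for (i in 1:50) th <- interconvert_phases(th, 0, params, dt)
  expected <- params$theta_base +
    (th0 - params$theta_base) * exp(-params$k_depoly * 50 * dt)
  expect_equal(th, expected, tolerance = 0.01)

  ## constant m: long-run value equals the algebraic balance
  mval <- 0.8
  th <- params$theta_base
  for (i in 1:4000) th <- interconvert_phases(th, mval, params, 0.5)
  a <- params$k_poly * mval
  th_star <- (a * params$theta_max + params$k_depoly * params$theta_base) /
    (a + params$k_depoly)
  expect_equal(th, th_star, tolerance = 1e-6)

  ## bounds always hold
  th <- interconvert_phases(c(0, 0.49), c(1e6, 1e6), params, 10)
  expect_true(all(th >= 0 & th <= params$theta_max))
})

test_that("prolate relaxation time scales linearly with viscosity", {
  ## a tension-driven rounding run: e-folding time of the asphericity is
  ## proportional to mu R / gamma, so doubling mu doubles it
  relax_time <- function(mu0) {
    params <- default_params(mu_network_0 = mu0)
    mesh <- build_initial_mesh()
    ## prolate perturbation: stretch z about the centroid by 8%
    zc <- mean(mesh$coords[, 2L])
    mesh$coords[, 2L] <- zc + (mesh$coords[, 2L] - zc) * 1.08
    mesh$coords[, 1L] <- mesh$coords[, 1L] / sqrt(1.08)
    mesh$coords[mesh$nid[, 1L], 1L] <- 0
    f <- init_fields(mesh, params)
    gam <- 50
    asp <- function(m) {
      xy <- m$coords[m$bmer, ]
      zr <- diff(range(xy[, 2L])) / 2
      rr <- max(xy[, 1L])
      zr / rr - 1
    }
    a0 <- asp(mesh)
    tsim <- 0
    ## timestep scaled with viscosity and small enough that the Courant
    ## bound never binds: both runs traverse the same scaled trajectory
    for (i in 1:40) {
      sol <- solve_momentum(mesh, f, params, gam)
      dt <- courant_timestep(mesh, sol$v_network, 1,
                             dt_max = mu0 / 40000)
      mesh <- advect_boundary(mesh, sol$v_network, dt, move_interior = TRUE)
      mesh <- reposition_interior(mesh, sweeps = 10L)
      tsim <- tsim + dt
    }
    a1 <- asp(mesh)
    tsim / log(a0 / a1)
  }
  t1 <- relax_time(4000)
  t2 <- relax_time(8000)
  expect_equal(t2 / t1, 2, tolerance = 0.1)
})
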