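# Cell-target interface: adhesion growth, effector stresses, tension
# timeline, target kinematics.

test_that("cortical tension follows the measured ramp-to-plateau law", {
  zym <- make_scenario("zymosan")
  ab <- make_scenario("antibody")
  expect_equal(cortical_tension(0, zym), 25)      # 0.025 mN/m = 25 pN/um
  expect_equal(cortical_tension(0, ab), 25)
  expect_equal(cortical_tension(1000, zym), 300)  # 0.3 mN/m plateau
  expect_equal(cortical_tension(1000, ab), 150)   # 0.15 mN/m plateau
  ## linear in between: halfway through the ramp
  tmid <- zym$ramp_onset + zym$ramp_duration / 2
  expect_equal(cortical_tension(tmid, zym), (25 + 300) / 2)
  expect_error(cortical_tension(-1, zym))
})

test_that("protrusive stress scales by zone exactly as the effector table", {
  params <- test_params()
  th <- c(0.1, 0.3)
  zym <- make_scenario("zymosan")
  ab <- make_scenario("antibody")
  free_z <- protrusive_stress(th, "free", zym, params)
  free_a <- protrusive_stress(th, "free", ab, params)
  expect_equal(free_z, free_a)                       # "same" at free membrane
  expect_equal(protrusive_stress(th, "contact", ab, params), c(0, 0))
  expect_equal(protrusive_stress(th, "contact", zym, params), 0.5 * free_z)
  full <- make_scenario("zymosan_full_contact_protrusion")
  expect_equal(protrusive_stress(th, "contact", full, params), free_z)
  expect_equal(protrusive_stress(0, "free", zym, params), 0)
  expect_error(protrusive_stress(th, "inside", zym, params), "zone")
})

test_that("attraction acts only on the adherent membrane of the antibody program", {
  params <- test_params()
  zym <- make_scenario("zymosan")
  ab <- make_scenario("antibody")
  expect_equal(attraction_stress("contact", zym, 0, params), 0)
  expect_equal(attraction_stress("free", ab, 0, params), 0)
  expect_gt(attraction_stress("contact", ab, 0, params), 0)
  ## short interaction range
  expect_equal(attraction_stress("contact", ab, params$attract_range * 2,
                                 params), 0)
  noat <- make_scenario("fcgamma_no_attraction")
  expect_equal(attraction_stress("contact", noat, 0, params), 0)
})

test_that("adhesion is irreversible and grows contiguously from the pole", {
  mesh <- build_initial_mesh()
  target <- attr(mesh, "target")
  expect_false(any(mesh$contact))
  up <- update_adhesion(mesh, target)
  expect_true(any(up$mesh$contact))
  expect_gte(up$target$phi_max, 0)
  ## adhered nodes sit exactly on the sphere
  xy <- up$mesh$coords[up$mesh$bmer[up$mesh$contact], , drop = FALSE]
  d <- sqrt(xy[, 1]^2 + (xy[, 2] - up$target$center_z)^2)
  expect_lt(max(abs(d - up$target$radius)), 1e-9)
  ## idempotent when nothing new is within tolerance
  up2 <- update_adhesion(up$mesh, up$target)
  expect_identical(up2$mesh$contact, up$mesh$contact)
  ## fresh nodes start their age clock at zero
  expect_true(all(up$mesh$patch_age[up$mesh$contact] == 0))
})

test_that("messenger source covers fresh patch plus the leading-edge annulus", {
  params <- test_params()
  ab <- make_scenario("antibody")
  mesh <- build_initial_mesh(initial_contact_angle = 0.35)
  flux <- messenger_source(mesh, ab, params)
  rim <- min(which(mesh$contact))
  expect_true(all(flux[mesh$contact] ==
                    ab$stimulus_scale * params$source_strength))
  expect_true(all(flux[(rim - params$leading_edge_width):(rim - 1)] > 0))
  expect_true(all(flux[1:(rim - params$leading_edge_width - 1)] == 0))

  ## the zymosan stimulus is 25% weaker
  zym <- make_scenario("zymosan")
  fz <- messenger_source(mesh, zym, params)
  expect_equal(max(fz) / max(flux), 0.75)

  ## aged patch stops producing
  mesh2 <- mesh
  mesh2$patch_age[mesh2$contact] <- params$tau_transient + 1
  f2 <- messenger_source(mesh2, ab, params)
  expect_true(all(f2[mesh2$contact] == 0))
  expect_true(any(f2 > 0))   # the annulus ahead of the rim stays active

  ## no contact, no flux
  m0 <- build_initial_mesh()
  expect_equal(messenger_source(m0, ab, params), numeric(length(m0$bmer)))
})

test_that("target force balance advances the centre and reports relative position", {
  tg <- target_sphere(1.6, center_z = 5.85)
  out <- target_force_balance(tg, W = 0, dt = 1, rear_z = -4.1)
  expect_equal(out$target$center_z, 5.85)
  out2 <- target_force_balance(tg, W = 0.02, dt = 2, rear_z = -4.1)
  expect_equal(out2$target$center_z, 5.89)
  expect_equal(out2$position, 5.89 + 4.1)
})

test_that("an outward pole push moves the target outward in the full solve", {
  mesh <- build_initial_mesh()
  target <- attr(mesh, "target")
  up <- update_adhesion(mesh, target)
  mesh <- up$mesh; target <- up$target
  params <- test_params()
  f <- init_fields(mesh, params)
  nb <- length(mesh$bmer)
  sig <- numeric(nb)
  sig[mesh$contact] <- 100      # outward push at the contact pole
  sol <- solve_momentum(mesh, f, params, tension = 25,
                        boundary_stresses = list(outward = sig),
                        target = target)
  expect_gt(sol$W, 0)
  ## and an inward (attraction-like) stress pulls it inward
  sig2 <- numeric(nb); sig2[mesh$contact] <- -100
  sol2 <- solve_momentum(mesh, f, params, tension = 25,
                         boundary_stresses = list(outward = sig2),
                         target = target)
  expect_lt(sol2$W, 0)
})
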