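# Scenario presets and the simulation driver.

test_that("presets encode the mechanoeffector switchboard", {
  zym <- make_scenario("zymosan")
  expect_equal(zym$stimulus_scale, 0.75)
  expect_equal(zym$contact_protrusion_scale, 0.5)
  expect_false(zym$attraction_on)
  expect_equal(zym$tension_rest, 0.025)
  expect_equal(zym$tension_plateau, 0.3)
  expect_equal(zym$viscosity_ramp_factor, 5)

  ab <- make_scenario("antibody")
  expect_equal(ab$stimulus_scale, 1)
  expect_equal(ab$contact_protrusion_scale, 0)
  expect_true(ab$attraction_on)
  expect_equal(ab$tension_plateau, 0.15)
  expect_equal(ab$viscosity_ramp_factor, 1)

  noat <- make_scenario("fcgamma_no_attraction")
  expect_false(noat$attraction_on)
  expect_equal(noat$contact_protrusion_scale, ab$contact_protrusion_scale)
  expect_equal(noat$tension_plateau, ab$tension_plateau)

  full <- make_scenario("zymosan_full_contact_protrusion")
  expect_equal(full$contact_protrusion_scale, 1)
  expect_equal(full$tension_plateau, zym$tension_plateau)

  expect_error(make_scenario("martian"))
  bad <- unclass(zym); bad$stimulus_scale <- 2
  expect_error(validate_scenario(bad), "stimulus_scale")
  bad2 <- unclass(zym); bad2$tension_plateau <- 0.01
  expect_error(validate_scenario(bad2), "tension_plateau")
})

test_that("the viscosity stimulation factor ramps in lockstep with tension", {
  zym <- make_scenario("zymosan")
  sfun <- phagoflow:::.stimulation_factor
  expect_equal(sfun(0, zym), 1)
  expect_equal(sfun(1e4, zym), 5)
  tmid <- zym$ramp_onset + zym$ramp_duration / 2
  expect_equal(sfun(tmid, zym), 3)
  ab <- make_scenario("antibody")
  expect_equal(sfun(1e4, ab), 1)      # constant throughout
})

test_that("repeated short runs are identical (bitwise determinism)", {
  sc <- make_scenario("antibody")
  sc$t_end <- 6; sc <- validate_scenario(sc)
  p <- test_params()
  t1 <- run_simulation(sc, p)
  t2 <- run_simulation(sc, p)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$target_position, t2$target_position)
  expect_identical(t1$engulfed_fraction, t2$engulfed_fraction)
})

test_that("with nothing driving motion the target stays put", {
  sc <- make_scenario("antibody")
  sc$tension_plateau <- sc$tension_rest   # no ramp
  sc$t_end <- 8
  sc <- validate_scenario(sc)
  ## zero all interface stresses: no protrusion, no attraction, no zipper
  p <- default_params(sigma_protrude = 0, sigma_attract = 0,
                      zip_speed = 0, zip_speed_attract = 0,
                      source_strength = 0)
  tr <- run_simulation(sc, p)
  ## after the initial discrete-shape relaxation transient, the target
  ## position settles (nothing drives sustained motion)
  late <- tr$time >= max(tr$time) / 2
  drift <- diff(range(tr$target_position[late]))
  expect_lt(drift, 0.05)
  expect_true(all(diff(tr$engulfed_fraction) >= 0))
  expect_true(all(diff(tr$time) > 0))
})
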