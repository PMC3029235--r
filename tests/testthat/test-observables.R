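# Metric extraction from trajectories: exact on constructed fixtures.

test_that("push-out distance is the peak displacement after contact, floored at 0", {
  tr <- make_known_trace(d = 1.3, T_complete = 120)
  expect_equal(push_out_distance(tr), 1.3)

  ## monotonically inward trace floors at zero
  inward <- list(time = 0:100, target_position = -0.02 * (0:100),
                 engulfed_fraction = pmin((0:100) / 100, 1), contact_time = 0)
  expect_equal(push_out_distance(inward), 0)

  no_contact <- list(time = 0:10, target_position = rep(0, 11),
                     engulfed_fraction = rep(0, 11))
  expect_error(push_out_distance(no_contact), "no contact")
})

test_that("engulfment time is the threshold crossing minus contact time", {
  tr <- make_known_trace(d = 0.5, T_complete = 66)
  expect_equal(engulfment_time(tr), 66)

  ## jump fixture: fraction 0 -> 1 at exactly t_contact + 66
  jump <- list(time = 0:200, target_position = numeric(201),
               engulfed_fraction = c(rep(1e-6, 66), rep(1, 135)),
               contact_time = 0)
  expect_equal(engulfment_time(jump), 66)

  ## zero threshold degenerates to 0
  expect_equal(engulfment_time(tr, completion_threshold = 0), 0)

  ## incomplete run is flagged, not a number
  inc <- make_known_trace(d = 0.5, T_complete = 500)
  inc$engulfed_fraction <- pmin(inc$engulfed_fraction, 0.5)
  et <- engulfment_time(inc)
  expect_true(is.na(et))
  expect_true(attr(et, "incomplete"))
})

test_that("max inward speed recovers a programmed linear ramp exactly", {
  tr <- make_known_trace(d = 1, T_complete = 150, v_in = 33 / 1000)
  expect_equal(max_inward_speed(tr), 33, tolerance = 1e-9)

  flat <- list(time = 0:100, target_position = rep(0.5, 101),
               engulfed_fraction = pmin((0:100) / 100, 1), contact_time = 0)
  expect_equal(max_inward_speed(flat), 0)

  short <- list(time = 0:3, target_position = rep(0, 4),
                engulfed_fraction = c(0, 1, 1, 1), contact_time = 0)
  expect_error(max_inward_speed(short, window = 10), "shorter")
})

test_that("speed metric is robust to a two-fold change of smoothing window", {
  tr <- make_known_trace(d = 1, T_complete = 150, v_in = 33 / 1000)
  v1 <- max_inward_speed(tr, window = 5)
  v2 <- max_inward_speed(tr, window = 10)
  v3 <- max_inward_speed(tr, window = 20)
  expect_lt(abs(v1 - v2) / v2, 0.1)
  expect_lt(abs(v3 - v2) / v2, 0.1)
})

test_that("trace comparison reports RMS deviation and metric deltas", {
  tr <- make_known_trace(d = 1, T_complete = 100)
  cmp0 <- compare_trace(tr, tr)
  expect_equal(cmp0$rms, 0)
  expect_equal(unname(cmp0$delta), c(0, 0, 0))

  off <- tr
  off$target_position <- tr$target_position + 0.25
  cmp <- compare_trace(off, tr)
  expect_equal(cmp$rms, 0.25, tolerance = 1e-12)

  late <- tr; late$time <- tr$time + 1e5
  expect_error(compare_trace(tr, late), "overlap")
})
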