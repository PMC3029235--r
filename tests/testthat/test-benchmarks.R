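# Synthetic experiment-like trace generator: exact parameter recovery on
# noise-free skeletons, determinism, and cohort statistics.

test_that("noise-free skeleton recovers the generating parameters exactly", {
  for (scn in c("zymosan", "antibody")) {
    tr <- gen_trace(scn, seed = 42, noise_sd = 0)
    sk <- list(time = tr$time, target_position = tr$skeleton,
               engulfed_fraction = tr$engulfed_fraction,
               contact_time = tr$contact_time)
    expect_equal(push_out_distance(sk), tr$true_params$push_out,
                 tolerance = 1e-10)
    expect_equal(as.numeric(engulfment_time(sk)),
                 tr$true_params$completion_time, tolerance = 1e-10)
    expect_equal(max_inward_speed(sk), tr$true_params$inward_speed,
                 tolerance = 1e-8)
  }
})

test_that("trace generation is reproducible per seed and leaves the RNG alone", {
  t1 <- gen_trace("zymosan", seed = 7)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  t2 <- gen_trace("zymosan", seed = 7)
  after <- runif(1)
  expect_identical(t1$position, t2$position)
  expect_identical(t1$true_params, t2$true_params)
  expect_equal(before, after)   # caller RNG stream undisturbed

  t3 <- gen_trace("zymosan", seed = 8)
  expect_false(identical(t1$position, t3$position))
})

test_that("tension timelines follow the prescribed piecewise-linear law", {
  tg <- seq(0, 200, by = 1)
  z <- gen_tension_timeline("zymosan", tg)
  a <- gen_tension_timeline("antibody", tg)
  expect_equal(z[1], 0.025)                 # resting value, mN/m
  expect_equal(a[1], 0.025)
  expect_equal(z[tg >= 70][1], 0.3)         # zymosan plateau
  expect_equal(a[tg >= 70][1], 0.15)        # antibody plateau
  expect_true(all(diff(z) >= 0))
  expect_error(gen_tension_timeline("zymosan", c(3, 2, 1)), "increasing")
})

test_that("a single-trace cohort summary equals that trace's metrics", {
  co <- gen_cohort("antibody", n = 1, seed = 5)
  tr <- co$traces[[1]]
  sk <- list(time = tr$time, target_position = tr$skeleton,
             engulfed_fraction = tr$engulfed_fraction, contact_time = 0)
  expect_equal(co$summary$mean[co$summary$metric == "push_out_um"],
               push_out_distance(sk))
  expect_equal(co$summary$mean[co$summary$metric == "completion_s"],
               as.numeric(engulfment_time(sk)))
  expect_error(gen_cohort("antibody", n = 0, seed = 1), "n >= 1")
})

test_that("cohort means and SDs approach the population statistics", {
  ## moderate n here keeps the unit test fast; the acceptance suite runs
  ## the full n = 1000 check
  co <- gen_cohort("antibody", n = 300, seed = 11)
  mu <- co$summary$mean[co$summary$metric == "completion_s"]
  se <- 19 / sqrt(300)
  expect_lt(abs(mu - 66), 3 * se)
  sd_hat <- co$summary$sd[co$summary$metric == "completion_s"]
  expect_lt(abs(sd_hat - 19) / 19, 0.15)
})
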