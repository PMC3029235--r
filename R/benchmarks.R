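# Synthetic experiment-like target trajectories with the measured
# population statistics (push-out 1.03 +/- 0.3 um and completion
# 167 +/- 73 s for zymosan; 0.12 +/- 0.14 um and 66 +/- 19 s for
# antibody-coated beads; inward speed ~33 nm/s in both), so that the
# observables and comparison stages are fully testable without any
# experimental data. The trace shape is an emulation, not measured ground
# truth: smooth rise to the push-out peak, plateau, then linear inward
# motion reaching completion at the drawn engulfment time.

.bench_stats <- list(
  zymosan = list(pushout_mean = 1.03, pushout_sd = 0.3,
                 time_mean = 167, time_sd = 73),
  antibody = list(pushout_mean = 0.12, pushout_sd = 0.14,
                  time_mean = 66, time_sd = 19)
)
.bench_inward_speed <- 33 / 1000   # um/s

## run code under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic experiment-like target trace
#'
#' Draws a push-out distance and completion time from the scenario's
#' population statistics (normal, truncated at zero), fixes the inward
#' speed at 33 nm/s, builds a smooth skeleton (cubic-smoothed rise to the
#' peak, plateau, linear inward segment reaching internalization at the
#' drawn completion time), and adds i.i.d. Gaussian positional measurement
#' noise. Reproducible per seed; sampled at 1 Hz.
#'
#' @param scenario `"zymosan"` or `"antibody"`.
#' @param seed integer seed for this trace.
#' @param noise_sd positional measurement noise SD (um), default 0.05
#'   (sub-pixel tracking scale).
#' @param dt sampling interval (s).
#' @return `phago_benchmark_trace`: `time`, `position` (noisy, um; also
#'   aliased as `target_position`), `skeleton` (noise-free position),
#'   `tension` (mN/m), `engulfed_fraction`, `contact_time` (0) and
#'   `true_params` (d*, T*, v*, noise SD).
#' @export
gen_trace <- function(scenario = c("zymosan", "antibody"), seed,
                      noise_sd = 0.05, dt = 1) {
  scenario <- match.arg(scenario)
  st <- .bench_stats[[scenario]]
  .with_seed(seed, {
    d_star <- stats::rnorm(1, st$pushout_mean, st$pushout_sd)
    while (d_star < 0) d_star <- stats::rnorm(1, st$pushout_mean, st$pushout_sd)
    T_star <- stats::rnorm(1, st$time_mean, st$time_sd)
    while (T_star < 20) T_star <- stats::rnorm(1, st$time_mean, st$time_sd)
    v_star <- .bench_inward_speed

    t_end <- T_star + 30
    ## the completion instant is included in the grid so that the
    ## engulfed-fraction threshold crossing is sampled exactly
    time <- sort(unique(c(seq(0, t_end, by = dt), T_star)))
    ## timeline: smooth rise over [0, t1], plateau, linear inward over
    ## [t2, T*]; the inward stretch is kept longer than the default
    ## 10 s speed-smoothing window
    t1 <- min(0.25 * T_star, 30)
    din <- max(25, 0.35 * T_star)
    t2 <- T_star - din
    if (t2 < t1) { t1 <- 0.4 * t2 + 1e-9; }
    s <- pmin(pmax(time / max(t1, 1e-9), 0), 1)
    rise <- d_star * s * s * (3 - 2 * s)          # cubic smoothstep
    pos <- rise
    late <- time > t2
    pos[late] <- d_star - v_star * (time[late] - t2)
    pos[time > T_star] <- d_star - v_star * (T_star - t2)

    thr <- completion_fraction()
    ef <- pmin(thr * time / T_star, 1)

    sc <- make_scenario(scenario)
    tension <- cortical_tension(time, sc) / 1000

    noisy <- pos + stats::rnorm(length(pos), 0, noise_sd)
    structure(list(
      time = time, position = noisy, target_position = noisy,
      skeleton = pos, tension = tension, engulfed_fraction = ef,
      contact_time = 0,
      true_params = list(push_out = d_star, completion_time = T_star,
                         inward_speed = v_star * 1000, noise_sd = noise_sd),
      scenario = scenario, seed = seed
    ), class = "phago_benchmark_trace")
  })
}

## deterministic child seed from a master seed and an index (kept < 2^31)
.child_seed <- function(master, index) {
  (as.numeric(master) %% 65011 * 9973 + 7919 * as.numeric(index) + 13) %% 2147483629
}

#' Generate a cohort of synthetic traces with summary statistics
#'
#' Child seeds derive deterministically from the master seed. Summary
#' metrics are extracted with the observables module from the noise-free
#' skeleton of each trace (so cohort statistics estimate the generating
#' population values free of tracking-noise bias).
#'
#' @param scenario `"zymosan"` or `"antibody"`.
#' @param n cohort size (>= 1).
#' @param seed master seed.
#' @param noise_sd per-trace measurement noise SD (um).
#' @return list `traces` (length n) and `summary`: per-metric mean and SD
#'   of push-out (um), completion time (s) and inward speed (nm/s).
#' @export
gen_cohort <- function(scenario = c("zymosan", "antibody"), n, seed,
                       noise_sd = 0.05) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n) || n < 1) stop("input error: need n >= 1")
  n <- as.integer(n)
  traces <- lapply(seq_len(n), function(i)
    gen_trace(scenario, seed = .child_seed(seed, i), noise_sd = noise_sd))
  met <- vapply(traces, function(tr) {
    sk <- list(time = tr$time, target_position = tr$skeleton,
               engulfed_fraction = tr$engulfed_fraction,
               contact_time = tr$contact_time)
    c(push_out = push_out_distance(sk),
      completion = as.numeric(engulfment_time(sk)),
      speed = max_inward_speed(sk))
  }, c(push_out = 0, completion = 0, speed = 0))
  summ <- data.frame(
    metric = c("push_out_um", "completion_s", "inward_speed_nm_s"),
    mean = apply(met, 1L, mean),
    sd = apply(met, 1L, stats::sd),
    row.names = NULL
  )
  list(traces = traces, summary = summ)
}

#' Prescribed cortical-tension timeline on a time grid
#'
#' The same piecewise-linear tension law used inside the simulation
#' (shared implementation with [cortical_tension()]), evaluated for a
#' scenario preset on an arbitrary increasing time grid.
#'
#' @param scenario `"zymosan"` or `"antibody"` (or a `phago_scenario`).
#' @param t_grid increasing times (s since contact).
#' @return tension series in mN/m.
#' @export
gen_tension_timeline <- function(scenario, t_grid) {
  if (is.unsorted(t_grid)) stop("input error: t_grid must be increasing")
  sc <- if (inherits(scenario, "phago_scenario")) scenario else make_scenario(scenario)
  cortical_tension(t_grid, sc) / 1000
}
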