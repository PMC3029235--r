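# Quantitative readouts of target trajectories: push-out distance,
# engulfment time, maximum inward target speed, and trace comparison.
# Sign convention: outward (away from the cell) positive.

## contact time of a trajectory-like object: first nonzero engulfed fraction
.contact_time_of <- function(traj) {
  if (!is.null(traj$contact_time) && !is.na(traj$contact_time))
    return(traj$contact_time)
  i <- which(traj$engulfed_fraction > 0)
  if (!length(i)) stop("input error: trace shows no contact")
  traj$time[i[1L]]
}

#' Push-out distance of a target trajectory
#'
#' Maximum outward displacement of the target relative to its position at
#' first contact, floored at zero (a monotonically inward trace has
#' push-out 0).
#'
#' @param traj a `phago_trajectory` or any list with `time`,
#'   `target_position` and `engulfed_fraction` (or `contact_time`).
#' @return push-out distance (um).
#' @export
push_out_distance <- function(traj) {
  tc <- .contact_time_of(traj)
  i0 <- which(traj$time >= tc)[1L]
  p0 <- traj$target_position[i0]
  max(max(traj$target_position[traj$time >= tc]) - p0, 0)
}

#' Engulfment time of a target trajectory
#'
#' First time the engulfed fraction reaches the completion threshold, minus
#' the contact time. Returns `NA` with attribute `incomplete = TRUE` if the
#' threshold is never reached.
#'
#' @param traj trajectory (see [push_out_distance()]).
#' @param completion_threshold engulfed-fraction threshold; defaults to the
#'   package's 175-degree criterion, [completion_fraction()].
#' @return engulfment duration (s), or flagged `NA`.
#' @export
engulfment_time <- function(traj, completion_threshold = completion_fraction()) {
  if (is.null(traj$engulfed_fraction)) stop("input error: no engulfed_fraction")
  if (completion_threshold <= 0) return(0)
  tc <- .contact_time_of(traj)
  i <- which(traj$engulfed_fraction >= completion_threshold & traj$time >= tc)
  if (!length(i)) return(structure(NA_real_, incomplete = TRUE))
  traj$time[i[1L]] - tc
}

#' Maximum inward target speed
#'
#' Maximum of the centred moving-average of `-d(position)/dt` restricted to
#' times after the push-out peak, in nm/s. The smoothing window (default
#' 10 s) suppresses tracking noise in experiment-like traces.
#'
#' @param traj trajectory.
#' @param window smoothing window (s); must span at least 2 samples.
#' @return maximum smoothed inward speed (nm/s).
#' @export
max_inward_speed <- function(traj, window = 10) {
  t <- traj$time; x <- traj$target_position
  if (length(t) < 3L || (max(t) - min(t)) < window)
    stop("input error: trace shorter than the smoothing window")
  tc <- .contact_time_of(traj)
  keep <- t >= tc
  t <- t[keep]; x <- x[keep]
  ipk <- which.max(x)[1L]
  ## centred moving average of the velocity on a uniform resample
  dtbar <- stats::median(diff(t))
  tu <- seq(t[1L], t[length(t)], by = dtbar)
  if (length(tu) < 3L) stop("input error: trace too short")
  xu <- stats::approx(t, x, xout = tu)$y
  v <- -diff(xu) / diff(tu)                   # inward positive
  tv <- (tu[-1L] + tu[-length(tu)]) / 2
  k <- max(1L, round(window / dtbar))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    v <- stats::filter(v, kern, sides = 2)
  }
  tpk <- t[ipk]
  sel <- which(tv >= tpk & !is.na(v))
  if (!length(sel)) return(0)
  max(max(v[sel]), 0) * 1000                  # um/s -> nm/s
}

#' Summary metrics of a trajectory
#'
#' @param traj trajectory.
#' @param window smoothing window for [max_inward_speed()].
#' @return list with `push_out_distance` (um), `engulfment_time` (s),
#'   `max_inward_speed` (nm/s), `time_of_peak` (s since contact) and
#'   `incomplete` flag.
#' @export
summarize_trajectory <- function(traj, window = 10) {
  tc <- .contact_time_of(traj)
  keep <- traj$time >= tc
  ipk <- which.max(traj$target_position[keep])[1L]
  et <- engulfment_time(traj)
  list(push_out_distance = push_out_distance(traj),
       engulfment_time = as.numeric(et),
       max_inward_speed = max_inward_speed(traj, window),
       time_of_peak = traj$time[keep][ipk] - tc,
       incomplete = isTRUE(attr(et, "incomplete")))
}

#' Compare a simulated trajectory with a benchmark trace
#'
#' Resamples the benchmark onto the simulation's time grid by linear
#' interpolation and reports the RMS positional deviation over the overlap
#' together with the differences of the three summary metrics.
#'
#' @param sim simulated `phago_trajectory`.
#' @param bench a `phago_benchmark_trace` (or trajectory-like list).
#' @return list `rms` (um) and `delta` (named metric differences,
#'   sim minus bench).
#' @export
compare_trace <- function(sim, bench) {
  lo <- max(min(sim$time), min(bench$time))
  hi <- min(max(sim$time), max(bench$time))
  if (hi <= lo) stop("input error: no time overlap")
  keep <- sim$time >= lo & sim$time <= hi
  bi <- stats::approx(bench$time, bench$target_position, xout = sim$time[keep])$y
  rms <- sqrt(mean((sim$target_position[keep] - bi)^2))
  ms <- summarize_trajectory(sim)
  mb <- summarize_trajectory(bench)
  list(rms = rms,
       delta = c(push_out_distance = ms$push_out_distance - mb$push_out_distance,
                 engulfment_time = ms$engulfment_time - mb$engulfment_time,
                 max_inward_speed = ms$max_inward_speed - mb$max_inward_speed))
}
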