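# Shared fixtures: small meshes, parameter sets, and lazily-cached full
# scenario runs (built once, reused across test files).

fixture_env <- new.env(parent = emptyenv())

## default calibrated parameters used by the scenario tests (the package
## default_params() already carries the calibration; this indirection lets
## the suite state problem sizes in one place)
test_params <- function() default_params()

## cached full scenario run (resolution 1 unless stated)
cached_run <- function(name, resolution = 1, mutate = NULL) {
  key <- paste0(name, "_res", resolution,
                if (!is.null(mutate)) paste0("_", paste(names(mutate), mutate,
                                                        collapse = "_")))
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  sc <- make_scenario(name)
  sc$resolution <- resolution
  if (!is.null(mutate)) for (k in names(mutate)) sc[[k]] <- mutate[[k]]
  sc <- validate_scenario(sc)
  fixture_env[[key]] <- run_simulation(sc, test_params())
  fixture_env[[key]]
}

## an axisymmetric cylinder ("box" in (r, z)) mesh of radius R and length L
## with the same structured topology as the cell mesh; used for diffusion
## oracles on a fixed domain
make_box_mesh <- function(mi = 24L, nj = 10L, R = 2, L = 6) {
  nid <- matrix(seq_len((mi + 1L) * (nj + 1L)), nrow = mi + 1L, ncol = nj + 1L)
  N <- (mi + 1L) * (nj + 1L)
  coords <- matrix(0, N, 2L)
  for (j in 0L:nj) {
    coords[nid[, j + 1L], 1L] <- j / nj * R
    coords[nid[, j + 1L], 2L] <- seq(0, L, length.out = mi + 1L)
  }
  quads <- matrix(0L, mi * nj, 4L)
  e <- 0L
  for (j in 0L:(nj - 1L)) for (i in 0L:(mi - 1L)) {
    e <- e + 1L
    quads[e, ] <- c(nid[i + 1L, j + 1L], nid[i + 1L, j + 2L],
                    nid[i + 2L, j + 2L], nid[i + 2L, j + 1L])
  }
  mer <- rbind(cbind(0L, 0L:nj), cbind(1L:(mi - 1L), nj), cbind(mi, nj:0L))
  bid <- nid[cbind(mer[, 1L] + 1L, mer[, 2L] + 1L)]
  structure(list(m = mi, n = nj, nid = nid, coords = coords, quads = quads,
                 bmer = bid, mer_ij = mer,
                 contact = logical(nrow(mer)),
                 patch_age = rep(NA_real_, nrow(mer)),
                 phi = rep(NA_real_, nrow(mer)),
                 rear_hold_len = 0, cell_radius = R, generation = 0L),
            class = "phago_mesh")
}

## piecewise-linear synthetic trajectory with known metrics
make_known_trace <- function(d = 1, T_complete = 100, v_in = 33 / 1000,
                             dt = 1, t_peak = 20) {
  thr <- completion_fraction()
  t_in <- T_complete - 40
  time <- sort(unique(c(seq(0, T_complete + 20, by = dt), T_complete)))
  pos <- ifelse(time <= t_peak, d * time / t_peak,
                ifelse(time <= t_in, d, d - v_in * (time - t_in)))
  ef <- pmin(thr * time / T_complete, 1)
  list(time = time, target_position = pos, engulfed_fraction = ef,
       contact_time = 0)
}
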