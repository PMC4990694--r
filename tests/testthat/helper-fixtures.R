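# Shared fixtures, memoized so the heavy objects (reduced dictionary,
# pipeline runs) are built once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_schedule <- function() memo("schedule", build_default_schedule())

default_plan <- function() {
  memo("plan", compression_plan(coil_sequence(default_schedule())))
}

# 8 x 8 x 6 x 6 reduced dictionary on the default schedule (~45 s once)
reduced_dictionary <- function() {
  memo("dict", build_dictionary(reduced_parameter_grid(), default_schedule()))
}

# a tiny schedule (short segments, same four-segment structure) for oracle
# tests that sweep many cases
tiny_schedule <- function(n_per_segment = 24L) {
  s <- build_default_schedule()
  keep <- s$excitations$index_in_segment < n_per_segment
  s$excitations <- s$excitations[keep, , drop = FALSE]
  rownames(s$excitations) <- NULL
  s
}

# random (schedule-mutation, tissue, B1) case for EPG-vs-isochromat sweeps
random_epg_case <- function() {
  s <- tiny_schedule(sample(8:30, 1))
  ex <- s$excitations
  n <- nrow(ex)
  ex$relative_drive <- runif(n, 0, 1)
  ex$rf_phase <- runif(n, 0, 2 * pi)
  ex$tr_to_next <- runif(n, 4.8, 8)
  s$excitations <- ex
  s$inter_segment_delays <- runif(3, 50, 500)
  list(schedule = s,
       tissue = tissue_params(runif(1, 150, 4500), runif(1, 15, 450),
                              runif(1, 0.5, 1.5)),
       b1 = complex(real = runif(2, 0, 12), imaginary = runif(2, -3, 3)))
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# slow direct DFT oracle, deliberately independent of the C++ path
slow_ndft <- function(img, traj, timepoint) {
  M <- nrow(img)
  coords <- (seq_len(M) - 1 - M / 2) / M
  xg <- matrix(coords, M, M)
  yg <- t(xg)
  ang <- traj$angles[timepoint, ]
  r <- traj$r0 + traj$dr * (seq_len(traj$samples_per_spoke) - 1)
  out <- matrix(0i, length(r), length(ang))
  for (q in seq_along(ang)) {
    for (si in seq_along(r)) {
      kx <- r[si] * cos(ang[q]); ky <- r[si] * sin(ang[q])
      out[si, q] <- sum(img * exp(-2i * pi * (kx * xg + ky * yg)))
    }
  }
  out
}
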