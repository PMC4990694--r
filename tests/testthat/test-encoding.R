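# Radial trajectory, exact non-uniform Fourier operators, sensitivity
# estimation and receive combination.

test_that("acceleration_factor reproduces the printed (M, N, R) triples", {
  expect_identical(acceleration_factor(160, 9), 28L)
  expect_identical(acceleration_factor(160, 5), 50L)
  expect_identical(acceleration_factor(160, 3), 84L)
  expect_identical(acceleration_factor(336, 12), 44L)
  expect_error(acceleration_factor(160, 0), "positive")
})

test_that("trajectories rotate by 14 x 6/N degrees and stay in band", {
  tr <- build_trajectory(160, 9, 5)
  expect_equal(tr$rotation_deg, 14 * 6 / 9)
  expect_equal(tr$rotation_deg, 9.3333, tolerance = 1e-4)
  # spokes within a time point are pi/N apart
  expect_equal(diff(tr$angles[1, ]), rep(pi / 9, 8))
  # rotation between time points
  expect_equal(tr$angles[2, ] - tr$angles[1, ], rep(14 * 6 / 9 * pi / 180, 9))
  # |k| <= M/2
  r <- tr$r0 + tr$dr * (seq_len(tr$samples_per_spoke) - 1)
  expect_true(all(abs(r) <= 80))
  # successive time points share no spoke direction for the N in use
  for (N in c(3, 5, 9, 12)) {
    rot <- (14 * 6 / N) * pi / 180
    expect_gt(min(rot %% (pi / N), pi / N - rot %% (pi / N)), 1e-6)
  }
  t1 <- build_trajectory(32, 1, 1)
  expect_equal(t1$angles[1, 1], 0)
})

test_that("forward sampling agrees with a direct DFT sum and is linear", {
  set.seed(9)
  M <- 32
  traj <- build_trajectory(M, 4, 3)
  img <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
  y <- forward_sample(img, traj, NULL, 2)
  expect_lt(rel_l2(y[, , 1], slow_ndft(img, traj, 2)), 1e-6)

  # unit impulse at the grid centre -> constant magnitude along every spoke
  delta <- matrix(0i, M, M)
  delta[M / 2 + 1, M / 2 + 1] <- 1
  yd <- forward_sample(delta, traj, NULL, 1)
  expect_equal(Mod(yd[, , 1]), matrix(1, dim(yd)[1], dim(yd)[2]),
               tolerance = 1e-12)

  img2 <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
  lin <- forward_sample((2 - 1i) * img + 0.3i * img2, traj, NULL, 2)
  expect_equal(lin, (2 - 1i) * y + 0.3i * forward_sample(img2, traj, NULL, 2),
               tolerance = 1e-12)

  expect_error(forward_sample(img[1:16, 1:16], traj), "trajectory expects")
})

test_that("forward and adjoint pass the inner-product test", {
  set.seed(10)
  M <- 24
  traj <- build_trajectory(M, 5, 2)
  for (rep in 1:5) {
    x <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
    y <- array(complex(real = rnorm(traj$samples_per_spoke * 5),
                       imaginary = rnorm(traj$samples_per_spoke * 5)),
               c(traj$samples_per_spoke, 5, 1))
    fx <- forward_sample(x, traj, NULL, 2)
    aty <- adjoint_recon(y, traj, 2, "none")[[1]]
    lhs <- sum(fx[, , 1] * Conj(y[, , 1]))
    rhs <- sum(x * Conj(aty))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
  expect_error(adjoint_recon(y, traj, 1, "voronoi"), "arg")
})

test_that("fully sampled ramp-compensated recon is self-consistent", {
  M <- 64
  N <- ceiling(pi * M / 2)
  coords <- (seq_len(M) - 1 - M / 2) / M
  xg <- matrix(coords, M, M); yg <- t(xg)
  traj <- build_trajectory(M, N, 1)

  # a smooth test image round-trips against itself
  gauss <- exp(-(xg^2 + yg^2) / (2 * 0.12^2)) + 0i
  rec <- adjoint_recon(forward_sample(gauss, traj), traj, 1, "ramp")[[1]]
  expect_lt(rel_l2(rec, gauss), 0.05)

  # a binary disk has ~5.5% of its energy outside the |k| <= M/2 circle that
  # radial spokes can observe, so it is compared against its circularly
  # band-limited version
  disk <- (xg^2 + yg^2 <= 0.35^2) + 0i
  kidx <- c(0:(M / 2 - 1), -(M / 2):-1)
  kk <- sqrt(outer(kidx^2, kidx^2, "+"))
  ft <- stats::fft(disk); ft[kk > M / 2] <- 0
  ref <- stats::fft(ft, inverse = TRUE) / (M * M)
  rec2 <- adjoint_recon(forward_sample(disk, traj), traj, 1, "ramp")[[1]]
  expect_lt(rel_l2(rec2, ref), 0.05)

  # zero k-space -> zero image
  z <- array(0i, c(traj$samples_per_spoke, N, 1))
  expect_true(all(adjoint_recon(z, traj, 1, "ramp")[[1]] == 0i))
})

test_that("receive sensitivities are recovered from central k-space", {
  M <- 48
  N <- ceiling(pi * M / 2)
  coords <- (seq_len(M) - 1 - M / 2) / M
  xg <- matrix(coords, M, M); yg <- t(xg)
  obj <- exp(-(xg^2 + yg^2) / (2 * 0.18^2)) + 0i
  support <- Mod(obj) > 0.3
  s1 <- 0.6 + exp(-((xg - 0.2)^2 + yg^2) / 0.18) + 0i
  s2 <- (0.6 + exp(-((xg + 0.2)^2 + yg^2) / 0.18)) * exp(0.5i) + 0i
  nt <- 30
  traj <- build_trajectory(M, N, nt)
  kdata <- array(0i, c(traj$samples_per_spoke, N, 2, nt))
  for (t in 1:nt) kdata[, , , t] <- forward_sample(obj, traj, list(s1, s2), t)
  plan <- compression_plan(rep_len(c(0L, 1L), 60))[1]  # first 15-index bin
  class(plan) <- "pnp_bin_map"
  rx <- estimate_rx_sensitivities(kdata, traj, plan)

  # unit root-sum-of-squares by construction
  rss <- sqrt(Mod(rx$maps[[1]])^2 + Mod(rx$maps[[2]])^2)
  expect_equal(rss[support], rep(1, sum(support)), tolerance = 1e-9)
  # relative magnitudes within 10% of truth inside the support
  true_rel <- Mod(s1) / sqrt(Mod(s1)^2 + Mod(s2)^2)
  expect_lt(max(abs(Mod(rx$maps[[1]])[support] - true_rel[support])), 0.1)

  # single uniform channel: sensitivity ~ 1 inside the support
  k1 <- array(0i, c(traj$samples_per_spoke, N, 1, nt))
  for (t in 1:nt) k1[, , 1, t] <- forward_sample(obj, traj, NULL, t)[, , 1]
  rx1 <- estimate_rx_sensitivities(k1, traj, plan)
  expect_lt(max(abs(Mod(rx1$maps[[1]])[support] - 1)), 0.05)

  expect_error(estimate_rx_sensitivities(array(0i, dim(kdata)), traj, plan),
               "all-zero")
})

test_that("matched-filter combination is exact on consistent inputs and raises SNR", {
  M <- 16
  set.seed(21)
  common <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
  s1 <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
  s2 <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)

  expect_equal(combine_rx(list(common), list(matrix(1 + 0i, M, M))), common,
               ignore_attr = TRUE)
  got <- combine_rx(list(s1 * common, s2 * common), list(s1, s2))
  expect_equal(got, common, ignore_attr = TRUE, tolerance = 1e-12)

  # Monte-Carlo SNR: combined noise variance never exceeds a single channel's
  sig <- matrix(1 + 0i, M, M)
  s1 <- matrix(1.2 + 0i, M, M); s2 <- matrix(0.8 + 0.3i, M, M)
  err_comb <- err_ch1 <- numeric(100)
  for (i in 1:100) {
    n1 <- matrix(complex(real = rnorm(M * M, sd = 0.1),
                         imaginary = rnorm(M * M, sd = 0.1)), M, M)
    n2 <- matrix(complex(real = rnorm(M * M, sd = 0.1),
                         imaginary = rnorm(M * M, sd = 0.1)), M, M)
    comb <- combine_rx(list(s1 * sig + n1, s2 * sig + n2), list(s1, s2))
    err_comb[i] <- mean(Mod(comb - sig)^2)
    err_ch1[i] <- mean(Mod((s1 * sig + n1) / s1 - sig)^2)
  }
  expect_lt(mean(err_comb), mean(err_ch1))
  expect_error(combine_rx(list(common), list(s1, s2)), "channel images")
})

test_that("successive time points have decorrelated point spread functions", {
  # the 14 x 6/N rotation moves the streak pattern between exposures
  M <- 32
  traj <- build_trajectory(M, 3, 2)
  ones <- array(1 + 0i, c(traj$samples_per_spoke, 3, 1))
  p1 <- adjoint_recon(ones, traj, 1, "ramp")[[1]]
  p2 <- adjoint_recon(ones, traj, 2, "ramp")[[1]]
  xcor <- Mod(sum(p1 * Conj(p2))) /
    sqrt(sum(Mod(p1)^2) * sum(Mod(p2)^2))
  expect_lt(xcor, 0.99)   # strictly below the autocorrelation (= 1)
})
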