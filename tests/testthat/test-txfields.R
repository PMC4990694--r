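# Synthetic transmit fields, coil modes, calibration and MLS shimming.

test_that("mode weights are discrete Fourier vectors", {
  w1 <- mode_weights(16, 1)
  steps <- Arg(w1[-1] * Conj(w1[-16]))   # phase advance, wrap-safe
  expect_equal(steps, rep(2 * pi / 16, 15), tolerance = 1e-12)
  expect_equal(Arg(w1[2] / w1[1]) * 180 / pi, 22.5, tolerance = 1e-12)

  w <- mode_weights(2, 1)
  expect_equal(w[1] / w[2], -1 + 0i, tolerance = 1e-12)

  for (K in c(2, 5, 16)) {
    G <- vapply(seq_len(K), function(n) mode_weights(K, n), complex(K))
    gram <- Conj(t(G)) %*% G
    expect_equal(gram, diag(K) + 0i, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(mode_weights(8, 9), "mode index")
})

test_that("combine_field is the linear superposition of element maps", {
  S <- synthetic_element_fields(24, K = 4)
  b <- c(0, 1, 0, 0)
  expect_identical(combine_field(S, b), S$fields[[2]])
  b1 <- mode_weights(4, 1); b2 <- mode_weights(4, 2)
  expect_equal(combine_field(S, b1 + b2),
               combine_field(S, b1) + combine_field(S, b2), tolerance = 1e-12)
  expect_equal(combine_field(S, (2 - 1i) * b1), (2 - 1i) * combine_field(S, b1),
               tolerance = 1e-12)
  expect_error(combine_field(S, c(1, 2)), "elements")
})

test_that("approximate-CP calibration phase-aligns the centre", {
  M <- 32
  S <- synthetic_element_fields(M, K = 8)
  centre <- matrix(FALSE, M, M)
  centre[(M / 2 - 1):(M / 2 + 2), (M / 2 - 1):(M / 2 + 2)] <- TRUE
  cal <- approx_cp_calibration(S, centre)

  contrib <- vapply(seq_len(S$K),
                    function(k) mean(S$fields[[k]][centre]) * cal$cp[k],
                    complex(1))
  spread <- diff(range(Arg(contrib)))
  expect_lt(spread, 1e-9)
  # coherent sum: centre magnitude equals the sum of element magnitudes
  expect_equal(Mod(sum(contrib)), sum(Mod(contrib)), tolerance = 1e-9)
  # against the ideal-phase oracle: aligning exact phases at the centroid
  ideal <- vapply(seq_len(S$K),
                  function(k) Mod(mean(S$fields[[k]][centre])), numeric(1))
  expect_gte(Mod(sum(contrib)), 0.99 * sum(ideal))
  # gradient mode differs by the azimuthal increment
  expect_equal(cal$gradient / cal$cp, exp(1i * 2 * pi / 8 * 1:8),
               tolerance = 1e-12)

  S0 <- S
  S0$fields[[3]][] <- 0i
  expect_error(approx_cp_calibration(S0, centre), "element 3")
})

test_that("MLS shim converges, is monotone and recovers planted solutions", {
  M <- 24
  S <- synthetic_element_fields(M, K = 6)
  mask <- matrix(FALSE, M, M)
  mask[6:18, 6:18] <- TRUE

  # K = 1 closed form: optimal |b| = <|s|, m> / <|s|, |s|>
  S1 <- S; S1$fields <- S$fields[1]; S1$K <- 1L
  m <- matrix(1, M, M)
  fit <- mls_shim(S1, m, mask, n_iter = 30)
  smag <- Mod(S$fields[[1]][mask])
  expect_equal(Mod(fit$b), sum(smag * 1) / sum(smag^2), tolerance = 1e-9)

  # planted solution: an achievable target is met to numerical precision
  b_star <- complex(real = c(1, -0.5, 0.2, 0.8, -0.1, 0.4),
                    imaginary = c(0.3, 0.1, -0.7, 0, 0.2, -0.3))
  m_star <- Mod(combine_field(S, b_star))
  m_star[m_star < 1e-6] <- 1e-6
  fit2 <- mls_shim(S, m_star, mask, n_iter = 60)
  expect_lt(tail(fit2$objective, 1), 1e-10)

  # monotone objective across random problems
  set.seed(33)
  for (rep in 1:10) {
    Sr <- synthetic_element_fields(16, K = 4, amp_jitter = 0.3, seed = rep)
    mr <- matrix(runif(256, 0.5, 1.5), 16, 16)
    maskr <- matrix(runif(256) > 0.3, 16, 16)
    fr <- mls_shim(Sr, mr, maskr, n_iter = 50, init = "random", seed = rep)
    expect_true(all(diff(fr$objective) <= 1e-10))
  }

  # shimmed CV never worse than the CP mode on the presets
  tgt <- matrix(1, M, M)
  for (K in c(6, 8)) {
    Sp <- synthetic_element_fields(M, K = K)
    cp_cv <- field_cv(combine_field(Sp, mode_weights(K, 1)), mask)
    sh <- mls_shim(Sp, tgt, mask, n_iter = 50)
    expect_lte(field_cv(sh$field, mask), cp_cv + 1e-12)
  }
})

test_that("field_cv matches an independent two-pass oracle", {
  m2 <- matrix(c(1, 3), 1, 2)
  expect_equal(field_cv(m2, matrix(TRUE, 1, 2)), 0.5)
  expect_equal(field_cv(matrix(2, 4, 4), matrix(TRUE, 4, 4)), 0)

  set.seed(8)
  f <- matrix(complex(real = rnorm(100), imaginary = rnorm(100)), 10, 10)
  mask <- matrix(runif(100) > 0.4, 10, 10)
  v <- Mod(f[mask])
  mu <- sum(v) / length(v)
  oracle <- sqrt(sum((v - mu)^2) / length(v)) / mu
  expect_equal(field_cv(f, mask), oracle, tolerance = 1e-12)
  expect_error(field_cv(matrix(0, 2, 2), matrix(TRUE, 2, 2)), "undefined")
})

test_that("synthetic element fields have the stated geometry and limits", {
  M <- 48
  # long-wavelength limit: CP combination nearly uniform near the centre
  Slong <- synthetic_element_fields(M, K = 8, wavelength = 1e3)
  cp <- combine_field(Slong, mode_weights(8, 1))
  centre <- matrix(FALSE, M, M)
  q <- M / 4
  centre[(M / 2 - q / 2):(M / 2 + q / 2), (M / 2 - q / 2):(M / 2 + q / 2)] <- TRUE
  expect_lt(field_cv(cp, centre), 0.05)

  # element field is largest at the ring sample nearest its own position
  S <- synthetic_element_fields(M, K = 8)
  coords <- (seq_len(M) - 1 - M / 2) / M * S$fov
  xg <- matrix(coords, M, M); yg <- t(xg)
  ring_r <- sqrt(S$positions[1, 1]^2 + S$positions[1, 2]^2)
  ring <- abs(sqrt(xg^2 + yg^2) - min(ring_r, 0.45 * S$fov)) < S$fov / M
  for (k in c(1, 4)) {
    fmag <- Mod(S$fields[[k]])
    at_max <- which(ring & fmag == max(fmag[ring]), arr.ind = TRUE)[1, ]
    d_own <- sqrt((xg[at_max[1], at_max[2]] - S$positions[k, 1])^2 +
                    (yg[at_max[1], at_max[2]] - S$positions[k, 2])^2)
    d_other <- vapply(setdiff(1:8, k), function(j) {
      sqrt((xg[at_max[1], at_max[2]] - S$positions[j, 1])^2 +
             (yg[at_max[1], at_max[2]] - S$positions[j, 2])^2)
    }, numeric(1))
    expect_lt(d_own, min(d_other))
  }
  expect_error(synthetic_element_fields(M, K = 1), "K must be")
})

test_that("preset illumination pairs have complementary coverage", {
  M <- 64
  coords <- (seq_len(M) - 1 - M / 2) / M
  xg <- matrix(coords, M, M); yg <- t(xg)
  subject <- sqrt(xg^2 + yg^2) <= 0.45   # the illuminated object region
  for (preset in c("ring_modes", "linear_pair")) {
    fl <- tx_field_preset(M, preset)
    m1 <- Mod(fl[[1]])[subject]; m2 <- Mod(fl[[2]])[subject]
    peak <- max(m1, m2)
    # non-overlapping voids: everywhere at least one illumination is strong
    expect_gt(min(pmax(m1, m2)) / peak, 0.15)
    # but each illumination alone does have a weak region
    expect_lt(min(m1) / peak, 0.1)
    expect_lt(min(m2) / peak, 0.1)
  }
  # ring preset: CP mode centre-bright, gradient mode centre-null
  fl <- tx_field_preset(M, "ring_modes")
  c0 <- M / 2
  expect_gt(Mod(fl[[1]][c0, c0]), Mod(fl[[2]][c0, c0]) * 3)
})
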