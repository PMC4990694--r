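# EPG state operations and fingerprint simulation, cross-checked against the
# brute-force isochromat ensemble oracle.

test_that("RF rotation closed forms hold exactly", {
  eq <- epg_state(m0 = 1, k_max = 8)

  inv <- apply_rf(eq, pi, 0)
  expect_equal(inv$z[1], -1 + 0i)
  expect_true(all(Mod(inv$f_plus) < 1e-15) && all(Mod(inv$f_minus) < 1e-15))

  ident <- apply_rf(eq, 0, 1.3)
  expect_identical(ident$z, eq$z)
  expect_identical(ident$f_plus, eq$f_plus)

  ninety <- apply_rf(eq, pi / 2, 0)
  expect_equal(Mod(ninety$f_plus[1]), 1)
  expect_lt(Mod(ninety$z[1]), 1e-15)

  expect_error(apply_rf(eq, NaN, 0), "finite")
})

test_that("RF rotation of a mixed state matches the isochromat oracle", {
  # state with f+0 = 0.3 + 0.1i, z0 = 0.5; ensemble: every spin holds the
  # same transverse value (order 0 only), f-0 = conj(f+0) implicitly
  st <- epg_state(m0 = 1, k_max = 4)
  st$f_plus[1] <- 0.3 + 0.1i
  st$f_minus[1] <- Conj(st$f_plus[1])
  st$z[1] <- 0.5 + 0i
  flip <- 37 * pi / 180; phase <- 55 * pi / 180
  out <- apply_rf(st, flip, phase)

  n <- 64
  mxy <- rep(0.3 + 0.1i, n)
  mz <- rep(0.5, n)
  ca <- cos(flip); sa <- sin(flip); eip <- exp(1i * phase)
  mxy_new <- (1 + ca) / 2 * mxy + eip^2 * (1 - ca) / 2 * Conj(mxy) -
    1i * eip * sa * mz
  mz_new <- sa * Im(mxy * Conj(eip)) + ca * mz
  expect_equal(out$f_plus[1], mean(mxy_new), tolerance = 1e-10)
  expect_equal(out$z[1], mean(mz_new) + 0i, tolerance = 1e-10)
})

test_that("RF rotation conserves ensemble population", {
  set.seed(11)
  for (rep in 1:20) {
    st <- epg_state(m0 = 1, k_max = 6)
    # random physical state built by a few random pulses and spoiler shifts
    tis <- tissue_params(800, 80)
    for (i in 1:4) {
      st <- apply_rf(st, runif(1, 0, pi), runif(1, 0, 2 * pi))
      st <- evolve(st, 0, tis, spoiler_shifts = 1L)
    }
    pop <- function(s) sum(Mod(s$f_plus)^2 + Mod(s$f_minus)^2 + 2 * Mod(s$z)^2)
    before <- pop(st)
    after <- pop(apply_rf(st, runif(1, 0, pi), runif(1, 0, 2 * pi)))
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("evolve implements relaxation, regrowth and spoiler shifts", {
  tis <- tissue_params(600, 60)
  st <- apply_rf(epg_state(1, 8), pi / 3, 0.4)

  expect_identical(evolve(st, 0, tis, 0L)$f_plus, st$f_plus)

  relaxed <- evolve(st, 100 * tis$t1, tis, 0L)
  expect_lt(max(Mod(relaxed$f_plus)), 1e-12)
  expect_equal(relaxed$z[1], 1 + 0i, tolerance = 1e-12)

  # closed-form transverse decay: |f+0| = exp(-1) after tau = T2
  st2 <- epg_state(1, 4)
  st2$f_plus[1] <- 1 + 0i
  st2$f_minus[1] <- 1 + 0i
  dec <- evolve(st2, 60, tissue_params(600, 60, m0 = 0), 0L)
  expect_equal(Mod(dec$f_plus[1]), exp(-1), tolerance = 1e-12)

  # spoiler shift moves f+ up and wraps f- through order 0
  sh <- evolve(st2, 0, tis, 1L)
  expect_equal(sh$f_plus[2], 1 + 0i)
  expect_equal(sh$f_plus[1], Conj(st2$f_minus[2]))

  expect_error(evolve(st, -1, tis), "tau")
})

test_that("fingerprints vanish at zero field and scale linearly in m0", {
  s <- tiny_schedule()
  tis <- tissue_params(600, 60)
  expect_true(all(simulate_fingerprint(s, tis, c(0 + 0i, 0 + 0i)) == 0))

  f1 <- simulate_fingerprint(s, tis, c(6 + 0i, 5 + 2i))
  f2 <- simulate_fingerprint(s, tissue_params(600, 60, m0 = 2), c(6 + 0i, 5 + 2i))
  expect_identical(f2, 2 * f1)

  expect_error(simulate_fingerprint(s, tis, c(6 + 0i)), "channels")
})

test_that("simulate_fingerprint equals composing apply_rf/evolve by hand", {
  # independent R-level route through the exported state operations
  s <- tiny_schedule(6L)
  tis <- tissue_params(420, 95, m0 = 1.3)
  b1 <- c(7 - 1i, 4 + 3i)
  ex <- s$excitations
  L <- nrow(ex)
  delays <- rep(0, L)
  seg_last <- cumsum(rle(ex$segment_id)$lengths)
  delays[seg_last[-length(seg_last)]] <- s$inter_segment_delays
  st <- epg_state(tis$m0, k_max = L + 5L)
  manual <- complex(L)
  for (j in seq_len(L)) {
    coil <- ex$coil_id[j] + 1L
    a <- ex$relative_drive[j] * (s$reference_flip / s$reference_b1) * Mod(b1[coil])
    st <- apply_rf(st, a, ex$rf_phase[j] + Arg(b1[coil]))
    manual[j] <- st$f_plus[1] * exp(-s$te / tis$t2) * exp(-1i * ex$rf_phase[j])
    st <- evolve(st, ex$tr_to_next[j], tis, 1L)
    if (delays[j] > 0) st <- evolve(st, delays[j], tis, 1L)
  }
  expect_equal(simulate_fingerprint(s, tis, b1), manual, tolerance = 1e-12)
})

test_that("EPG fingerprints match the isochromat Bloch oracle", {
  set.seed(202)
  for (rep in 1:10) {
    cs <- random_epg_case()
    f_epg <- simulate_fingerprint(cs$schedule, cs$tissue, cs$b1)
    f_iso <- isochromat_fingerprint(cs$schedule, cs$tissue, cs$b1,
                                    n_spins = 256L)
    expect_lt(rel_l2(f_epg, f_iso), 1e-6)
  }
})

test_that("slice profiles behave as advertised", {
  expect_error(slice_profile_from_pulse(2, 3, "gauss"), "arg")

  flat <- slice_profile_from_pulse(2, 3, "rect", 9L)
  expect_identical(flat$relative_flip_scales, rep(1, 9L))

  p1 <- slice_profile_from_pulse(2, 3, "sinc", 1L)
  expect_identical(p1$relative_flip_scales, 1)
  s <- tiny_schedule(6L)
  tis <- tissue_params(600, 60)
  expect_equal(simulate_fingerprint(s, tis, c(6 + 0i, 6 + 0i), profile = p1),
               simulate_fingerprint(s, tis, c(6 + 0i, 6 + 0i)))

  p <- slice_profile_from_pulse(2, 3, "sinc", 33L)
  sc <- p$relative_flip_scales
  expect_equal(sc, rev(sc), tolerance = 1e-12)        # symmetric
  expect_equal(sc[17], 1)                             # centre normalized
  # a truncated sinc has passband ripple, so the centre is near-maximal
  # rather than the strict maximum; the profile decays toward the edges
  expect_lte(max(sc), 1.1)
  expect_lt(sc[1], 0.3)
  expect_equal(sum(p$weights), 1)

  # profile-weighted fingerprint equals the weighted sum of scaled trains
  f_prof <- simulate_fingerprint(s, tis, c(6 + 0i, 6 + 0i), profile = p)
  parts <- vapply(seq_along(sc), function(i) {
    s2 <- s
    s2$excitations$relative_drive <- s$excitations$relative_drive * sc[i]
    simulate_fingerprint(s2, tis, c(6 + 0i, 6 + 0i)) * p$weights[i]
  }, complex(nrow(s$excitations)))
  expect_equal(f_prof, rowSums(parts), tolerance = 1e-12)
})
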