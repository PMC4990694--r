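# Extended-phase-graph (EPG) simulation of a single voxel's signal evolution.
#
# The magnetization is decomposed into Fourier dephasing orders: transverse
# configurations F+_k and F-_k (with F-_k the conjugate of F+ at order -k) and
# longitudinal configurations Z_k. RF pulses mix the three states order by
# order, relaxation decays them, and gradient spoilers shift the transverse
# ladder by one order. The echo-time signal is F+_0 after transverse decay
# over TE, demodulated by the transmit RF phase.
#
# Phase convention: a 90 degree pulse with phase 0 applied to equilibrium
# m0 = 1 produces F+_0 = -1i (rotating-frame convention). Tests against the
# brute-force isochromat oracle pin the convention down numerically.

#' Create an EPG configuration state at thermal equilibrium
#'
#' @param m0 Equilibrium magnetization (non-negative, arbitrary units).
#' @param k_max Highest dephasing order retained (>= 1).
#' @return An object of class `epg_state`: complex vectors `f_plus`,
#'   `f_minus`, `z` over orders `0..k_max`, plus `m0`, `k_max` and a
#'   `truncated` flag set when population is pushed past order `k_max`.
#' @examples
#' s <- epg_state(m0 = 1, k_max = 8)
#' s$z[1]  # order 0 holds m0
#' @export
epg_state <- function(m0 = 1, k_max = 32) {
  if (!is.finite(m0) || m0 < 0) .stop_arg("m0 must be a finite non-negative number")
  if (k_max < 1) .stop_arg("k_max must be >= 1")
  structure(list(
    f_plus = complex(k_max + 1L), f_minus = complex(k_max + 1L),
    z = c(complex(real = m0), complex(k_max)),
    m0 = m0, k_max = as.integer(k_max), truncated = FALSE
  ), class = "epg_state")
}

#' Apply an RF rotation to an EPG state
#'
#' Mixes `(F+_k, F-_k, Z_k)` at every order with the standard EPG rotation
#' matrix for a pulse of the given flip angle and phase. The input state is
#' not modified.
#'
#' @param state An [epg_state()].
#' @param flip Flip angle in radians.
#' @param phase RF phase in radians.
#' @return The rotated `epg_state`.
#' @examples
#' s <- apply_rf(epg_state(1, 4), pi, 0)   # perfect inversion
#' Re(s$z[1])                              # -1
#' @export
apply_rf <- function(state, flip, phase) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(flip) || !is.finite(phase)) {
    .stop_arg("flip and phase must be finite")
  }
  ca <- cos(flip); sa <- sin(flip)
  c2 <- (1 + ca) / 2; s2 <- (1 - ca) / 2
  eip <- exp(1i * phase); ei2p <- eip^2
  fp <- state$f_plus; fm <- state$f_minus; z <- state$z
  state$f_plus <- c2 * fp + ei2p * s2 * fm + (-1i * eip * sa) * z
  state$f_minus <- Conj(ei2p) * s2 * fp + c2 * fm + (1i * Conj(eip) * sa) * z
  state$z <- (-0.5i * Conj(eip) * sa) * fp + (0.5i * eip * sa) * fm + ca * z
  state
}

#' Relax, regrow and spoil an EPG state
#'
#' Transverse orders decay by `exp(-tau/T2)`, longitudinal orders by
#' `exp(-tau/T1)` with `Z_0` regrowing toward `m0`; afterwards the transverse
#' ladder is shifted up by `spoiler_shifts` orders (with the standard
#' `F- -> F+` wrap through order 0).
#'
#' @param state An [epg_state()].
#' @param tau Evolution time in ms (>= 0).
#' @param tissue A [tissue_params()] with fields `t1`, `t2`, `m0`.
#' @param spoiler_shifts Number of unit gradient-spoiler shifts (integer >= 0).
#' @return The evolved `epg_state`; `truncated` is set if non-negligible
#'   population is pushed past order `k_max`.
#' @export
evolve <- function(state, tau, tissue, spoiler_shifts = 0L) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(tau) || tau < 0) .stop_arg("tau must be >= 0")
  spoiler_shifts <- as.integer(spoiler_shifts)
  if (spoiler_shifts < 0) .stop_arg("spoiler_shifts must be >= 0")
  e1 <- exp(-tau / tissue$t1); e2 <- exp(-tau / tissue$t2)
  state$f_plus <- state$f_plus * e2
  state$f_minus <- state$f_minus * e2
  state$z <- state$z * e1
  state$z[1] <- state$z[1] + (1 - e1) * tissue$m0
  K <- state$k_max + 1L
  for (i in seq_len(spoiler_shifts)) {
    if (Mod(state$f_plus[K]) > 1e-14 || Mod(state$z[K]) > 1e-14) {
      state$truncated <- TRUE
    }
    state$f_plus <- c(Conj(state$f_minus[2]), state$f_plus[-K])
    state$f_minus <- c(state$f_minus[-1], 0)
  }
  state
}

#' Tissue relaxation parameters
#'
#' @param t1,t2 Longitudinal and transverse relaxation times in ms (> 0).
#' @param m0 Relative proton density (equilibrium magnetization, >= 0).
#' @return A `tissue_params` list. `t2 <= t1` is not enforced: the dictionary
#'   keeps the full Cartesian parameter product.
#' @export
tissue_params <- function(t1, t2, m0 = 1) {
  if (!is.finite(t1) || t1 <= 0 || !is.finite(t2) || t2 <= 0) {
    .stop_arg("t1 and t2 must be positive")
  }
  if (m0 < 0) .stop_arg("m0 must be non-negative")
  structure(list(t1 = t1, t2 = t2, m0 = m0), class = "tissue_params")
}

#' Slice profile from the Fourier transform of the RF waveform
#'
#' The across-slice flip-angle modulation is taken as the magnitude of the
#' discrete Fourier transform of the pulse waveform, sampled at `n_subslices`
#' positions spanning +/- one slice thickness around the slice centre and
#' normalized so the centre has scale 1. Sub-slice weights are uniform.
#'
#' @param duration Pulse duration in ms.
#' @param time_bandwidth Time-bandwidth product of the pulse.
#' @param shape `"sinc"` or `"rect"`.
#' @param n_subslices Number of sub-slice isochromat families (>= 1).
#' @return A `slice_profile`: `relative_flip_scales` and `weights` (summing
#'   to 1) of equal length.
#' @examples
#' p <- slice_profile_from_pulse(2, 3, "sinc", 33)
#' which.max(p$relative_flip_scales)  # centre
#' @export
slice_profile_from_pulse <- function(duration, time_bandwidth, shape = c("sinc", "rect"),
                                     n_subslices = 33L) {
  shape <- match.arg(shape)
  n_subslices <- as.integer(n_subslices)
  if (n_subslices < 1) .stop_arg("n_subslices must be >= 1")
  if (n_subslices == 1L) {
    return(structure(list(relative_flip_scales = 1, weights = 1),
                     class = "slice_profile"))
  }
  if (shape == "rect") {
    # hard-pulse small-tip limit: no slice selectivity, flat profile
    return(structure(list(relative_flip_scales = rep(1, n_subslices),
                          weights = rep(1 / n_subslices, n_subslices)),
                     class = "slice_profile"))
  }
  # Waveform sampled finely in time; the slice direction is the Fourier
  # conjugate of time under the slice-select gradient. The nominal slice
  # covers frequencies |f| <= BW/2 = TBW/(2*duration); sub-slices span twice
  # that (+/- one slice thickness).
  nt <- 512L
  tt <- seq(-duration / 2, duration / 2, length.out = nt)
  w <- switch(shape,
    sinc = {
      x <- time_bandwidth * tt / duration
      ifelse(x == 0, 1, sin(pi * x) / (pi * x))
    },
    rect = rep(1, nt)
  )
  bw <- time_bandwidth / duration                   # kHz, full nominal bandwidth
  f <- seq(-bw, bw, length.out = n_subslices)        # span +/- one slice thickness
  ft <- vapply(f, function(fi) Mod(sum(w * exp(-2i * pi * fi * tt))), numeric(1))
  centre <- Mod(sum(w))
  structure(list(relative_flip_scales = ft / centre,
                 weights = rep(1 / n_subslices, n_subslices)),
            class = "slice_profile")
}

# Build per-excitation achieved flip (rad) and RF phase (rad) matrices for a
# batch of entries from schedule drives and complex per-channel B1.
# b1 is an n x n_channels complex matrix in microtesla per unit drive.
.epg_flip_phase <- function(schedule, b1) {
  ex <- schedule$excitations
  coil <- ex$coil_id + 1L
  amp <- Mod(b1); ph <- Arg(b1)
  scale <- schedule$reference_flip / schedule$reference_b1
  flip <- (ex$relative_drive * scale) * t(amp[, coil, drop = FALSE])
  phase <- ex$rf_phase + t(ph[, coil, drop = FALSE])
  list(flip = flip, phase = phase)
}

# Batched fingerprint simulation shared by simulate_fingerprint() and
# build_dictionary(). t1, t2, m0: length n; b1: n x n_channels complex matrix.
# Returns an L x n complex matrix (L = number of excitations).
.epg_fingerprints <- function(schedule, t1, t2, m0, b1, profile = NULL,
                              k_max = NULL) {
  ex <- schedule$excitations
  L <- nrow(ex)
  delays <- rep(0, L)
  seg_last <- cumsum(rle(ex$segment_id)$lengths)
  nseg <- length(seg_last)
  if (nseg > 1) delays[seg_last[-nseg]] <- schedule$inter_segment_delays
  # one spoiler shift per TR plus one per inter-segment delay: k_max must
  # cover every shift event or T2 > T1 entries trip the truncation guard
  if (is.null(k_max)) k_max <- L + sum(delays > 0) + 1L
  fp <- .epg_flip_phase(schedule, b1)
  scales <- 1; weights <- 1
  if (!is.null(profile)) {
    scales <- profile$relative_flip_scales
    weights <- profile$weights
  }
  out <- NULL
  for (i in seq_along(scales)) {
    res <- cpp_epg_fingerprints(fp$flip * scales[i], fp$phase, ex$rf_phase,
                                t1, t2, m0, schedule$te, ex$tr_to_next,
                                delays, as.integer(k_max))
    if (res$truncated) {
      warning("EPG population reached maximum order k_max; result truncated",
              call. = FALSE)
    }
    sig <- res$signal * weights[i]
    out <- if (is.null(out)) sig else out + sig
  }
  out
}

#' Simulate a voxel fingerprint under a sequence schedule
#'
#' Runs the EPG recursion over the full excitation train. The achieved flip
#' of excitation `j` is `relative_drive[j] * |b1[coil_j]| / reference_b1 *
#' reference_flip` (times the sub-slice scale when a slice profile is given);
#' its RF phase is the schedule phase plus `arg(b1[coil_j])`. The returned
#' signal is `F+_0` after TE decay, demodulated by the schedule RF phase, so
#' it is linear in `m0`.
#'
#' @param schedule A [build_default_schedule()] sequence schedule.
#' @param tissue A [tissue_params()].
#' @param b1 Complex vector, one entry per transmit channel (microtesla per
#'   unit drive; real values mean zero transmit phase).
#' @param profile Optional [slice_profile_from_pulse()] result; the fingerprint
#'   is then the weighted sum over sub-slice isochromat families.
#' @param k_max Highest retained EPG order (default: number of excitations + 1,
#'   i.e. no truncation).
#' @return Complex vector with one demodulated echo sample per excitation.
#' @export
simulate_fingerprint <- function(schedule, tissue, b1, profile = NULL,
                                 k_max = NULL) {
  stopifnot(inherits(schedule, "pnp_schedule"))
  if (length(b1) != schedule$n_channels) {
    .stop_arg("b1 has %d channels but the schedule expects %d",
              length(b1), schedule$n_channels)
  }
  b1 <- matrix(as.complex(b1), nrow = 1)
  drop(.epg_fingerprints(schedule, tissue$t1, tissue$t2, tissue$m0, b1,
                         profile = profile, k_max = k_max))
}
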