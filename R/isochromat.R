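# Brute-force isochromat (Bloch ensemble) oracle. A family of spins with
# deterministic, uniformly spaced intra-voxel dephasing angles is rotated in
# 3-D through the full pulse train; the voxel signal is the ensemble mean of
# the transverse magnetization. With n_spins uniform on a grid, the discrete
# ensemble average reproduces the EPG configuration F+_0 exactly for every
# dephasing order below n_spins, so agreement with the EPG path is limited
# only by floating-point rounding.

#' Isochromat Bloch-ensemble fingerprint (independent oracle)
#'
#' Simulates the same acquisition as [simulate_fingerprint()] by explicit 3-D
#' rotation of a deterministic ensemble of uniformly dephased spins. Intended
#' as a brute-force cross-check of the EPG recursion; it shares no state code
#' with it.
#'
#' @inheritParams simulate_fingerprint
#' @param n_spins Number of uniformly dephased isochromats per spoiler period
#'   (must exceed the highest dephasing order reached; >= 2048 recommended
#'   for full 480-excitation trains).
#' @return Complex vector of demodulated echo samples, one per excitation.
#' @export
isochromat_fingerprint <- function(schedule, tissue, b1, profile = NULL,
                                   n_spins = 2048L) {
  stopifnot(inherits(schedule, "pnp_schedule"))
  if (length(b1) != schedule$n_channels) {
    .stop_arg("b1 has %d channels but the schedule expects %d",
              length(b1), schedule$n_channels)
  }
  ex <- schedule$excitations
  L <- nrow(ex)
  theta <- 2 * pi * (seq_len(n_spins) - 1L) / n_spins
  deph <- exp(1i * theta)
  delays <- rep(0, L)
  seg_last <- cumsum(rle(ex$segment_id)$lengths)
  if (length(seg_last) > 1) {
    delays[seg_last[-length(seg_last)]] <- schedule$inter_segment_delays
  }
  amp <- Mod(b1); bph <- Arg(b1)
  scale <- schedule$reference_flip / schedule$reference_b1
  scales <- 1; weights <- 1
  if (!is.null(profile)) {
    scales <- profile$relative_flip_scales
    weights <- profile$weights
  }
  sig <- complex(L)
  for (ss in seq_along(scales)) {
    mxy <- complex(n_spins)
    mz <- rep(tissue$m0, n_spins)
    for (j in seq_len(L)) {
      coil <- ex$coil_id[j] + 1L
      a <- ex$relative_drive[j] * scale * amp[coil] * scales[ss]
      p <- ex$rf_phase[j] + bph[coil]
      # 3-D rotation about the transverse axis at azimuth p
      ca <- cos(a); sa <- sin(a)
      eip <- exp(1i * p)
      mxy_new <- (1 + ca) / 2 * mxy + eip^2 * (1 - ca) / 2 * Conj(mxy) -
        1i * eip * sa * mz
      mz <- sa * Im(mxy * Conj(eip)) + ca * mz
      mxy <- mxy_new
      # echo at TE (transverse decay only affects the recorded sample)
      e2te <- exp(-schedule$te / tissue$t2)
      sig[j] <- sig[j] + weights[ss] * mean(mxy) * e2te *
        exp(-1i * ex$rf_phase[j])
      # full-TR relaxation, spoiler dephasing, optional recovery delay
      e1 <- exp(-ex$tr_to_next[j] / tissue$t1)
      mxy <- mxy * exp(-ex$tr_to_next[j] / tissue$t2) * deph
      mz <- mz * e1 + (1 - e1) * tissue$m0
      if (delays[j] > 0) {
        e1 <- exp(-delays[j] / tissue$t1)
        mxy <- mxy * exp(-delays[j] / tissue$t2) * deph
        mz <- mz * e1 + (1 - e1) * tissue$m0
      }
    }
  }
  sig
}
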