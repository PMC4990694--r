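# Radial k-space encoding. Each fingerprint time point is sampled with N
# evenly distributed spokes (pi/N apart, spanning the k-space diameter); the
# whole spoke set rotates by 14 * 6/N degrees between excitations so that
# successive time points cover complementary regions of k-space and their
# streak artefacts decorrelate. The forward model and the adjoint
# (density-compensated) reconstruction are exact non-uniform DFTs.

#' Radial acceleration factor
#'
#' Ratio of the fully sampled radial spoke count (`pi * M / 2`) to the spokes
#' actually acquired per time point, rounded to the nearest integer.
#'
#' @param M Image matrix size.
#' @param N Spokes per time point.
#' @return Integer acceleration factor R.
#' @examples
#' acceleration_factor(160, 9)  # 28
#' acceleration_factor(336, 12) # 44
#' @export
acceleration_factor <- function(M, N) {
  if (length(M) != 1 || length(N) != 1 || M < 1 || N < 1) {
    .stop_arg("M and N must be positive integers")
  }
  as.integer(round(pi * M / (2 * N)))
}

#' Build a rotating radial trajectory
#'
#' Spoke `j` (0-based) of time point `t` (0-based) lies at angle
#' `j * pi/N + t * (14 * 6/N) * pi/180`, sampled at `samples_per_spoke`
#' uniformly spaced radii covering the k-space diameter (`|k| <= M/2`
#' cycles/FOV).
#'
#' @param M Matrix size.
#' @param N Spokes per time point.
#' @param n_timepoints Number of time points.
#' @param samples_per_spoke Read-out samples per spoke (default `2 * M`,
#'   two-fold read-out oversampling).
#' @return A `radial_trajectory`: `angles` (`n_timepoints x N` matrix, rad),
#'   sample radii start `r0` and spacing `dr` (cycles/FOV), and the scalars
#'   above.
#' @export
build_trajectory <- function(M, N, n_timepoints, samples_per_spoke = 2L * M) {
  if (M < 1 || N < 1 || n_timepoints < 1 || samples_per_spoke < 1) {
    .stop_arg("all trajectory dimensions must be positive")
  }
  rot <- (14 * 6 / N) * pi / 180
  tt <- seq_len(n_timepoints) - 1L
  jj <- seq_len(N) - 1L
  angles <- outer(tt * rot, jj * pi / N, `+`)
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_timepoints = as.integer(n_timepoints),
                 samples_per_spoke = as.integer(samples_per_spoke),
                 angles = angles, r0 = -M / 2, dr = M / samples_per_spoke,
                 rotation_deg = 14 * 6 / N),
            class = "radial_trajectory")
}

# Sample radii of a trajectory, cycles/FOV.
.traj_radii <- function(traj) {
  traj$r0 + traj$dr * (seq_len(traj$samples_per_spoke) - 1L)
}

# Ramp density-compensation weights (|k| * dr * pi/N cell areas) with the
# flat-centre convention: the r = 0 sample gets 1/4 of the first ring weight.
.dc_weights <- function(traj, compensation = c("ramp", "none")) {
  compensation <- match.arg(compensation)
  r <- .traj_radii(traj)
  if (compensation == "none") return(rep(1, length(r)))
  w <- abs(r) * traj$dr * (pi / traj$N)
  ctr <- abs(r) < traj$dr / 2
  w[ctr] <- (traj$dr^2 * pi / traj$N) / 4
  # 1/M^2 converts the k-space quadrature into the inverse-DFT normalization
  w / traj$M^2
}

#' Forward radial sampling of an image
#'
#' Per receive channel: exact non-uniform DFT of `sensitivity * image` at the
#' time point's spoke coordinates.
#'
#' @param image Complex `M x M` matrix.
#' @param traj A [build_trajectory()] result.
#' @param sens List of complex `M x M` receive sensitivity maps, or `NULL`
#'   for a single uniform channel.
#' @param timepoint 1-based time point index.
#' @return Complex array `[samples_per_spoke, N, n_channels]`.
#' @export
forward_sample <- function(image, traj, sens = NULL, timepoint = 1L) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (!all(dim(image) == traj$M)) {
    .stop_arg("image is %dx%d but the trajectory expects %dx%d",
              nrow(image), ncol(image), traj$M, traj$M)
  }
  if (timepoint < 1 || timepoint > traj$n_timepoints) {
    .stop_arg("timepoint %d outside 1..%d", timepoint, traj$n_timepoints)
  }
  if (is.null(sens)) sens <- list(matrix(1 + 0i, traj$M, traj$M))
  ang <- traj$angles[timepoint, ]
  out <- array(0i, c(traj$samples_per_spoke, traj$N, length(sens)))
  for (ch in seq_along(sens)) {
    out[, , ch] <- cpp_ndft_forward(as.matrix(sens[[ch]] * image), cos(ang),
                                    sin(ang), traj$r0, traj$dr,
                                    traj$samples_per_spoke)
  }
  out
}

#' Adjoint (density-compensated) reconstruction of one time point
#'
#' Per channel: weighted adjoint non-uniform DFT. With ramp compensation and
#' a fully sampled spoke set (`N >= pi * M / 2`) this reconstructs a test
#' image to within a few percent relative l2 error.
#'
#' @param kdata Complex array `[samples_per_spoke, N, n_channels]` (one time
#'   point) or `[.., .., .., T]` with `timepoint` selecting the frame.
#' @param traj The matching trajectory.
#' @param timepoint 1-based time point index (selects the spoke angles).
#' @param density_compensation `"ramp"` (radial cell-area weights, flat
#'   centre) or `"none"` (pure adjoint, used by the operator tests).
#' @return List of complex `M x M` images, one per channel.
#' @export
adjoint_recon <- function(kdata, traj, timepoint = 1L,
                          density_compensation = c("ramp", "none")) {
  stopifnot(inherits(traj, "radial_trajectory"))
  w <- .dc_weights(traj, density_compensation)
  if (length(dim(kdata)) == 4L) {
    kdata <- array(kdata[, , , timepoint], dim(kdata)[1:3])
  }
  d <- dim(kdata)
  if (d[1] != traj$samples_per_spoke || d[2] != traj$N) {
    .stop_arg("k-space block %dx%d does not match trajectory %dx%d",
              d[1], d[2], traj$samples_per_spoke, traj$N)
  }
  ang <- traj$angles[timepoint, ]
  lapply(seq_len(d[3]), function(ch) {
    cpp_ndft_adjoint(matrix(kdata[, , ch], d[1], d[2]), cos(ang), sin(ang),
                     w, traj$r0, traj$dr, traj$M)
  })
}

#' Estimate relative receive sensitivities from central k-space
#'
#' Grids the spokes of the excitations in the first compression bin, apodizes
#' to the central k-space region (Hann window), reconstructs a low-resolution
#' image per channel and divides by the root sum of squares across channels.
#'
#' @param kdata Complex array `[samples_per_spoke, N, n_channels, T]`.
#' @param traj The matching trajectory.
#' @param plan A [compression_plan()]; its first bin defines the time points
#'   used.
#' @param k_cut_frac Apodization cut-off as a fraction of the maximum k-space
#'   radius.
#' @return An `rx_sensitivities`: `maps` (list of complex `M x M`, unit root
#'   sum of squares inside the support) and `rss_lowres` (root sum of squares
#'   of the un-normalized low-resolution channel images).
#' @export
estimate_rx_sensitivities <- function(kdata, traj, plan, k_cut_frac = 0.3) {
  stopifnot(inherits(plan, "pnp_bin_map"))
  tps <- plan[[1]]$indices
  d <- dim(kdata)
  if (all(abs(kdata) == 0)) .stop_arg("cannot estimate sensitivities from all-zero data")
  r <- .traj_radii(traj)
  k_cut <- k_cut_frac * traj$M / 2
  apod <- ifelse(abs(r) < k_cut, cos(pi * abs(r) / (2 * k_cut))^2, 0)
  w <- .dc_weights(traj, "ramp") * apod
  low <- vector("list", d[3])
  for (ch in seq_len(d[3])) low[[ch]] <- matrix(0i, traj$M, traj$M)
  for (t in tps) {
    ang <- traj$angles[t, ]
    for (ch in seq_len(d[3])) {
      low[[ch]] <- low[[ch]] +
        cpp_ndft_adjoint(matrix(kdata[, , ch, t], d[1], d[2]), cos(ang),
                         sin(ang), w, traj$r0, traj$dr, traj$M)
    }
  }
  rss <- sqrt(Reduce(`+`, lapply(low, function(m) Mod(m)^2)))
  maps <- lapply(low, function(m) {
    out <- m
    out[rss > 0] <- m[rss > 0] / rss[rss > 0]
    out[rss == 0] <- 0i
    out
  })
  structure(list(maps = maps, rss_lowres = rss), class = "rx_sensitivities")
}

#' Matched-filter receive combination
#'
#' `sum(conj(s_c) * image_c) / sum(|s_c|^2)`; voxels where the sensitivity
#' root sum of squares vanishes are set to zero and reported in the
#' `"flagged"` attribute.
#'
#' @param images List of complex `M x M` per-channel images.
#' @param sens An `rx_sensitivities` (or list of sensitivity maps).
#' @return Combined complex `M x M` image.
#' @export
combine_rx <- function(images, sens) {
  maps <- if (inherits(sens, "rx_sensitivities")) sens$maps else sens
  if (length(images) != length(maps)) {
    .stop_arg("%d channel images but %d sensitivity maps",
              length(images), length(maps))
  }
  num <- Reduce(`+`, Map(function(im, s) Conj(s) * im, images, maps))
  den <- Reduce(`+`, lapply(maps, function(s) Mod(s)^2))
  out <- num
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[den == 0] <- 0i
  attr(out, "flagged") <- which(den == 0)
  out
}
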