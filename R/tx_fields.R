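# Synthetic multi-element transmit (B1+) field models and RF shimming.
# Full-wave electrodynamic fields are replaced by an analytic ring-source
# model: element k on a ring radiates A * exp(-r/decay) * exp(-i*2*pi*r/lambda)
# from its position. Short wavelengths produce the interference nulls (B1+
# voids) that motivate interleaving complementary illuminations; the model
# reproduces the qualitative structures (centre-bright CP mode, centre-null
# gradient mode, non-overlapping voids), not any measured uniformity numbers.

#' Orthogonal drive modes of a ring transmit array
#'
#' Mode `n` drives element `k` with `exp(1i * n * alpha * k) / sqrt(K)`,
#' `alpha = 2 * pi / K`. Mode 1 is the circularly polarized (CP) mode, mode 2
#' the gradient mode; the K mode vectors are mutually orthonormal.
#'
#' @param K Number of elements.
#' @param n Mode index in `1..K`.
#' @return Complex weight vector of length `K`.
#' @export
mode_weights <- function(K, n) {
  if (n < 1 || n > K) .stop_arg("mode index n = %d outside 1..%d", n, K)
  alpha <- 2 * pi / K
  exp(1i * n * alpha * seq_len(K)) / sqrt(K)
}

#' Combine element fields under a drive vector
#'
#' @param S An `element_field_set` (see [synthetic_element_fields()]).
#' @param b Complex drive vector, one weight per element.
#' @return Complex net B1+ map (`S %*% b` pointwise over the grid).
#' @export
combine_field <- function(S, b) {
  if (length(b) != S$K) {
    .stop_arg("drive vector length %d but field set has %d elements",
              length(b), S$K)
  }
  Reduce(`+`, Map(function(f, w) f * w, S$fields, as.list(b)))
}

#' Approximate-CP calibration by central phase alignment
#'
#' Aligns the per-element signal phases in a central region: element `k`
#' receives weight `exp(-1i * arg(mean field over the region))`. The derived
#' approximate gradient mode increments these weights by the azimuthal angle
#' of the elements.
#'
#' @param S An `element_field_set`.
#' @param centre_mask Logical matrix selecting the central region.
#' @return List with drive vectors `cp` and `gradient`.
#' @export
approx_cp_calibration <- function(S, centre_mask) {
  if (!any(centre_mask)) .stop_arg("centre region is empty")
  mu <- vapply(S$fields, function(f) mean(f[centre_mask]), complex(1))
  dead <- which(Mod(mu) == 0)
  if (length(dead)) {
    .stop_arg("degenerate calibration: element %d has zero mean field in the centre region",
              dead[1])
  }
  cp <- exp(-1i * Arg(mu))
  alpha <- 2 * pi / S$K
  list(cp = cp, gradient = cp * exp(1i * alpha * seq_len(S$K)))
}

#' Magnitude least squares RF shim
#'
#' Variable-exchange iteration for `min_b || |S b| - m ||^2` over the mask:
#' alternately fit `S b` to `m * exp(1i * arg(S b))` by complex least squares
#' and update the phase. The objective is non-increasing per iteration.
#'
#' @param S An `element_field_set`.
#' @param m Target magnitude map (positive on the mask).
#' @param mask Logical matrix (non-empty).
#' @param n_iter Iterations.
#' @param init `"cp"` (CP-mode weights, deterministic default) or `"random"`.
#' @param seed Seed for the random initialization.
#' @return List: `b` (drive vector), `objective` (per-iteration values),
#'   `field` (net map).
#' @export
mls_shim <- function(S, m, mask, n_iter = 50L, init = c("cp", "random"),
                     seed = NULL) {
  init <- match.arg(init)
  if (!any(mask)) .stop_arg("shim mask is empty")
  A <- vapply(S$fields, function(f) f[mask], complex(sum(mask)))
  tgt_mag <- m[mask]
  if (any(tgt_mag <= 0)) .stop_arg("target magnitude must be positive on the mask")
  b <- if (init == "cp") {
    mode_weights(S$K, 1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    complex(real = rnorm(S$K), imaginary = rnorm(S$K))
  }
  solve_ls <- function(rhs) {
    tryCatch(qr.solve(A, rhs), error = function(e) {
      warning("rank-deficient element fields on mask; using pseudo-inverse",
              call. = FALSE)
      sv <- svd(A)
      keep <- sv$d > max(sv$d) * 1e-12
      sv$v[, keep, drop = FALSE] %*%
        ((Conj(t(sv$u[, keep, drop = FALSE])) %*% rhs) / sv$d[keep])
    })
  }
  obj <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    z <- drop(A %*% b)
    ph <- ifelse(Mod(z) > 0, z / Mod(z), 1 + 0i)
    b <- drop(solve_ls(tgt_mag * ph))
    z <- drop(A %*% b)
    obj[it] <- sum((Mod(z) - tgt_mag)^2)
  }
  field <- combine_field(S, b)
  list(b = b, objective = obj, field = field)
}

#' Coefficient of variation of a field magnitude over a mask
#'
#' Population standard deviation of `|field|` divided by its mean.
#'
#' @param field Complex (or numeric) map.
#' @param mask Logical matrix.
#' @return Non-negative scalar.
#' @export
field_cv <- function(field, mask) {
  if (!any(mask)) .stop_arg("mask is empty")
  v <- Mod(field[mask])
  mu <- mean(v)
  if (mu == 0) .stop_arg("coefficient of variation undefined for a zero-mean field")
  sqrt(mean((v - mu)^2)) / mu
}

#' Analytic synthetic transmit element fields
#'
#' Places `K` elements on a ring of radius `ring_radius` around the field of
#' view; the field of element `k` is
#' `A * exp(-r / decay_scale) * exp(-1i * 2 * pi * r / wavelength)` with `r`
#' the distance from the element. Short wavelengths create interference nulls
#' when elements are combined. Deterministic; `seed` only drives the optional
#' per-element amplitude jitter.
#'
#' @param M Grid size.
#' @param K Number of elements (>= 2).
#' @param fov Field of view in metres.
#' @param wavelength Effective RF wavelength in the medium, metres.
#' @param decay_scale Amplitude decay length, metres.
#' @param ring_radius Element ring radius, metres (default just outside the
#'   field of view).
#' @param amplitude Peak per-element amplitude, microtesla per unit drive.
#' @param amp_jitter Relative per-element amplitude jitter (0 = none).
#' @param seed Seed for the jitter draw.
#' @return An `element_field_set`: `fields` (list of complex `M x M` maps),
#'   `positions` (`K x 2`, metres), `K`, `M`, `fov`.
#' @export
synthetic_element_fields <- function(M, K = 8L, fov = 0.24, wavelength = 0.12,
                                     decay_scale = 0.25,
                                     ring_radius = 0.62 * fov,
                                     amplitude = 1, amp_jitter = 0,
                                     seed = NULL) {
  if (K < 2) .stop_arg("K must be >= 2")
  if (wavelength <= 0) .stop_arg("wavelength must be positive")
  alpha <- 2 * pi / K
  amp <- rep(amplitude, K)
  if (amp_jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- amplitude * (1 + amp_jitter * rnorm(K))
  }
  coords <- (seq_len(M) - 1 - M / 2) / M * fov
  xg <- matrix(coords, M, M)
  yg <- t(xg)
  pos <- cbind(ring_radius * cos(alpha * seq_len(K)),
               ring_radius * sin(alpha * seq_len(K)))
  fields <- lapply(seq_len(K), function(k) {
    r <- sqrt((xg - pos[k, 1])^2 + (yg - pos[k, 2])^2)
    # exp(-i*alpha*k): the B1+ orientation phase of a rotated element -- the
    # reason the CP drive phases equal the azimuthal angles, and what makes
    # mode 1 constructive at the ring centre
    amp[k] * exp(-r / decay_scale) * exp(-1i * 2 * pi * r / wavelength) *
      exp(-1i * alpha * k)
  })
  structure(list(fields = fields, positions = pos, K = as.integer(K),
                 M = as.integer(M), fov = fov),
            class = "element_field_set")
}

#' Preset pairs of complementary illumination fields
#'
#' `"ring_modes"`: CP and gradient modes of an 8-element ring at a short
#' effective wavelength (centre-bright vs centre-null, non-overlapping
#' voids). `"linear_pair"`: the two linear modes of a 2-port drive, each with
#' an off-centre interference void on opposite sides. Fields are scaled so
#' the 95th percentile of the brighter |B1+| map is `b1_scale` microtesla.
#'
#' @param M Grid size.
#' @param preset Preset name.
#' @param b1_scale Target 95th-percentile amplitude, microtesla.
#' @return List of two complex `M x M` B1+ maps (microtesla), with the
#'   element set in attribute `"elements"`.
#' @export
tx_field_preset <- function(M, preset = c("ring_modes", "linear_pair"),
                            b1_scale = 12) {
  preset <- match.arg(preset)
  if (preset == "ring_modes") {
    S <- synthetic_element_fields(M, K = 8L, wavelength = 0.14)
    f1 <- combine_field(S, mode_weights(8L, 1))
    f2 <- combine_field(S, mode_weights(8L, 2))
  } else {
    S <- synthetic_element_fields(M, K = 8L, wavelength = 0.14)
    # the two linear drive modes (cosine/sine element weightings), whose
    # interference voids are 90-degree rotated copies of each other
    a <- 2 * pi / 8 * (1:8)
    f1 <- combine_field(S, cos(a) / 2)
    f2 <- combine_field(S, sin(a) / 2)
  }
  ref <- max(quantile(Mod(f1), 0.95), quantile(Mod(f2), 0.95))
  out <- list(f1 * (b1_scale / ref), f2 * (b1_scale / ref))
  attr(out, "elements") <- S
  attr(out, "preset") <- preset
  out
}
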