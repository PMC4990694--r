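# The four-segment PnP-MRF sequence schedule: 4 x 120 excitations. Segments
# 1 and 3 are RF-spoiled gradient echoes alternating echo-to-echo between the
# two transmit coil configurations (encoding B1+ and T1); segments 2 and 4
# each dedicate a single coil configuration, use 0/180 phase cycling with
# gradient spoilers so stimulated echoes can form (encoding T2), and drive
# larger flip angles to emphasize the refocusing component. Recovery delays
# between segments let the longitudinal magnetization partially regrow.

#' Schedule configuration defaults
#'
#' The exact drive-voltage and phase-increment trains of the reference
#' implementation are not published; the defaults here are declared stand-ins
#' with the documented structure: smooth half-sine drive ramps per segment
#' peaking at 25 degrees (segments 1/3) and 60 degrees (segments 2/4) at the
#' reference B1, quadratic 117-degree RF spoiling in segments 1/3, and 0/180
#' phase cycling in segments 2/4.
#'
#' @param tr Repetition interval within segments, ms (within `[4.8, 8]`).
#' @param te Echo time, ms.
#' @param delta_t Inter-segment recovery delay, ms.
#' @param peak_flip_spoiled Peak nominal flip of segments 1/3 at the
#'   reference B1, degrees.
#' @param peak_flip_refocus Peak nominal flip of segments 2/4, degrees.
#' @param rf_spoil_increment Quadratic RF-spoiling phase increment, degrees.
#' @param reference_b1 B1 amplitude (microtesla) at which a unit-drive
#'   excitation achieves `peak_flip_refocus`. The 6 microtesla default puts
#'   the declared 3--12 microtesla operating range at 30--120 degree peak
#'   refocusing flips: low-field voxels keep enough flip for T1/B1
#'   discrimination, while the upper range drives the large refocusing
#'   pulses the stimulated-echo segments are meant to emphasize.
#' @param rf_duration,rf_time_bandwidth,rf_shape RF pulse descriptor (2 ms
#'   sinc with time-bandwidth product 3 by default).
#' @return A named list of configuration values.
#' @export
schedule_config <- function(tr = 4.8, te = 2.3, delta_t = 3000,
                            peak_flip_spoiled = 25, peak_flip_refocus = 60,
                            rf_spoil_increment = 117, reference_b1 = 6,
                            rf_duration = 2, rf_time_bandwidth = 3,
                            rf_shape = "sinc") {
  list(tr = tr, te = te, delta_t = delta_t,
       peak_flip_spoiled = peak_flip_spoiled,
       peak_flip_refocus = peak_flip_refocus,
       rf_spoil_increment = rf_spoil_increment,
       reference_b1 = reference_b1,
       rf_duration = rf_duration, rf_time_bandwidth = rf_time_bandwidth,
       rf_shape = rf_shape,
       n_segments = 4L, n_per_segment = 120L)
}

#' Build the default four-segment schedule
#'
#' @param config A [schedule_config()] list.
#' @return A `pnp_schedule`: a 480-row excitation table (`segment_id`,
#'   `index_in_segment`, `coil_id`, `relative_drive`, `rf_phase`,
#'   `tr_to_next`, `spoiled`), the three inter-segment delays, `te`, the RF
#'   pulse descriptor, `n_channels = 2` and the flip calibration
#'   (`reference_flip` at `reference_b1` for unit drive).
#' @examples
#' s <- build_default_schedule()
#' nrow(s$excitations)         # 480
#' head(s$excitations$coil_id) # 0 1 0 1 0 1
#' @export
build_default_schedule <- function(config = schedule_config()) {
  viol <- character()
  if (config$tr < 4.8 || config$tr > 8) {
    viol <- c(viol, sprintf("tr = %g ms outside [4.8, 8] ms", config$tr))
  }
  if (config$te <= 0 || config$te >= config$tr) {
    viol <- c(viol, "te must lie in (0, tr)")
  }
  if (config$n_segments != 4L || config$n_per_segment != 120L) {
    viol <- c(viol, "segment structure must be 4 segments x 120 excitations")
  }
  if (length(viol)) {
    .stop_arg("invalid schedule configuration:\n- %s",
              paste(viol, collapse = "\n- "))
  }
  np <- config$n_per_segment
  idx <- seq_len(np) - 1L
  ramp <- sin(pi * (idx + 0.5) / np)  # half-sine drive envelope
  peak_ratio <- config$peak_flip_spoiled / config$peak_flip_refocus
  quad <- (config$rf_spoil_increment * pi / 180) * idx * (idx + 1) / 2
  alt <- rep_len(c(0, pi), np)
  seg <- function(segment_id, coil, drive, phase, spoiled) {
    data.frame(segment_id = segment_id, index_in_segment = idx,
               coil_id = coil, relative_drive = drive, rf_phase = phase %% (2 * pi),
               tr_to_next = config$tr, spoiled = spoiled)
  }
  ex <- rbind(
    seg(1L, rep_len(c(0L, 1L), np), ramp * peak_ratio, quad, TRUE),
    seg(2L, 0L, ramp, alt, FALSE),
    seg(3L, rep_len(c(0L, 1L), np), ramp * peak_ratio, quad, TRUE),
    seg(4L, 1L, ramp, alt, FALSE)
  )
  rownames(ex) <- NULL
  structure(list(
    excitations = ex,
    inter_segment_delays = rep(config$delta_t, 3),
    te = config$te,
    rf_pulse = list(duration = config$rf_duration,
                    time_bandwidth = config$rf_time_bandwidth,
                    shape = config$rf_shape),
    n_channels = 2L,
    reference_flip = config$peak_flip_refocus * pi / 180,
    reference_b1 = config$reference_b1
  ), class = "pnp_schedule")
}

#' Build a single-illumination comparison schedule
#'
#' Identical timing, drive and phase trains to [build_default_schedule()],
#' but every excitation uses one transmit coil configuration. This is the
#' conventional-fingerprinting stand-in used to demonstrate that a lone
#' illumination fails inside its own B1+ void while the interleaved
#' two-illumination schedule recovers it. Deliberately violates the
#' interleaving invariants, so [validate_schedule()] reports it.
#'
#' @param coil_id The single coil configuration used throughout (0 or 1).
#' @param config A [schedule_config()].
#' @return A `pnp_schedule`.
#' @export
build_single_coil_schedule <- function(coil_id = 0L, config = schedule_config()) {
  s <- build_default_schedule(config)
  s$excitations$coil_id <- as.integer(coil_id)
  s
}

#' Validate a sequence schedule against its structural invariants
#'
#' Reports (never throws). Checks the 4 x 120 structure, repetition-interval
#' bounds, echo-to-echo coil alternation in segments 1/3, the dedicated coil
#' of segments 2/4, 0/180 phase cycling and the larger drive of the
#' refocusing segments.
#'
#' @param s A `pnp_schedule`.
#' @return Character vector of violations; empty when the schedule is valid.
#' @export
validate_schedule <- function(s) {
  v <- character()
  ex <- s$excitations
  if (nrow(ex) != 480L) {
    v <- c(v, sprintf("excitation count: expected 480, found %d", nrow(ex)))
  }
  segs <- split(seq_len(nrow(ex)), ex$segment_id)
  if (length(segs) != 4L) {
    v <- c(v, sprintf("segment count: expected 4, found %d", length(segs)))
  }
  for (sid in names(segs)) {
    rows <- segs[[sid]]
    if (length(rows) != 120L) {
      v <- c(v, sprintf("segment %s: expected 120 excitations, found %d",
                        sid, length(rows)))
    }
  }
  bad_tr <- which(ex$tr_to_next < 4.8 | ex$tr_to_next > 8)
  for (i in head(bad_tr, 5)) {
    v <- c(v, sprintf("excitation %d: tr_to_next = %g ms outside [4.8, 8] ms",
                      i, ex$tr_to_next[i]))
  }
  bad_coil <- which(!ex$coil_id %in% c(0L, 1L))
  for (i in head(bad_coil, 5)) {
    v <- c(v, sprintf("excitation %d: coil_id %d not in {0, 1}", i, ex$coil_id[i]))
  }
  for (sid in intersect(c("1", "3"), names(segs))) {
    rows <- segs[[sid]]
    expect <- rep_len(c(0L, 1L), length(rows))
    bad <- rows[ex$coil_id[rows] != expect]
    for (i in head(bad, 3)) {
      v <- c(v, sprintf("excitation %d: segment %s must alternate coils 0,1,...",
                        i, sid))
    }
    if (!all(ex$spoiled[rows])) {
      v <- c(v, sprintf("segment %s: RF spoiling must be active", sid))
    }
  }
  dedicated <- c("2" = 0L, "4" = 1L)
  for (sid in intersect(names(dedicated), names(segs))) {
    rows <- segs[[sid]]
    bad <- rows[ex$coil_id[rows] != dedicated[[sid]]]
    for (i in head(bad, 3)) {
      v <- c(v, sprintf("excitation %d: segment %s is dedicated to coil %d",
                        i, sid, dedicated[[sid]]))
    }
    ph <- ex$rf_phase[rows]
    if (!all(abs(ph) < 1e-9 | abs(ph - pi) < 1e-9)) {
      v <- c(v, sprintf("segment %s: rf_phase must alternate 0/180 degrees", sid))
    }
    if (any(ex$spoiled[rows])) {
      v <- c(v, sprintf("segment %s: stimulated-echo segment must not be RF-spoiled", sid))
    }
  }
  if (all(c("1", "2") %in% names(segs))) {
    if (max(ex$relative_drive[segs[["2"]]]) <= max(ex$relative_drive[segs[["1"]]])) {
      v <- c(v, "segment 2 must drive larger flips than segment 1")
    }
  }
  if (all(c("3", "4") %in% names(segs))) {
    if (max(ex$relative_drive[segs[["4"]]]) <= max(ex$relative_drive[segs[["3"]]])) {
      v <- c(v, "segment 4 must drive larger flips than segment 3")
    }
  }
  if (!identical(s$n_channels, 2L)) {
    v <- c(v, sprintf("n_channels: expected 2, found %s", s$n_channels))
  }
  v
}

#' Per-excitation transmit coil ids in acquisition order
#'
#' @param s A `pnp_schedule`.
#' @return Integer vector (0/1) of length `nrow(s$excitations)`.
#' @export
coil_sequence <- function(s) {
  stopifnot(inherits(s, "pnp_schedule"))
  s$excitations$coil_id
}

# ---- serialization: flat config header + one CSV row per excitation -------

.fmt <- function(x) sprintf("%.17g", x)

#' Write a schedule to its canonical text container
#'
#' Header lines `# key=value` carry the scalar fields (full `%.17g`
#' precision); the body is one CSV row per excitation. The round trip through
#' [read_schedule()] is bit-exact.
#'
#' @param s A `pnp_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(s, path) {
  hdr <- c(
    sprintf("# te=%s", .fmt(s$te)),
    sprintf("# inter_segment_delays=%s", paste(.fmt(s$inter_segment_delays), collapse = ",")),
    sprintf("# rf_duration=%s", .fmt(s$rf_pulse$duration)),
    sprintf("# rf_time_bandwidth=%s", .fmt(s$rf_pulse$time_bandwidth)),
    sprintf("# rf_shape=%s", s$rf_pulse$shape),
    sprintf("# n_channels=%d", s$n_channels),
    sprintf("# reference_flip=%s", .fmt(s$reference_flip)),
    sprintf("# reference_b1=%s", .fmt(s$reference_b1))
  )
  ex <- s$excitations
  body <- sprintf("%d,%d,%d,%s,%s,%s,%d", ex$segment_id, ex$index_in_segment,
                  ex$coil_id, .fmt(ex$relative_drive), .fmt(ex$rf_phase),
                  .fmt(ex$tr_to_next), as.integer(ex$spoiled))
  writeLines(c(hdr, "segment_id,index_in_segment,coil_id,relative_drive,rf_phase,tr_to_next,spoiled",
               body), path)
  invisible(path)
}

#' Read a schedule written by [write_schedule()]
#'
#' @param path Input file path.
#' @return A `pnp_schedule`.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- lines[!startsWith(lines, "#")]
  ex <- read.csv(text = body, stringsAsFactors = FALSE)
  ex$spoiled <- as.logical(ex$spoiled)
  structure(list(
    excitations = ex,
    inter_segment_delays = as.numeric(strsplit(vals[["inter_segment_delays"]], ",")[[1]]),
    te = as.numeric(vals[["te"]]),
    rf_pulse = list(duration = as.numeric(vals[["rf_duration"]]),
                    time_bandwidth = as.numeric(vals[["rf_time_bandwidth"]]),
                    shape = vals[["rf_shape"]]),
    n_channels = as.integer(vals[["n_channels"]]),
    reference_flip = as.numeric(vals[["reference_flip"]]),
    reference_b1 = as.numeric(vals[["reference_b1"]])
  ), class = "pnp_schedule")
}

#' Hash a schedule (binds dictionaries to the schedule they were built for)
#'
#' 32-bit FNV-1a over the canonical serialized form.
#'
#' @param s A `pnp_schedule`.
#' @return Hash as an 8-character lowercase hex string.
#' @export
schedule_hash <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_schedule(s, tmp)
  txt <- paste(readLines(tmp), collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  # FNV-1a in double arithmetic mod 2^32 (split multiply keeps precision)
  h <- 2166136261
  for (b in bytes) {
    h <- .bitxor32(h, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two non-negative doubles < 2^32
.bitxor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}
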