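# 4-D fingerprint dictionary: T1 x T2 x B1(channel 1) x B1(channel 2).
# Relaxation axes are geometric (5% steps, constant relative accuracy);
# B1 axes are arithmetic. Each entry's 480-sample complex fingerprint is
# reduced by view-sharing compression - the complex sum of every run of 15
# consecutive same-coil samples, followed by the modulus - to 32 real values,
# then unit-normalized with the pre-normalization norm retained for proton
# density estimation.

#' Build the 4-D dictionary parameter grid
#'
#' Relaxation axes are generated multiplicatively from the minimum
#' (`v0 * ratio^n`); the number of steps is chosen so the final value matches
#' the requested maximum at its printed precision (the defaults reproduce the
#' 71-value axes 150..4564 ms and 15..456 ms). B1 axes include both endpoints.
#'
#' @param t1_min,t1_max,t1_ratio T1 axis, ms (defaults 150..4564, 5% steps).
#' @param t2_min,t2_max,t2_ratio T2 axis, ms (defaults 15..456, 5% steps).
#' @param b1_min,b1_max,b1_step B1 axis, microtesla (defaults 0..15 by 0.2),
#'   shared by both transmit channels.
#' @param n_channels Number of transmit channels (2).
#' @return A `parameter_grid`: `t1`, `t2` (ms), `b1` (microtesla, one axis
#'   used for every channel) and `n_channels`.
#' @examples
#' g <- make_axes()
#' head(g$t1, 3)   # 150.000 157.500 165.375
#' length(g$b1)    # 76
#' @export
make_axes <- function(t1_min = 150, t1_max = 4564, t1_ratio = 1.05,
                      t2_min = 15, t2_max = 456, t2_ratio = 1.05,
                      b1_min = 0, b1_max = 15, b1_step = 0.2,
                      n_channels = 2L) {
  geom_axis <- function(lo, hi, ratio) {
    if (lo <= 0 || hi <= lo || ratio <= 1) .stop_arg("invalid geometric axis range")
    n <- round(log(hi / lo) / log(ratio))
    lo * ratio^(0:n)
  }
  if (b1_max <= b1_min || b1_step <= 0) .stop_arg("invalid B1 axis range")
  structure(list(
    t1 = geom_axis(t1_min, t1_max, t1_ratio),
    t2 = geom_axis(t2_min, t2_max, t2_ratio),
    b1 = seq(b1_min, b1_max, by = b1_step),
    n_channels = as.integer(n_channels)
  ), class = "parameter_grid")
}

#' Number of entries in a parameter grid
#' @param grid A `parameter_grid`.
#' @return Entry count of the full Cartesian product.
#' @export
grid_size <- function(grid) {
  length(grid$t1) * length(grid$t2) * length(grid$b1)^grid$n_channels
}

#' A reduced sub-grid for desk-scale experiments
#'
#' Selects evenly spread values from the full default axes, so reduced-grid
#' atoms are identical to the corresponding full-grid atoms.
#'
#' @param n_t1,n_t2 Number of relaxation values kept per axis.
#' @param n_b1 Number of B1 values kept (even subsample of 0..15 microtesla).
#' @return A `parameter_grid`.
#' @export
reduced_parameter_grid <- function(n_t1 = 8L, n_t2 = 8L, n_b1 = 6L) {
  full <- make_axes()
  pick <- function(axis, n) axis[unique(round(seq(1, length(axis), length.out = n)))]
  structure(list(
    t1 = pick(full$t1, n_t1), t2 = pick(full$t2, n_t2),
    b1 = pick(full$b1, n_b1), n_channels = full$n_channels
  ), class = "parameter_grid")
}

#' Derive the view-sharing compression plan from a coil sequence
#'
#' Partitions the excitation indices into bins of `bin_size` consecutive
#' occurrences of the same coil ("consecutive" counts every other echo in the
#' alternating segments). For the default schedule this yields 32 bins: 4 per
#' coil in each alternating segment and 8 in each dedicated segment.
#'
#' @param coil_seq Integer vector of per-excitation coil ids.
#' @param bin_size Samples integrated per compressed point (15).
#' @return A `pnp_bin_map`: list of bins, each with `coil` and `indices`
#'   (1-based excitation indices), ordered by first contributing index.
#' @export
compression_plan <- function(coil_seq, bin_size = 15L) {
  open_idx <- list()
  bins <- list()
  for (i in seq_along(coil_seq)) {
    key <- as.character(coil_seq[i])
    open_idx[[key]] <- c(open_idx[[key]], i)
    if (length(open_idx[[key]]) == bin_size) {
      bins[[length(bins) + 1L]] <- list(coil = coil_seq[i],
                                        indices = open_idx[[key]])
      open_idx[[key]] <- integer()
    }
  }
  leftover <- Filter(length, open_idx)
  if (length(leftover)) {
    first_bad <- min(vapply(leftover, `[`, 0L, 1L))
    .stop_arg(paste0("coil sequence cannot be partitioned into same-coil sets",
                     " of %d: %d samples left over starting at index %d"),
              bin_size, sum(lengths(leftover)), first_bad)
  }
  ord <- order(vapply(bins, function(b) b$indices[1], 0L))
  structure(bins[ord], class = "pnp_bin_map", bin_size = as.integer(bin_size))
}

#' Compress a fingerprint by view sharing
#'
#' Per bin: complex sum of its samples, then the absolute value. Phase
#' variations that are constant within a bin (such as the per-coil transmit
#' phase) are thereby discarded; a 480-sample complex fingerprint (960 reals)
#' becomes 32 reals, a 30-fold storage reduction.
#'
#' @param fingerprint Complex vector covering all plan indices.
#' @param plan A [compression_plan()].
#' @return Non-negative numeric vector, one value per bin.
#' @export
compress_fingerprint <- function(fingerprint, plan) {
  stopifnot(inherits(plan, "pnp_bin_map"))
  needed <- max(vapply(plan, function(b) max(b$indices), 0L))
  if (length(fingerprint) < needed) {
    .stop_arg("fingerprint length %d shorter than compression plan (needs %d)",
              length(fingerprint), needed)
  }
  vapply(plan, function(b) Mod(sum(fingerprint[b$indices])), numeric(1))
}

# Compress many fingerprints at once; fps is L x n complex, returns n x n_bins.
.compress_batch <- function(fps, plan) {
  nb <- length(plan)
  out <- matrix(0, ncol(fps), nb)
  for (k in seq_len(nb)) {
    idx <- plan[[k]]$indices
    out[, k] <- Mod(colSums(fps[idx, , drop = FALSE]))
  }
  out
}

#' Build a compressed fingerprint dictionary
#'
#' Simulates every grid entry's fingerprint with the EPG engine, compresses
#' it, records the pre-normalization norm and stores the unit-normalized atom.
#' The build is chunked over entries and deterministic: atoms are identical
#' for any chunk size. Entries with zero compressed norm (both B1 values 0)
#' are kept but flagged invalid so the matcher skips them.
#'
#' @param grid A [make_axes()] or [reduced_parameter_grid()] grid.
#' @param schedule A `pnp_schedule`.
#' @param profile Optional slice profile (weighted sub-slice sum).
#' @param chunk_size Entries simulated per batch.
#' @param k_max Highest retained EPG order (see [simulate_fingerprint()]).
#' @param max_entries Resource guard; grids larger than this abort with
#'   advice to reduce the grid.
#' @param verbose Log chunk progress to stderr.
#' @return A `pnp_dictionary`: `grid`, `params` (one row per entry:
#'   `t1`, `t2`, `b1_1`, `b1_2` in grid order, T1 fastest), `atoms`
#'   (entries x bins, unit row norm), `norms`, `valid`, `plan`,
#'   `schedule_hash`.
#' @export
build_dictionary <- function(grid, schedule, profile = NULL, chunk_size = 512L,
                             k_max = NULL, max_entries = 2^22, verbose = FALSE) {
  stopifnot(inherits(grid, "parameter_grid"), inherits(schedule, "pnp_schedule"))
  n <- grid_size(grid)
  if (n > max_entries) {
    .stop_arg(paste0("dictionary would hold %d entries (budget %d); reduce the",
                     " grid (see reduced_parameter_grid) or raise max_entries"),
              n, max_entries)
  }
  params <- expand.grid(t1 = grid$t1, t2 = grid$t2, b1_1 = grid$b1,
                        b1_2 = grid$b1, KEEP.OUT.ATTRS = FALSE)
  plan <- compression_plan(coil_sequence(schedule))
  nb <- length(plan)
  atoms <- matrix(0, n, nb)
  norms <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s0 in starts) {
    rows <- s0:min(s0 + chunk_size - 1L, n)
    b1 <- cbind(complex(real = params$b1_1[rows]),
                complex(real = params$b1_2[rows]))
    fps <- .epg_fingerprints(schedule, params$t1[rows], params$t2[rows],
                             rep(1, length(rows)), b1, profile = profile,
                             k_max = k_max)
    comp <- .compress_batch(fps, plan)
    nrm <- sqrt(rowSums(comp^2))
    norms[rows] <- nrm
    atoms[rows, ] <- comp / pmax(nrm, .Machine$double.xmin)
    if (verbose) {
      message(sprintf("dictionary: %d / %d entries", max(rows), n))
    }
  }
  valid <- norms > 0
  structure(list(grid = grid, params = params, atoms = atoms, norms = norms,
                 valid = valid, plan = plan,
                 schedule_hash = schedule_hash(schedule)),
            class = "pnp_dictionary")
}

#' Write a dictionary to a plain-text directory container
#'
#' Layout: `meta.json` (axes, schedule hash, norms, validity, format
#' version) and `atoms.csv` (one row per entry). Values round-trip at full
#' double precision.
#'
#' @param dict A `pnp_dictionary`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "pnpmrf-dictionary-v1",
               t1 = dict$grid$t1, t2 = dict$grid$t2, b1 = dict$grid$b1,
               n_channels = dict$grid$n_channels,
               norms = dict$norms, valid = dict$valid,
               schedule_hash = dict$schedule_hash,
               plan_coils = vapply(dict$plan, function(b) b$coil, 0L),
               plan_indices = lapply(dict$plan, function(b) b$indices))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  data.table::fwrite(data.table::as.data.table(dict$atoms),
                     file.path(path, "atoms.csv"))
  invisible(path)
}

#' Read a dictionary container written by [write_dictionary()]
#' @param path Container directory.
#' @return A `pnp_dictionary`.
#' @export
read_dictionary <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "pnpmrf-dictionary-v1")) {
    .stop_arg("not a pnpmrf dictionary container: %s", path)
  }
  grid <- structure(list(t1 = meta$t1, t2 = meta$t2, b1 = meta$b1,
                         n_channels = as.integer(meta$n_channels)),
                    class = "parameter_grid")
  atoms <- as.matrix(data.table::fread(file.path(path, "atoms.csv")))
  dimnames(atoms) <- NULL
  idx_list <- meta$plan_indices
  if (is.matrix(idx_list)) {  # jsonlite simplifies equal-length bins
    idx_list <- lapply(seq_len(nrow(idx_list)), function(i) idx_list[i, ])
  }
  plan <- Map(function(coil, idx) list(coil = coil, indices = as.integer(idx)),
              meta$plan_coils, idx_list)
  plan <- structure(unname(plan), class = "pnp_bin_map",
                    bin_size = length(plan[[1]]$indices))
  params <- expand.grid(t1 = grid$t1, t2 = grid$t2, b1_1 = grid$b1,
                        b1_2 = grid$b1, KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, params = params, atoms = atoms,
                 norms = meta$norms, valid = meta$valid, plan = plan,
                 schedule_hash = meta$schedule_hash),
            class = "pnp_dictionary")
}
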