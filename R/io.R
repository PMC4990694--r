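# Plain-text containers for the remaining interchange objects. All payloads
# are CSV (full double precision via data.table) with a JSON metadata file;
# complex arrays are stored as re/im column pairs.

#' Write a radial k-space series to a directory container
#'
#' @param kspace A [simulate_acquisition()] result.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_kspace <- function(kspace, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  traj <- kspace$traj
  meta <- list(format = "pnpmrf-kspace-v1",
               M = traj$M, N = traj$N, n_timepoints = traj$n_timepoints,
               samples_per_spoke = traj$samples_per_spoke,
               noise_sd_abs = kspace$noise_sd_abs, seed = kspace$seed,
               dims = dim(kspace$data))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  flat <- as.vector(kspace$data)
  data.table::fwrite(data.table::data.table(re = Re(flat), im = Im(flat)),
                     file.path(path, "data.csv"))
  invisible(path)
}

#' Read a k-space container written by [write_kspace()]
#'
#' Rebuilds the trajectory from the stored geometry; synthetic-only fields
#' (ground truth, true sensitivities) are not persisted.
#'
#' @param path Container directory.
#' @return A `radial_kspace_series` (data + trajectory + noise/seed record).
#' @export
read_kspace <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "pnpmrf-kspace-v1")) {
    .stop_arg("not a pnpmrf k-space container: %s", path)
  }
  dt <- data.table::fread(file.path(path, "data.csv"))
  data <- array(complex(real = dt$re, imaginary = dt$im), meta$dims)
  traj <- build_trajectory(meta$M, meta$N, meta$n_timepoints,
                           meta$samples_per_spoke)
  structure(list(data = data, traj = traj, noise_sd_abs = meta$noise_sd_abs,
                 seed = meta$seed, sens_true = NULL, ground_truth = NULL,
                 scenario = NULL),
            class = "radial_kspace_series")
}
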