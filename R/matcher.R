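# Exhaustive compressed-fingerprint matching. The correlation is the cosine
# similarity between the measured compressed fingerprint and each
# unit-normalized dictionary atom (both real and non-negative after the
# modulus projection); proton density is the least-squares scale between the
# measured and the un-normalized simulated fingerprint.

#' Match one compressed fingerprint against the dictionary
#'
#' @param measured Numeric compressed fingerprint (length = number of bins).
#' @param dict A [build_dictionary()] result.
#' @return List with `t1`, `t2`, `b1` (per-channel vector), `pd`,
#'   `correlation` and the matched `entry` index. An all-zero input yields a
#'   masked-out result (`correlation = 0`, `pd = 0`, `entry = NA`). Ties
#'   break toward the lowest entry index.
#' @examples
#' \dontrun{
#' m <- dict$atoms[42, ] * dict$norms[42]
#' match_voxel(m, dict)$entry  # 42, correlation 1, pd 1
#' }
#' @export
match_voxel <- function(measured, dict) {
  stopifnot(inherits(dict, "pnp_dictionary"))
  if (length(measured) != ncol(dict$atoms)) {
    .stop_arg("measured fingerprint has %d points, dictionary atoms have %d",
              length(measured), ncol(dict$atoms))
  }
  nrm <- sqrt(sum(measured^2))
  if (nrm == 0) {
    return(list(t1 = 0, t2 = 0, b1 = numeric(dict$grid$n_channels), pd = 0,
                correlation = 0, entry = NA_integer_))
  }
  corr <- drop(dict$atoms %*% (measured / nrm))
  corr[!dict$valid] <- -Inf
  best <- which.max(corr)
  p <- dict$params[best, ]
  list(t1 = p$t1, t2 = p$t2, b1 = c(p$b1_1, p$b1_2),
       pd = nrm * corr[best] / dict$norms[best],
       correlation = corr[best], entry = best)
}

#' Match an image series voxel by voxel
#'
#' The series is compressed per voxel (complex bin sums, then modulus) if
#' still raw, a support mask is derived from the first compressed bin, and
#' every in-mask voxel is matched exhaustively. Proton density is corrected
#' by dividing out the root sum of squares of the supplied receive
#' sensitivity maps (a no-op for maps already normalized to unit root sum of
#' squares).
#'
#' @param series Complex array `[M, M, T]` with `T` = excitation count (raw)
#'   or real array `[M, M, n_bins]` (pre-compressed).
#' @param plan The [compression_plan()] matching the schedule.
#' @param dict The dictionary to search.
#' @param rx Optional `rx_sensitivities` for the proton-density correction.
#' @param schedule Optional `pnp_schedule`; when given, its hash must match
#'   `dict$schedule_hash` (guards against matching with the wrong dictionary).
#' @param mask_threshold_frac Mask threshold as a fraction of the 95th
#'   percentile of the compressed-fingerprint l2 norm (total signal energy).
#' @return A `parameter_maps` object: `pd`, `t1`, `t2`, `b1`
#'   (`M x M x n_channels`), `correlation`, `mask` (all maps zero outside the
#'   mask).
#' @export
match_image <- function(series, plan, dict, rx = NULL, schedule = NULL,
                        mask_threshold_frac = 0.05) {
  stopifnot(inherits(dict, "pnp_dictionary"))
  if (!is.null(schedule)) {
    h <- schedule_hash(schedule)
    if (!identical(h, dict$schedule_hash)) {
      .stop_arg("schedule hash %s does not match dictionary hash %s",
                h, dict$schedule_hash)
    }
  }
  d <- dim(series)
  M <- d[1]; nb <- length(plan)
  nvox <- M * d[2]
  if (d[3] == nb && !is.complex(series)) {
    comp <- matrix(series, nvox, nb)
  } else {
    flat <- matrix(series, nvox, d[3])
    comp <- matrix(0, nvox, nb)
    for (k in seq_len(nb)) {
      idx <- plan[[k]]$indices
      comp[, k] <- Mod(rowSums(flat[, idx, drop = FALSE]))
    }
  }
  # support mask from the total compressed signal energy: a single-bin
  # criterion would exclude voxels sitting in that coil's B1+ void, exactly
  # the voxels the complementary illumination is there to save
  energy <- sqrt(rowSums(comp^2))
  thr <- mask_threshold_frac * quantile(energy, 0.95, names = FALSE)
  mask <- energy > thr
  empty <- function() matrix(0, M, d[2])
  maps <- list(pd = empty(), t1 = empty(), t2 = empty(),
               b1 = array(0, c(M, d[2], dict$grid$n_channels)),
               correlation = empty(), mask = matrix(mask, M, d[2]))
  if (any(mask)) {
    V <- comp[mask, , drop = FALSE]
    vn <- sqrt(rowSums(V^2))
    live <- vn > 0
    corr <- matrix(0, nrow(V), nrow(dict$atoms))
    corr[live, ] <- (V[live, , drop = FALSE] / vn[live]) %*% t(dict$atoms)
    corr[, !dict$valid] <- -Inf
    best <- max.col(corr, ties.method = "first")
    cbest <- corr[cbind(seq_len(nrow(V)), best)]
    cbest[!live] <- 0
    pd <- ifelse(live, vn * cbest / dict$norms[best], 0)
    if (!is.null(rx)) {
      rss <- sqrt(Reduce(`+`, lapply(rx$maps, function(m) Mod(m)^2)))
      rssv <- as.vector(rss)[mask]
      pd <- ifelse(rssv > 0, pd / rssv, 0)
    }
    maps$pd[mask] <- pd
    maps$t1[mask] <- dict$params$t1[best]
    maps$t2[mask] <- dict$params$t2[best]
    for (ch in seq_len(dict$grid$n_channels)) {
      slab <- maps$b1[, , ch]
      slab[mask] <- dict$params[[paste0("b1_", ch)]][best]
      maps$b1[, , ch] <- slab
    }
    maps$correlation[mask] <- pmax(cbest, 0)
  }
  structure(maps, class = "parameter_maps")
}

#' Export parameter maps as CSV files with a JSON provenance sidecar
#'
#' @param maps A `parameter_maps`.
#' @param path Output directory.
#' @param provenance Named list merged into the sidecar (seeds, hashes,
#'   thresholds).
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path, provenance = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(path, paste0(name, ".csv")))
  }
  wr(maps$pd, "pd"); wr(maps$t1, "t1"); wr(maps$t2, "t2")
  wr(maps$correlation, "correlation"); wr(maps$mask * 1L, "mask")
  for (ch in seq_len(dim(maps$b1)[3])) wr(maps$b1[, , ch], paste0("b1_ch", ch))
  sidecar <- c(list(format = "pnpmrf-maps-v1", created = format(Sys.time())),
               provenance)
  jsonlite::write_json(sidecar, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
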