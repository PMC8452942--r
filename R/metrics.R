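# Per-cell track metrics:
#   total displacement  = path length, sum of step magnitudes (um)
#   net displacement    = |last - first| (um)
#   velocity            = total / elapsed (um min^-1)
#   motility coefficient = net^2 / (6 * elapsed) (um^2 min^-1, 3-D)
#   meandering index    = sqrt(elapsed) * net / total (min^0.5; duration-
#                         corrected straightness, can exceed 1)
#   scanning rate       = number of distinct lattice voxels containing any
#                         sampled position
# Elapsed time is in minutes throughout. Stationary tracks (total = 0)
# return 0 for velocity, motility coefficient and meandering index.

#' Compute per-cell migration metrics from a track
#'
#' @param positions numeric matrix (timepoints x 3) of sampled positions in
#'   um.
#' @param times sampling times in minutes (strictly increasing, one per
#'   row).
#' @param voxel_spacing lattice spacing (um) used for the scanning rate.
#' @return one-row `data.frame` with `total_displacement`,
#'   `net_displacement`, `velocity`, `motility_coefficient`,
#'   `meandering_index`, `scanning_rate`.
#' @examples
#' pos <- cbind(0:10 * 2, 0, 0) # straight line, 2 um/min
#' compute_metrics(pos, 0:10)
#' @export
compute_metrics <- function(positions, times, voxel_spacing = 10) {
  positions <- as.matrix(positions)
  nt <- nrow(positions)
  if (nt < 2L) stop("a track needs at least two timepoints")
  if (length(times) != nt) stop("times and positions lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  steps <- diff(positions)
  total <- sum(sqrt(rowSums(steps^2)))
  net <- sqrt(sum((positions[nt, ] - positions[1, ])^2))
  elapsed <- times[nt] - times[1]
  vel <- if (total > 0) total / elapsed else 0
  mc <- net^2 / (6 * elapsed)
  mi <- if (total > 0) sqrt(elapsed) * net / total else 0
  vox <- unique(floor(positions / voxel_spacing))
  data.frame(
    total_displacement = total, net_displacement = net, velocity = vel,
    motility_coefficient = mc, meandering_index = mi,
    scanning_rate = nrow(vox)
  )
}

#' Median and quartiles of per-cell metrics
#'
#' @param metrics data.frame of per-cell metrics ([compute_metrics()] rows).
#' @return data.frame with one row per metric: `median`, `q1`, `q3`.
#' @export
summarize_metrics <- function(metrics) {
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  out <- t(vapply(num, function(x) {
    stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  }, numeric(3)))
  data.frame(metric = rownames(out), median = out[, 1], q1 = out[, 2],
             q3 = out[, 3], row.names = NULL)
}

#' Write per-cell metrics and the run summary
#'
#' Writes `<prefix>_metrics.csv` (per cell) and `<prefix>_summary.json`
#' (medians and quartiles in `median [q1 - q3]` form).
#'
#' @param run a `follisim_run`.
#' @param prefix output path prefix.
#' @export
write_run_summary <- function(run, prefix) {
  utils::write.csv(run$metrics, paste0(prefix, "_metrics.csv"),
                   row.names = FALSE)
  s <- run$summary
  jsonlite::write_json(
    stats::setNames(
      lapply(seq_len(nrow(s)), function(i) {
        list(median = s$median[i], q1 = s$q1[i], q3 = s$q3[i],
             printed = sprintf("%.3g [%.3g - %.3g]", s$median[i], s$q1[i],
                               s$q3[i]))
      }), s$metric),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}
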