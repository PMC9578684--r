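# Displacement analytics over tracked soma positions: interval distances,
# cumulative displacement (path length and net), cohort distributions and
# the displacement-to-electrode-pitch relation.

#' Interval displacements of one trajectory
#'
#' Euclidean distance between consecutive samples.
#'
#' @param traj A `trajectory`.
#' @return Data frame with columns `dpi_from`, `dpi_to`, `distance_um`
#'   (empty when the trajectory has fewer than two samples).
#' @export
interval_displacements <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  if (nrow(s) < 2L)
    return(data.frame(dpi_from = integer(), dpi_to = integer(),
                      distance_um = numeric()))
  d <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  data.frame(dpi_from = s$dpi[-nrow(s)], dpi_to = s$dpi[-1L],
             distance_um = d)
}

#' Cumulative displacement of one trajectory
#'
#' `path_length` sums the consecutive interval distances; `net` is the
#' straight-line distance from the first to the last sample. Path length
#' always dominates net displacement (triangle inequality).
#'
#' @param traj A `trajectory`.
#' @param mode `"path_length"` or `"net"`.
#' @return Distance in micrometres.
#' @export
cumulative_displacement <- function(traj, mode = c("path_length", "net")) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  s <- traj$samples
  if (nrow(s) < 2L) return(0)
  if (mode == "path_length")
    sum(interval_displacements(traj)$distance_um)
  else
    sqrt((s$x[nrow(s)] - s$x[1L])^2 + (s$y[nrow(s)] - s$y[1L])^2)
}

#' Distribution of cumulative displacements across a cohort
#'
#' Percentage of neurons whose cumulative displacement falls in each
#' half-open bin `[lo, hi)`.
#'
#' @param cohort List of `trajectory` objects (>= 1).
#' @param bin_edges Strictly increasing edges in micrometres; the final
#'   edge may be `Inf`.
#' @param mode Cumulative mode, see [cumulative_displacement()].
#' @return Named numeric vector of percentages, one per bin.
#' @export
displacement_distribution <- function(cohort, bin_edges = c(0, 50, 200, Inf),
                                      mode = c("path_length", "net")) {
  mode <- match.arg(mode)
  if (!length(cohort)) stop("cohort must contain at least one trajectory")
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 values")
  vals <- vapply(cohort, cumulative_displacement, numeric(1), mode = mode)
  idx <- findInterval(vals, bin_edges, left.open = FALSE)
  idx <- idx[idx >= 1L & idx < length(bin_edges)]
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  pct <- 100 * counts / length(vals)
  names(pct) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                       bin_edges[-1L], ")")
  pct
}

#' Displacement expressed in electrode pitches
#'
#' Number of whole electrode pitches covered by a mean displacement:
#' `floor(mean_displacement / pitch)`. A 224 micrometre average shift at a
#' 17 micrometre pitch crosses 13 electrodes.
#'
#' @param mean_displacement Mean displacement in micrometres.
#' @param pitch Electrode pitch in micrometres (> 0).
#' @return Integer electrode count.
#' @export
displacement_in_pitches <- function(mean_displacement, pitch) {
  if (!is.numeric(pitch) || pitch <= 0) stop("pitch must be > 0")
  as.integer(floor(mean_displacement / pitch))
}

#' Cohort displacement report
#'
#' Per-neuron interval distances, cumulative path length and net
#' displacement, plus cohort mean and SEM per dpi interval. Both
#' cumulative modes are always reported because "cumulative displacement"
#' is ambiguous between them; the columns are labelled explicitly.
#'
#' @param cohort List of `trajectory` objects.
#' @return List with `per_neuron` (data frame: `neuron_id`,
#'   `path_length_um`, `net_um`), `per_interval` (long data frame of
#'   interval distances) and `interval_summary` (mean, SEM and n per dpi
#'   pair).
#' @export
displacement_report <- function(cohort) {
  if (!length(cohort)) stop("cohort must contain at least one trajectory")
  per_neuron <- data.frame(
    neuron_id = vapply(cohort, function(t) t$neuron_id, character(1)),
    path_length_um = vapply(cohort, cumulative_displacement, numeric(1),
                            mode = "path_length"),
    net_um = vapply(cohort, cumulative_displacement, numeric(1),
                    mode = "net"),
    stringsAsFactors = FALSE)
  per_interval <- do.call(rbind, lapply(cohort, function(t) {
    d <- interval_displacements(t)
    if (nrow(d)) cbind(neuron_id = t$neuron_id, d) else NULL
  }))
  if (is.null(per_interval))
    per_interval <- data.frame(neuron_id = character(), dpi_from = integer(),
                               dpi_to = integer(), distance_um = numeric())
  key <- interaction(per_interval$dpi_from, per_interval$dpi_to, drop = TRUE)
  interval_summary <- if (nrow(per_interval)) {
    do.call(rbind, lapply(split(per_interval, key), function(g) {
      s <- summarize_mean_sem(g$distance_um)
      data.frame(dpi_from = g$dpi_from[1L], dpi_to = g$dpi_to[1L],
                 mean_um = s$mean, sem_um = s$sem, n = nrow(g))
    }))
  } else {
    data.frame(dpi_from = integer(), dpi_to = integer(), mean_um = numeric(),
               sem_um = numeric(), n = integer())
  }
  rownames(interval_summary) <- NULL
  list(per_neuron = per_neuron, per_interval = per_interval,
       interval_summary = interval_summary)
}
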