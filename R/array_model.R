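# HD-MEA geometry, active-electrode criteria, block-wise full-scan
# emulation, top-K electrode selection and activity-map frames.
# Electrodes are indexed 0-based and row-major with the origin at the
# top-left corner; y increases downward (image convention) so maps overlay
# microscopy frames directly.

#' Electrode grid geometry
#'
#' Defaults describe a 120 x 220 array at 17.5 micrometre centre-to-centre
#' pitch (26,400 electrodes covering 3.85 x 2.10 mm).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param pitch Centre-to-centre electrode pitch in micrometres.
#' @return An object of class `electrode_grid`.
#' @export
electrode_grid <- function(n_rows = 120L, n_cols = 220L, pitch = 17.5) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (!is.numeric(pitch) || pitch <= 0) stop("pitch must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 total = n_rows * n_cols),
            class = "electrode_grid")
}

#' Physical position of electrodes on the grid
#'
#' Row-major, 0-based indexing: `x = col * pitch`, `y = row * pitch`.
#'
#' @param grid An [electrode_grid()].
#' @param index Integer vector of 0-based electrode indices.
#' @return Data frame with columns `index`, `row`, `col`, `x_um`, `y_um`.
#' @export
electrode_position <- function(grid, index) {
  stopifnot(inherits(grid, "electrode_grid"))
  index <- as.integer(index)
  if (any(index < 0L | index >= grid$total))
    stop(sprintf("electrode index out of range [0, %d)", grid$total))
  row <- index %/% grid$n_cols
  col <- index %% grid$n_cols
  data.frame(index = index, row = row, col = col,
             x_um = col * grid$pitch, y_um = row * grid$pitch)
}

#' Bounding box of the sensor area
#'
#' Uses the cell model `count * pitch` per side, so the default grid spans
#' 3.85 x 2.10 mm.
#'
#' @param grid An [electrode_grid()].
#' @return Named vector `c(width_um, height_um)`.
#' @export
sensor_bounding_box <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  c(width_um = grid$n_cols * grid$pitch, height_um = grid$n_rows * grid$pitch)
}

#' Per-electrode activity map for one session frame
#'
#' @param grid An [electrode_grid()].
#' @param firing_rate Numeric vector of per-electrode rates (Hz), length
#'   `grid$total`.
#' @param mean_amplitude Numeric vector of per-electrode mean spike
#'   amplitudes (microvolts), same length.
#' @param frame_label Integer dpi label of the frame.
#' @return An object of class `activity_map`.
#' @export
activity_map <- function(grid, firing_rate, mean_amplitude,
                         frame_label = NA_integer_) {
  stopifnot(inherits(grid, "electrode_grid"))
  firing_rate <- as.numeric(firing_rate)
  mean_amplitude <- as.numeric(mean_amplitude)
  if (length(firing_rate) != grid$total || length(mean_amplitude) != grid$total)
    stop("firing_rate and mean_amplitude must have one entry per electrode")
  if (any(firing_rate < 0, na.rm = TRUE)) stop("rates must be >= 0")
  structure(list(grid = grid, firing_rate = firing_rate,
                 mean_amplitude = mean_amplitude,
                 frame_label = as.integer(frame_label)),
            class = "activity_map")
}

#' Active-electrode mask
#'
#' An electrode is active when its AP frequency is strictly above
#' `min_rate` AND its mean amplitude strictly above `min_amp`.
#'
#' @param map An [activity_map()].
#' @param min_rate Rate threshold, Hz (default 0.1).
#' @param min_amp Amplitude threshold, microvolts (default 20).
#' @return Logical vector, one entry per electrode.
#' @export
active_electrode_mask <- function(map, min_rate = 0.1, min_amp = 20) {
  stopifnot(inherits(map, "activity_map"))
  map$firing_rate > min_rate & map$mean_amplitude > min_amp
}

#' Select the most active electrodes
#'
#' Active electrodes sorted by firing rate descending (ties broken by
#' ascending electrode index); at most `k` are returned, fewer when fewer
#' are active.
#'
#' @param map An [activity_map()].
#' @param mask Logical active mask (default from
#'   [active_electrode_mask()]).
#' @param k Maximum number of electrodes (default 1024).
#' @return Integer vector of 0-based electrode indices, most active first.
#' @export
select_top_k <- function(map, mask = active_electrode_mask(map), k = 1024L) {
  stopifnot(inherits(map, "activity_map"))
  k <- as.integer(k)
  if (k <= 0L) stop("k must be > 0")
  idx <- which(mask) - 1L
  if (!length(idx)) return(integer())
  o <- order(-map$firing_rate[idx + 1L], idx)
  utils::head(idx[o], k)
}

#' Full-scan configuration
#'
#' @param block_size Electrodes recorded simultaneously per block
#'   (default 1000).
#' @param dwell Recording time per block in seconds (default 30).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(block_size = 1000L, dwell = 30) {
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1")
  if (!is.numeric(dwell) || dwell <= 0) stop("dwell must be > 0")
  structure(list(block_size = block_size, dwell = dwell),
            class = "scan_config")
}

#' Emulate a block-wise full scan of the array
#'
#' Partitions all electrode indices into `ceiling(total / block_size)`
#' consecutive blocks, block `i` recorded during
#' `[i * dwell, (i + 1) * dwell)`. Every electrode appears exactly once.
#'
#' @param grid An [electrode_grid()].
#' @param scan A [scan_config()].
#' @return Data frame with columns `electrode`, `block`, `t_start`,
#'   `t_end`.
#' @export
emulate_full_scan <- function(grid, scan = scan_config()) {
  stopifnot(inherits(grid, "electrode_grid"), inherits(scan, "scan_config"))
  electrode <- seq_len(grid$total) - 1L
  block <- electrode %/% scan$block_size
  data.frame(electrode = electrode, block = block,
             t_start = block * scan$dwell, t_end = (block + 1) * scan$dwell)
}

#' Build an activity map from a session with electrode assignments
#'
#' Each electrode's rate is the sum of the AP frequencies of the units
#' assigned to it; its amplitude is the mean of the units' amplitudes
#' (0 where no unit provides one). Rates are stored unnormalized;
#' normalization, if any, belongs to export/rendering.
#'
#' @param session A `recording_session` whose units carry
#'   `electrode_index`.
#' @param grid An [electrode_grid()].
#' @return An [activity_map()] labelled with the session's dpi.
#' @export
map_from_session <- function(session, grid = electrode_grid()) {
  stopifnot(inherits(session, "recording_session"),
            inherits(grid, "electrode_grid"))
  rate <- numeric(grid$total)
  amp_sum <- numeric(grid$total)
  amp_n <- integer(grid$total)
  for (u in session$units) {
    e <- u$electrode_index
    if (is.na(e)) stop(sprintf("unit %s has no electrode_index",
                               u$train$unit_id))
    if (e < 0L || e >= grid$total)
      stop(sprintf("electrode index %d of unit %s outside grid [0, %d)",
                   e, u$train$unit_id, grid$total))
    rate[e + 1L] <- rate[e + 1L] + ap_frequency(u$train)
    if (!is.na(u$amplitude)) {
      amp_sum[e + 1L] <- amp_sum[e + 1L] + u$amplitude
      amp_n[e + 1L] <- amp_n[e + 1L] + 1L
    }
  }
  amp <- ifelse(amp_n > 0L, amp_sum / pmax(amp_n, 1L), 0)
  activity_map(grid, rate, amp, frame_label = session$dpi)
}
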