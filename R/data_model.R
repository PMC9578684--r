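# Core domain objects: spike trains, unit records, recording sessions and
# soma trajectories, plus CSV readers/writers for the exchange formats.
# Conventions: time in seconds, coordinates in micrometres, developmental
# age as integer days post induction (dpi). Recording windows are half-open
# [t_start, t_stop), so rate denominators are unambiguous.

#' Construct a spike train
#'
#' A spike train holds the sorted spike times of one unit over a known
#' recording window. Times must be strictly increasing and lie inside the
#' half-open window `[t_start, t_stop)`.
#'
#' @param unit_id Character scalar identifying the unit.
#' @param times Numeric vector of spike times in seconds (may be empty).
#' @param t_start,t_stop Recording window in seconds; `t_stop > t_start`.
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' st <- spike_train("u1", c(0.5, 1.2, 3.0), t_stop = 300)
#' n_spikes(st)
spike_train <- function(unit_id, times = numeric(), t_start = 0, t_stop) {
  if (!is.character(unit_id) || length(unit_id) != 1L || is.na(unit_id))
    stop("unit_id must be a single character string")
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (!is.numeric(t_start) || !is.numeric(t_stop) || !(t_stop > t_start))
    stop("t_stop must be greater than t_start")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1L] < t_start || times[length(times)] >= t_stop))
    stop("spike times must lie in [t_start, t_stop)")
  structure(
    list(unit_id = unit_id, times = times,
         t_start = as.numeric(t_start), t_stop = as.numeric(t_stop)),
    class = "spike_train"
  )
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' @rdname spike_train
#' @export
train_duration <- function(x) x$t_stop - x$t_start

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes in [%g, %g) s\n",
              x$unit_id, n_spikes(x), x$t_start, x$t_stop))
  invisible(x)
}

#' Construct a unit record
#'
#' Bundles a spike train with the quality-control attributes used for
#' automated curation (ISI-violation rate, signal-to-noise ratio, firing
#' rate) and an optional electrode assignment and mean spike amplitude.
#' QC attributes may be left `NA` at construction; curation requires them
#' (and recomputes what it can from the train). When a firing rate is
#' supplied it must agree with `count / (t_stop - t_start)` to 1e-9.
#'
#' @param train A `spike_train`.
#' @param isi_violation_rate Fraction of ISIs violating the refractory
#'   period, in `[0, 1]`, or `NA`.
#' @param snr Signal-to-noise ratio (dimensionless, >= 0) or `NA`.
#' @param firing_rate Mean firing rate in Hz or `NA`.
#' @param electrode_index Optional 0-based electrode index.
#' @param amplitude Optional mean spike amplitude in microvolts.
#' @return An object of class `unit_record`.
#' @export
unit_record <- function(train, isi_violation_rate = NA_real_, snr = NA_real_,
                        firing_rate = NA_real_, electrode_index = NA_integer_,
                        amplitude = NA_real_) {
  if (!inherits(train, "spike_train")) stop("train must be a spike_train")
  isi_violation_rate <- as.numeric(isi_violation_rate)
  if (!is.na(isi_violation_rate) &&
      (isi_violation_rate < 0 || isi_violation_rate > 1))
    stop("isi_violation_rate must lie in [0, 1]")
  snr <- as.numeric(snr)
  if (!is.na(snr) && snr < 0) stop("snr must be >= 0")
  firing_rate <- as.numeric(firing_rate)
  if (!is.na(firing_rate)) {
    if (firing_rate < 0) stop("firing_rate must be >= 0")
    expected <- n_spikes(train) / train_duration(train)
    if (abs(firing_rate - expected) > 1e-9)
      stop(sprintf(
        "firing_rate (%.10g Hz) inconsistent with train (%.10g Hz) for unit %s",
        firing_rate, expected, train$unit_id))
  }
  structure(
    list(train = train, isi_violation_rate = isi_violation_rate, snr = snr,
         firing_rate = firing_rate,
         electrode_index = as.integer(electrode_index),
         amplitude = as.numeric(amplitude)),
    class = "unit_record"
  )
}

#' Construct a recording session
#'
#' One simultaneous network recording: a set of unit records sharing the
#' window `[0, duration)`, annotated with culture age (dpi) and an
#' experimental condition.
#'
#' @param units List of `unit_record` objects with unique unit ids.
#' @param duration Recording duration in seconds.
#' @param session_id Character scalar label.
#' @param dpi Integer days post induction (or `NA`).
#' @param condition One of `"baseline"`, `"treatment"`, `"washout"`, `"none"`.
#' @param drug Optional drug label for treatment sessions.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(units = list(), duration, session_id = "session",
                              dpi = NA_integer_, condition = "none",
                              drug = NULL) {
  condition <- match.arg(condition, c("baseline", "treatment", "washout", "none"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.list(units) || !all(vapply(units, inherits, logical(1), "unit_record")))
    stop("units must be a list of unit_record objects")
  ids <- vapply(units, function(u) u$train$unit_id, character(1))
  if (anyDuplicated(ids)) stop("unit ids must be unique within a session")
  for (u in units) {
    if (u$train$t_start != 0 || u$train$t_stop != duration)
      stop(sprintf("unit %s window [%g, %g) does not match session [0, %g)",
                   u$train$unit_id, u$train$t_start, u$train$t_stop, duration))
  }
  names(units) <- ids
  structure(
    list(session_id = session_id, dpi = as.integer(dpi), condition = condition,
         drug = drug, units = units, duration = as.numeric(duration)),
    class = "recording_session"
  )
}

#' @rdname recording_session
#' @param x A `recording_session`.
#' @export
n_units <- function(x) length(x$units)

#' @rdname recording_session
#' @export
unit_ids <- function(x) names(x$units)

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %s: %d units, %g s, dpi %s, condition %s\n",
              x$session_id, n_units(x), x$duration,
              ifelse(is.na(x$dpi), "?", x$dpi), x$condition))
  invisible(x)
}

#' Construct a soma trajectory
#'
#' The tracked position of one neuronal soma (or the centroid of the
#' cluster it joined) across imaging time points.
#'
#' @param neuron_id Character scalar track label.
#' @param dpi Integer vector of days post induction, strictly increasing.
#' @param x,y Numeric coordinates in micrometres, same length as `dpi`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(neuron_id, dpi, x, y) {
  if (!is.character(neuron_id) || length(neuron_id) != 1L)
    stop("neuron_id must be a single character string")
  dpi <- as.integer(dpi)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(dpi) < 1L) stop("a trajectory needs at least one sample")
  if (length(x) != length(dpi) || length(y) != length(dpi))
    stop("dpi, x and y must have equal length")
  if (anyNA(dpi) || anyNA(x) || anyNA(y)) stop("trajectory samples must be finite")
  if (length(dpi) > 1L && any(diff(dpi) <= 0))
    stop("dpi must be strictly increasing")
  structure(list(neuron_id = neuron_id,
                 samples = data.frame(dpi = dpi, x = x, y = y)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d samples, dpi %d-%d\n", x$neuron_id,
              nrow(x$samples), min(x$samples$dpi), max(x$samples$dpi)))
  invisible(x)
}

# ---- spike table CSV --------------------------------------------------------

.qc_cols <- c("isi_violation_rate", "snr", "firing_rate", "electrode_index")

#' Read a spike-time table into a recording session
#'
#' The canonical exchange format is a CSV with header
#' `unit_id,time_s` plus optional per-unit QC columns
#' `isi_violation_rate,snr,firing_rate,electrode_index` (constant within a
#' unit; the first row of each unit is used). Rows may appear in any order;
#' times are sorted ascending within each unit on load, and unit identity
#' order follows first appearance in the file.
#'
#' @param path CSV file path.
#' @param duration Recording duration in seconds; all times must lie in
#'   `[0, duration)`.
#' @param session_id,dpi,condition,drug Session annotations, see
#'   [recording_session()].
#' @return A `recording_session`.
#' @export
load_spike_table <- function(path, duration, session_id = basename(path),
                             dpi = NA_integer_, condition = "none",
                             drug = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("unit_id", "time_s")
  if (!all(required %in% names(df)))
    stop(sprintf("spike table must have columns %s",
                 paste(required, collapse = ", ")))
  if (nrow(df) == 0L)
    return(recording_session(list(), duration, session_id, dpi, condition, drug))

  t <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(t))
  if (length(bad))
    stop(sprintf("malformed time_s value '%s' at line %d of %s",
                 df$time_s[bad[1L]], bad[1L] + 1L, path))
  out <- which(t < 0 | t >= duration)
  if (length(out))
    stop(sprintf("spike time %.6f s at line %d outside [0, %g)",
                 t[out[1L]], out[1L] + 1L, duration))

  num_qc <- function(col, line_ok = TRUE) {
    if (!col %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(df[[col]]))
    blank <- !nzchar(trimws(df[[col]])) | toupper(trimws(df[[col]])) == "NA"
    bad <- which(is.na(v) & !blank)
    if (length(bad))
      stop(sprintf("malformed %s value '%s' at line %d", col,
                   df[[col]][bad[1L]], bad[1L] + 1L))
    v
  }
  qc <- lapply(stats::setNames(.qc_cols, .qc_cols), num_qc)

  ids <- unique(df$unit_id)  # first-appearance order preserved
  units <- lapply(ids, function(id) {
    sel <- which(df$unit_id == id)
    st <- spike_train(id, sort(t[sel]), t_start = 0, t_stop = duration)
    first <- sel[1L]
    unit_record(
      st,
      isi_violation_rate = if (is.null(qc$isi_violation_rate)) NA_real_ else qc$isi_violation_rate[first],
      snr = if (is.null(qc$snr)) NA_real_ else qc$snr[first],
      firing_rate = if (is.null(qc$firing_rate)) NA_real_ else qc$firing_rate[first],
      electrode_index = if (is.null(qc$electrode_index)) NA_integer_ else as.integer(qc$electrode_index[first])
    )
  })
  recording_session(units, duration, session_id, dpi, condition, drug)
}

#' Write a recording session as a spike-time table
#'
#' Inverse of [load_spike_table()]: rows are grouped by unit in session
#' order with times ascending, and times are printed with nine decimal
#' places (nanosecond resolution). QC columns are emitted whenever any
#' unit carries a QC attribute.
#'
#' @param session A `recording_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  has_qc <- any(vapply(session$units, function(u) {
    !is.na(u$isi_violation_rate) || !is.na(u$snr) ||
      !is.na(u$firing_rate) || !is.na(u$electrode_index)
  }, logical(1)))
  header <- c("unit_id", "time_s", if (has_qc) .qc_cols)
  fmt9 <- function(v) ifelse(is.na(v), "", sprintf("%.9f", v))
  rows <- unlist(lapply(session$units, function(u) {
    k <- n_spikes(u$train)
    if (k == 0L) return(character())
    base <- paste(u$train$unit_id, sprintf("%.9f", u$train$times), sep = ",")
    if (has_qc) {
      qc <- paste(fmt9(u$isi_violation_rate), fmt9(u$snr), fmt9(u$firing_rate),
                  ifelse(is.na(u$electrode_index), "", u$electrode_index),
                  sep = ",")
      base <- paste(base, qc, sep = ",")
    }
    base
  }), use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con)
  invisible(path)
}

# ---- tracking table CSV -----------------------------------------------------

#' Read a soma-tracking table
#'
#' Accepts two dialects: the native header `track_id,dpi,x_um,y_um`
#' (coordinates already in micrometres) and the ImageJ Manual Tracking
#' export (`Track n°, Slice n°, X, Y`), which requires a slice-to-dpi map
#' and, when coordinates are in pixels, a pixel size in micrometres per
#' pixel. One `trajectory` is returned per track, samples ordered by dpi.
#'
#' @param path CSV file path.
#' @param pixel_size Micrometres per pixel applied to the coordinates
#'   (`NULL` means coordinates are already micrometres).
#' @param slice_to_dpi Named vector or list mapping slice numbers (names)
#'   to dpi values; required for the ImageJ dialect.
#' @return A named list of `trajectory` objects.
#' @export
load_tracking_table <- function(path, pixel_size = NULL, slice_to_dpi = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  if (all(c("track_id", "dpi", "x_um", "y_um") %in% nm)) {
    track <- as.character(df$track_id)
    dpi <- df$dpi; xs <- df$x_um; ys <- df$y_um
  } else {
    tcol <- grep("^Track", nm, value = TRUE)
    scol <- grep("^Slice", nm, value = TRUE)
    if (length(tcol) != 1L || length(scol) != 1L ||
        !all(c("X", "Y") %in% nm))
      stop("unrecognized tracking table header; expected track_id,dpi,x_um,y_um or the ImageJ Manual Tracking columns")
    if (is.null(slice_to_dpi))
      stop("the ImageJ dialect requires a slice_to_dpi map")
    track <- as.character(df[[tcol]])
    slice <- as.character(df[[scol]])
    map <- unlist(slice_to_dpi)
    unknown <- setdiff(unique(slice), names(map))
    if (length(unknown))
      stop(sprintf("slice %s missing from slice_to_dpi map", unknown[1L]))
    dpi <- unname(map[slice])
    xs <- df$X; ys <- df$Y
  }
  check_num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric %s value '%s' at line %d", what,
                   as.character(v)[bad[1L]], bad[1L] + 1L))
    out
  }
  dpi <- check_num(dpi, "dpi")
  xs <- check_num(xs, "x"); ys <- check_num(ys, "y")
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), pixel_size > 0)
    xs <- xs * pixel_size; ys <- ys * pixel_size
  }
  if (anyDuplicated(paste(track, dpi)))
    stop("duplicate (track, dpi) rows in tracking table")
  ids <- unique(track)
  out <- lapply(ids, function(id) {
    sel <- which(track == id)
    o <- order(dpi[sel])
    trajectory(id, dpi[sel][o], xs[sel][o], ys[sel][o])
  })
  stats::setNames(out, ids)
}

#' Read a run configuration file
#'
#' JSON (`.json`) or YAML (anything else) configuration declaring e.g.
#' coordinate units, pixel size and the slice-to-dpi mapping used by
#' [load_tracking_table()].
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
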