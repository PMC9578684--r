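# Poisson-surprise burst detection with surprise maximization.
#
# The surprise of a window of duration T containing N spikes from a unit
# firing at mean rate lambda is S = -log P, where P is the probability
# that a homogeneous Poisson process at rate lambda produces N or more
# spikes in T (the upper Poisson tail). Bursts are grown from triplets of
# unusually short ISIs, extended while ISIs stay at or below the mean ISI,
# and the extension length maximizing S is kept, subject to minimum
# surprise, duration and spike-count thresholds.

#' Surprise-detector parameters
#'
#' Defaults follow the standard surprise-method settings for cultured
#' networks: minimum surprise 4 (natural log, i.e. tail probability below
#' about e^-4), minimum burst duration 20 ms and at least 4 spikes.
#'
#' @param min_surprise Minimum surprise of an emitted burst.
#' @param min_duration Minimum burst duration in seconds (first to last
#'   spike).
#' @param min_spikes Minimum number of spikes in a burst (>= 2).
#' @param seed_isi_factor A burst candidate starts where both ISIs of
#'   three consecutive spikes fall below this fraction of the train's mean
#'   ISI (default 0.5).
#' @param extension_isi_factor Spikes are appended while the next ISI does
#'   not exceed this fraction of the mean ISI (default 1).
#' @param log_base `"natural"` (default) or `"base10"` for the surprise
#'   logarithm.
#' @param refine_start Also maximize the surprise over trailing
#'   subwindows, allowing leading spikes of the candidate to be shed
#'   (off by default).
#' @return An object of class `surprise_params`.
#' @export
surprise_params <- function(min_surprise = 4, min_duration = 0.020,
                            min_spikes = 4L, seed_isi_factor = 0.5,
                            extension_isi_factor = 1.0,
                            log_base = c("natural", "base10"),
                            refine_start = FALSE) {
  log_base <- match.arg(log_base)
  min_spikes <- as.integer(min_spikes)
  if (min_spikes < 2L) stop("min_spikes must be >= 2")
  if (seed_isi_factor <= 0 || extension_isi_factor <= 0)
    stop("ISI factors must be > 0")
  if (min_surprise < 0 || min_duration < 0)
    stop("min_surprise and min_duration must be >= 0")
  structure(list(min_surprise = min_surprise, min_duration = min_duration,
                 min_spikes = min_spikes, seed_isi_factor = seed_isi_factor,
                 extension_isi_factor = extension_isi_factor,
                 log_base = log_base, refine_start = refine_start),
            class = "surprise_params")
}

#' Poisson surprise of a spike-count window
#'
#' `S = -log P(X >= N)` for `X ~ Poisson(rate * window)`, evaluated via
#' the numerically stable log upper-tail routine (the regularized
#' incomplete gamma function underlying `ppois`). Vectorized over
#' `n_spikes` and `window`. `S = 0` when `N = 0` (the whole distribution).
#'
#' @param n_spikes Spike count N (>= 0).
#' @param window Window duration T in seconds (> 0).
#' @param rate Mean firing rate lambda in Hz (> 0).
#' @param log_base `"natural"` or `"base10"`.
#' @return Surprise value(s), dimensionless, >= 0.
#' @export
#' @examples
#' poisson_surprise(5, 0.1, 10)  # about 5.61 nats
poisson_surprise <- function(n_spikes, window, rate,
                             log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  if (any(rate <= 0)) stop("rate must be > 0: surprise is undefined")
  if (any(window <= 0)) stop("window must be > 0: surprise is undefined")
  n_spikes <- as.numeric(n_spikes)
  if (any(n_spikes < 0)) stop("n_spikes must be >= 0")
  s <- -stats::ppois(n_spikes - 1, rate * window,
                     lower.tail = FALSE, log.p = TRUE)
  if (log_base == "base10") s <- s / log(10)
  pmax(s, 0)
}

# surprise over candidate window ends; shared by detector and summary
.candidate_best <- function(times, i, E, lambda, params) {
  first_end <- i + params$min_spikes - 1L
  if (first_end > E) return(NULL)
  ends <- seq.int(first_end, E)
  S <- poisson_surprise(ends - i + 1L, times[ends] - times[i], lambda,
                        params$log_base)
  k <- which.max(S)  # ties: first index = shortest extension
  list(end = ends[k], surprise = S[k])
}

#' Detect bursts in a spike train by surprise maximization
#'
#' Scanning left to right, a candidate burst starts at the first of three
#' consecutive spikes whose two ISIs both fall below
#' `seed_isi_factor * mean ISI`. Spikes are appended while the next ISI is
#' at most `extension_isi_factor * mean ISI`. The surprise is evaluated at
#' every candidate length of at least `min_spikes` (window T spanning
#' first to last candidate spike; lambda is the whole-train mean rate,
#' count / recording duration) and the length maximizing S is selected,
#' ties going to the shortest extension. The candidate is emitted only if
#' it meets the minimum surprise, duration and spike count; scanning then
#' resumes after the burst end (after a rejected candidate, at the next
#' spike). Emitted bursts are disjoint and time-ordered.
#'
#' @param train A `spike_train`.
#' @param params A [surprise_params()] object.
#' @return Data frame with columns `unit_id`, `t_start`, `t_end`,
#'   `n_spikes`, `surprise`, plus attribute `spike_index` (list of the
#'   member-spike index ranges).
#' @export
detect_bursts <- function(train, params = surprise_params()) {
  stopifnot(inherits(train, "spike_train"),
            inherits(params, "surprise_params"))
  empty <- data.frame(unit_id = character(), t_start = numeric(),
                      t_end = numeric(), n_spikes = integer(),
                      surprise = numeric(), stringsAsFactors = FALSE)
  attr(empty, "spike_index") <- list()
  times <- train$times
  n <- length(times)
  if (n < max(params$min_spikes, 3L)) return(empty)
  isi <- diff(times)
  mean_isi <- mean(isi)
  lambda <- n / train_duration(train)
  seed_th <- params$seed_isi_factor * mean_isi
  ext_th <- params$extension_isi_factor * mean_isi

  starts <- ends <- integer(); surprises <- numeric()
  i <- 1L
  while (i <= n - 2L) {
    if (isi[i] < seed_th && isi[i + 1L] < seed_th) {
      E <- i + 2L
      while (E < n && isi[E] <= ext_th) E <- E + 1L
      best <- .candidate_best(times, i, E, lambda, params)
      if (!is.null(best)) {
        j <- best$end; smax <- best$surprise
        if (params$refine_start && j - i + 1L > params$min_spikes) {
          # shed leading spikes if a trailing subwindow is more surprising
          for (s2 in seq.int(i + 1L, j - params$min_spikes + 1L)) {
            s_val <- poisson_surprise(j - s2 + 1L, times[j] - times[s2],
                                      lambda, params$log_base)
            if (s_val > smax) { smax <- s_val; i <- s2 }
          }
        }
        dur <- times[j] - times[i]
        if (smax >= params$min_surprise && dur >= params$min_duration &&
            (j - i + 1L) >= params$min_spikes) {
          starts <- c(starts, i); ends <- c(ends, j)
          surprises <- c(surprises, smax)
          i <- j + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  out <- data.frame(unit_id = rep(train$unit_id, length(starts)),
                    t_start = times[starts], t_end = times[ends],
                    n_spikes = ends - starts + 1L, surprise = surprises,
                    stringsAsFactors = FALSE)
  attr(out, "spike_index") <- Map(seq.int, starts, ends)
  out
}

#' Detect bursts in every unit of a session
#'
#' @param session A `recording_session`.
#' @param params A [surprise_params()] object.
#' @return One data frame of bursts across units (columns as in
#'   [detect_bursts()]).
#' @export
detect_session_bursts <- function(session, params = surprise_params()) {
  stopifnot(inherits(session, "recording_session"))
  per_unit <- lapply(session$units, function(u) detect_bursts(u$train, params))
  out <- do.call(rbind, c(per_unit, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(unit_id = character(), t_start = numeric(),
                      t_end = numeric(), n_spikes = integer(),
                      surprise = numeric(), stringsAsFactors = FALSE)
  out
}

#' Summarize the burst activity of one unit
#'
#' Burst frequency is bursts per second of recording; the mean burst
#' duration is undefined (NA, flagged) when there are no bursts; the
#' percentage of APs in bursts is the share of all the unit's spikes that
#' fall inside burst events.
#'
#' @param train A `spike_train`.
#' @param bursts Data frame from [detect_bursts()] for this train.
#' @return One-row data frame: `unit_id`, `n_bursts`, `burst_frequency`
#'   (Hz), `mean_burst_duration` (s, NA when no bursts),
#'   `pct_aps_in_burst` (percent).
#' @export
burst_summary <- function(train, bursts) {
  stopifnot(inherits(train, "spike_train"), is.data.frame(bursts))
  if (nrow(bursts) && !all(bursts$unit_id == train$unit_id))
    stop("bursts do not belong to this train")
  nb <- nrow(bursts)
  total <- n_spikes(train)
  inside <- if (nb) sum(bursts$n_spikes) else 0L  # bursts are disjoint
  data.frame(
    unit_id = train$unit_id,
    n_bursts = nb,
    burst_frequency = nb / train_duration(train),
    mean_burst_duration = if (nb) mean(bursts$t_end - bursts$t_start) else NA_real_,
    pct_aps_in_burst = if (total) 100 * inside / total else 0,
    stringsAsFactors = FALSE)
}

#' Network-burst detection configuration
#'
#' A network burst is an epoch where single-unit bursts co-occur across a
#' sufficient number of active units: time is binned, and bins where at
#' least `max(min_units_absolute, ceiling(min_unit_fraction * n_active))`
#' units have an ongoing burst are merged into network-burst intervals.
#'
#' @param bin_width Bin width in seconds (default 0.1).
#' @param min_unit_fraction Minimum fraction of active units bursting
#'   concurrently (default 0.2).
#' @param min_units_absolute Absolute minimum number of concurrently
#'   bursting units (default 5).
#' @return An object of class `network_burst_config`.
#' @export
network_burst_config <- function(bin_width = 0.1, min_unit_fraction = 0.2,
                                 min_units_absolute = 5L) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (min_unit_fraction <= 0 || min_unit_fraction > 1)
    stop("min_unit_fraction must lie in (0, 1]")
  structure(list(bin_width = bin_width, min_unit_fraction = min_unit_fraction,
                 min_units_absolute = as.integer(min_units_absolute)),
            class = "network_burst_config")
}

#' Detect network bursts from per-unit bursts
#'
#' @param session A curated `recording_session`.
#' @param bursts Data frame of per-unit bursts (from
#'   [detect_session_bursts()]).
#' @param cfg A [network_burst_config()] object.
#' @param min_rate Activity threshold used to count active units, Hz.
#' @return Data frame with columns `t_start`, `t_end`, `n_units`, and a
#'   list column `members` of participating unit ids; attribute
#'   `threshold_units` records the concurrency threshold used.
#' @export
detect_network_bursts <- function(session, bursts,
                                  cfg = network_burst_config(),
                                  min_rate = 0.1) {
  stopifnot(inherits(session, "recording_session"), is.data.frame(bursts),
            inherits(cfg, "network_burst_config"))
  n_active <- length(classify_active_units(session, min_rate)$active)
  thr <- max(cfg$min_units_absolute,
             as.integer(ceiling(cfg$min_unit_fraction * n_active)))
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      n_units = integer())
  empty$members <- list()
  attr(empty, "threshold_units") <- thr
  if (!nrow(bursts)) return(empty)

  bw <- cfg$bin_width
  n_bins <- as.integer(ceiling(session$duration / bw))
  # distinct (unit, bin) pairs for every bin a burst overlaps
  b0 <- pmin(pmax(floor(bursts$t_start / bw), 0), n_bins - 1L)
  b1 <- pmin(pmax(floor(bursts$t_end / bw), 0), n_bins - 1L)
  reps <- b1 - b0 + 1L
  pair_bin <- unlist(Map(seq.int, b0, b1), use.names = FALSE)
  pair_unit <- rep(bursts$unit_id, reps)
  keep <- !duplicated(paste(pair_unit, pair_bin))
  counts <- tabulate(pair_bin[keep] + 1L, nbins = n_bins)

  qual <- counts >= thr
  if (!any(qual)) return(empty)
  r <- rle(qual)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  sel <- which(r$values)
  t_start <- (run_start[sel] - 1L) * bw
  t_end <- pmin(run_end[sel] * bw, session$duration)
  members <- lapply(seq_along(sel), function(k) {
    ov <- bursts$t_start < t_end[k] & bursts$t_end > t_start[k]
    sort(unique(bursts$unit_id[ov]))
  })
  out <- data.frame(t_start = t_start, t_end = t_end,
                    n_units = lengths(members))
  out$members <- members
  attr(out, "threshold_units") <- thr
  out
}

#' Units participating in network bursts
#'
#' A unit participates when at least one of its bursts overlaps at least
#' one network-burst interval.
#'
#' @param session A `recording_session`.
#' @param network_bursts Data frame from [detect_network_bursts()].
#' @return List with `count` and the participating `unit_ids`.
#' @export
units_in_network_bursts <- function(session, network_bursts) {
  stopifnot(inherits(session, "recording_session"),
            is.data.frame(network_bursts))
  ids <- if (nrow(network_bursts))
    sort(unique(unlist(network_bursts$members, use.names = FALSE)))
  else character()
  list(count = length(ids), unit_ids = ids)
}
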