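# Action-potential frequency, frequency-domain histograms, instantaneous
# firing frequency (inverse ISI) and fast-spiking classification.

#' Mean action-potential frequency of a train
#'
#' Total spike count divided by the recording duration in seconds.
#'
#' @param train A `spike_train`.
#' @return Rate in Hz.
#' @export
ap_frequency <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n_spikes(train) / train_duration(train)
}

#' Per-unit AP frequencies of a session
#'
#' @param session A `recording_session`.
#' @return Named numeric vector of rates in Hz.
#' @export
session_ap_frequencies <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  vapply(session$units, function(u) ap_frequency(u$train), numeric(1))
}

#' Count units per firing-frequency domain
#'
#' Assigns each (by default, active) unit to exactly one half-open
#' frequency bin `[lo, hi)` by its AP frequency. The default edges
#' `c(0, 1, 2, 5, 10, Inf)` cover the sub-2 Hz and above-5 Hz classes
#' commonly reported for developing cultures; a unit exactly at an edge
#' falls in the higher bin.
#'
#' @param session A `recording_session`.
#' @param bin_edges Strictly increasing numeric vector of bin edges in Hz;
#'   the final edge may be `Inf`.
#' @param active_only Restrict to active units (rate > `min_rate`)?
#' @param min_rate Activity threshold in Hz when `active_only` is `TRUE`.
#' @return Named integer vector of counts, one per bin.
#' @export
frequency_domain_histogram <- function(session,
                                       bin_edges = c(0, 1, 2, 5, 10, Inf),
                                       active_only = TRUE, min_rate = 0.1) {
  stopifnot(inherits(session, "recording_session"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L) stop("at least two bin edges are required")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  rates <- session_ap_frequencies(session)
  if (active_only) rates <- rates[rates > min_rate]
  # findInterval with left-closed intervals: edge value goes to higher bin
  idx <- findInterval(rates, bin_edges, left.open = FALSE)
  idx <- idx[idx >= 1L & idx < length(bin_edges)]
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  names(counts) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                          bin_edges[-1L], ")")
  counts
}

#' Instantaneous firing frequencies of a train
#'
#' The instantaneous frequency of each AP pair is the inverse of its
#' interspike interval; the event is timestamped at the second spike of
#' the pair (an ISI is only known once its closing spike occurs). Trains
#' with fewer than two spikes yield an empty series.
#'
#' @param train A `spike_train`.
#' @return An object of class `inst_freq_series` with fields `unit_id`,
#'   `event_times` (s) and `event_freqs` (Hz).
#' @export
#' @examples
#' s <- instantaneous_frequencies(spike_train("u", c(0, 0.01, 0.02), t_stop = 1))
#' s$event_freqs  # 100 100
instantaneous_frequencies <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  isi <- diff(train$times)
  if (any(isi == 0)) stop("duplicate spike timestamps give a zero ISI")
  structure(list(unit_id = train$unit_id,
                 event_times = train$times[-1L],
                 event_freqs = if (length(isi)) 1 / isi else numeric()),
            class = "inst_freq_series")
}

#' Fast-spiking configuration
#'
#' @param fast_threshold Instantaneous frequency above which an event is
#'   "fast", Hz (strict; default 150).
#' @param upper_bound Upper plausibility bound, Hz (default 600); events
#'   above it still count as fast but are flagged.
#' @param neuron_fast_event_fraction Minimum fraction of fast events for a
#'   unit to be classified fast-spiking (inclusive; default 0.05).
#' @return An object of class `fast_spiking_config`.
#' @export
fast_spiking_config <- function(fast_threshold = 150, upper_bound = 600,
                                neuron_fast_event_fraction = 0.05) {
  if (!(fast_threshold > 0 && fast_threshold < upper_bound))
    stop("need 0 < fast_threshold < upper_bound")
  if (neuron_fast_event_fraction < 0 || neuron_fast_event_fraction > 1)
    stop("neuron_fast_event_fraction must lie in [0, 1]")
  structure(list(fast_threshold = fast_threshold, upper_bound = upper_bound,
                 neuron_fast_event_fraction = neuron_fast_event_fraction),
            class = "fast_spiking_config")
}

#' Fraction of fast spiking events in a series
#'
#' Fraction of instantaneous-frequency events strictly above the fast
#' threshold. An empty series returns 0 with attribute `no_events = TRUE`.
#' Events above the upper bound are included and counted in attribute
#' `n_above_upper`.
#'
#' @param series An `inst_freq_series`.
#' @param cfg A [fast_spiking_config()].
#' @return Fraction in `[0, 1]`.
#' @export
fast_event_fraction <- function(series, cfg = fast_spiking_config()) {
  stopifnot(inherits(series, "inst_freq_series"),
            inherits(cfg, "fast_spiking_config"))
  f <- series$event_freqs
  if (!length(f))
    return(structure(0, no_events = TRUE, n_above_upper = 0L))
  structure(mean(f > cfg$fast_threshold),
            no_events = FALSE,
            n_above_upper = sum(f > cfg$upper_bound))
}

#' Partition units into fast- and slow-spiking
#'
#' A unit is fast-spiking when at least `neuron_fast_event_fraction` of
#' its instantaneous-frequency events exceed the fast threshold
#' (inclusive at the fraction, strict at the frequency); all other units,
#' including those with fewer than two spikes, are slow.
#'
#' @param session A `recording_session`.
#' @param cfg A [fast_spiking_config()].
#' @return List with character vectors `fast` and `slow`, plus the
#'   per-unit fast-event fractions as `fractions`.
#' @export
classify_fast_units <- function(session, cfg = fast_spiking_config()) {
  stopifnot(inherits(session, "recording_session"))
  frac <- vapply(session$units, function(u) {
    as.numeric(fast_event_fraction(instantaneous_frequencies(u$train), cfg))
  }, numeric(1))
  fast <- frac >= cfg$neuron_fast_event_fraction
  list(fast = unit_ids(session)[fast], slow = unit_ids(session)[!fast],
       fractions = frac)
}

#' Mean instantaneous frequency per unit and for the session
#'
#' Each eligible unit (>= 2 spikes) contributes the mean of its
#' instantaneous-frequency events. The session aggregate averages over
#' units (each unit one value) with its SEM; averaging over pooled events
#' is available as an alternative.
#'
#' @param session A `recording_session`.
#' @param pool `"units"` (default) averages per-unit means; `"events"`
#'   averages all events pooled across units.
#' @return List with `per_unit` (named vector, Hz), `mean`, `sem` and `n`.
#' @export
mean_instantaneous_frequency <- function(session, pool = c("units", "events")) {
  stopifnot(inherits(session, "recording_session"))
  pool <- match.arg(pool)
  series <- lapply(session$units, function(u)
    instantaneous_frequencies(u$train))
  eligible <- vapply(series, function(s) length(s$event_freqs) > 0, logical(1))
  if (!any(eligible))
    stop("no unit has two or more spikes; mean instantaneous frequency undefined")
  per_unit <- vapply(series[eligible], function(s) mean(s$event_freqs),
                     numeric(1))
  if (pool == "units") {
    agg <- summarize_mean_sem(per_unit)
    list(per_unit = per_unit, mean = agg$mean, sem = agg$sem, n = length(per_unit))
  } else {
    ev <- unlist(lapply(series[eligible], `[[`, "event_freqs"),
                 use.names = FALSE)
    agg <- summarize_mean_sem(ev)
    list(per_unit = per_unit, mean = agg$mean, sem = agg$sem, n = length(ev))
  }
}
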