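# Automated post-sorting unit curation and the active-unit rule.
# Boundary semantics are deliberately strict and asymmetric: a unit is
# removed when its ISI-violation rate is ABOVE the threshold, its SNR is
# BELOW the minimum, or its firing rate is BELOW the minimum; a unit is
# active when its rate is strictly ABOVE the activity threshold.

#' Curation thresholds
#'
#' @param max_isi_violation Maximum tolerated ISI-violation fraction;
#'   units strictly above are removed. Default 0.2.
#' @param min_snr Minimum signal-to-noise ratio; units strictly below are
#'   removed. Default 5.
#' @param min_rate Minimum firing rate in Hz; units strictly below are
#'   removed. Default 0.1.
#' @param refractory_ms Refractory period in milliseconds used when the
#'   violation rate must be computed from the train. Default 1.5.
#' @return An object of class `curation_thresholds`.
#' @export
curation_thresholds <- function(max_isi_violation = 0.2, min_snr = 5,
                                min_rate = 0.1, refractory_ms = 1.5) {
  vals <- c(max_isi_violation, min_snr, min_rate, refractory_ms)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all curation thresholds must be finite and >= 0")
  structure(list(max_isi_violation = max_isi_violation, min_snr = min_snr,
                 min_rate = min_rate, refractory_ms = refractory_ms),
            class = "curation_thresholds")
}

#' Interspike-interval violation rate
#'
#' Fraction of interspike intervals shorter than the refractory period.
#' This is the plain fraction (not a rate-corrected contamination
#' estimator), matching a threshold expressed as a fraction. Trains with
#' fewer than two spikes have no ISIs and return 0.
#'
#' @param train A `spike_train`.
#' @param refractory_ms Refractory period in milliseconds (default 1.5).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' isi_violation_rate(spike_train("u", c(0.1, 0.101, 0.3), t_stop = 1))
isi_violation_rate <- function(train, refractory_ms = 1.5) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(refractory_ms) || refractory_ms < 0)
    stop("refractory_ms must be >= 0")
  if (n_spikes(train) < 2L) return(0)
  isi <- diff(train$times)
  mean(isi < refractory_ms / 1000)
}

#' Curate the units of a session
#'
#' Removes every unit satisfying at least one of: ISI-violation rate above
#' `max_isi_violation`, SNR smaller than `min_snr`, firing rate below
#' `min_rate`. Violation rate and firing rate are computed from the train
#' when the QC attribute is unset; SNR cannot be recomputed (it needs
#' waveforms) and must be supplied.
#'
#' @param session A `recording_session`.
#' @param th A [curation_thresholds()] object.
#' @return List with `kept` (a curated `recording_session`) and `removed`
#'   (data frame: unit id plus one logical column per triggering rule).
#' @export
curate_units <- function(session, th = curation_thresholds()) {
  stopifnot(inherits(session, "recording_session"),
            inherits(th, "curation_thresholds"))
  ids <- unit_ids(session)
  viol <- snr <- rate <- numeric(length(ids))
  for (i in seq_along(ids)) {
    u <- session$units[[i]]
    viol[i] <- if (!is.na(u$isi_violation_rate)) u$isi_violation_rate
      else isi_violation_rate(u$train, th$refractory_ms)
    rate[i] <- if (!is.na(u$firing_rate)) u$firing_rate
      else n_spikes(u$train) / train_duration(u$train)
    if (is.na(u$snr))
      stop(sprintf(
        "unit %s has no SNR; supply an snr QC column (SNR cannot be computed from spike times)",
        ids[i]))
    snr[i] <- u$snr
  }
  isi_rule <- viol > th$max_isi_violation
  snr_rule <- snr < th$min_snr
  rate_rule <- rate < th$min_rate
  drop <- isi_rule | snr_rule | rate_rule
  removed <- data.frame(unit_id = ids[drop],
                        isi_rule = isi_rule[drop], snr_rule = snr_rule[drop],
                        rate_rule = rate_rule[drop],
                        stringsAsFactors = FALSE)
  kept <- recording_session(session$units[!drop], session$duration,
                            session$session_id, session$dpi,
                            session$condition, session$drug)
  list(kept = kept, removed = removed)
}

#' Partition units into active and inactive
#'
#' A unit is active when its firing rate is strictly greater than
#' `min_rate` (default 0.1 Hz); a unit at exactly the threshold is
#' inactive.
#'
#' @param session A `recording_session`.
#' @param min_rate Activity threshold in Hz.
#' @return List with character vectors `active` and `inactive`.
#' @export
classify_active_units <- function(session, min_rate = 0.1) {
  stopifnot(inherits(session, "recording_session"))
  ids <- unit_ids(session)
  rate <- vapply(session$units, function(u) {
    if (!is.na(u$firing_rate)) u$firing_rate
    else n_spikes(u$train) / train_duration(u$train)
  }, numeric(1))
  list(active = ids[rate > min_rate], inactive = ids[rate <= min_rate])
}
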