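# Seeded synthetic-session generators with ground truth. The generator
# emulates the regimes seen in developing cultures on HD-MEAs: sparse
# background spiking early on, single-unit bursts, partially synchronized
# network bursts, and a fast-spiking subpopulation firing doublets at
# short ISIs. Every draw flows from one explicit seed.

#' Stage parameters for the synthetic session generator
#'
#' One developmental "stage" of a culture is summarized by a homogeneous
#' Poisson background rate per unit, a rate of embedded single-unit bursts,
#' the within-burst firing rate and mean burst duration, the rate and
#' participation fraction of network-wide burst events, and the size of a
#' fast-spiking subpopulation that fires doublets at `fast_isi_ms`.
#'
#' Within-burst spikes are laid out quasi-regularly at `1/intra_burst_rate`
#' with +/-10% uniform jitter, so that burst ISIs stay well below the
#' fast-spiking instantaneous-frequency threshold when
#' `intra_burst_rate <= 120` Hz; fast/slow labels then depend only on the
#' injected doublets.
#'
#' @param n_units Number of units in the session.
#' @param baseline_rate Background Poisson rate per unit, Hz.
#' @param burst_rate_per_unit Rate of embedded single-unit bursts, bursts/s.
#' @param burst_duration_mean Mean burst duration, s (gamma-distributed,
#'   shape 4).
#' @param intra_burst_rate Within-burst firing rate, Hz.
#' @param sync_fraction Fraction of units participating in each network
#'   burst event (membership resampled per event).
#' @param network_burst_rate Rate of network burst events, events/s.
#' @param jitter_sd SD of the normal start-time jitter of members within a
#'   network burst, s.
#' @param fast_unit_fraction Fraction of units labelled fast-spiking.
#' @param fast_isi_ms Doublet interspike interval of fast units, ms.
#' @param doublet_prob Probability that a background spike of a fast unit
#'   is followed by a doublet partner.
#' @param duration Session duration, s.
#' @param snr_range Range from which per-unit SNR QC values are drawn.
#' @param amplitude_range Range (microvolts) for per-unit mean amplitudes.
#' @param seed Optional default seed used by [gen_stage_session()].
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(n_units = 50, baseline_rate = 2,
                         burst_rate_per_unit = 0.2, burst_duration_mean = 0.2,
                         intra_burst_rate = 100, sync_fraction = 0.5,
                         network_burst_rate = 0.05, jitter_sd = 0.02,
                         fast_unit_fraction = 0.1, fast_isi_ms = 4,
                         doublet_prob = 0.25, duration = 300,
                         snr_range = c(6, 20), amplitude_range = c(30, 100),
                         seed = NULL) {
  p <- list(n_units = as.integer(n_units), baseline_rate = baseline_rate,
            burst_rate_per_unit = burst_rate_per_unit,
            burst_duration_mean = burst_duration_mean,
            intra_burst_rate = intra_burst_rate,
            sync_fraction = sync_fraction,
            network_burst_rate = network_burst_rate, jitter_sd = jitter_sd,
            fast_unit_fraction = fast_unit_fraction, fast_isi_ms = fast_isi_ms,
            doublet_prob = doublet_prob, duration = duration,
            snr_range = snr_range, amplitude_range = amplitude_range,
            seed = seed)
  rates <- c(p$baseline_rate, p$burst_rate_per_unit, p$intra_burst_rate,
             p$network_burst_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  fracs <- c(p$sync_fraction, p$fast_unit_fraction, p$doublet_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$n_units < 0) stop("n_units must be >= 0")
  if (!is.numeric(p$duration) || p$duration <= 0) stop("duration must be > 0")
  if (p$jitter_sd < 0 || p$burst_duration_mean < 0)
    stop("jitter_sd and burst_duration_mean must be >= 0")
  structure(p, class = "stage_params")
}

# quasi-regular spike layout inside one burst; jitter kept at +/-10% of the
# nominal ISI so consecutive ISIs stay within [0.8, 1.2] / intra_rate
.burst_spikes <- function(start, dur, intra_rate) {
  n <- max(4L, as.integer(round(dur * intra_rate)) + 1L)
  isi <- 1 / intra_rate
  t <- start + (seq_len(n) - 1L) * isi + stats::runif(n, -0.1, 0.1) * isi
  sort(t)
}

#' Generate one synthetic recording session with ground truth
#'
#' Background spikes are homogeneous Poisson at `baseline_rate`. Embedded
#' single-unit bursts arrive as a Poisson process at `burst_rate_per_unit`,
#' each with a gamma-distributed duration around `burst_duration_mean` and
#' quasi-regular spikes at `intra_burst_rate`. Network burst events arrive
#' at `network_burst_rate`; each event places a co-occurring burst in
#' `ceiling(sync_fraction * n_units)` units resampled per event, with
#' normal start jitter. Fast units receive doublet partners at
#' `fast_isi_ms` after a fraction of their background spikes. All spikes
#' are superposed, sorted, and near-coincident duplicates (< 0.1 ms apart)
#' collapsed. A single unit never runs two bursts at once: an injection
#' (single-unit or network-driven) that would overlap an earlier burst of
#' the same unit within a 20 ms margin is skipped, so injected bursts never
#' interleave into spuriously short ISIs.
#'
#' @param params A [stage_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param session_id,dpi,condition Session annotations.
#' @return A list with elements `session` (a `recording_session`) and
#'   `truth` (injected burst intervals per unit, network events with
#'   member units, expected per-unit rates, fast/slow labels).
#' @export
gen_stage_session <- function(params, seed = params$seed,
                              session_id = "synthetic", dpi = NA_integer_,
                              condition = "none") {
  stopifnot(inherits(params, "stage_params"))
  if (is.null(seed)) stop("a seed is required (params$seed or the seed argument)")
  set.seed(as.integer(seed))
  dur <- params$duration
  nu <- params$n_units
  ids <- sprintf("u%03d", seq_len(nu))

  n_fast <- as.integer(floor(params$fast_unit_fraction * nu))
  fast_ids <- if (n_fast > 0) sample(ids, n_fast) else character()
  is_fast <- stats::setNames(ids %in% fast_ids, ids)

  spikes <- stats::setNames(vector("list", nu), ids)
  truth_bursts <- list()
  # occupied burst intervals per unit: one unit cannot run two bursts at
  # once, so a new injection overlapping an existing one (20 ms margin)
  # is skipped rather than interleaved
  occupied <- stats::setNames(rep(list(matrix(numeric(), ncol = 2L)), nu), ids)
  overlaps <- function(id, s, e, margin = 0.02) {
    occ <- occupied[[id]]
    nrow(occ) > 0 && any(s - margin < occ[, 2L] & e + margin > occ[, 1L])
  }

  # per-unit background + embedded single-unit bursts
  for (id in ids) {
    n_bg <- stats::rpois(1L, params$baseline_rate * dur)
    bg <- sort(stats::runif(n_bg, 0, dur))
    parts <- list(bg)
    n_b <- stats::rpois(1L, params$burst_rate_per_unit * dur)
    if (n_b > 0 && params$intra_burst_rate > 0) {
      starts <- stats::runif(n_b, 0, dur)
      durs <- stats::rgamma(n_b, shape = 4, rate = 4 / params$burst_duration_mean)
      for (k in seq_len(n_b)) {
        sp <- .burst_spikes(starts[k], durs[k], params$intra_burst_rate)
        sp <- sp[sp >= 0 & sp < dur]
        if (length(sp) >= 2L && !overlaps(id, sp[1L], sp[length(sp)])) {
          parts[[length(parts) + 1L]] <- sp
          occupied[[id]] <- rbind(occupied[[id]], c(sp[1L], sp[length(sp)]))
          truth_bursts[[length(truth_bursts) + 1L]] <- data.frame(
            unit_id = id, t_start = sp[1L], t_end = sp[length(sp)],
            n_spikes = length(sp), source = "unit",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (is_fast[[id]] && length(bg) && params$doublet_prob > 0) {
      sel <- stats::rbinom(length(bg), 1L, params$doublet_prob) == 1L
      parts[[length(parts) + 1L]] <- bg[sel] + params$fast_isi_ms / 1000
    }
    spikes[[id]] <- parts
  }

  # network burst events: membership resampled per event
  n_members <- as.integer(ceiling(params$sync_fraction * nu))
  n_ev <- if (params$network_burst_rate > 0)
    stats::rpois(1L, params$network_burst_rate * dur) else 0L
  ev_times <- if (n_ev > 0) sort(stats::runif(n_ev, 0, dur)) else numeric()
  ev_members <- vector("list", n_ev)
  if (n_ev > 0 && n_members > 0 && params$intra_burst_rate > 0) {
    for (e in seq_len(n_ev)) {
      members <- sample(ids, min(n_members, nu))
      ev_members[[e]] <- members
      for (id in members) {
        s <- ev_times[e] + stats::rnorm(1L, 0, params$jitter_sd)
        d <- stats::rgamma(1L, shape = 4, rate = 4 / params$burst_duration_mean)
        sp <- .burst_spikes(s, d, params$intra_burst_rate)
        sp <- sp[sp >= 0 & sp < dur]
        if (length(sp) >= 2L && !overlaps(id, sp[1L], sp[length(sp)])) {
          occupied[[id]] <- rbind(occupied[[id]], c(sp[1L], sp[length(sp)]))
          spikes[[id]][[length(spikes[[id]]) + 1L]] <- sp
          truth_bursts[[length(truth_bursts) + 1L]] <- data.frame(
            unit_id = id, t_start = sp[1L], t_end = sp[length(sp)],
            n_spikes = length(sp), source = "network",
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  snr <- stats::runif(nu, params$snr_range[1L], params$snr_range[2L])
  amp <- stats::runif(nu, params$amplitude_range[1L], params$amplitude_range[2L])
  elec <- if (nu > 0) sample.int(26400L, nu) - 1L else integer()

  units <- vector("list", nu)
  for (i in seq_along(ids)) {
    all_t <- sort(unlist(spikes[[ids[i]]], use.names = FALSE))
    all_t <- all_t[all_t >= 0 & all_t < dur]
    if (length(all_t) > 1L)
      all_t <- all_t[c(TRUE, diff(all_t) >= 1e-4)]  # collapse near-duplicates
    st <- spike_train(ids[i], all_t, 0, dur)
    units[[i]] <- unit_record(
      st,
      isi_violation_rate = isi_violation_rate(st),
      snr = snr[i],
      firing_rate = length(all_t) / dur,
      electrode_index = elec[i],
      amplitude = amp[i])
  }

  burst_df <- if (length(truth_bursts)) do.call(rbind, truth_bursts) else
    data.frame(unit_id = character(), t_start = numeric(), t_end = numeric(),
               n_spikes = integer(), source = character(),
               stringsAsFactors = FALSE)
  exp_burst_spikes <- params$burst_duration_mean * params$intra_burst_rate
  true_rate <- stats::setNames(
    params$baseline_rate * (1 + ifelse(is_fast, params$doublet_prob, 0)) +
      params$burst_rate_per_unit * exp_burst_spikes +
      params$network_burst_rate * params$sync_fraction * exp_burst_spikes,
    ids)

  list(
    session = recording_session(units, dur, session_id, dpi, condition),
    truth = list(unit_bursts = burst_df,
                 network_events = list(times = ev_times, members = ev_members),
                 true_rate = true_rate,
                 fast_units = is_fast,
                 params = params)
  )
}

#' Generate a baseline / treatment / washout pharmacology experiment
#'
#' The treatment session is regenerated with the stage parameters scaled
#' by the effect multipliers (`rate` scales the background rate,
#' `burst_rate` scales both single-unit and network burst rates,
#' `burst_duration` scales the mean burst duration). The washout session
#' interpolates between baseline and treatment parameters by
#' `washout_persistence` (0 = full recovery).
#'
#' @param base A [stage_params()] object describing the baseline.
#' @param effect Named list of multipliers `rate`, `burst_rate`,
#'   `burst_duration` (all > 0, default 1).
#' @param washout_persistence Fraction of the effect persisting after
#'   washout, in `[0, 1]`.
#' @param seed Integer master seed; per-condition seeds are derived from it.
#' @return List with `baseline`, `treatment`, `washout` (each a
#'   `recording_session`) and `truth` (the per-condition ground truths).
#' @export
gen_pharmacology_experiment <- function(base,
                                        effect = list(rate = 1, burst_rate = 1,
                                                      burst_duration = 1),
                                        washout_persistence = 0, seed) {
  stopifnot(inherits(base, "stage_params"))
  eff <- utils::modifyList(list(rate = 1, burst_rate = 1, burst_duration = 1),
                           as.list(effect))
  if (any(unlist(eff) <= 0)) stop("effect multipliers must be > 0")
  if (washout_persistence < 0 || washout_persistence > 1)
    stop("washout_persistence must lie in [0, 1]")
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483646L, 3L)

  scale_params <- function(p, m) {
    q <- unclass(p)
    q$baseline_rate <- q$baseline_rate * m$rate
    q$burst_rate_per_unit <- q$burst_rate_per_unit * m$burst_rate
    q$network_burst_rate <- q$network_burst_rate * m$burst_rate
    q$burst_duration_mean <- q$burst_duration_mean * m$burst_duration
    do.call(stage_params, q[setdiff(names(q), "seed")])
  }
  wash_mult <- lapply(eff, function(m) 1 + washout_persistence * (m - 1))

  b <- gen_stage_session(base, seed = seeds[1L], session_id = "baseline",
                         condition = "baseline")
  t <- gen_stage_session(scale_params(base, eff), seed = seeds[2L],
                         session_id = "treatment", condition = "treatment")
  w <- gen_stage_session(scale_params(base, wash_mult), seed = seeds[3L],
                         session_id = "washout", condition = "washout")
  list(baseline = b$session, treatment = t$session, washout = w$session,
       truth = list(baseline = b$truth, treatment = t$truth,
                    washout = w$truth, effect = eff,
                    washout_persistence = washout_persistence))
}

#' Generate migrating soma trajectories with attractor-driven clustering
#'
#' Each neuron performs a 2-D random walk with isotropic normal steps of
#' scale `step_scale` plus a per-step drift of `attraction_gain` toward its
#' nearest attractor, emulating the gradual clustering of somata on the
#' sensor surface. With `attraction_gain` close to 1, positions converge
#' onto the attractors.
#'
#' @param n_neurons,n_timepoints Counts (>= 1).
#' @param step_scale SD of the random step, micrometres.
#' @param n_attractors Number of attractor (cluster) centres.
#' @param attraction_gain Per-step fraction of the distance to the nearest
#'   attractor removed, in `[0, 1]`.
#' @param seed Integer seed.
#' @param dpi_start,dpi_step Sampling schedule in days post induction.
#' @param field Sensor extent `c(width, height)` in micrometres.
#' @return List with `trajectories` (named list of `trajectory`) and
#'   `attractors` (matrix of centre coordinates).
#' @export
gen_trajectories <- function(n_neurons, n_timepoints, step_scale = 10,
                             n_attractors = 5, attraction_gain = 0.2, seed,
                             dpi_start = 22L, dpi_step = 7L,
                             field = c(3850, 2100)) {
  stopifnot(n_neurons >= 1, n_timepoints >= 1, n_attractors >= 1,
            step_scale >= 0, attraction_gain >= 0, attraction_gain <= 1)
  set.seed(as.integer(seed))
  dpis <- dpi_start + dpi_step * (seq_len(n_timepoints) - 1L)
  att <- cbind(x = stats::runif(n_attractors, 0, field[1L]),
               y = stats::runif(n_attractors, 0, field[2L]))
  px <- stats::runif(n_neurons, 0, field[1L])
  py <- stats::runif(n_neurons, 0, field[2L])
  X <- matrix(NA_real_, n_neurons, n_timepoints)
  Y <- matrix(NA_real_, n_neurons, n_timepoints)
  X[, 1L] <- px; Y[, 1L] <- py
  if (n_timepoints > 1L) {
    for (t in 2L:n_timepoints) {
      d2 <- outer(px, att[, "x"], "-")^2 + outer(py, att[, "y"], "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      px <- px + attraction_gain * (att[nearest, "x"] - px) +
        stats::rnorm(n_neurons, 0, step_scale)
      py <- py + attraction_gain * (att[nearest, "y"] - py) +
        stats::rnorm(n_neurons, 0, step_scale)
      X[, t] <- px; Y[, t] <- py
    }
  }
  ids <- sprintf("n%04d", seq_len(n_neurons))
  trajs <- stats::setNames(lapply(seq_len(n_neurons), function(i) {
    trajectory(ids[i], dpis, X[i, ], Y[i, ])
  }), ids)
  list(trajectories = trajs, attractors = att)
}
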