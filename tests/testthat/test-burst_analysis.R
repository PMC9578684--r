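test_that("poisson_surprise matches the direct tail-series oracle", {
  # frozen example: N = 5 spikes in 0.1 s at 10 Hz (lambda*T = 1)
  expect_equal(poisson_surprise(5, 0.1, 10), 5.6105, tolerance = 1e-4)
  expect_equal(poisson_surprise(0, 0.1, 10), 0)
  # N = 1: S = -log(1 - exp(-lambda*T))
  expect_equal(poisson_surprise(1, 0.5, 4), -log(1 - exp(-2)), tolerance = 1e-12)
  for (n in c(1, 2, 5, 17, 50)) {
    for (lt in c(0.01, 0.3, 1, 5, 20)) {
      expect_equal(poisson_surprise(n, lt, 1), oracle_surprise(n, lt),
                   tolerance = 1e-9, label = sprintf("N=%d lT=%g", n, lt))
    }
  }
  expect_equal(poisson_surprise(5, 0.1, 10, log_base = "base10"),
               5.6105 / log(10), tolerance = 1e-4)
  expect_error(poisson_surprise(5, 0.1, 0), "rate")
  expect_error(poisson_surprise(5, 0, 10), "window")
})

test_that("surprise is monotone in N and in lambda*T, and scale-invariant", {
  for (lt in c(0.5, 2, 10)) {
    s <- poisson_surprise(1:30, lt, 1)
    expect_true(all(diff(s) > 0))
  }
  for (n in c(3, 10, 25)) {
    s <- poisson_surprise(n, seq(0.1, 10, by = 0.1), 1)
    expect_true(all(diff(s) < 0))
  }
  # t -> c t, lambda -> lambda / c leaves S unchanged
  expect_equal(poisson_surprise(7, 0.25, 12),
               poisson_surprise(7, 0.25 * 1000, 12 / 1000))
})

test_that("degenerate trains yield no bursts", {
  p <- surprise_params()
  expect_equal(nrow(detect_bursts(spike_train("e", numeric(), 0, 10), p)), 0)
  expect_equal(nrow(detect_bursts(spike_train("t", c(1, 2, 3), 0, 10), p)), 0)
  # constant-ISI train: no ISI below half the mean, seeding impossible
  reg <- spike_train("r", seq(0.5, 99.5, by = 0.5), 0, 100)
  expect_equal(nrow(detect_bursts(reg, p)), 0)
})

test_that("an injected dense burst is recovered exactly", {
  bg <- seq(0.5, 299.5, by = 1)           # regular 1 Hz background
  inj <- 150 + (0:9) * 0.01               # 10 spikes at 100 Hz
  t <- sort(c(bg[abs(bg - 150.05) > 1], inj))
  train <- spike_train("u", t, 0, 300)
  b <- detect_bursts(train)
  expect_equal(nrow(b), 1)
  expect_equal(b$t_start, 150)
  expect_equal(b$t_end, 150.09)
  expect_equal(b$n_spikes, 10L)
  expect_gte(b$surprise, 4)
  # oracle agreement on the same train
  o <- oracle_detect_bursts(train)
  expect_equal(b$t_start, o$t_start)
  expect_equal(b$surprise, o$surprise, tolerance = 1e-9)
})

test_that("detector equals the exhaustive-window oracle on random trains", {
  set.seed(42)
  p <- surprise_params()
  for (rep in 1:60) {
    tr <- random_train()
    got <- detect_bursts(tr, p)
    want <- oracle_detect_bursts(tr, p)
    expect_equal(nrow(got), nrow(want), label = sprintf("rep %d count", rep))
    if (nrow(got)) {
      expect_equal(got$t_start, want$t_start)
      expect_equal(got$t_end, want$t_end)
      expect_equal(got$n_spikes, want$n_spikes)
      expect_equal(got$surprise, want$surprise, tolerance = 1e-9)
    }
  }
})

test_that("emitted bursts are disjoint and satisfy all thresholds", {
  set.seed(77)
  p <- surprise_params()
  for (rep in 1:20) {
    tr <- random_train(n_clusters = 4)
    b <- detect_bursts(tr, p)
    if (nrow(b) > 1)
      expect_true(all(b$t_start[-1] > b$t_end[-nrow(b)]))
    if (nrow(b)) {
      expect_true(all(b$surprise >= p$min_surprise))
      expect_true(all(b$t_end - b$t_start >= p$min_duration))
      expect_true(all(b$n_spikes >= p$min_spikes))
    }
  }
})

test_that("burst_summary reports frequency, duration and percent in bursts", {
  tr <- spike_train("u", seq(0.5, 299.5, length.out = 300), 0, 300)
  none <- detect_bursts(tr)  # regular train, no bursts
  s0 <- burst_summary(tr, none)
  expect_equal(s0$burst_frequency, 0)
  expect_equal(s0$pct_aps_in_burst, 0)
  expect_true(is.na(s0$mean_burst_duration))
  # hand-built burst table: 3 bursts of 0.1 s, 30 of 300 spikes inside
  b <- data.frame(unit_id = "u", t_start = c(10, 20, 30),
                  t_end = c(10.1, 20.1, 30.1), n_spikes = c(10L, 10L, 10L),
                  surprise = c(9, 9, 9))
  s1 <- burst_summary(tr, b)
  expect_equal(s1$burst_frequency, 0.01)
  expect_equal(s1$mean_burst_duration, 0.1)
  expect_equal(s1$pct_aps_in_burst, 10)
})

test_that("injected bursts are recovered with high recall and precision", {
  p <- stage_params()  # 50 units, 300 s defaults
  g <- gen_stage_session(p, seed = 19)
  rec <- prec <- numeric(0)
  tp_i <- n_i <- tp_d <- n_d <- 0
  for (id in unit_ids(g$session)) {
    det <- detect_bursts(g$session$units[[id]]$train)
    inj <- g$truth$unit_bursts[g$truth$unit_bursts$unit_id == id, ]
    m <- match_bursts(det, inj)
    tp_i <- tp_i + m$recalled; n_i <- n_i + m$n_injected
    tp_d <- tp_d + m$matched_det; n_d <- n_d + m$n_detected
  }
  expect_gte(tp_i / n_i, 0.9)   # recall
  expect_gte(tp_d / n_d, 0.9)   # precision
})

test_that("network bursts need enough concurrent units and match ground truth", {
  # single-unit session: below the absolute minimum
  tr <- spike_train("solo", sort(c(seq(1, 299), 150.3 + (0:9) * 0.01)), 0, 300)
  s1 <- recording_session(list(unit_record(tr, snr = 10,
                                           firing_rate = n_spikes(tr) / 300)),
                          duration = 300)
  b1 <- detect_session_bursts(s1)
  expect_equal(nrow(detect_network_bursts(s1, b1)), 0)

  # synchronized scenario: detected event count close to injected
  p <- stage_params(n_units = 30, duration = 200, burst_rate_per_unit = 0.05,
                    network_burst_rate = 0.05)
  g <- gen_stage_session(p, seed = 13)
  nb <- detect_network_bursts(g$session, detect_session_bursts(g$session))
  n_inj <- length(g$truth$network_events$times)
  expect_lt(abs(nrow(nb) - n_inj), max(2, 0.25 * n_inj))

  # participation: members overlap network intervals; all-sync case covers
  # (nearly) every active unit
  part <- units_in_network_bursts(g$session, nb)
  expect_true(all(part$unit_ids %in% unit_ids(g$session)))
  truth_members <- unique(unlist(g$truth$network_events$members))
  expect_gt(length(intersect(part$unit_ids, truth_members)),
            0.8 * length(truth_members))
})

test_that("asynchronous bursts do not form network bursts", {
  # 20 units each bursting once, far apart in time
  dur <- 400
  units <- lapply(1:20, function(i) {
    burst <- (i * 15) + (0:9) * 0.01
    t <- sort(c(seq(0.3, dur - 0.3, by = 1.7) + i * 0.013, burst))
    t <- t[t > 0 & t < dur]
    t <- t[c(TRUE, diff(t) > 1e-4)]
    unit_record(spike_train(sprintf("u%02d", i), t, 0, dur), snr = 10,
                firing_rate = length(t) / dur)
  })
  s <- recording_session(units, dur)
  nb <- detect_network_bursts(s, detect_session_bursts(s))
  expect_equal(nrow(nb), 0)
  expect_equal(units_in_network_bursts(s, nb)$count, 0)
})
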