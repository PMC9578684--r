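test_that("ap_frequency is count over duration and concatenation-consistent", {
  expect_equal(ap_frequency(spike_train("e", numeric(), 0, 300)), 0)
  expect_equal(ap_frequency(spike_train("u", seq(0.25, 299.75, length.out = 600),
                                        0, 300)), 2)
  set.seed(5)
  t <- sort(runif(rpois(1, 600), 0, 300))
  expect_lt(abs(ap_frequency(spike_train("p", t, 0, 300)) - 2),
            3 * sqrt(2 / 300))
  # duration-weighted mean of two disjoint windows
  a <- spike_train("a", sort(runif(50, 0, 100)), 0, 100)
  b <- spike_train("b", sort(runif(200, 100, 300)), 100, 300)
  joint <- spike_train("j", c(a$times, b$times), 0, 300)
  expect_equal(ap_frequency(joint),
               (100 * ap_frequency(a) + 200 * ap_frequency(b)) / 300)
})

test_that("frequency-domain histogram assigns each active unit to one bin", {
  mk <- function(id, rate, dur = 300) {
    n <- round(rate * dur)
    unit_record(spike_train(id, seq(0.1, dur - 0.1, length.out = n), 0, dur),
                firing_rate = n / dur, snr = 10)
  }
  s <- recording_session(list(mk("a", 1.5), mk("b", 2), mk("c", 7),
                              mk("d", 0.05)), duration = 300)
  h <- frequency_domain_histogram(s, c(0, 2, 5, Inf))
  expect_equal(unname(h), c(1L, 1L, 1L))     # edge value 2 goes up a bin
  expect_equal(names(h), c("[0,2)", "[2,5)", "[5,Inf)"))
  cls <- classify_active_units(s)
  expect_equal(sum(h), length(cls$active))   # inactive unit excluded
  expect_error(frequency_domain_histogram(s, c(5)), "two bin edges")
})

test_that("instantaneous frequencies invert ISIs at the closing spike", {
  s <- instantaneous_frequencies(spike_train("u", c(0, 0.01, 0.02), 0, 1))
  expect_equal(s$event_freqs, c(100, 100))
  expect_equal(s$event_times, c(0.01, 0.02))
  expect_length(instantaneous_frequencies(
    spike_train("one", 0.5, 0, 1))$event_freqs, 0)
  s2 <- instantaneous_frequencies(spike_train("d", c(0, 0.004), 0, 1))
  expect_equal(s2$event_freqs, 250)
})

test_that("fast_event_fraction counts strictly-above-threshold events", {
  mk_series <- function(freqs) {
    isi <- 1 / freqs
    instantaneous_frequencies(spike_train("u", cumsum(c(0.001, isi)), 0,
                                          sum(isi) + 1))
  }
  expect_equal(as.numeric(fast_event_fraction(mk_series(rep(100, 10)))), 0)
  s <- mk_series(c(rep(100, 18), 200, 700))
  f <- fast_event_fraction(s)
  expect_equal(as.numeric(f), 0.10)          # 2 of 20 above 150 Hz
  expect_equal(attr(f, "n_above_upper"), 1L) # the 700 Hz event flagged
  empty <- fast_event_fraction(instantaneous_frequencies(
    spike_train("e", 0.5, 0, 1)))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "no_events"))
})

test_that("fast/slow partition is inclusive at 5% and covers all units", {
  # exactly 5% fast events -> fast; no events -> slow
  freqs_5pct <- c(rep(100, 19), 200)
  mk <- function(id, freqs, dur = 300) {
    t <- cumsum(c(0.01, 1 / freqs))
    unit_record(spike_train(id, t, 0, dur), snr = 10,
                firing_rate = length(t) / dur)
  }
  s <- recording_session(list(
    mk("edge", freqs_5pct), mk("slow", rep(100, 40)),
    unit_record(spike_train("lonely", 1, 0, 300), snr = 10,
                firing_rate = 1 / 300)), duration = 300)
  cls <- classify_fast_units(s)
  expect_equal(cls$fast, "edge")
  expect_setequal(cls$slow, c("slow", "lonely"))
  expect_equal(sort(c(cls$fast, cls$slow)), sort(unit_ids(s)))
})

test_that("generator-labelled fast units are recovered from doublets", {
  p <- stage_params(n_units = 30, baseline_rate = 2, duration = 300)
  g <- gen_stage_session(p, seed = 61)
  cls <- classify_fast_units(g$session)
  truth_fast <- names(which(g$truth$fast_units))
  expect_setequal(cls$fast, truth_fast)
})

test_that("mean instantaneous frequency averages over units with SEM", {
  mk <- function(id, f, n = 11, dur = 10) {
    unit_record(spike_train(id, seq(0, by = 1 / f, length.out = n), 0, dur),
                snr = 10, firing_rate = n / dur)
  }
  one <- recording_session(list(mk("u", 100)), duration = 10)
  r <- mean_instantaneous_frequency(one)
  expect_equal(r$mean, 100)
  expect_equal(r$sem, 0)
  two <- recording_session(list(mk("a", 50), mk("b", 150)), duration = 10)
  r2 <- mean_instantaneous_frequency(two)
  expect_equal(r2$mean, 100)
  expect_equal(r2$sem, 50)
  # brute-force recomputation on a random mixture
  set.seed(8)
  g <- gen_stage_session(stage_params(n_units = 10, duration = 60), seed = 8)
  r3 <- mean_instantaneous_frequency(g$session)
  direct <- vapply(g$session$units, function(u) {
    isi <- diff(u$train$times); mean(1 / isi)
  }, numeric(1))
  expect_equal(r3$mean, mean(direct))
  r4 <- mean_instantaneous_frequency(g$session, pool = "events")
  pooled <- unlist(lapply(g$session$units,
                          function(u) 1 / diff(u$train$times)))
  expect_equal(r4$mean, mean(pooled))
  empty <- recording_session(list(unit_record(
    spike_train("x", 1, 0, 10), snr = 10, firing_rate = 0.1)), duration = 10)
  expect_error(mean_instantaneous_frequency(empty), "undefined")
})
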