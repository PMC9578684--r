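# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the surprise oracle sums the Poisson tail term by
# term, and the burst oracle enumerates candidate windows naively.

# Direct tail-series Poisson surprise. Sums whichever tail is small:
# the lower tail (few terms, then -log1p) when N - 1 < lambdaT, otherwise
# the upper tail term by term until terms fall below 1e-18 of the sum.
oracle_surprise <- function(n, lambdaT, log_base = "natural") {
  stopifnot(lambdaT > 0, n >= 0)
  if (n == 0) return(0)
  log_term <- function(k) -lambdaT + k * log(lambdaT) - lgamma(k + 1)
  if (n - 1 < lambdaT) {
    p_low <- sum(exp(log_term(0:(n - 1))))
    s <- -log1p(-p_low)
  } else {
    total <- 0
    k <- n
    repeat {
      term <- exp(log_term(k))
      total <- total + term
      if (term < total * 1e-18 || k > n + 10000) break
      k <- k + 1
    }
    s <- -log(total)
  }
  if (log_base == "base10") s / log(10) else s
}

# Naive burst detector sharing the seeding/extension protocol but
# evaluating every candidate end with the series oracle and an explicit
# loop-based maximization.
oracle_detect_bursts <- function(train, params = surprise_params()) {
  times <- train$times
  n <- length(times)
  res <- data.frame(t_start = numeric(), t_end = numeric(),
                    n_spikes = integer(), surprise = numeric())
  if (n < max(params$min_spikes, 3L)) return(res)
  isi <- diff(times)
  mean_isi <- mean(isi)
  lambda <- n / (train$t_stop - train$t_start)
  i <- 1L
  while (i <= n - 2L) {
    if (isi[i] < params$seed_isi_factor * mean_isi &&
        isi[i + 1L] < params$seed_isi_factor * mean_isi) {
      E <- i + 2L
      while (E < n && isi[E] <= params$extension_isi_factor * mean_isi)
        E <- E + 1L
      first_end <- i + params$min_spikes - 1L
      if (first_end <= E) {
        best_s <- -Inf; best_j <- NA_integer_
        for (j in first_end:E) {
          s <- oracle_surprise(j - i + 1L, lambda * (times[j] - times[i]),
                               params$log_base)
          if (s > best_s + 1e-12) { best_s <- s; best_j <- j }
        }
        if (best_s >= params$min_surprise &&
            times[best_j] - times[i] >= params$min_duration &&
            best_j - i + 1L >= params$min_spikes) {
          res <- rbind(res, data.frame(t_start = times[i],
                                       t_end = times[best_j],
                                       n_spikes = best_j - i + 1L,
                                       surprise = best_s))
          i <- best_j + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  res
}

# Random spike train: Poisson background with optional injected dense
# clusters, so that burst candidates actually arise.
random_train <- function(n_max = 200, duration = 60, rate = 1.5,
                         n_clusters = 2, cluster_rate = 80,
                         id = "rt") {
  bg <- sort(runif(rpois(1, rate * duration), 0, duration))
  extra <- numeric()
  if (n_clusters > 0) {
    for (k in seq_len(rpois(1, n_clusters) + 1)) {
      s <- runif(1, 0, duration * 0.95)
      m <- sample(4:12, 1)
      extra <- c(extra, s + cumsum(rexp(m, cluster_rate)))
    }
  }
  t <- sort(c(bg, extra))
  t <- t[t >= 0 & t < duration]
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 1e-6)]
  if (length(t) > n_max) t <- sort(sample(t, n_max))
  spike_train(id, t, 0, duration)
}

# Random valid session with QC attributes, for round-trip testing.
random_session <- function(n_units = 4, duration = 30) {
  units <- lapply(seq_len(n_units), function(i) {
    t <- sort(runif(rpois(1, 2 * duration), 0, duration - 1e-6))
    t <- round(t[c(TRUE, diff(t) > 1e-6)], 6)  # writer precision friendly
    st <- spike_train(sprintf("u%02d", i), t, 0, duration)
    unit_record(st,
                isi_violation_rate = round(runif(1), 6),
                snr = round(runif(1, 1, 20), 6),
                firing_rate = length(t) / duration,
                electrode_index = sample.int(26400, 1) - 1L)
  })
  recording_session(units, duration, session_id = "rand", dpi = 42L,
                    condition = "baseline")
}

# Overlap-based matching of detected vs injected burst intervals for one
# unit; returns TP counts from the injected and detected sides.
match_bursts <- function(detected, injected) {
  if (!nrow(injected))
    return(list(recalled = 0L, n_injected = 0L,
                matched_det = 0L, n_detected = nrow(detected)))
  ov <- function(a0, a1, b0, b1) a0 <= b1 & a1 >= b0
  recalled <- sum(vapply(seq_len(nrow(injected)), function(i) {
    any(ov(detected$t_start, detected$t_end,
           injected$t_start[i], injected$t_end[i]))
  }, logical(1)))
  matched_det <- if (nrow(detected)) sum(vapply(seq_len(nrow(detected)),
    function(i) any(ov(injected$t_start, injected$t_end,
                       detected$t_start[i], detected$t_end[i])),
    logical(1))) else 0L
  list(recalled = recalled, n_injected = nrow(injected),
       matched_det = matched_det, n_detected = nrow(detected))
}
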