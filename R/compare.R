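# Nonparametric condition comparison: Kruskal-Wallis omnibus, Dunn's
# multiple-comparison post hoc (hand-computed mean-rank z statistics with
# tie correction; the omnibus delegates to stats::kruskal.test), and
# mean +/- SEM summaries. Units are the statistical unit of analysis: one
# value per neuron, independent groups.

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator); a single
#' value has SEM 0.
#'
#' @param values Numeric vector (>= 1 value, finite).
#' @return List with `mean`, `sem`, `n`.
#' @export
summarize_mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must contain at least one element")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else 0,
       n = n)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group must contain at least one value")
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("group values must be finite")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction; p from the chi-square approximation
#' with k - 1 degrees of freedom. A thin wrapper around
#' [stats::kruskal.test()] operating on a named list of group vectors.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .check_groups(groups)
  k <- stats::kruskal.test(groups)
  list(H = unname(k$statistic), df = unname(k$parameter),
       p_value = k$p.value)
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics from mean-rank differences over the pooled
#' ranking, with tie-corrected pooled variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`. Two-sided
#' p-values are adjusted over all pairs by the configured method
#' (Bonferroni by default).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none"),
                         alpha = 0.05) {
  groups <- .check_groups(groups)
  adjust <- match.arg(adjust)
  labs <- names(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(pooled)
  N <- length(pooled)
  mean_rank <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- apply(pairs, 2L, function(p) {
    (mean_rank[p[1L]] - mean_rank[p[2L]]) /
      sqrt(base_var * (1 / n[p[1L]] + 1 / n[p[2L]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = switch(adjust,
    bonferroni = "bonferroni", holm = "holm", none = "none"))
  data.frame(group1 = labs[pairs[1L, ]], group2 = labs[pairs[2L, ]],
             z = unname(z), p_value = unname(p_raw),
             p_adjusted = unname(p_adj),
             significant = unname(p_adj < alpha),
             stringsAsFactors = FALSE)
}

# per-unit metric vectors for one session
.session_metric_vectors <- function(session, metrics, burst_params) {
  out <- list()
  need_bursts <- any(metrics %in%
    c("burst_frequency", "mean_burst_duration", "pct_aps_in_burst"))
  summaries <- NULL
  if (need_bursts) {
    summaries <- do.call(rbind, lapply(session$units, function(u) {
      burst_summary(u$train, detect_bursts(u$train, burst_params))
    }))
  }
  for (m in metrics) {
    out[[m]] <- switch(m,
      ap_frequency = unname(session_ap_frequencies(session)),
      burst_frequency = summaries$burst_frequency,
      mean_burst_duration = summaries$mean_burst_duration[
        !is.na(summaries$mean_burst_duration)],
      pct_aps_in_burst = summaries$pct_aps_in_burst,
      stop(sprintf("unknown metric '%s'", m)))
  }
  out
}

#' Compare activity metrics across experimental conditions
#'
#' For each requested metric, per-unit values are computed in each
#' condition (one value per neuron; units with no bursts are excluded
#' from the mean-burst-duration vector) and fed to the Kruskal-Wallis
#' omnibus followed by Dunn's post hoc. A metric that cannot be computed
#' in some condition (e.g. no bursts anywhere) is skipped with a warning.
#'
#' @param sessions Named list of `recording_session` objects, e.g.
#'   `list(baseline = ..., treatment = ..., washout = ...)`.
#' @param metrics Character vector from `ap_frequency`, `burst_frequency`,
#'   `mean_burst_duration`, `pct_aps_in_burst`.
#' @param burst_params [surprise_params()] used for burst metrics.
#' @param adjust Dunn adjustment method.
#' @param alpha Significance level.
#' @return Named list, one entry per metric, each with `groups` (mean,
#'   SEM, n per condition), `kruskal` (H, df, p), `dunn` (pairwise table)
#'   and `direction` (sign of each non-reference condition's mean minus
#'   the first condition's mean).
#' @export
compare_conditions <- function(sessions,
                               metrics = c("ap_frequency", "burst_frequency",
                                           "mean_burst_duration",
                                           "pct_aps_in_burst"),
                               burst_params = surprise_params(),
                               adjust = "bonferroni", alpha = 0.05) {
  if (!is.list(sessions) || length(sessions) < 2L)
    stop("at least two sessions are required")
  if (is.null(names(sessions)))
    names(sessions) <- vapply(sessions, function(s) s$condition, character(1))
  stopifnot(all(vapply(sessions, inherits, logical(1), "recording_session")))
  metrics <- match.arg(metrics, several.ok = TRUE)

  vectors <- lapply(sessions, .session_metric_vectors, metrics = metrics,
                    burst_params = burst_params)
  report <- list()
  for (m in metrics) {
    groups <- lapply(vectors, `[[`, m)
    if (any(vapply(groups, length, integer(1)) < 2L)) {
      warning(sprintf("metric '%s' unavailable in at least one condition; skipped", m))
      next
    }
    kw <- kruskal_wallis(groups)
    dn <- dunn_posthoc(groups, adjust = adjust, alpha = alpha)
    sums <- lapply(groups, summarize_mean_sem)
    ref <- sums[[1L]]$mean
    direction <- vapply(sums[-1L], function(s) sign(s$mean - ref), numeric(1))
    report[[m]] <- list(groups = sums, kruskal = kw, dunn = dn,
                        direction = direction)
  }
  report
}
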