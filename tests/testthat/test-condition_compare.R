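test_that("summarize_mean_sem follows the n-1 convention", {
  expect_equal(summarize_mean_sem(c(2, 2, 2))[c("mean", "sem")],
               list(mean = 2, sem = 0))
  expect_equal(summarize_mean_sem(c(0, 2))[c("mean", "sem")],
               list(mean = 1, sem = 1))
  expect_equal(summarize_mean_sem(5)$sem, 0)
  set.seed(3)
  v <- rnorm(40)
  s <- summarize_mean_sem(v)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sem, sd(v) / sqrt(40))
  expect_error(summarize_mean_sem(numeric()), "at least one")
})

test_that("kruskal_wallis handles degenerate and two-group cases", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  k <- kruskal_wallis(same)
  expect_equal(k$H, 0)
  expect_equal(k$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())), "at least one")

  # two groups: p agrees with the normal-approximation Mann-Whitney
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  k2 <- kruskal_wallis(list(x = x, y = y))
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(k2$p_value, w$p.value, tolerance = 1e-6)
})

test_that("kruskal_wallis p agrees with an exact rank permutation at tiny n", {
  groups <- list(a = c(8.2, 6.5, 7.8), b = c(5.5, 5.3, 7.9), c = c(0.2, 4.8))
  k <- kruskal_wallis(groups)
  # enumerate all assignments of the 8 pooled ranks to the group sizes
  pooled <- unlist(groups)
  n <- lengths(groups)
  r <- rank(pooled)
  H_of <- function(assign) {
    grp <- split(r[assign], rep(seq_along(n), n))
    N <- length(r)
    12 / (N * (N + 1)) * sum(vapply(grp, function(g)
      length(g) * (mean(g) - (N + 1) / 2)^2, numeric(1)))
  }
  # the observed H itself must equal the textbook rank formula (no ties)
  expect_equal(k$H, H_of(seq_len(8)), tolerance = 1e-12)
  perms <- combn(8, 3)
  count <- 0; total <- 0
  for (i in seq_len(ncol(perms))) {
    rest <- setdiff(1:8, perms[, i])
    inner <- combn(rest, 3)
    for (j in seq_len(ncol(inner))) {
      assign <- c(perms[, i], inner[, j], setdiff(rest, inner[, j]))
      total <- total + 1
      if (H_of(assign) >= H_of(1:8) - 1e-12) count <- count + 1
    }
  }
  expect_lt(abs(k$p_value - count / total), 0.01)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(25)
  g <- list(a = runif(15), b = runif(15, 0.2), c = runif(15, 0.4))
  h1 <- kruskal_wallis(g)$H
  h2 <- kruskal_wallis(lapply(g, function(v) exp(5 * v)))$H
  expect_equal(h1, h2)
})

test_that("dunn_posthoc adjusts pairwise p-values as configured", {
  same <- list(a = rep(c(1, 2, 3), 4), b = rep(c(1, 2, 3), 4),
               c = rep(c(1, 2, 3), 4))
  d <- dunn_posthoc(same)
  expect_true(all(d$p_adjusted == 1))
  expect_false(any(d$significant))

  set.seed(33)
  g <- list(a = rnorm(20), b = rnorm(20, 0.7), c = rnorm(20))
  raw <- dunn_posthoc(g, adjust = "none")
  bon <- dunn_posthoc(g, adjust = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, raw$p_value * 3))
  holm <- dunn_posthoc(g, adjust = "holm")
  expect_true(all(holm$p_adjusted >= raw$p_value - 1e-15))
  expect_true(all(bon$p_adjusted >= holm$p_adjusted - 1e-15))
})

test_that("a shifted group is flagged with high power", {
  set.seed(44)
  hits <- vapply(1:200, function(i) {
    g <- list(a = rnorm(100), b = rnorm(100), c = rnorm(100, 1))
    d <- dunn_posthoc(g)
    all(d$significant[d$group1 == "c" | d$group2 == "c"])
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("the omnibus + posthoc chain keeps its type-I error near alpha", {
  set.seed(55)
  rej <- vapply(1:400, function(i) {
    g <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    kw <- kruskal_wallis(g)
    kw$p_value < 0.05 && any(dunn_posthoc(g)$significant)
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.09)
})

test_that("compare_conditions reproduces pharmacological effect directions", {
  base <- stage_params(n_units = 30, duration = 120)
  # GABA-A blockade scenario: more, shorter bursts under treatment
  ex <- gen_pharmacology_experiment(base,
                                    effect = list(burst_rate = 1.5,
                                                  burst_duration = 0.6),
                                    seed = 71)
  rep <- compare_conditions(list(baseline = ex$baseline,
                                 treatment = ex$treatment,
                                 washout = ex$washout),
                            metrics = c("burst_frequency",
                                        "mean_burst_duration"))
  bf <- rep$burst_frequency
  expect_equal(unname(bf$direction["treatment"]), 1)
  pair <- bf$dunn[(bf$dunn$group1 == "baseline" & bf$dunn$group2 == "treatment") |
                    (bf$dunn$group1 == "treatment" & bf$dunn$group2 == "baseline"), ]
  expect_true(pair$significant)
  bd <- rep$mean_burst_duration
  expect_equal(unname(bd$direction["treatment"]), -1)

  # glutamate blockade scenario: bursts switched off in treatment
  ex2 <- gen_pharmacology_experiment(base,
                                     effect = list(burst_rate = 1e-6,
                                                   rate = 0.5),
                                     seed = 72)
  rep2 <- compare_conditions(list(baseline = ex2$baseline,
                                  treatment = ex2$treatment,
                                  washout = ex2$washout),
                             metrics = "burst_frequency")
  expect_equal(unname(rep2$burst_frequency$direction["treatment"]), -1)
})

test_that("identical sessions yield no significant pairs most of the time", {
  base <- stage_params(n_units = 25, duration = 60, network_burst_rate = 0)
  set.seed(66)
  n_sig <- 0
  for (i in 1:10) {
    ex <- gen_pharmacology_experiment(base, seed = 100 + i)
    rep <- compare_conditions(list(baseline = ex$baseline,
                                   treatment = ex$treatment,
                                   washout = ex$washout),
                              metrics = "ap_frequency")
    if (any(rep$ap_frequency$dunn$significant)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 2)
})
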