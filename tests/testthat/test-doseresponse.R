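make_paired_table <- function(ids, base, treat, group = "drug",
                              conc = 1e-7, metric = "force_nN") {
  data.frame(
    recording_id = rep(ids, each = 2), group = group,
    concentration_molar = conc,
    phase = rep(c("baseline", "treatment"), length(ids)),
    metric = metric,
    value = as.vector(rbind(base, treat)),
    stringsAsFactors = FALSE)
}

test_that("relative responses divide treatment by the paired baseline", {
  tab <- make_paired_table(c("r1", "r2"), base = c(100, 90),
                           treat = c(140, 90))
  rel <- relative_response(tab)
  # 140 / 100: a 40% force increase over the recording's own baseline
  expect_equal(rel$relative_response, c(1.4, 1.0))
  expect_identical(rel$phase, c("treatment", "treatment"))
})

test_that("controls are normalised to the control-group mean", {
  tab <- make_paired_table(c("c1", "c2"), base = c(80, 120),
                           treat = c(90, 110), group = "control", conc = NA)
  rel <- relative_response(tab)
  expect_equal(rel$relative_response, c(90, 110) / 100)
  # a control equal to the control mean maps to exactly 1
  expect_equal(mean(rel$relative_response), 1)
})

test_that("relative responses are scale invariant per recording", {
  tab <- make_paired_table("r1", base = 100, treat = 140)
  tab2 <- tab
  tab2$value <- tab2$value * 7.3
  expect_equal(relative_response(tab)$relative_response,
               relative_response(tab2)$relative_response,
               tolerance = 1e-12)
})

test_that("treated rows without a usable baseline are excluded loudly", {
  tab <- make_paired_table(c("r1", "r2"), base = c(100, 90),
                           treat = c(140, 90))
  tab <- tab[-1, ]  # drop r1's baseline
  expect_warning(rel <- relative_response(tab), "without usable baseline")
  expect_identical(rel$recording_id, "r2")
})

test_that("the dose-response slope matches an independent OLS oracle", {
  set.seed(61)
  for (i in 1:20) {
    conc <- rep(c(1e-8, 1e-7, 1e-6, 1e-5), each = 5)
    y <- 1 + 0.05 * log10(conc) + rnorm(20, 0, 0.1)
    ds <- dose_slope(conc, y)
    oracle <- ols_brute(log10(conc), y)
    expect_equal(ds$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(ds$se, oracle$se, tolerance = 1e-10)
    expect_equal(ds$wald_stat, oracle$t, tolerance = 1e-10)
    expect_equal(ds$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate regressions take their limiting values", {
  ds <- dose_slope(c(1, 2, 3, 4), rep(2, 4), conc_scale = "linear")
  expect_identical(ds$slope, 0)
  expect_identical(ds$p, 1)

  line <- dose_slope(c(1, 2, 3, 4), 2 * (1:4) + 1, conc_scale = "linear")
  expect_equal(line$slope, 2, tolerance = 1e-12)
  expect_lt(line$p, 1e-20)

  expect_error(dose_slope(c(1, 2), c(1, 2)), "at least 3")
  expect_error(dose_slope(c(1, 1, 1), c(1, 2, 3), conc_scale = "linear"),
               "distinct")
  expect_error(dose_slope(c(0, 1e-8, 1e-7), c(1, 2, 3)), "positive")
})

test_that("Holm-Sidak adjustment matches the hand formula and is monotone", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  set.seed(62)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
})

test_that("identical groups produce a null omnibus result", {
  y <- rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- compare_groups(y, g, "anova_holm_sidak")
  expect_gt(res$omnibus$p, 0.99)
  expect_false(any(res$pairwise$significant))
})

test_that("two-group designs reduce to the classical tests", {
  set.seed(63)
  y <- c(rnorm(10), rnorm(12, 0.8, 2))
  g <- rep(c("a", "b"), c(10, 12))
  gh <- compare_groups(y, g, "welch_bf_games_howell")
  tt <- t.test(y[g == "a"], y[g == "b"])
  expect_equal(abs(gh$pairwise$statistic), abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(gh$pairwise$p_adj, tt$p.value, tolerance = 1e-10)

  kd <- compare_groups(y, g, "kruskal_dunn")
  kw <- kruskal.test(y, factor(g))
  expect_equal(kd$pairwise$statistic^2, unname(kw$statistic),
               tolerance = 1e-10)
})

test_that("Games-Howell matches an independent reference implementation", {
  # expected values computed with pingouin.pairwise_gameshowell (Python)
  y <- c(1.1, 0.9, 1.3, 1.0, 1.2, 0.8,
         1.5, 1.9, 1.4, 1.8, 2.2,
         0.7, 0.6, 1.1, 0.9, 0.8, 1.0, 0.75)
  g <- rep(c("a", "b", "c"), c(6, 5, 7))
  res <- compare_groups(y, g, "welch_bf_games_howell")
  expect_equal(res$pairwise$statistic, c(-4.366992, 2.121320, 5.849119),
               tolerance = 1e-6)
  expect_equal(res$pairwise$p_adj, c(0.010499, 0.133058, 0.003147),
               tolerance = 1e-4)
})

test_that("groups below the minimum size are excluded with a warning", {
  y <- c(rnorm(5), rnorm(5, 1), rnorm(2, 2))
  g <- rep(c("a", "b", "tiny"), c(5, 5, 2))
  expect_warning(res <- compare_groups(y, g, "anova_holm_sidak"),
                 "n < 3")
  expect_identical(sort(unique(c(res$pairwise$group1, res$pairwise$group2))),
                   c("a", "b"))
})

test_that("Holm-Sidak pairwise comparisons control the family-wise error", {
  set.seed(64)
  n_rep <- 200
  fwe <- 0L
  for (i in seq_len(n_rep)) {
    y <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    res <- compare_groups(y, g, "anova_holm_sidak")
    if (any(res$pairwise$significant)) fwe <- fwe + 1L
  }
  expect_lte(fwe / n_rep, 0.07)
})

test_that("outlier flagging matches its rules on constructed data", {
  fo <- suppressMessages(flag_outliers(c(1, 1, 1, 1, 100)))
  expect_identical(which(fo$flagged), 5L)

  expect_false(any(flag_outliers(rep(2, 6))$flagged))

  set.seed(65)
  x <- rnorm(1000)
  frac <- mean(flag_outliers(x, mad_k = 5)$flagged)
  expect_lt(frac, 0.005)

  expect_error(flag_outliers(c(1, 2, 3)), "n >= 4")
})

test_that("zero-MAD data with distinct values falls back to the IQR fence", {
  expect_message(fo <- flag_outliers(c(rep(1, 6), 50)), "IQR")
  expect_identical(fo$rule, "iqr")
  expect_identical(which(fo$flagged), 7L)
})
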