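test_that("specific productivity is slope over biomass", {
  s <- cultivation_series(0:10, P_mg_per_L = 10 * (0:10), X_g_per_L = rep(2, 11))
  qp <- specific_productivity(s)
  expect_equal(qp$qP_mg_per_g_per_d, rep(5, 11), tolerance = 1e-12)
  flat <- cultivation_series(0:10, rep(25, 11), rep(2, 11))
  expect_equal(specific_productivity(flat)$qP_mg_per_g_per_d, rep(0, 11))
})

test_that("qP matches the analytic logistic derivative on a fine grid", {
  p <- cultivation_gen_params(t_grid = seq(0, 10, by = 0.1), noise_sd = 0,
                              seed = 1L)
  s <- generate_cultivation_series(p)
  qp <- specific_productivity(s)
  # analytic dP/dt of the truncated logistic product model
  t_half <- p$production_onset_day + 2 / p$production_rate
  L <- function(t) 1 / (1 + exp(-p$production_rate * (t - t_half)))
  L0 <- L(p$production_onset_day)
  dPdt <- function(t) ifelse(t <= p$production_onset_day, 0,
                             p$P_max * p$production_rate * L(t) * (1 - L(t)) / (1 - L0))
  interior <- seq(3, nrow(s) - 2)
  away_from_kink <- abs(s$t_days[interior] - p$production_onset_day) > 0.3
  idx <- interior[away_from_kink]
  expected <- dPdt(s$t_days[idx]) / s$X_g_per_L[idx]
  got <- qp$qP_mg_per_g_per_d[idx]
  big <- expected > 0.05 * max(expected)
  expect_lt(max(abs(got[big] - expected[big]) / expected[big]), 0.05)
})

test_that("qP flags zero-biomass points instead of dividing by zero", {
  s <- cultivation_series(0:4, P_mg_per_L = c(0, 1, 2, 3, 4),
                          X_g_per_L = c(0, 1, 1, 1, 1))
  qp <- specific_productivity(s)
  expect_false(qp$defined[1])
  expect_true(is.na(qp$qP_mg_per_g_per_d[1]))
  expect_true(all(qp$defined[-1]))
})

test_that("qP is linear in the product signal", {
  set.seed(12)
  P <- cumsum(runif(8)); X <- runif(8, 1, 3)
  s1 <- cultivation_series(1:8, P, X)
  s2 <- cultivation_series(1:8, 3 * P + 7, X)
  expect_equal(specific_productivity(s2)$qP_mg_per_g_per_d,
               3 * specific_productivity(s1)$qP_mg_per_g_per_d,
               tolerance = 1e-9)
})

test_that("the one-way F statistic matches hand-computed sums of squares", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, F = (1.5/1)/(4/4) = 1.5
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$f_value, 1.5, tolerance = 1e-12)
  expect_identical(a$df_between, 1L)
  expect_identical(a$df_within, 4L)
  # equal means: F = 0
  z <- anova_oneway(list(c(1, 3), c(2, 2)))
  expect_equal(z$f_value, 0)
  expect_false(z$significant)
  # well-separated groups
  w <- anova_oneway(list(c(0, 0.1, 0.2), c(10, 10.1, 10.2)))
  expect_true(w$significant)
  expect_lt(w$p_value, 1e-6)
})

test_that("F and p agree with the reference linear-model ANOVA", {
  set.seed(5)
  groups <- list(rnorm(6, 0), rnorm(9, 0.5), rnorm(4, 1))
  mine <- anova_oneway(groups)
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- anova(lm(y ~ g, data = d))
  expect_equal(mine$f_value, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_identical(mine$df_between, 2L)
  expect_identical(mine$df_within, 16L)
})

test_that("F is invariant to location and scale shifts", {
  set.seed(6)
  groups <- list(rnorm(5), rnorm(7, 1))
  f0 <- anova_oneway(groups)$f_value
  expect_equal(anova_oneway(lapply(groups, function(g) g + 100))$f_value, f0,
               tolerance = 1e-9)
  expect_equal(anova_oneway(lapply(groups, function(g) g * 0.01))$f_value, f0,
               tolerance = 1e-9)
})

test_that("degenerate and underpowered inputs are rejected", {
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(c(1, 2), 3)), "at least 2 observations")
  expect_error(anova_oneway(list(c(2, 2), c(2, 2))), "between and within")
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "within-group variance")
})

test_that("per-day comparisons skip, test and report degeneracy per day", {
  tbl <- rbind(
    data.frame(day = 1, condition = "A", value = c(1.0, 1.2, 0.9)),
    data.frame(day = 1, condition = "B", value = c(2.0, 2.1, 1.9)),
    data.frame(day = 2, condition = "A", value = c(1.0, 1.1, 1.0)),   # B missing
    data.frame(day = 3, condition = "A", value = c(1, 1, 1)),
    data.frame(day = 3, condition = "B", value = c(2, 2, 2)))         # zero within-MS
  res <- compare_conditions_per_day(tbl)
  expect_identical(res$status, c("tested", "skipped", "degenerate"))
  expect_true(res$significant[1])
  expect_match(res$reason[2], "fewer than 2 conditions")
  expect_match(res$reason[3], "within-group")
  single <- data.frame(day = 1:3, condition = "A", value = rnorm(3))
  all_skipped <- compare_conditions_per_day(single)
  expect_true(all(all_skipped$status == "skipped"))
})

test_that("the per-day test holds its nominal size under the null", {
  set.seed(17)
  reps <- 200
  hits <- 0
  for (i in seq_len(reps)) {
    tbl <- data.frame(day = 1, condition = rep(c("A", "B"), each = 4),
                      value = rnorm(8))
    hits <- hits + compare_conditions_per_day(tbl)$significant[1]
  }
  rate <- hits / reps
  ci <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci + 1e-12)
})
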