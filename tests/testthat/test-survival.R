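# brute-force product-limit oracle
naive_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ut, survival = surv)
}

test_that("Kaplan-Meier matches hand computations and the brute-force loop", {
  simple <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(simple)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  censored <- tibble::tibble(time = c(2, 5, 9), event = c(0, 0, 0))
  expect_true(all(km_estimate(censored)$survival == 1))

  dup <- dplyr::bind_rows(simple, simple)
  expect_equal(km_estimate(dup)$survival, km$survival)

  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    df <- tibble::tibble(time = sample(1:10, n, TRUE),
                         event = rbinom(n, 1, 0.7))
    if (sum(df$event) == 0) df$event[1] <- 1L
    got <- km_estimate(df)
    want <- naive_km(df$time, df$event)
    got_events <- got[got$n_event > 0, ]
    expect_equal(got_events$time, want$time)
    expect_equal(got_events$survival, want$survival, tolerance = 1e-12)
  }
  expect_error(km_estimate(tibble::tibble(time = c(1, -2), event = c(1, 1))),
               "positive")
})

test_that("log-rank is symmetric, rank-invariant and null on equal groups", {
  df <- tibble::tibble(time = c(1, 2, 3, 1, 2, 3),
                       event = c(1, 0, 1, 1, 0, 1),
                       group = rep(c("a", "b"), each = 3))
  same <- logrank_test(df)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(2)
  rnd <- tibble::tibble(time = rexp(40) + 0.1,
                        event = rbinom(40, 1, 0.8),
                        group = rep(c("a", "b"), 20))
  base <- logrank_test(rnd)
  swapped <- dplyr::mutate(rnd, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(swapped)$statistic, base$statistic,
               tolerance = 1e-12)
  # invariant under strictly increasing time transforms
  trans <- dplyr::mutate(rnd, time = time^2)
  expect_equal(logrank_test(trans)$statistic, base$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(dplyr::filter(rnd, group == "a")), "two")
})

test_that("log-rank detects a strong planted hazard ratio", {
  rej <- vapply(1:10, function(s) {
    coh <- simulate_survival_cohort(300, hazard_ratio = 3,
                                    censor_rate = 0.2, seed = 100 + s)
    st <- coh$survival
    st$group <- ifelse(st$CCL19 > median(st$CCL19), "high", "low")
    logrank_test(st)$p_value <= 0.05
  }, logical(1))
  expect_true(all(rej))
})

test_that("optimal cutpoint lands in the separating gap and warns", {
  set.seed(4)
  lo <- tibble::tibble(expr = rnorm(30, 0, 0.3),
                       time = rexp(30, 0.05) + 0.1, event = 1)
  hi <- tibble::tibble(expr = rnorm(30, 10, 0.3),
                       time = rexp(30, 1) + 0.1, event = 1)
  df <- dplyr::bind_rows(lo, hi)
  expect_warning(fit <- optimal_cutpoint(df, expr), "inflat")
  expect_gt(fit$cutpoint, max(lo$expr))
  expect_lt(fit$cutpoint, min(hi$expr))
  expect_lt(fit$p_value, 1e-6)
  expect_identical(sort(unique(fit$data$group)), c("high", "low"))

  # broom-style accessors
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_identical(gl$cutpoint, fit$cutpoint)

  # infeasible min_prop: odd n cannot be split 50/50
  odd <- df[1:11, ]
  expect_error(suppressWarnings(optimal_cutpoint(odd, expr,
                                                 min_prop = 0.5)),
               "split")
  expect_error(suppressWarnings(
    optimal_cutpoint(dplyr::mutate(df, expr = 1), expr)), "constant")
})

test_that("post-selection log-rank p-values are anticonservative under the null", {
  rej <- vapply(1:40, function(s) {
    coh <- simulate_survival_cohort(60, hazard_ratio = 1, censor_rate = 0.2,
                                    seed = 400 + s)
    st <- coh$survival
    fit <- suppressWarnings(optimal_cutpoint(st, CCL19))
    fit$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.05)
})

test_that("Mann-Whitney reproduces exact and approximate references", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  expect_equal(mann_whitney(c(5, 7, 9), c(5, 7, 9))$p_value, 1)

  # extreme separation attains the minimal two-sided p for the sizes
  extreme <- mann_whitney(1:3, 101:104)
  expect_equal(extreme$p_value, 2 / choose(7, 3), tolerance = 1e-12)

  # independent oracle: wilcox.test exact p on random untied small samples
  set.seed(31)
  for (rep in 1:10) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    x <- sample(1:100, na)
    y <- sample(setdiff(1:100, x), nb)
    got <- mann_whitney(x, y)
    want <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$u, unname(want$statistic))
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }

  # tie-corrected normal branch against wilcox.test without continuity
  set.seed(32)
  x <- sample(1:8, 30, TRUE)
  y <- sample(2:9, 25, TRUE)
  got <- mann_whitney(x, y)
  expect_identical(got$method, "normal approximation (tie-corrected)")
  want <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = FALSE))
  expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
})

test_that("IHC composite is the exact intensity x area product with bounds", {
  expect_identical(ihc_composite(3, 4), 12L)
  expect_identical(ihc_composite(0, 4), 0L)
  expect_identical(ihc_composite(2, 3), 6L)
  expect_error(ihc_composite(4, 2), "0..3")
  expect_error(ihc_composite(2, 5), "0..4")
})
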