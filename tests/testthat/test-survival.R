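test_that("median dichotomization sends ties to the low group", {
  d <- dichotomize(setNames(c(1, 2, 3, 4), paste0("s", 1:4)))
  expect_equal(unname(d$group), c("low", "low", "high", "high"))
  expect_equal(d$cutoff, 2.5)
  d2 <- dichotomize(setNames(c(1, 2, 2, 5), paste0("s", 1:4)))
  expect_equal(unname(d2$group[2:3]), c("low", "low"))   # ties at the median
  expect_error(dichotomize(setNames(rep(3, 4), paste0("s", 1:4))),
               "all scores equal")
})

test_that("cutoff scan tests k-1 cutoffs and finds a clean changepoint", {
  set.seed(2)
  n <- 40
  scores <- setNames(1:n, paste0("s", 1:n))
  # true changepoint at 20: high scorers die early, low scorers late
  time <- ifelse(scores > 20, 1 + runif(n, 0, 0.5), 10 + runif(n, 0, 0.5))
  d <- dichotomize(scores, "scan", time = time, event = rep(1, n))
  expect_equal(d$n_cutoffs_tested, n - 1)
  expect_equal(unname(d$cutoff), 20)
  expect_setequal(names(d$group)[d$group == "high"], paste0("s", 21:n))
  expect_error(dichotomize(scores, "scan"), "needs time and event")
})

test_that("product-limit estimator matches hand-computed tables", {
  # all censored: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # three events: 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  # 6 subjects with a tie (event + censoring at t = 2): events precede
  # censoring, so the risk set at 2 still holds 5 subjects
  km2 <- km_estimate(c(1, 2, 2, 4, 5, 6), c(1, 1, 0, 1, 0, 1))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$time, c(1, 2, 4, 6))
  expect_equal(ev$n_risk, c(6, 5, 3, 1))
  expect_equal(ev$survival, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("product-limit estimator matches a risk-set simulation on random data", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 40
    time <- round(rexp(n, 0.2), 1)           # rounding forces ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    got <- km_estimate(time, event)
    got <- got[got$n_event > 0, ]
    want <- naive_km(time, event)
    expect_equal(got$time, want$time)
    expect_equal(got$n_risk, want$n_risk)
    expect_equal(got$survival, want$survival)
  }
})

test_that("log-rank statistic matches the hand-computed O/E/V table", {
  # group A: events at 1, 3, censored 5; group B: events at 2, 6, censored 4
  # O_A = 2, E_A = 0.5 + 0.4 + 0.5 + 0 = 1.4, sum V = 0.25 + 0.24 + 0.25
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  group <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, (2 - 1.4)^2 / 0.74, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq((2 - 1.4)^2 / 0.74, 1, lower.tail = FALSE))
  # symmetry under label swap
  lr2 <- logrank_test(time, event, c("B", "B", "B", "A", "A", "A")[c(4, 5, 6, 1, 2, 3)])
  expect_equal(lr2$statistic, lr$statistic)
  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), "two groups")
  expect_error(logrank_test(1:4, c(0, 0, 0, 0), rep(c("A", "B"), 2)), "one observed event")
})

test_that("simulated survival follows the exponential proportional-hazards model", {
  set.seed(77)
  scores <- setNames(runif(1000), paste0("s", 1:1000))
  # null: the two score groups have identical event-time distributions
  s0 <- simulate_survival(scores, hazard_ratio = 1, censoring_rate = 0)
  ks <- suppressWarnings(ks.test(s0$time[s0$group == "high"],
                                 s0$time[s0$group == "low"]))
  expect_gt(ks$p.value, 0.01)
  # hazard ratio 2, no censoring: group medians differ by a factor ~2
  s2 <- simulate_survival(scores, hazard_ratio = 2, censoring_rate = 0)
  ratio <- median(s2$time[s2$group == "low"]) / median(s2$time[s2$group == "high"])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
  # censoring rate is honored in expectation
  s3 <- simulate_survival(scores, hazard_ratio = 2, censoring_rate = 0.3)
  expect_equal(mean(1 - s3$event), 0.3, tolerance = 0.06)
  expect_error(simulate_survival(numeric(0)), "empty score list")
  # determinism under an explicit seed
  expect_identical(simulate_survival(scores, seed = 5),
                   simulate_survival(scores, seed = 5))
})

test_that("log-rank power at hazard ratio 2 with 30% censoring is high", {
  set.seed(99)
  rej <- replicate(20, {
    scores <- setNames(runif(400), paste0("s", 1:400))
    s <- simulate_survival(scores, hazard_ratio = 2, censoring_rate = 0.3)
    logrank_test(s$time, s$event, s$group)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.9)
})
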