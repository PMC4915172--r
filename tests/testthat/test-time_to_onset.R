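test_that("parse_partial_date classifies precision and parses day dates", {
  p <- parse_partial_date(c("2010-03-01", "2010-03", "2010", "", "20100304",
                            "201003", "2010-02-31"))
  expect_equal(p$precision,
               c("day", "month", "year", "missing", "day", "month", "missing"))
  expect_equal(p$date[1], as.Date("2010-03-01"))
  expect_equal(p$date[5], as.Date("2010-03-04"))
  expect_true(is.na(p$date[2]))
})

test_that("compute_durations uses first prescription and complete dates only", {
  db <- load_fixture_db()
  # two start dates for allopurinol in R01: earliest (2010-02-20) counts
  d <- compute_durations(db, "allopurinol")
  expect_setequal(d$report_id, c("R01", "R09"))
  expect_equal(d$duration_days[d$report_id == "R01"], 9)
  expect_equal(d$duration_days[d$report_id == "R09"], 20)

  # simple calendar arithmetic: start 2011-05-10, onset 2011-05-13
  d2 <- compute_durations(db, "loxoprofen")
  expect_equal(d2$duration_days, 3)  # R05 excluded: month-precision start
  expect_equal(unname(attr(d2, "exclusions")["partial_start"]), 1)

  # onset before start is excluded and counted
  d3 <- compute_durations(db, "carbamazepine")
  expect_equal(nrow(d3), 0)
  expect_equal(unname(attr(d3, "exclusions")["negative"]), 1)

  # interacting-role drug records never enter
  d4 <- compute_durations(db, "acetaminophen")
  expect_equal(d4$report_id, "R04")
  expect_equal(d4$duration_days, 14)
})

test_that("summarize_durations uses (n+1)p quartiles and exact extremes", {
  s <- summarize_durations(c(1, 2, 3, 8, 20))
  expect_equal(s$median, 3)
  expect_equal(s$lower_quartile, 1.5)
  expect_equal(s$upper_quartile, 14)
  expect_equal(s$minimum, 1)
  expect_equal(s$maximum, 20)

  s1 <- summarize_durations(7)
  expect_equal(unlist(s1[c("median", "lower_quartile", "upper_quartile",
                           "minimum", "maximum")]),
               c(median = 7, lower_quartile = 7, upper_quartile = 7,
                 minimum = 7, maximum = 7))
  expect_error(summarize_durations(numeric(0)), "at least one")
})

test_that("duration summary ordering invariant holds on random inputs", {
  set.seed(41)
  for (i in 1:50) {
    x <- rweibull(sample(1:60, 1), shape = runif(1, 0.3, 3),
                  scale = runif(1, 1, 50))
    s <- summarize_durations(x)
    expect_true(s$minimum <= s$lower_quartile)
    expect_true(s$lower_quartile <= s$median)
    expect_true(s$median <= s$upper_quartile)
    expect_true(s$upper_quartile <= s$maximum)
  }
})

test_that("summary of simulated durations tracks the generating quantiles", {
  set.seed(42)
  x <- rweibull(340, shape = 0.64, scale = 9.44)
  s <- summarize_durations(x)
  expect_equal(s$median, qweibull(0.5, 0.64, 9.44), tolerance = 0.25)
  expect_equal(s$lower_quartile, qweibull(0.25, 0.64, 9.44), tolerance = 0.35)
  expect_equal(s$upper_quartile, qweibull(0.75, 0.64, 9.44), tolerance = 0.25)
})

test_that("fit_weibull matches the dense grid-search oracle to 4 decimals", {
  # fixed 20-point toy sample
  t20 <- c(0.8, 1.4, 2.1, 2.7, 3.3, 4.0, 4.8, 5.1, 6.6, 7.2,
           8.9, 10.4, 12.8, 14.1, 17.9, 21.3, 26.7, 33.2, 44.6, 58.1)
  fit <- suppressWarnings(fit_weibull(t20))
  oracle <- grid_weibull_mle(t20)
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-4)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-4)
  expect_gte(fit$loglik, oracle$loglik - 1e-8)
})

test_that("the fitted likelihood dominates a surrounding grid", {
  set.seed(43)
  x <- rweibull(120, shape = 1.3, scale = 12)
  fit <- fit_weibull(x)
  alphas <- seq(fit$alpha * 0.5, fit$alpha * 1.5, length.out = 200)
  betas <- seq(fit$beta * 0.5, fit$beta * 1.5, length.out = 200)
  best_grid <- max(vapply(betas, function(b) {
    max(length(x) * log(b) - length(x) * b * log(alphas) +
          (b - 1) * sum(log(x)) - sum(x^b) / alphas^b)
  }, numeric(1)))
  expect_gte(fit$loglik, best_grid - 1e-8)
})

test_that("shape fixed at 1 reduces to the exponential closed form", {
  set.seed(44)
  x <- rweibull(150, shape = 1, scale = 20)
  fit <- fit_weibull(x, shape_fixed = 1)
  expect_equal(fit$alpha, mean(x), tolerance = 1e-12)
  expect_equal(fit$beta, 1)
})

test_that("fit_weibull agrees with the fitdistrplus cross-check", {
  skip_if_not_installed("fitdistrplus")
  set.seed(45)
  x <- rweibull(250, shape = 0.74, scale = 6.17)
  fit <- fit_weibull(x)
  oracle <- fitdistrplus::fitdist(x, "weibull")
  # fitdistrplus optimizes with optim's default tolerances; agree to ~1e-3
  expect_equal(fit$beta, unname(oracle$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(oracle$estimate["scale"]), tolerance = 1e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_gte(fit$loglik, oracle$loglik - 1e-10)  # ours is the true maximizer
})

test_that("scale equivariance: t -> k*t scales alpha and fixes beta", {
  set.seed(46)
  x <- rweibull(180, shape = 0.9, scale = 15)
  fit <- fit_weibull(x)
  for (k in c(0.1, 3, 250)) {
    fk <- fit_weibull(k * x)
    expect_equal(fk$alpha, k * fit$alpha, tolerance = 1e-6)
    expect_equal(fk$beta, fit$beta, tolerance = 1e-6)
  }
})

test_that("zero durations are shifted for fitting; small n warns; tiny n errors", {
  set.seed(47)
  x <- c(0, 0, round(rweibull(58, 0.8, 10)))
  x[x < 0] <- 0
  expect_silent(fit <- suppressWarnings(fit_weibull(x)))
  expect_true(fit$converged)
  expect_warning(fit_weibull(rweibull(30, 1, 5)), "cautiously")
  expect_error(suppressWarnings(fit_weibull(rweibull(5, 1, 5))), "below the minimum")
  expect_error(suppressWarnings(fit_weibull(c(-1, rweibull(20, 1, 5)))), ">= 0")
})

test_that("profile CIs bracket the estimate and resemble Wald CIs", {
  set.seed(48)
  x <- rweibull(200, shape = 0.7, scale = 10)
  fw <- fit_weibull(x)
  fp <- fit_weibull(x, ci_method = "profile")
  expect_true(fp$beta_ci[1] < fp$beta && fp$beta < fp$beta_ci[2])
  expect_true(fp$alpha_ci[1] < fp$alpha && fp$alpha < fp$alpha_ci[2])
  expect_equal(fp$beta_ci, fw$beta_ci, tolerance = 0.05)
})

test_that("classify_hazard implements the shape-parameter test rules", {
  mk <- function(beta, lo, hi) {
    structure(list(beta = beta, beta_ci = c(lo, hi), converged = TRUE),
              class = "weibull_fit")
  }
  expect_equal(classify_hazard(mk(0.64, 0.59, 0.69)), "DECREASING")
  expect_equal(classify_hazard(mk(1.02, 0.94, 1.10)), "CONSTANT_COMPATIBLE")
  # a CI bound touching 1 exactly does not exclude it
  expect_equal(classify_hazard(mk(1.17, 1.00, 1.35)), "CONSTANT_COMPATIBLE")
  expect_equal(classify_hazard(mk(0.81, 0.65, 1.00)), "CONSTANT_COMPATIBLE")
  expect_equal(classify_hazard(mk(1.17, 1.001, 1.35)), "INCREASING")
  unconverged <- mk(1, 0.9, 1.1)
  unconverged$converged <- FALSE
  expect_error(classify_hazard(unconverged), "converge")
})

test_that("hazard classification is calibrated for exponential data", {
  set.seed(49)
  classes <- replicate(200, {
    classify_hazard(fit_weibull(rweibull(200, shape = 1, scale = 15)))
  })
  rate <- mean(classes == "CONSTANT_COMPATIBLE")
  expect_gte(rate, 0.90)  # nominal 0.95 coverage of shape = 1
})

test_that("onset_histogram bins by day with an overflow bin", {
  h <- onset_histogram(c(0, 1, 1, 3))
  expect_equal(h$count[h$bin_start == 0], 1)
  expect_equal(h$count[h$bin_start == 1], 2)
  expect_equal(h$count[h$bin_start == 3], 1)
  expect_equal(sum(h$count), 4)

  h2 <- onset_histogram(c(60, 70, 100))
  expect_equal(h2$count[is.infinite(h2$bin_end)], 3)
  expect_equal(sum(h2$count[is.finite(h2$bin_end)]), 0)
})

test_that("short-latency drugs put most mass in the first days", {
  # generating distribution with scale 6.17, shape 0.74 concentrates more
  # than half of onsets within 4 days of treatment start
  expect_gt(pweibull(5, shape = 0.74, scale = 6.17), 0.5)
  set.seed(50)
  x <- round(rweibull(310, shape = 0.74, scale = 6.17))
  h <- onset_histogram(x)
  expect_gt(sum(h$count[h$bin_start <= 4]) / sum(h$count), 0.5)
})
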