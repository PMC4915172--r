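test_that("build_design codes year offset, gender and stratum indicators", {
  ds <- make_ds(8)  # spans all five strata, both sexes, years 2004..2011
  ds$sex[2] <- "female"; ds$age_stratum[2] <- "Y20_39"
  ds$reporting_year[2] <- 2010; ds$is_case[2] <- TRUE
  d <- build_design(ds, base_year = 2004)
  expect_equal(colnames(d$X),
               c("(Intercept)", "year", "female", "ageLE19", "ageY20_39",
                 "ageY60_79", "ageGE80"))
  expect_equal(unname(d$X[2, ]), c(1, 6, 1, 0, 1, 0, 0))
  expect_equal(d$y[2], 1)
  # full rank on a fixture spanning all strata (independent linear algebra check)
  expect_equal(qr(d$X)$rank, 7)
})

test_that("constant design columns are dropped with a warning", {
  ds <- make_ds(20, cases = c(1, 5, 9))
  ds$sex <- "male"
  expect_warning(d <- build_design(ds), "female")
  expect_false("female" %in% colnames(d$X))
})

test_that("reports without a reporting year are excluded and counted", {
  ds <- make_ds(20, cases = c(1, 5, 9))
  ds$reporting_year[3:4] <- NA
  d <- suppressMessages(build_design(ds))
  expect_equal(d$n_missing_year, 2)
  expect_equal(nrow(d$X), 18)
})

test_that("single-covariate logistic exp(beta) equals the 2x2 sample OR exactly", {
  # saturated 2x2 logistic reproduces the sample odds ratio in closed form
  exposed <- rep(c(1, 0), c(10, 90))
  y <- c(rep(1, 4), rep(0, 6), rep(1, 6), rep(0, 84))
  X <- cbind(`(Intercept)` = 1, exposed = exposed)
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$beta["exposed"])), (4 / 6) / (6 / 84),
               tolerance = 1e-9)
})

test_that("fit_logistic matches the glm oracle on multi-covariate data", {
  set.seed(31)
  n <- 600
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_logistic(X, y)
  oracle <- suppressWarnings(glm(y ~ X[, -1], family = binomial()))
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-4)
  expect_true(fit$loglik <= 0)
})

test_that("fit_logistic rejects degenerate inputs", {
  X <- cbind(1, rbinom(50, 1, 0.5))
  expect_error(fit_logistic(X, rep(0, 50)), "variation")
  expect_error(fit_logistic(cbind(X, X[, 2]), rbinom(50, 1, 0.5)),
               "rank")
  # perfectly separated data must raise, not return garbage
  xsep <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(cbind(1, xsep), xsep), "separat")
})

test_that("adjusted_ror_table exponentiates coefficients with Wald intervals", {
  set.seed(32)
  n <- 500
  X <- cbind(`(Intercept)` = 1, x = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1.5 + 0.6 * X[, "x"]))
  fit <- fit_logistic(X, y)
  tab <- adjusted_ror_table(fit)
  expect_equal(tab$term, "x")
  expect_equal(tab$ror, exp(tab$beta), tolerance = 1e-12)
  expect_equal(tab$ci_low, exp(tab$beta - 1.959964 * tab$se), tolerance = 1e-12)
  expect_true(tab$ci_low <= tab$ror && tab$ror <= tab$ci_high)
})

test_that("lrt_term equals the G-statistic on 2x2 data", {
  exposed <- rep(c(1, 0), c(10, 90))
  y <- c(rep(1, 4), rep(0, 6), rep(1, 6), rep(0, 84))
  X <- cbind(`(Intercept)` = 1, exposed = exposed)
  fit <- fit_logistic(X, y)
  lrt <- lrt_term(X, y, fit, "exposed")
  expect_equal(lrt$statistic, g_statistic(4, 6, 6, 84), tolerance = 1e-8)
  expect_equal(lrt$statistic, 7.46895651507, tolerance = 1e-8)
})

test_that("lrt_term matches the glm deviance-difference oracle", {
  set.seed(33)
  n <- 400
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * X[, "x1"]))
  fit <- fit_logistic(X, y)
  lrt <- lrt_term(X, y, fit, "x2")
  g_full <- glm(y ~ X[, "x1"] + X[, "x2"], family = binomial())
  g_red <- glm(y ~ X[, "x1"], family = binomial())
  expect_equal(lrt$statistic, g_red$deviance - g_full$deviance,
               tolerance = 1e-6)
  expect_true(lrt$statistic >= 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
})

test_that("Wald and LRT p-values agree within an order of magnitude", {
  set.seed(34)
  n <- 2000
  checked <- 0
  for (effect in c(0, 0.05, 0.1, 0.15, 0.2)) {
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    y <- rbinom(n, 1, plogis(-1.8 + effect * X[, "x"]))
    fit <- fit_logistic(X, y)
    tab <- adjusted_ror_table(fit)
    zstat <- abs(tab$beta / tab$se)
    if (zstat > 0 && zstat < 3) {
      p_wald <- 2 * pnorm(-zstat)
      p_lrt <- lrt_term(X, y, fit, "x")$p_value
      expect_lt(abs(log10(p_wald) - log10(p_lrt)), 1)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("parameter recovery from the synthetic generator is within 3 SE", {
  cfg <- default_sim_config(n_reports = 20000, rng_seed = 101)
  gen <- generate_database(cfg)
  ds <- suppressMessages(build_analysis_dataset(gen$db))
  d <- build_design(ds, base_year = 2004)
  fit <- fit_logistic(d$X, d$y)
  se <- sqrt(diag(fit$cov))
  truth <- c(year = cfg$beta_year, female = cfg$beta_female,
             ageLE19 = unname(cfg$beta_age["LE19"]),
             ageY20_39 = unname(cfg$beta_age["Y20_39"]),
             ageY60_79 = unname(cfg$beta_age["Y60_79"]),
             ageGE80 = unname(cfg$beta_age["GE80"]))
  for (term in names(truth)) {
    expect_lt(abs(fit$beta[term] - truth[term]), 3 * se[term])
  }
})

test_that("run_adjusted_analysis produces a whole-data block plus drug blocks", {
  cfg <- default_sim_config(n_reports = 30000, rng_seed = 102)
  gen <- generate_database(cfg)
  ds <- suppressMessages(build_analysis_dataset(gen$db))
  out <- suppressWarnings(suppressMessages(
    run_adjusted_analysis(ds, list(allopurinol = "allopurinol",
                                   loxoprofen = "loxoprofen"))))
  expect_equal(unique(out$block)[1], "total")
  expect_true(all(c("allopurinol", "loxoprofen") %in% out$block))
  expect_true(all(out$ci_low <= out$ror & out$ror <= out$ci_high))
  # subset equal to the whole data reproduces the whole-data block
  all_drugs <- unique(unlist(ds$suspected_drugs))
  out2 <- suppressMessages(
    run_adjusted_analysis(ds, list(everything = all_drugs)))
  total <- out2[out2$block == "total", c("beta", "ror", "lrt_p")]
  every <- out2[out2$block == "everything", c("beta", "ror", "lrt_p")]
  expect_equal(total, every, tolerance = 1e-9, ignore_attr = TRUE)
})
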