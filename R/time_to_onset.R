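# Time-to-onset analysis: drug-to-onset durations, descriptive quartiles,
# two-parameter Weibull maximum likelihood with Wald/profile CIs, and
# hazard-shape classification (the Weibull shape parameter test).

#' Parse a partial-precision date string
#'
#' Accepts "YYYY-MM-DD" (day precision), "YYYY-MM" (month), "YYYY" (year)
#' and "" (missing). Compact "YYYYMMDD"/"YYYYMM" forms are also accepted.
#'
#' @param x Character vector.
#' @return Data frame with columns `date` (Date; NA unless day precision)
#'   and `precision` (`"day"`, `"month"`, `"year"`, `"missing"`).
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  precision <- rep("missing", length(x))
  precision[grepl("^[0-9]{4}$", x)] <- "year"
  precision[grepl("^[0-9]{4}-[0-9]{2}$", x) | grepl("^[0-9]{6}$", x)] <- "month"
  is_day <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x) | grepl("^[0-9]{8}$", x)
  precision[is_day] <- "day"
  date <- rep(as.Date(NA), length(x))
  compact <- is_day & !grepl("-", x)
  date[is_day & !compact] <- as.Date(x[is_day & !compact], format = "%Y-%m-%d")
  date[compact] <- as.Date(x[compact], format = "%Y%m%d")
  precision[is_day & is.na(date)] <- "missing"  # e.g. 2010-02-31
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

#' Compute drug-to-onset durations for case reports
#'
#' For each (report, drug) pair where the drug is suspected, both the
#' start and onset dates have full day precision, and the report matches
#' the case definition: duration = earliest qualifying onset date minus
#' the earliest start date of that drug in the report, in whole days.
#' Combinations with partial/missing dates, and negative durations
#' (onset before first prescription), are excluded and counted.
#'
#' @param db A `report_database`.
#' @param drug_names Drugs (or a drug group) defining exposure.
#' @param case_def A `case_definition`.
#' @return Data frame (`report_id`, `drug_name`, `duration_days`) with an
#'   `exclusions` attribute: counts of pairs dropped for incomplete dates
#'   or negative durations.
#' @export
compute_durations <- function(db, drug_names, case_def = case_definition()) {
  stopifnot(inherits(db, "report_database"))
  targets <- normalize_drug_name(drug_names)

  reac <- db$reac[trimws(db$reac$pt_code) %in% case_def$pt_codes, , drop = FALSE]
  onset <- parse_partial_date(reac$onset_date)
  n_onset_partial <- sum(onset$precision != "day")
  reac <- reac[onset$precision == "day", , drop = FALSE]
  onset_date <- onset$date[onset$precision == "day"]
  # earliest qualifying onset per report
  first_onset <- tapply(onset_date, reac$report_id, min)

  drug <- db$drug[db$drug$role_code == "suspected", , drop = FALSE]
  drug <- drug[normalize_drug_name(drug$drug_name) %in% targets, , drop = FALSE]
  drug <- drug[drug$report_id %in% names(first_onset), , drop = FALSE]
  start <- parse_partial_date(drug$start_date)
  n_start_partial <- sum(start$precision != "day")
  drug <- drug[start$precision == "day", , drop = FALSE]
  start_date <- start$date[start$precision == "day"]

  if (nrow(drug) == 0L) {
    out <- data.frame(report_id = character(0), drug_name = character(0),
                      duration_days = numeric(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(drug$report_id, normalize_drug_name(drug$drug_name), sep = "\r")
    first_start <- tapply(start_date, key, min)
    ids <- sub("\r.*$", "", names(first_start))
    dn <- sub("^.*\r", "", names(first_start))
    dur <- as.numeric(unname(first_onset[ids]) - unname(first_start))
    out <- data.frame(report_id = ids, drug_name = dn, duration_days = dur,
                      stringsAsFactors = FALSE)
  }
  n_negative <- sum(out$duration_days < 0)
  out <- out[out$duration_days >= 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(partial_onset = n_onset_partial,
                               partial_start = n_start_partial,
                               negative = n_negative)
  out
}

#' Descriptive summary of time-to-onset durations
#'
#' Median and quartiles use the (n+1)p linear-interpolation convention
#' (R's quantile type 6); minimum and maximum are exact.
#'
#' @param durations Numeric vector of durations in days (or a data frame
#'   from [compute_durations()]).
#' @return List of class `duration_summary`: `n`, `median`,
#'   `lower_quartile`, `upper_quartile`, `minimum`, `maximum`.
#' @export
summarize_durations <- function(durations) {
  if (is.data.frame(durations)) durations <- durations$duration_days
  durations <- as.numeric(durations)
  if (length(durations) == 0L || any(is.na(durations))) {
    stop("summarize_durations: need at least one non-missing duration")
  }
  q <- stats::quantile(durations, probs = c(0.25, 0.5, 0.75), type = 6,
                       names = FALSE)
  structure(list(n = length(durations), median = q[2], lower_quartile = q[1],
                 upper_quartile = q[3], minimum = min(durations),
                 maximum = max(durations)),
            class = "duration_summary")
}

weibull_loglik <- function(t, alpha, beta) {
  n <- length(t)
  n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(log(t)) -
    sum((t / alpha)^beta)
}

# profile score for the shape: d/dbeta of the profile log-likelihood,
# with the scale concentrated out as alpha(beta) = mean(t^beta)^(1/beta)
weibull_profile_score <- function(t, beta) {
  n <- length(t)
  tb <- t^beta
  n / beta + sum(log(t)) - n * sum(tb * log(t)) / sum(tb)
}

weibull_profile_score_deriv <- function(t, beta) {
  n <- length(t)
  tb <- t^beta
  s0 <- sum(tb); s1 <- sum(tb * log(t)); s2 <- sum(tb * log(t)^2)
  -n / beta^2 - n * (s2 * s0 - s1^2) / s0^2
}

#' Two-parameter Weibull maximum-likelihood fit for time-to-onset data
#'
#' Maximizes the uncensored Weibull log-likelihood. The scale is profiled
#' out in closed form and the shape solves the profile score equation by
#' safeguarded Newton iteration (bisection fallback inside a bracketing
#' interval). Confidence intervals are Wald intervals on (log scale,
#' log shape) from the observed information, exponentiated; profile
#' likelihood intervals are available via `ci_method = "profile"`.
#'
#' Zero durations (events on the day of first prescription) are shifted
#' to `zero_shift` days before fitting, since the log-density is
#' undefined at 0; descriptive statistics elsewhere keep the raw zeros.
#'
#' @param durations Numeric vector of durations (days), all >= 0, or a
#'   data frame from [compute_durations()].
#' @param tol Convergence tolerance on the profile score (default 1e-10).
#' @param floor_n Minimum sample size; below it the fit is refused
#'   (default 10). Between `floor_n` and 100 a small-sample caution is
#'   emitted as a warning.
#' @param zero_shift Replacement value for zero durations (default 0.5).
#' @param shape_fixed Optional fixed shape; if supplied only the scale is
#'   estimated (shape 1 gives the exponential special case, where the
#'   scale estimate is the sample mean).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @return Object of class `weibull_fit`: `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci`, `n`, `loglik`, `converged`, `iterations`.
#' @export
fit_weibull <- function(durations, tol = 1e-10, floor_n = 10, zero_shift = 0.5,
                        shape_fixed = NULL, conf_level = 0.95,
                        ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  if (is.data.frame(durations)) durations <- durations$duration_days
  t <- as.numeric(durations)
  if (any(is.na(t)) || any(t < 0)) stop("fit_weibull: durations must be >= 0")
  n <- length(t)
  if (n < floor_n) {
    stop(sprintf("fit_weibull: n = %d below the minimum of %d", n, floor_n))
  }
  if (n < 100) {
    warning(sprintf(
      "fit_weibull: n = %d < 100; interpret the fit cautiously", n))
  }
  t[t == 0] <- zero_shift
  if (stats::var(t) == 0 && is.null(shape_fixed)) {
    stop("fit_weibull: all durations identical; shape is unbounded")
  }

  # condition by scaling to geometric mean 1; alpha rescales afterwards
  gm <- exp(mean(log(t)))
  s <- t / gm

  if (!is.null(shape_fixed)) {
    beta <- shape_fixed
    alpha_s <- mean(s^beta)^(1 / beta)
    converged <- TRUE
    iter <- 0L
  } else {
    # moment-style start from var(log T) = pi^2 / (6 beta^2)
    beta <- 1.2825 / stats::sd(log(s))
    lo <- beta; hi <- beta
    while (weibull_profile_score(s, lo) < 0 && lo > 1e-8) lo <- lo / 2
    while (weibull_profile_score(s, hi) > 0 && hi < 1e8) hi <- hi * 2
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      g <- weibull_profile_score(s, beta)
      if (abs(g) < tol) { converged <- TRUE; break }
      if (g > 0) lo <- beta else hi <- beta
      step <- g / weibull_profile_score_deriv(s, beta)
      cand <- beta - step
      if (!is.finite(cand) || cand <= lo || cand >= hi) cand <- (lo + hi) / 2
      if (abs(cand - beta) < 1e-14 * beta) { beta <- cand; converged <- TRUE; break }
      beta <- cand
      if (iter >= 200) break
    }
    alpha_s <- mean(s^beta)^(1 / beta)
  }
  alpha <- alpha_s * gm
  ll <- weibull_loglik(t, alpha, beta)

  # observed information on (log alpha, log beta) by central differences
  ll_uv <- function(u, v) weibull_loglik(t, exp(u), exp(v))
  u0 <- log(alpha); v0 <- log(beta)
  h <- 1e-4
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (ll_uv(u0 + h, v0) - 2 * ll_uv(u0, v0) + ll_uv(u0 - h, v0)) / h^2
  H[2, 2] <- (ll_uv(u0, v0 + h) - 2 * ll_uv(u0, v0) + ll_uv(u0, v0 - h)) / h^2
  H[1, 2] <- H[2, 1] <- (ll_uv(u0 + h, v0 + h) - ll_uv(u0 + h, v0 - h) -
                           ll_uv(u0 - h, v0 + h) + ll_uv(u0 - h, v0 - h)) / (4 * h^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!is.null(shape_fixed)) {
    se_u <- sqrt(-1 / H[1, 1])
    alpha_ci <- exp(u0 + c(-1, 1) * z * se_u)
    beta_ci <- c(beta, beta)
  } else if (ci_method == "wald") {
    covm <- solve(-H)
    se <- sqrt(diag(covm))
    alpha_ci <- exp(u0 + c(-1, 1) * z * se[1])
    beta_ci <- exp(v0 + c(-1, 1) * z * se[2])
  } else {
    alpha_ci <- profile_ci_alpha(t, alpha, beta, ll, conf_level)
    beta_ci <- profile_ci_beta(t, alpha, beta, ll, conf_level)
  }

  structure(list(alpha = alpha, beta = beta,
                 alpha_ci = alpha_ci, beta_ci = beta_ci,
                 n = n, loglik = ll, converged = converged,
                 iterations = iter, ci_method = ci_method),
            class = "weibull_fit")
}

profile_ci_beta <- function(t, alpha_hat, beta_hat, ll_max, conf_level) {
  crit <- stats::qchisq(conf_level, 1) / 2
  pl <- function(beta) {
    a <- mean(t^beta)^(1 / beta)
    weibull_loglik(t, a, beta) - (ll_max - crit)
  }
  lo <- beta_hat
  while (pl(lo) > 0 && lo > beta_hat / 1e4) lo <- lo / 1.5
  hi <- beta_hat
  while (pl(hi) > 0 && hi < beta_hat * 1e4) hi <- hi * 1.5
  c(stats::uniroot(pl, c(lo, beta_hat))$root,
    stats::uniroot(pl, c(beta_hat, hi))$root)
}

profile_ci_alpha <- function(t, alpha_hat, beta_hat, ll_max, conf_level) {
  crit <- stats::qchisq(conf_level, 1) / 2
  pl <- function(alpha) {
    opt <- stats::optimize(function(b) weibull_loglik(t, alpha, b),
                           interval = c(beta_hat / 50, beta_hat * 50),
                           maximum = TRUE)
    opt$objective - (ll_max - crit)
  }
  lo <- alpha_hat
  while (pl(lo) > 0 && lo > alpha_hat / 1e4) lo <- lo / 1.5
  hi <- alpha_hat
  while (pl(hi) > 0 && hi < alpha_hat * 1e4) hi <- hi * 1.5
  c(stats::uniroot(pl, c(lo, alpha_hat))$root,
    stats::uniroot(pl, c(alpha_hat, hi))$root)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull fit (n = %d): scale %.2f (%.2f-%.2f), shape %.2f (%.2f-%.2f) [%s]\n",
    x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], classify_hazard(x)))
  invisible(x)
}

#' Classify the hazard shape from a Weibull fit
#'
#' The Weibull shape parameter test: the hazard is `INCREASING` when the
#' shape exceeds 1 and its 95% CI excludes 1, `DECREASING` when it is
#' below 1 and the CI excludes 1 (early-failure pattern), and
#' `CONSTANT_COMPATIBLE` otherwise — including when a CI bound touches 1
#' exactly, which does not exclude it.
#'
#' @param fit A converged `weibull_fit`.
#' @return One of `"DECREASING"`, `"CONSTANT_COMPATIBLE"`, `"INCREASING"`.
#' @export
classify_hazard <- function(fit) {
  if (!isTRUE(fit$converged)) stop("classify_hazard: fit did not converge")
  if (fit$beta > 1 && fit$beta_ci[1] > 1) return("INCREASING")
  if (fit$beta < 1 && fit$beta_ci[2] < 1) return("DECREASING")
  "CONSTANT_COMPATIBLE"
}

#' Histogram of onset durations in day bins
#'
#' Integer counts per `bin_width`-day bin from 0 to `range_max` days, plus
#' an overflow bin for longer durations.
#'
#' @param durations Numeric vector (days) or data frame from
#'   [compute_durations()].
#' @param bin_width Bin width in days (default 1).
#' @param range_max Upper edge of the binned range in days (default 56).
#' @return Data frame with `bin_start`, `bin_end` (the overflow row has
#'   `bin_end = Inf`) and `count`.
#' @export
onset_histogram <- function(durations, bin_width = 1, range_max = 56) {
  if (is.data.frame(durations)) durations <- durations$duration_days
  durations <- as.numeric(durations)
  starts <- seq(0, range_max, by = bin_width)
  counts <- vapply(starts, function(s)
    sum(durations >= s & durations < s + bin_width), integer(1))
  data.frame(bin_start = c(starts, range_max + bin_width),
             bin_end = c(starts + bin_width, Inf),
             count = c(counts, sum(durations >= range_max + bin_width)))
}
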