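# Crude reporting odds ratio (ROR), Woolf confidence interval, signal
# classification and reporting ratios from 2x2 contingency tables of
# report counts.

Z95 <- 1.959964  # two-sided 95% normal quantile

#' Construct a 2x2 contingency table of report counts
#'
#' Cells follow the usual disproportionality layout: `a` reports with the
#' drug and the event, `b` with the drug and other events, `c` without the
#' drug and the event, `d` with neither.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency_table: cells must be non-negative integers")
  }
  structure(as.list(cells), n = sum(cells), class = "contingency_table")
}

#' Cross-classify reports by drug exposure and case status
#'
#' The counting unit is the report: a report listing two suspected drugs
#' from `drug_names` contributes a single count to the exposed margin.
#'
#' @param ds An `analysis_dataset`.
#' @param drug_names Character vector of suspected-drug names defining
#'   exposure (may be a drug group).
#' @return A `contingency_table` whose cells sum to `nrow(ds)`.
#' @export
build_contingency <- function(ds, drug_names) {
  if (nrow(ds) == 0L) stop("build_contingency: empty dataset")
  exposed <- if (length(drug_names) == 0L) {
    rep(FALSE, nrow(ds))
  } else {
    is_exposed(ds, drug_names)
  }
  case <- ds$is_case
  contingency_table(
    a = sum(exposed & case),
    b = sum(exposed & !case),
    c = sum(!exposed & case),
    d = sum(!exposed & !case)
  )
}

#' Crude reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a/b)/(c/d) = ad/(bc), with the log-normal (Woolf) interval
#' exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d)). If any cell is zero, 0.5
#' is added to all four cells (Haldane–Anscombe continuity correction)
#' and the result is flagged `corrected`.
#'
#' @param tab A `contingency_table`.
#' @param alpha_level Two-sided significance level for the interval
#'   (default 0.05 for a 95% CI).
#' @return An object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `signal`, `corrected`, plus the (possibly corrected) cells.
#' @export
crude_ror <- function(tab, alpha_level = 0.05) {
  stopifnot(inherits(tab, "contingency_table"))
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) {
    stop("crude_ror: a margin of the table is entirely zero; ROR undefined")
  }
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  z <- stats::qnorm(1 - alpha_level / 2)
  log_ror <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  res <- structure(list(
    ror = exp(log_ror),
    ci_low = exp(log_ror - z * se),
    ci_high = exp(log_ror + z * se),
    corrected = corrected,
    cells = c(a = a, b = b, c = cc, d = d)
  ), class = "ror_result")
  res$signal <- classify_signal(res)
  res
}

#' Classify a reporting odds ratio as a safety signal
#'
#' A signal requires both the point estimate and the lower 95% confidence
#' limit to be greater than or equal to 1.
#'
#' @param r A `ror_result`, or anything with `ror` and `ci_low` elements.
#' @return `TRUE` if the pair constitutes a signal.
#' @export
classify_signal <- function(r) {
  if (!is.finite(r$ror) || !is.finite(r$ci_low)) {
    stop("classify_signal: non-finite ROR or CI bound")
  }
  isTRUE(r$ror >= 1 && r$ci_low >= 1)
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.2f (95%% CI %.2f-%.2f)%s%s\n", x$ror, x$ci_low, x$ci_high,
              if (x$signal) " *signal*" else "",
              if (x$corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Reporting ratio: percentage of a drug's reports naming the event
#'
#' @param cases Number of reports of the event for the drug.
#' @param total Total number of reports for the drug.
#' @return Percentage `100 * cases / total` (full precision; render with
#'   one or two decimals for tables).
#' @export
reporting_ratio <- function(cases, total) {
  if (is.na(total) || total <= 0) stop("reporting_ratio: total must be positive")
  if (is.na(cases) || cases < 0 || cases > total) {
    stop("reporting_ratio: cases must lie in [0, total]")
  }
  100 * cases / total
}
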