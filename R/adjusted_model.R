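# Adjusted reporting odds ratios: logistic regression of case status on
# reporting year, gender and age stratum, fit by Newton-Raphson/IRLS, with
# Wald intervals and likelihood-ratio tests, on the whole dataset and on
# per-drug subsets.

DESIGN_TERMS <- c("year", "female", "ageLE19", "ageY20_39", "ageY60_79", "ageGE80")

#' Build the design matrix for the adjustment model
#'
#' Codes log(odds of case) = b0 + b1*Y + b2*G + b3*A where Y is the
#' reporting year (a single linear term, offset by `base_year` for
#' conditioning), G is a female indicator, and A is four indicators for
#' the age strata LE19, Y20_39, Y60_79 and GE80 with Y40_59 as the
#' reference (carried as all-zero indicators). Reports with an unknown
#' reporting year are dropped (counted); columns that are constant in the
#' data (e.g. an unpopulated stratum) are dropped with a warning as a
#' perfect-separation guard.
#'
#' @param ds An `analysis_dataset` (complete-case).
#' @param base_year Year subtracted from `reporting_year`; defaults to the
#'   minimum observed year.
#' @return List with elements `X` (matrix, intercept first), `y` (0/1
#'   outcome), `base_year`, `dropped` (names of dropped constant columns)
#'   and `n_missing_year`.
#' @export
build_design <- function(ds, base_year = NULL) {
  ok <- !is.na(ds$reporting_year)
  n_missing_year <- sum(!ok)
  if (n_missing_year > 0) {
    message(sprintf("build_design: %d report(s) without reporting year excluded",
                    n_missing_year))
  }
  ds <- ds[ok, , drop = FALSE]
  if (nrow(ds) == 0L) stop("build_design: no reports with a reporting year")
  if (is.null(base_year)) base_year <- min(ds$reporting_year)
  X <- cbind(
    `(Intercept)` = 1,
    year = ds$reporting_year - base_year,
    female = as.numeric(ds$sex == "female"),
    ageLE19 = as.numeric(ds$age_stratum == "LE19"),
    ageY20_39 = as.numeric(ds$age_stratum == "Y20_39"),
    ageY60_79 = as.numeric(ds$age_stratum == "Y60_79"),
    ageGE80 = as.numeric(ds$age_stratum == "GE80")
  )
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1L)
  dropped <- names(const)[const]
  if (length(dropped)) {
    warning("build_design: constant column(s) dropped: ",
            paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  list(X = X, y = as.numeric(ds$is_case), base_year = base_year,
       dropped = dropped, n_missing_year = n_missing_year)
}

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  # numerically stable log(1 + exp(eta))
  log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - log1pe)
}

#' Fit a logistic regression by Newton-Raphson (IRLS) maximum likelihood
#'
#' Convergence when the score sup-norm falls below `tol` or the relative
#' change in log-likelihood does. The covariance is the inverse observed
#' information at the optimum. Divergence of the coefficients is treated
#' as perfect separation and raised as an error.
#'
#' @param X Design matrix (full column rank; intercept included).
#' @param y 0/1 outcome vector.
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return Object of class `logistic_fit`: `beta`, `cov`, `loglik`, `n`,
#'   `converged`, `iterations`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) {
    stop("fit_logistic: outcome has no variation")
  }
  if (qr(X)$rank < ncol(X)) stop("fit_logistic: design matrix is rank-deficient")
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  ll <- logistic_loglik(X, y, beta)
  converged <- FALSE
  iter <- 0
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- stats::plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) {
      stop("fit_logistic: singular information matrix (possible separation)")
    })
    # step-halving so the log-likelihood never decreases
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- logistic_loglik(X, y, cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) stop("fit_logistic: step-halving failed to improve likelihood")
    }
    beta <- cand
    if (max(abs(beta)) > 30) {
      stop("fit_logistic: coefficients diverging; data are likely perfectly separated")
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    if (max(abs(score)) < tol || rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  covb <- solve(H)
  dimnames(covb) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(beta = beta, cov = covb, loglik = ll, n = nrow(X),
                 converged = converged, iterations = iter),
            class = "logistic_fit")
}

#' Adjusted reporting odds ratios from a logistic fit
#'
#' One row per non-intercept term: the coefficient, its exponential (the
#' adjusted ROR) and the Wald 95% CI exp(beta ± z·SE).
#'
#' @param fit A converged `logistic_fit`.
#' @param z Normal quantile for the interval (default 1.959964).
#' @return Data frame with columns `term`, `beta`, `se`, `ror`, `ci_low`,
#'   `ci_high`.
#' @export
adjusted_ror_table <- function(fit, z = Z95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("adjusted_ror_table: fit did not converge")
  terms <- setdiff(names(fit$beta), "(Intercept)")
  se <- sqrt(diag(fit$cov))[terms]
  b <- fit$beta[terms]
  data.frame(term = terms, beta = unname(b), se = unname(se),
             ror = unname(exp(b)),
             ci_low = unname(exp(b - z * se)),
             ci_high = unname(exp(b + z * se)),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test for a single model term
#'
#' Refits the model without the term's column; the statistic
#' 2·(loglik_full − loglik_reduced) is referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param X,y The design matrix and outcome used for `fit_full`.
#' @param fit_full The full-model `logistic_fit`.
#' @param term Column name of the term to test.
#' @return List with `statistic`, `p_value` and `converged` (of the
#'   reduced fit); `p_value` is `NA` when the reduced fit fails.
#' @export
lrt_term <- function(X, y, fit_full, term) {
  X <- as.matrix(X)
  if (!term %in% colnames(X)) stop("lrt_term: unknown term: ", term)
  X_red <- X[, setdiff(colnames(X), term), drop = FALSE]
  fit_red <- tryCatch(fit_logistic(X_red, y), error = function(e) NULL)
  if (is.null(fit_red) || !fit_red$converged) {
    return(list(statistic = NA_real_, p_value = NA_real_, converged = FALSE))
  }
  stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       converged = TRUE)
}

fit_block <- function(ds, block, base_year, z) {
  if (length(unique(ds$is_case)) < 2L) {
    warning(sprintf("adjusted analysis: block '%s' has no outcome variation; skipped",
                    block))
    return(NULL)
  }
  d <- build_design(ds, base_year = base_year)
  fit <- tryCatch(fit_logistic(d$X, d$y), error = function(e) {
    warning(sprintf("adjusted analysis: block '%s' failed to fit (%s); skipped",
                    block, conditionMessage(e)))
    NULL
  })
  if (is.null(fit)) return(NULL)
  tab <- adjusted_ror_table(fit, z = z)
  tab$lrt_p <- vapply(tab$term, function(tm)
    lrt_term(d$X, d$y, fit, tm)$p_value, numeric(1))
  tab$significant <- !is.na(tab$lrt_p) & tab$lrt_p <= 0.05
  tab$block <- block
  tab$n <- fit$n
  tab[, c("block", "term", "n", "beta", "se", "lrt_p", "ror",
          "ci_low", "ci_high", "significant")]
}

#' Whole-database and per-drug-subset adjusted ROR analysis
#'
#' Fits the adjustment model on the whole dataset, then separately within
#' each drug (or drug-group) subset — the intraclass subset strategy: the
#' exposed reports form a population sharing a therapeutic context, and
#' the age/gender/year coefficients inside it are the subset-adjusted
#' RORs. Each term also gets a one-degree-of-freedom likelihood-ratio
#' test (significance at p <= 0.05).
#'
#' @param ds An `analysis_dataset`.
#' @param drugs Named list of character vectors: each element a drug or
#'   drug group to analyse as a subset. Empty list = whole data only.
#' @param base_year Offset for the year term (default: minimum year in
#'   `ds`).
#' @param z Normal quantile for Wald intervals.
#' @return Data frame, one row per (block, term), the whole-data block
#'   labelled `"total"` first.
#' @export
run_adjusted_analysis <- function(ds, drugs = list(), base_year = NULL, z = Z95) {
  if (is.character(drugs)) drugs <- as.list(stats::setNames(drugs, drugs))
  if (is.null(base_year)) base_year <- min(ds$reporting_year, na.rm = TRUE)
  blocks <- list(fit_block(ds, "total", base_year, z))
  for (nm in names(drugs)) {
    sub <- tryCatch(subset_by_drug(ds, drugs[[nm]]), error = function(e) {
      warning(sprintf("adjusted analysis: block '%s' empty; skipped", nm))
      NULL
    })
    if (!is.null(sub)) blocks <- c(blocks, list(fit_block(sub, nm, base_year, z)))
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
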