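# Synthetic JADER-schema database generator with known ground truth, so
# that ingestion, disproportionality, adjustment and time-to-onset stages
# can all be validated end to end without external data.

#' Build and validate a simulation configuration
#'
#' The generator draws, per report: sex, a 10-year age band, a reporting
#' year; independent per-drug suspected-exposure indicators from a drug
#' catalogue; case status from a logistic model
#' log(odds) = b0 + b_year*(year - first year) + b_female*G + b_age[stratum]
#' whose odds are multiplied, for every exposed catalogue drug, by that
#' drug's `enrichment_or` (this induces a drug-event association of known
#' odds ratio without putting drug terms in the logistic model, so crude
#' and adjusted recovery can be tested independently); and, for each
#' suspected catalogue drug on a case report, an onset date equal to the
#' drug start date plus a rounded Weibull(scale = latency_alpha, shape =
#' latency_beta) latency in days. Missingness is completely at random,
#' applied after generation.
#'
#' @param n_reports Number of reports to generate.
#' @param year_range Integer vector `c(first, last)` reporting year.
#' @param sex_probs Named probabilities for `male`/`female` (sum to 1).
#' @param age_band_probs Named probabilities per decade band ("0s"...).
#' @param drugs Data frame with columns `name`, `exposure_prob`,
#'   `enrichment_or`, `latency_alpha`, `latency_beta`.
#' @param beta0,beta_year,beta_female Logistic model coefficients.
#' @param beta_age Named vector of stratum coefficients for `LE19`,
#'   `Y20_39`, `Y60_79`, `GE80` (reference `Y40_59` = 0).
#' @param missingness Named list of MCAR rates: `sex`, `age`,
#'   `start_date`, `onset_date`.
#' @param case_pt_codes PT codes emitted for case reactions.
#' @param background_pt_codes PT codes for non-case reactions.
#' @param filler_drugs Names of background suspected drugs (every report
#'   gets one, so every report has at least one suspected drug).
#' @param concomitant_prob Probability a report carries an additional
#'   concomitant-role drug record (exercises the role-code filter).
#' @param background_latency `c(alpha, beta)` Weibull latency used for
#'   case reports with no catalogue exposure.
#' @param rng_seed Default seed used by [generate_database()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_reports,
                       year_range = c(2004, 2015),
                       sex_probs = c(male = 0.508, female = 0.492),
                       age_band_probs = c("0s" = 0.038, "10s" = 0.038,
                                          "20s" = 0.052, "30s" = 0.052,
                                          "40s" = 0.110, "50s" = 0.110,
                                          "60s" = 0.238, "70s" = 0.238,
                                          "80s" = 0.099, "90s" = 0.025),
                       drugs = NULL,
                       beta0 = -4.0,
                       beta_year = -0.025,
                       beta_female = 0.104,
                       beta_age = c(LE19 = 0.284, Y20_39 = 0.579,
                                    Y60_79 = -0.349, GE80 = -0.327),
                       missingness = list(sex = 0, age = 0,
                                          start_date = 0, onset_date = 0),
                       case_pt_codes = c("10042033", "10030081", "10044223"),
                       background_pt_codes = sprintf("20%06d", 1:40),
                       filler_drugs = sprintf("background_drug_%02d", 1:30),
                       concomitant_prob = 0.3,
                       background_latency = c(alpha = 20, beta = 1),
                       rng_seed = 1L) {
  if (is.null(drugs)) {
    drugs <- data.frame(name = character(0), exposure_prob = numeric(0),
                        enrichment_or = numeric(0), latency_alpha = numeric(0),
                        latency_beta = numeric(0))
  }
  cfg <- structure(list(
    n_reports = as.integer(n_reports), year_range = as.integer(year_range),
    sex_probs = sex_probs, age_band_probs = age_band_probs, drugs = drugs,
    beta0 = beta0, beta_year = beta_year, beta_female = beta_female,
    beta_age = beta_age, missingness = missingness,
    case_pt_codes = as.character(case_pt_codes),
    background_pt_codes = as.character(background_pt_codes),
    filler_drugs = filler_drugs, concomitant_prob = concomitant_prob,
    background_latency = background_latency,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ok_prob <- function(p) all(is.finite(p)) && all(p >= 0) && all(p <= 1)
  if (cfg$n_reports < 1) stop("sim_config: n_reports must be positive")
  if (!ok_prob(cfg$sex_probs) || abs(sum(cfg$sex_probs) - 1) > 1e-8) {
    stop("sim_config: sex_probs must be probabilities summing to 1")
  }
  if (!ok_prob(cfg$age_band_probs) || abs(sum(cfg$age_band_probs) - 1) > 1e-8) {
    stop("sim_config: age_band_probs must be probabilities summing to 1")
  }
  if (any(map_age_band(names(cfg$age_band_probs)) == "UNKNOWN")) {
    stop("sim_config: age_band_probs names must be decade labels")
  }
  miss <- unlist(cfg$missingness[c("sex", "age", "start_date", "onset_date")])
  if (length(miss) != 4L || !ok_prob(miss)) {
    stop("sim_config: missingness must give rates in [0,1] for sex, age, start_date, onset_date")
  }
  d <- cfg$drugs
  if (nrow(d)) {
    need <- c("name", "exposure_prob", "enrichment_or", "latency_alpha", "latency_beta")
    if (!all(need %in% names(d))) stop("sim_config: drugs lacks required columns")
    if (!ok_prob(d$exposure_prob)) stop("sim_config: exposure_prob out of [0,1]")
    if (any(d$enrichment_or <= 0) || any(d$latency_alpha <= 0) ||
        any(d$latency_beta <= 0)) {
      stop("sim_config: enrichment_or and latency parameters must be positive")
    }
  }
  if (length(cfg$case_pt_codes) == 0L) stop("sim_config: case_pt_codes empty")
  invisible(cfg)
}

#' Expected marginal case fraction implied by a configuration
#'
#' Exact expectation of the case probability over the discrete covariate
#' distribution (sex x age band x year) and all catalogue-drug exposure
#' combinations; used to calibrate the intercept.
#'
#' @param cfg A `sim_config`.
#' @return The expected proportion of case reports.
#' @export
expected_case_fraction <- function(cfg) {
  years <- cfg$year_range[1]:cfg$year_range[2]
  strata <- map_age_band(names(cfg$age_band_probs))
  grid <- expand.grid(sex = names(cfg$sex_probs), band = seq_along(strata),
                      year = years, KEEP.OUT.ATTRS = FALSE)
  w <- cfg$sex_probs[grid$sex] * cfg$age_band_probs[grid$band] / length(years)
  age_eff <- ifelse(strata[grid$band] %in% names(cfg$beta_age),
                    cfg$beta_age[strata[grid$band]], 0)
  eta <- cfg$beta0 + cfg$beta_year * (grid$year - cfg$year_range[1]) +
    cfg$beta_female * (grid$sex == "female") + age_eff
  nd <- nrow(cfg$drugs)
  if (nd == 0L) return(sum(w * stats::plogis(eta)))
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), nd)))
  p_combo <- apply(combos, 1, function(e)
    prod(ifelse(e == 1, cfg$drugs$exposure_prob, 1 - cfg$drugs$exposure_prob)))
  log_mult <- drop(combos %*% log(cfg$drugs$enrichment_or))
  sum(vapply(seq_len(nrow(combos)), function(k)
    p_combo[k] * sum(w * stats::plogis(eta + log_mult[k])), numeric(1)))
}

random_date_in_year <- function(year) {
  start <- as.Date(sprintf("%d-01-01", year))
  ndays <- ifelse(format(as.Date(sprintf("%d-12-31", year)), "%j") == "366",
                  366L, 365L)
  start + floor(stats::runif(length(year)) * ndays)
}

#' Generate a synthetic JADER-schema database with ground truth
#'
#' See [sim_config()] for the generative model. Identical seeds produce
#' identical databases.
#'
#' @param cfg A `sim_config`.
#' @param seed Seed overriding `cfg$rng_seed`.
#' @return List with `db` (a `report_database`) and `truth` (class
#'   `sim_truth`): the coefficient vector, per-drug realized exposed /
#'   exposed-case counts and latency parameters, the per-report latent
#'   case probabilities, the realized case fraction, and the number of
#'   reports with complete sex and age after missingness.
#' @export
generate_database <- function(cfg, seed = cfg$rng_seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  n <- cfg$n_reports
  years <- cfg$year_range[1]:cfg$year_range[2]

  report_id <- sprintf("R%07d", seq_len(n))
  sex <- sample(names(cfg$sex_probs), n, TRUE, prob = cfg$sex_probs)
  age_band <- sample(names(cfg$age_band_probs), n, TRUE,
                     prob = cfg$age_band_probs)
  year <- sample(years, n, TRUE)
  stratum <- map_age_band(age_band)

  age_eff <- ifelse(stratum %in% names(cfg$beta_age), cfg$beta_age[stratum], 0)
  eta <- cfg$beta0 + cfg$beta_year * (year - cfg$year_range[1]) +
    cfg$beta_female * (sex == "female") + age_eff

  nd <- nrow(cfg$drugs)
  exposure <- matrix(FALSE, n, max(nd, 1))
  if (nd > 0) {
    exposure <- matrix(stats::runif(n * nd), n, nd) <
      matrix(cfg$drugs$exposure_prob, n, nd, byrow = TRUE)
    eta <- eta + drop(exposure %*% log(cfg$drugs$enrichment_or))
  }
  p_case <- stats::plogis(eta)
  is_case <- stats::runif(n) < p_case

  # drug table: one background suspected drug per report, catalogue
  # exposures as suspected, optional concomitant noise
  filler_name <- sample(cfg$filler_drugs, n, TRUE)
  filler_start <- random_date_in_year(year)
  drug_rows <- list(data.frame(
    report_id = report_id, drug_name = filler_name, role_code = "suspected",
    start_date = format(filler_start, "%Y-%m-%d"), stringsAsFactors = FALSE))

  catalog_start <- vector("list", max(nd, 0))
  if (nd > 0) {
    for (j in seq_len(nd)) {
      idx <- which(exposure[, j])
      sd_j <- random_date_in_year(year[idx])
      catalog_start[[j]] <- list(idx = idx, start = sd_j)
      drug_rows[[length(drug_rows) + 1L]] <- data.frame(
        report_id = report_id[idx], drug_name = cfg$drugs$name[j],
        role_code = "suspected", start_date = format(sd_j, "%Y-%m-%d"),
        stringsAsFactors = FALSE)
    }
  }
  conc <- which(stats::runif(n) < cfg$concomitant_prob)
  if (length(conc)) {
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      report_id = report_id[conc],
      drug_name = sample(cfg$filler_drugs, length(conc), TRUE),
      role_code = "concomitant",
      start_date = format(random_date_in_year(year[conc]), "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }
  drug_tab <- do.call(rbind, drug_rows)

  # reac table: per (case report, exposed catalogue drug) one case PT with
  # Weibull latency from that drug's start date; background-only cases get
  # one case PT; non-cases get one background PT
  reac_rows <- list()
  covered <- rep(FALSE, n)
  if (nd > 0) {
    for (j in seq_len(nd)) {
      idx <- catalog_start[[j]]$idx
      ci <- is_case[idx]
      if (!any(ci)) next
      lat <- round(stats::rweibull(sum(ci), shape = cfg$drugs$latency_beta[j],
                                   scale = cfg$drugs$latency_alpha[j]))
      onset <- catalog_start[[j]]$start[ci] + lat
      reac_rows[[length(reac_rows) + 1L]] <- data.frame(
        report_id = report_id[idx][ci],
        pt_code = sample(cfg$case_pt_codes, sum(ci), TRUE),
        onset_date = format(onset, "%Y-%m-%d"), stringsAsFactors = FALSE)
      covered[idx[ci]] <- TRUE
    }
  }
  bg_case <- which(is_case & !covered)
  if (length(bg_case)) {
    lat <- round(stats::rweibull(length(bg_case),
                                 shape = cfg$background_latency["beta"],
                                 scale = cfg$background_latency["alpha"]))
    reac_rows[[length(reac_rows) + 1L]] <- data.frame(
      report_id = report_id[bg_case],
      pt_code = sample(cfg$case_pt_codes, length(bg_case), TRUE),
      onset_date = format(filler_start[bg_case] + lat, "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }
  noncase <- which(!is_case)
  reac_rows[[length(reac_rows) + 1L]] <- data.frame(
    report_id = report_id[noncase],
    pt_code = sample(cfg$background_pt_codes, length(noncase), TRUE),
    onset_date = format(random_date_in_year(year[noncase]), "%Y-%m-%d"),
    stringsAsFactors = FALSE)
  reac_tab <- do.call(rbind, reac_rows)

  hist_idx <- which(stats::runif(n) < 0.3)
  hist_tab <- data.frame(
    report_id = report_id[hist_idx],
    condition = sample(sprintf("condition_%02d", 1:15), length(hist_idx), TRUE),
    stringsAsFactors = FALSE)

  # MCAR missingness, applied after generation
  miss_sex <- stats::runif(n) < cfg$missingness$sex
  miss_age <- stats::runif(n) < cfg$missingness$age
  demo_tab <- data.frame(
    report_id = report_id,
    sex = ifelse(miss_sex, "unknown", sex),
    age_band = ifelse(miss_age, "", age_band),
    reporting_year = as.character(year), stringsAsFactors = FALSE)
  drug_tab$start_date[stats::runif(nrow(drug_tab)) < cfg$missingness$start_date] <- ""
  reac_tab$onset_date[stats::runif(nrow(reac_tab)) < cfg$missingness$onset_date] <- ""

  rownames(demo_tab) <- rownames(drug_tab) <- rownames(reac_tab) <-
    rownames(hist_tab) <- NULL

  counts <- lapply(list(demo = demo_tab, drug = drug_tab, reac = reac_tab,
                        hist = hist_tab),
                   function(tab) list(rows = nrow(tab), malformed = 0L))
  db <- structure(list(demo = demo_tab, drug = drug_tab, reac = reac_tab,
                       hist = hist_tab, counts = counts),
                  class = "report_database")

  per_drug <- NULL
  if (nd > 0) {
    per_drug <- data.frame(
      name = cfg$drugs$name,
      n_exposed = colSums(exposure),
      n_exposed_case = vapply(seq_len(nd), function(j)
        sum(exposure[, j] & is_case), numeric(1)),
      enrichment_or = cfg$drugs$enrichment_or,
      latency_alpha = cfg$drugs$latency_alpha,
      latency_beta = cfg$drugs$latency_beta,
      stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    seed = seed,
    n_reports = n,
    coefficients = c(beta0 = cfg$beta0, year = cfg$beta_year,
                     female = cfg$beta_female, cfg$beta_age),
    per_drug = per_drug,
    n_cases = sum(is_case),
    case_fraction = mean(is_case),
    p_case = p_case,
    n_complete_sex_age = sum(!miss_sex & !miss_age)
  ), class = "sim_truth")

  list(db = db, truth = truth)
}

#' Write a report database to a directory of four CSV files
#'
#' @param db A `report_database`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(demo = file.path(dir, "demo.csv"), drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"), hist = file.path(dir, "hist.csv"))
  for (tn in names(paths)) {
    utils::write.csv(db[[tn]], paths[[tn]], row.names = FALSE, quote = TRUE,
                     na = "")
  }
  invisible(paths)
}

#' Write simulation ground truth as JSON
#'
#' The per-report latent probabilities are summarized (mean), not dumped.
#'
#' @param truth A `sim_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth[c("seed", "n_reports", "n_cases",
                 "case_fraction", "n_complete_sex_age")]
  out$coefficients <- as.list(truth$coefficients)
  out$mean_p_case <- mean(truth$p_case)
  out$per_drug <- truth$per_drug
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default simulation configuration emulating a national-scale SRS
#'
#' Study conditions of a JADER-like database: sex and age-band mix and a
#' 1.86% marginal case fraction matching a national spontaneous-report
#' database; five catalogue drugs whose exposure probabilities and
#' enrichment odds ratios reproduce the count structure of the most
#' frequently implicated SJS/TEN drugs (crude ORs about 14.9, 7.1, 19.9,
#' 5.7 and 11.5), with per-drug Weibull onset latencies (scale, shape) of
#' (45.66, 0.62), (9.44, 0.64), (6.17, 0.74), (31.20, 1.02) and
#' (46.66, 0.71) days; stratum coefficients 0.284, 0.579, -0.349, -0.327
#' (reference 40-59 years), year -0.025, female 0.104. The intercept is
#' solved numerically so the expected case fraction hits the target.
#' Default missingness: sex 1.7%, age 5% (about 6.6% of reports fail the
#' complete-case filter), start date 5%, onset date 4.7%.
#'
#' @param n_reports Number of reports (default 50000).
#' @param target_case_fraction Marginal case prevalence (default 0.0186).
#' @param missingness MCAR rates; see [sim_config()].
#' @param rng_seed Default generation seed.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_reports = 50000,
                               target_case_fraction = 0.0186,
                               missingness = list(sex = 0.017, age = 0.05,
                                                  start_date = 0.05,
                                                  onset_date = 0.047),
                               rng_seed = 1L) {
  drugs <- data.frame(
    name = c("allopurinol", "loxoprofen", "acetaminophen",
             "carbamazepine", "lamotrigine"),
    exposure_prob = c(0.00746, 0.01332, 0.00544, 0.01276, 0.00671),
    enrichment_or = c(14.86, 7.12, 19.89, 5.73, 11.45),
    latency_alpha = c(45.66, 9.44, 6.17, 31.20, 46.66),
    latency_beta = c(0.62, 0.64, 0.74, 1.02, 0.71),
    stringsAsFactors = FALSE)
  cfg <- sim_config(n_reports = n_reports, drugs = drugs,
                    missingness = missingness, rng_seed = rng_seed)
  f <- function(b0) {
    cfg$beta0 <- b0
    expected_case_fraction(cfg) - target_case_fraction
  }
  cfg$beta0 <- stats::uniroot(f, c(-12, 0), tol = 1e-10)$root
  cfg
}
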