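# Config-driven orchestration: reproduce the three result tables (counts /
# crude ROR, adjusted ROR, time-to-onset) and per-drug onset histograms on
# any JADER-schema input, with a run manifest of filter-step counts.

#' Default drug and drug-group definitions
#'
#' The five single drugs most frequently implicated in SJS/TEN plus two
#' published drug classes: a 6-drug ACE-inhibitor group and an 11-drug
#' corticosteroid group.
#'
#' @return Named list of character vectors of drug names.
#' @export
default_drug_groups <- function() {
  list(
    allopurinol = "allopurinol",
    loxoprofen = "loxoprofen",
    acetaminophen = "acetaminophen",
    carbamazepine = "carbamazepine",
    lamotrigine = "lamotrigine",
    ace_inhibitors = c("imidapril hydrochloride", "enalapril maleate",
                       "temocapril hydrochloride", "lisinopril hydrate",
                       "perindopril erbumine", "alacepril"),
    corticosteroids = c("dexamethasone", "dexamethasone sodium phosphate",
                        "dexamethasone acetate", "triamcinolone acetonide",
                        "prednisolone", "prednisolone acetate",
                        "betamethasone",
                        "betamethasone/d-chlorpheniramine maleate mixture",
                        "betamethasone valerate/gentamicin sulfate",
                        "methylprednisolone",
                        "methylprednisolone sodium succinate")
  )
}

#' Crude-ROR counts table across strata (machine twin of a counts table)
#'
#' One row per (drug group, subgroup): the 2x2 cells, crude ROR with 95%
#' CI, signal flag and reporting ratio, for the overall dataset and for
#' each age-stratum x sex subgroup.
#'
#' @param ds An `analysis_dataset`.
#' @param drug_groups Named list of drug-name vectors.
#' @return Data frame.
#' @export
counts_table <- function(ds, drug_groups) {
  subgroups <- list(list(label = "total", keep = rep(TRUE, nrow(ds))))
  for (st in c("LE19", "Y20_39", "Y40_59", "Y60_79", "GE80")) {
    for (sx in c("male", "female")) {
      subgroups[[length(subgroups) + 1L]] <- list(
        label = paste(st, sx, sep = "_"),
        keep = ds$age_stratum == st & ds$sex == sx)
    }
  }
  rows <- list()
  for (gname in names(drug_groups)) {
    for (sg in subgroups) {
      sub <- ds[sg$keep, , drop = FALSE]
      class(sub) <- class(ds)
      if (nrow(sub) == 0L) next
      tab <- build_contingency(sub, drug_groups[[gname]])
      n_drug <- tab$a + tab$b
      row <- data.frame(drug = gname, subgroup = sg$label,
                        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                        reporting_ratio = if (n_drug > 0)
                          reporting_ratio(tab$a, n_drug) else NA_real_,
                        ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        signal = NA, corrected = NA,
                        stringsAsFactors = FALSE)
      r <- tryCatch(crude_ror(tab), error = function(e) NULL)
      if (!is.null(r)) {
        row$ror <- r$ror; row$ci_low <- r$ci_low; row$ci_high <- r$ci_high
        row$signal <- r$signal; row$corrected <- r$corrected
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-to-onset table across drug groups (machine twin of a Weibull table)
#'
#' @param db A `report_database`.
#' @param drug_groups Named list of drug-name vectors.
#' @param case_def A `case_definition`.
#' @param floor_n Minimum sample size for a Weibull fit (default 10);
#'   groups below it get descriptive statistics only.
#' @return List with `table` (data frame, one row per group) and
#'   `durations` (named list of duration data frames, for histograms).
#' @export
tto_table <- function(db, drug_groups, case_def = case_definition(),
                      floor_n = 10) {
  rows <- list()
  durs <- list()
  for (gname in names(drug_groups)) {
    d <- compute_durations(db, drug_groups[[gname]], case_def)
    durs[[gname]] <- d
    row <- data.frame(drug = gname, n = nrow(d), median = NA_real_,
                      lower_quartile = NA_real_, upper_quartile = NA_real_,
                      minimum = NA_real_, maximum = NA_real_,
                      alpha = NA_real_, alpha_ci_low = NA_real_,
                      alpha_ci_high = NA_real_, beta = NA_real_,
                      beta_ci_low = NA_real_, beta_ci_high = NA_real_,
                      hazard_class = NA_character_, stringsAsFactors = FALSE)
    if (nrow(d) >= 1) {
      s <- summarize_durations(d)
      row$median <- s$median; row$lower_quartile <- s$lower_quartile
      row$upper_quartile <- s$upper_quartile
      row$minimum <- s$minimum; row$maximum <- s$maximum
    }
    if (nrow(d) >= floor_n) {
      fit <- tryCatch(suppressWarnings(fit_weibull(d, floor_n = floor_n)),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        row$alpha <- fit$alpha
        row$alpha_ci_low <- fit$alpha_ci[1]; row$alpha_ci_high <- fit$alpha_ci[2]
        row$beta <- fit$beta
        row$beta_ci_low <- fit$beta_ci[1]; row$beta_ci_high <- fit$beta_ci[2]
        row$hazard_class <- classify_hazard(fit)
      }
    } else {
      message(sprintf("tto_table: '%s' has %d durations (< %d); Weibull fit skipped",
                      gname, nrow(d), floor_n))
    }
    rows[[length(rows) + 1L]] <- row
  }
  list(table = do.call(rbind, rows), durations = durs)
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    case_pt_codes = c("10042033", "10030081", "10044223"),
    case_label = "SJS/TEN",
    drug_groups = NULL,
    analyses = list(counts = TRUE, adjusted = TRUE, tto = TRUE),
    tto_floor_n = 10,
    histogram_range = 56
  )
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in names(defaults$analyses)) {
    if (is.null(config$analyses[[k]])) config$analyses[[k]] <- TRUE
  }
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("run_pipeline: config needs either 'input' paths or a 'simulate' block")
  }
  if (!any(unlist(config$analyses))) stop("run_pipeline: no analysis enabled")
  config
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a JADER-schema database, builds the complete-case
#' analysis dataset, and writes: `table1_counts.csv` (cells, crude RORs,
#' reporting ratios by drug and stratum/sex subgroup),
#' `table2_adjusted_ror.csv` (whole-data and per-drug-subset adjusted
#' RORs with likelihood-ratio p-values), `table3_tto.csv` (quartiles,
#' Weibull parameters and hazard class per drug group), per-drug onset
#' histograms under `histograms/`, the archived analysis dataset, and
#' `manifest.json` with the filter-step accounting (raw reports,
#' complete-case reports, per-group counts).
#'
#' @param config A YAML file path or a list. Keys: `input` (named demo /
#'   drug / reac / hist file paths) or `simulate` (list with `n_reports`
#'   and optional `seed`, using [default_sim_config()]); `case_pt_codes`;
#'   `drug_groups` (named list; default [default_drug_groups()] filtered
#'   to drugs present); `analyses` toggles (`counts`, `adjusted`, `tto`);
#'   `tto_floor_n`; `histogram_range`.
#' @param outdir Output directory, created if needed.
#' @param seed Overrides the simulate-block seed.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  config <- resolve_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("srsignal")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cfg <- default_sim_config(
        n_reports = if (is.null(sim$n_reports)) 50000 else sim$n_reports,
        rng_seed = if (!is.null(seed)) seed
                   else if (is.null(sim$seed)) 1L else sim$seed)
      gen <- generate_database(cfg)
      db <- gen$db
      manifest$input <- list(mode = "simulate", n_reports = cfg$n_reports,
                             seed = cfg$rng_seed)
      write_truth(gen$truth, file.path(outdir, "sim_truth.json"))
    } else {
      db <- load_database(config$input)
      manifest$input <- list(mode = "files", paths = as.list(config$input))
    }
    manifest$counts <- list(raw_reports = db$counts$demo$rows)

    stage <- "analysis_dataset"
    case_def <- case_definition(config$case_pt_codes, config$case_label)
    ds <- build_analysis_dataset(db, case_def)
    manifest$counts$complete_case_reports <- nrow(ds)
    manifest$counts$removed_missing_sex_age <- attr(ds, "n_removed")
    manifest$counts$cases <- sum(ds$is_case)
    write_analysis_dataset(ds, file.path(outdir, "analysis_dataset.csv"))

    groups <- config$drug_groups
    if (is.null(groups)) {
      groups <- default_drug_groups()
      present <- vapply(groups, function(g) any(is_exposed(ds, g)), logical(1))
      groups <- groups[present]
    }
    manifest$drug_groups <- lapply(groups, as.list)

    if (isTRUE(config$analyses$counts)) {
      stage <- "counts"
      t1 <- counts_table(ds, groups)
      utils::write.csv(t1, file.path(outdir, "table1_counts.csv"),
                       row.names = FALSE)
      manifest$counts$drug_group_reports <- as.list(stats::setNames(
        t1$a[t1$subgroup == "total"] + t1$b[t1$subgroup == "total"],
        t1$drug[t1$subgroup == "total"]))
    }

    if (isTRUE(config$analyses$adjusted)) {
      stage <- "adjusted"
      t2 <- run_adjusted_analysis(ds, groups)
      utils::write.csv(t2, file.path(outdir, "table2_adjusted_ror.csv"),
                       row.names = FALSE)
    }

    if (isTRUE(config$analyses$tto)) {
      stage <- "time_to_onset"
      tt <- tto_table(db, groups, case_def, floor_n = config$tto_floor_n)
      utils::write.csv(tt$table, file.path(outdir, "table3_tto.csv"),
                       row.names = FALSE)
      hdir <- file.path(outdir, "histograms")
      dir.create(hdir, showWarnings = FALSE)
      for (gname in names(tt$durations)) {
        h <- onset_histogram(tt$durations[[gname]],
                             range_max = config$histogram_range)
        utils::write.csv(h, file.path(hdir, paste0(gname, ".csv")),
                         row.names = FALSE)
      }
      manifest$counts$tto_durations <- as.list(stats::setNames(
        vapply(tt$durations, nrow, integer(1)), names(tt$durations)))
    }
    TRUE
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop(sprintf("run_pipeline: stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
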