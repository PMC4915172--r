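# Ingestion, validation and filtering of JADER-schema spontaneous report
# tables (demo, drug, reac, hist) into an analysis-ready per-report dataset.

REQUIRED_COLUMNS <- list(
  demo = c("report_id", "sex", "age_band", "reporting_year"),
  drug = c("report_id", "drug_name", "role_code", "start_date"),
  reac = c("report_id", "pt_code", "onset_date"),
  hist = c("report_id")
)

AGE_STRATA <- c("LE19", "Y20_39", "Y40_59", "Y60_79", "GE80", "UNKNOWN")

ROLE_CODE_MAP <- c(
  suspected = "suspected", interacting = "interacting",
  concomitant = "concomitant",
  # romanised JADER role labels
  higiyaku = "suspected", sougosayou = "interacting", heiyouyaku = "concomitant"
)

#' Normalize a drug name for exact matching
#'
#' Applies Unicode NFKC normalization and case-folding, and trims
#' surrounding whitespace. Brand/generic synonym mapping is deliberately
#' not built in; callers can apply their own synonym table first.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  trimws(stringi::stri_trans_nfkc_casefold(as.character(x)))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out
}

normalize_role <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- unname(ROLE_CODE_MAP[x])
  out[is.na(out)] <- "unknown"
  out
}

#' Define the adverse event of interest as a set of MedDRA PT codes
#'
#' The default matches Stevens-Johnson syndrome / toxic epidermal
#' necrolysis: PT 10042033 (SJS), 10030081 (oculomucocutaneous syndrome),
#' and 10044223 (TEN). PT codes are treated as opaque strings; no MedDRA
#' hierarchy is consulted.
#'
#' @param pt_codes Character vector of MedDRA preferred-term codes.
#' @param label Human-readable label for the case definition.
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(pt_codes = c("10042033", "10030081", "10044223"),
                            label = "SJS/TEN") {
  pt_codes <- unique(as.character(pt_codes))
  if (length(pt_codes) == 0L || any(!nzchar(pt_codes))) {
    stop("case_definition: pt_codes must be a non-empty set of non-empty strings")
  }
  structure(list(pt_codes = pt_codes, label = label), class = "case_definition")
}

read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

apply_schema_map <- function(tab, table_name, schema_config) {
  map <- schema_config[[table_name]]
  if (is.null(map)) return(tab)
  # map: canonical name -> column name in file
  for (canonical in names(map)) {
    src <- map[[canonical]]
    if (src %in% names(tab)) {
      names(tab)[names(tab) == src] <- canonical
    }
  }
  tab
}

#' Load a four-table JADER-schema database from delimited text files
#'
#' Reads the demo, drug, reac and hist tables (comma- or tab-separated,
#' chosen by file extension; UTF-8 with a header row), optionally renaming
#' raw headers to the canonical schema via `schema_config`. Rows with an
#' empty `report_id`, or drug rows with an unrecognized role code, are
#' counted as malformed but retained in the raw tables; no deduplication
#' or record linkage is performed, mirroring how spontaneous-report
#' databases without a case-identification key are analysed.
#'
#' @param paths Named list or vector with elements `demo`, `drug`, `reac`,
#'   `hist` giving file locations.
#' @param schema_config Optional named list (per table) mapping canonical
#'   column names to the column names found in the files, e.g.
#'   `list(demo = list(report_id = "識別番号"))`. May be a
#'   path to a YAML file with the same structure.
#' @return An object of class `report_database`: the four data frames plus
#'   a `counts` list of row and malformed-row tallies.
#' @export
load_database <- function(paths, schema_config = NULL) {
  need <- c("demo", "drug", "reac", "hist")
  missing_tabs <- setdiff(need, names(paths))
  if (length(missing_tabs)) {
    stop("load_database: missing table paths: ", paste(missing_tabs, collapse = ", "))
  }
  if (is.character(schema_config) && length(schema_config) == 1L) {
    schema_config <- yaml::read_yaml(schema_config)
  }
  tables <- list()
  counts <- list()
  for (tn in need) {
    path <- paths[[tn]]
    if (!file.exists(path)) stop("load_database: file not found: ", path)
    tab <- read_delim_auto(path)
    tab <- apply_schema_map(tab, tn, schema_config)
    req <- REQUIRED_COLUMNS[[tn]]
    absent <- setdiff(req, names(tab))
    if (length(absent)) {
      stop(sprintf("load_database: table '%s' lacks required column(s): %s",
                   tn, paste(absent, collapse = ", ")))
    }
    malformed <- sum(!nzchar(trimws(tab$report_id)))
    if (tn == "drug") {
      tab$role_code <- normalize_role(tab$role_code)
      malformed <- malformed + sum(tab$role_code == "unknown")
    }
    if (tn == "demo") tab$sex <- normalize_sex(tab$sex)
    counts[[tn]] <- list(rows = nrow(tab), malformed = malformed)
    if (malformed > 0) {
      message(sprintf("load_database: %d malformed row(s) in '%s' (retained)",
                      malformed, tn))
    }
    tables[[tn]] <- tab
  }
  structure(c(tables, list(counts = counts)), class = "report_database")
}

#' @export
print.report_database <- function(x, ...) {
  cat("JADER-schema report database\n")
  for (tn in c("demo", "drug", "reac", "hist")) {
    cat(sprintf("  %s: %d rows (%d malformed)\n", tn,
                x$counts[[tn]]$rows, x$counts[[tn]]$malformed))
  }
  invisible(x)
}

#' Map a 10-year age band label to an analysis stratum
#'
#' Age in the JADER schema is recorded in decade bands ("0s", "10s", ...).
#' These are merged into five analysable strata: `LE19` (under 20),
#' `Y20_39`, `Y40_59`, `Y60_79` and `GE80` (80 and over, including "90s"
#' and "100s"); anything unparsable maps to `UNKNOWN`. Total function —
#' never errors.
#'
#' @param age_band Character vector of decade labels.
#' @return Character vector of stratum labels.
#' @examples
#' map_age_band(c("30s", "90s", ""))
#' @export
map_age_band <- function(age_band) {
  x <- trimws(as.character(age_band))
  m <- regmatches(x, regexec("^([0-9]+)s$", x))
  dec <- vapply(m, function(g) if (length(g) == 2L) as.numeric(g[2]) else NA_real_,
                numeric(1))
  out <- rep("UNKNOWN", length(x))
  out[!is.na(dec) & dec < 20] <- "LE19"
  out[!is.na(dec) & dec >= 20 & dec < 40] <- "Y20_39"
  out[!is.na(dec) & dec >= 40 & dec < 60] <- "Y40_59"
  out[!is.na(dec) & dec >= 60 & dec < 80] <- "Y60_79"
  out[!is.na(dec) & dec >= 80] <- "GE80"
  out
}

parse_year <- function(x) {
  x <- trimws(as.character(x))
  y <- suppressWarnings(as.integer(substr(x, 1, 4)))
  y[!grepl("^[0-9]{4}", x)] <- NA_integer_
  y
}

#' Build the per-report analysis dataset
#'
#' Collapses the loaded database to one row per report: sex, age stratum,
#' reporting year, case status (any reaction record matching the case
#' definition) and the set of suspected drugs. Reports with unknown sex or
#' unknown age stratum are removed (complete-case filter); the number
#' removed is recorded in the `n_removed` attribute. Reports whose only
#' drugs are interacting or concomitant remain in the dataset (they count
#' in denominators) but contribute to no drug's exposed cell.
#'
#' @param db A `report_database`.
#' @param case_def A `case_definition`.
#' @return A data frame of class `analysis_dataset` with columns
#'   `report_id`, `sex`, `age_stratum`, `reporting_year`, `is_case` and a
#'   list column `suspected_drugs` (normalized names). Attributes:
#'   `n_raw`, `n_removed`, `case_label`.
#' @export
build_analysis_dataset <- function(db, case_def = case_definition()) {
  stopifnot(inherits(db, "report_database"), inherits(case_def, "case_definition"))
  demo <- db$demo[nzchar(trimws(db$demo$report_id)), , drop = FALSE]
  demo <- demo[!duplicated(demo$report_id), , drop = FALSE]

  stratum <- map_age_band(demo$age_band)
  year <- parse_year(demo$reporting_year)

  case_ids <- unique(db$reac$report_id[
    trimws(db$reac$pt_code) %in% case_def$pt_codes])

  sus <- db$drug[db$drug$role_code == "suspected" &
                   nzchar(trimws(db$drug$report_id)), c("report_id", "drug_name")]
  sus$drug_name <- normalize_drug_name(sus$drug_name)
  sus_by_report <- split(sus$drug_name, sus$report_id)

  ds <- data.frame(
    report_id = demo$report_id,
    sex = demo$sex,
    age_stratum = stratum,
    reporting_year = year,
    is_case = demo$report_id %in% case_ids,
    stringsAsFactors = FALSE
  )
  ds$suspected_drugs <- lapply(sus_by_report[ds$report_id],
                               function(d) unique(d[nzchar(d)]))
  empty <- vapply(ds$suspected_drugs, is.null, logical(1))
  ds$suspected_drugs[empty] <- list(character(0))
  names(ds$suspected_drugs) <- NULL

  keep <- ds$sex %in% c("male", "female") & ds$age_stratum != "UNKNOWN"
  n_removed <- sum(!keep)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("build_analysis_dataset: no reports remain after complete-case filtering")
  }
  message(sprintf(
    "build_analysis_dataset: %d of %d reports retained (%d removed for missing sex/age)",
    nrow(out), nrow(ds), n_removed))
  attr(out, "n_raw") <- nrow(ds)
  attr(out, "n_removed") <- n_removed
  attr(out, "case_label") <- case_def$label
  class(out) <- c("analysis_dataset", "data.frame")
  out
}

#' Test which reports list any of a set of drugs as suspected
#'
#' @param ds An `analysis_dataset`.
#' @param drug_names Character vector of drug names (normalized internally).
#' @return Logical vector, one element per report.
#' @export
is_exposed <- function(ds, drug_names) {
  targets <- normalize_drug_name(drug_names)
  vapply(ds$suspected_drugs, function(d) any(d %in% targets), logical(1))
}

#' Subset an analysis dataset to reports exposed to given drugs
#'
#' Selects the reports whose suspected-drug set intersects `drug_names`;
#' each report appears once even if it lists several of the drugs. Used
#' for per-drug subset analyses and for drug groups (e.g. a 6-drug ACE
#' inhibitor class or an 11-drug corticosteroid class).
#'
#' @inheritParams is_exposed
#' @return An `analysis_dataset` restricted to exposed reports.
#' @export
subset_by_drug <- function(ds, drug_names) {
  if (length(drug_names) == 0L) stop("subset_by_drug: drug_names must be non-empty")
  keep <- is_exposed(ds, drug_names)
  if (!any(keep)) {
    stop("subset_by_drug: no report lists any of: ",
         paste(drug_names, collapse = ", "))
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_raw", "n_removed", "case_label")) attr(out, a) <- attr(ds, a)
  class(out) <- class(ds)
  out
}

#' Write an analysis dataset to CSV
#'
#' Fixed column order `report_id, sex, age_stratum, reporting_year,
#' is_case, suspected_drugs`, with the drug set semicolon-joined.
#'
#' @param ds An `analysis_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_dataset <- function(ds, path) {
  flat <- data.frame(
    report_id = ds$report_id,
    sex = ds$sex,
    age_stratum = ds$age_stratum,
    reporting_year = ds$reporting_year,
    is_case = ds$is_case,
    suspected_drugs = vapply(ds$suspected_drugs, paste, character(1),
                             collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back an analysis dataset written by [write_analysis_dataset()]
#'
#' @param path CSV file path.
#' @return An `analysis_dataset`.
#' @export
read_analysis_dataset <- function(path) {
  flat <- utils::read.csv(path, colClasses = c(
    report_id = "character", sex = "character", age_stratum = "character",
    reporting_year = "integer", is_case = "logical",
    suspected_drugs = "character"), na.strings = "")
  flat$suspected_drugs[is.na(flat$suspected_drugs)] <- ""
  ds <- flat
  ds$suspected_drugs <- lapply(strsplit(flat$suspected_drugs, ";", fixed = TRUE),
                               function(d) d[nzchar(d)])
  class(ds) <- c("analysis_dataset", "data.frame")
  ds
}
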