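# In-code fixture builders: a small four-table database exercising role
# codes, partial dates, missing demographics and the case definition.

fixture_tables <- function() {
  demo <- data.frame(
    report_id = sprintf("R%02d", 1:10),
    sex = c("male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    age_band = c("30s", "40s", "60s", "80s", "10s", "50s", "70s", "0s", "", ""),
    reporting_year = c(2010, 2011, 2012, 2013, 2008, 2009, 2014, 2005, 2010, 2011),
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    report_id = c("R01", "R01", "R01", "R02", "R03", "R04", "R05", "R06",
                  "R07", "R08", "R09", "R10"),
    drug_name = c("allopurinol", "allopurinol", "vitamin c", "loxoprofen",
                  "allopurinol", "acetaminophen", "loxoprofen", "Carbamazepine",
                  "enalapril maleate", "acetaminophen", "allopurinol",
                  "loxoprofen"),
    role_code = c("suspected", "suspected", "heiyouyaku", "suspected",
                  "suspected", "suspected", "suspected", "suspected",
                  "suspected", "sougosayou", "suspected", "suspected"),
    start_date = c("2010-03-01", "2010-02-20", "2010-03-01", "2011-05-10",
                   "2012-01-15", "2013-07-01", "2008-06", "2009-02-01",
                   "2014-03-03", "2005-01-01", "2010-04-01", "2011-01-01"),
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    report_id = sprintf("R%02d", 1:10),
    pt_code = c("10042033", "10044223", "20000001", "10030081", "10042033",
                "10044223", "20000002", "10042033", "10042033", "20000003"),
    onset_date = c("2010-03-01", "2011-05-13", "2012-02-01", "2013-07-15",
                   "2008-06-20", "2009-01-20", "2014-04-01", "2005-02-01",
                   "2010-04-21", "2011-02-01"),
    stringsAsFactors = FALSE
  )
  hist <- data.frame(
    report_id = c("R01", "R03"),
    condition = c("hypertension", "diabetes"),
    stringsAsFactors = FALSE
  )
  list(demo = demo, drug = drug, reac = reac, hist = hist)
}

write_fixture <- function(tables = fixture_tables(), dir = tempfile("fixdb")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(demo = file.path(dir, "demo.csv"), drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"), hist = file.path(dir, "hist.csv"))
  for (tn in names(paths)) {
    utils::write.csv(tables[[tn]], paths[[tn]], row.names = FALSE, na = "")
  }
  paths
}

load_fixture_db <- function() {
  suppressMessages(load_database(write_fixture()))
}

# Construct an analysis_dataset directly: reports 1..n, the given indices
# exposed to `drug` (others list a filler drug) and the given indices cases.
make_ds <- function(n, exposed = integer(0), cases = integer(0),
                    drug = "drugx") {
  ds <- data.frame(
    report_id = sprintf("S%05d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age_stratum = rep(c("LE19", "Y20_39", "Y40_59", "Y60_79", "GE80"),
                      length.out = n),
    reporting_year = rep(2004:2015, length.out = n),
    is_case = seq_len(n) %in% cases,
    stringsAsFactors = FALSE
  )
  ds$suspected_drugs <- lapply(seq_len(n), function(i)
    if (i %in% exposed) drug else "filler_drug")
  class(ds) <- c("analysis_dataset", "data.frame")
  ds
}
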