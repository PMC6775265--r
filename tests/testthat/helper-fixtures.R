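# Shared fixtures, all built in code at test time.

# A small hand-enumerable report set: 10 reports, one drug of interest
# ("doacx") with known exposure/case pattern:
#   exposed cases: 1, 2, 3   exposed non-cases: 4, 5
#   unexposed case: 6        unexposed non-cases: 7, 8, 9, 10
toy_report_set <- function() {
  reports <- tibble::tibble(
    primary_id = as.character(1:10),
    case_id = sprintf("C%02d", 1:10),
    report_year = c(2010L, 2011L, 2012L, 2013L, 2014L,
                    2010L, 2011L, 2012L, NA, 2014L),
    age_years = c(45, 70, 59, 61, 30, 80, 55, 66, 48, NA),
    sex = c("F", "M", "F", "F", "M", "F", "M", NA, "F", "M"),
    source_tag = "toy"
  )
  drugs <- tibble::tibble(
    primary_id = c("1", "2", "3", "4", "5", "7", "3"),
    drug_code = c(rep("doacx", 5), "otherdrug", "otherdrug"),
    role = c("suspect_primary", "suspect_secondary", "suspect_primary",
             "suspect_primary", "suspect_secondary", "concomitant",
             "concomitant"),
    start_date = c("2010-03-01", "2011-05-10", "2012-07", NA, "2014-02-01",
                   "2011-01-01", "2012-01-01")
  )
  reactions <- tibble::tibble(
    primary_id = c("1", "2", "3", "6", "4", "5", "7", "8", "9"),
    pt_code = c("EV1", "EV2", "EV1", "EV1", "OTH1", "OTH2", "OTH1",
                "OTH3", "OTH1"),
    onset_date = c("2010-03-31", "2011-06-01", "2012-08-01", "2010-05-05",
                   NA, NA, NA, NA, NA)
  )
  new_report_set(reports, drugs, reactions)
}

toy_event_terms <- function() c("EV1", "EV2", "EV3")

# Write FAERS-style "$"-delimited fixture files; returns the four paths.
write_faers_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- function(name, lines) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    p
  }
  demo <- w("demo.txt", c(
    "primaryid$caseid$event_yr$age$age_cod$sex",
    "1001$A1$2012$64$YR$M",
    "1002$A2$2013$18$MON$F",
    "1003$A3$2014$XX$YR$F"
  ))
  drug <- w("drug.txt", c(
    "primaryid$drug_seq$drugname$role_cod",
    "1001$1$Rivaroxaban $PS",
    "1001$2$aspirin$C",
    "1002$1$DABIGATRAN$SS"
  ))
  reac <- w("reac.txt", c(
    "primaryid$pt",
    "1001$EV1",
    "1002$OTH1"
  ))
  ther <- w("ther.txt", c(
    "primaryid$dsg_drug_seq$start_dt",
    "1001$1$20120215",
    "1001$1$20120301",
    "1002$1$201305"
  ))
  list(demo = demo, drug = drug, reac = reac, ther = ther)
}

# Expand a 2x2 table of counts into unit records and fit a one-indicator
# logistic model with stats::glm (the independent route used to cross-check
# compute_ror against a regression fit).
glm_or_from_table <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  fit <- stats::glm(y ~ x, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12))
  exp(unname(stats::coef(fit)[2]))
}
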