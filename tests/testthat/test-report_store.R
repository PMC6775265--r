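test_that("FAERS-style ASCII tables join into one report per DEMO row", {
  paths <- write_faers_fixture()
  rs <- read_faers_ascii(paths$demo, paths$drug, paths$reac, paths$ther)

  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 3)
  expect_equal(sum(rs$drugs$primary_id == "1001"), 2)
  expect_equal(sum(rs$reactions$primary_id == "1001"), 1)
  expect_equal(rs$provenance$demo_rows, 3)
  expect_equal(rs$provenance$drug_rows, 3)

  # role codes map to the canonical vocabulary, drug names are case-folded
  r1001 <- rs$drugs[rs$drugs$primary_id == "1001", ]
  expect_setequal(r1001$drug_code, c("rivaroxaban", "aspirin"))
  expect_setequal(r1001$role, c("suspect_primary", "concomitant"))
})

test_that("unparseable fields become missing without dropping the row", {
  paths <- write_faers_fixture()
  rs <- read_faers_ascii(paths$demo, paths$drug, paths$reac, paths$ther)
  r3 <- rs$reports[rs$reports$primary_id == "1003", ]
  expect_true(is.na(r3$age_years))
  expect_equal(rs$provenance$age_unparseable, 1)
  expect_equal(n_reports(rs), 3)
})

test_that("age unit codes convert to years", {
  paths <- write_faers_fixture()
  rs <- read_faers_ascii(paths$demo, paths$drug, paths$reac, paths$ther)
  expect_equal(rs$reports$age_years[rs$reports$primary_id == "1002"], 1.5)
  expect_equal(rs$reports$age_years[rs$reports$primary_id == "1001"], 64)
})

test_that("therapy start dates join per drug at the earliest complete date", {
  paths <- write_faers_fixture()
  rs <- read_faers_ascii(paths$demo, paths$drug, paths$reac, paths$ther)
  riva <- rs$drugs[rs$drugs$drug_code == "rivaroxaban", ]
  expect_equal(riva$start_date, "2012-02-15")
  dabi <- rs$drugs[rs$drugs$drug_code == "dabigatran", ]
  expect_equal(dabi$start_date, "2013-05")  # YM completeness preserved
})

test_that("reader fails fatally on missing files and unmapped id columns", {
  paths <- write_faers_fixture()
  expect_error(
    read_faers_ascii(file.path(tempdir(), "nope.txt"), paths$drug,
                     paths$reac),
    "nope.txt"
  )
  cm <- faers_column_map()
  cm$demo["primary_id"] <- "not_a_column"
  expect_error(
    read_faers_ascii(paths$demo, paths$drug, paths$reac, column_map = cm),
    "not_a_column"
  )
})

test_that("canonical write/read round-trips all fields", {
  cf <- scenario_preset("paper_like", n_reports = 100, seed = 11)
  rs <- generate_reports(cf)$report_set
  dir <- withr::local_tempdir()
  write_canonical(rs, dir)
  back <- read_canonical(dir)
  expect_equal(back$reports, rs$reports)
  expect_equal(back$drugs, rs$drugs)
  expect_equal(back$reactions, rs$reactions)

  # partial-date completeness survives
  lv <- date_completeness(back$drugs$start_date)
  expect_equal(lv, date_completeness(rs$drugs$start_date))
  expect_true(any(lv == "YM", na.rm = TRUE))
})

test_that("an empty report set round-trips as a header-only file", {
  rs <- new_report_set(tibble::tibble(primary_id = character(),
                                      case_id = character()))
  dir <- withr::local_tempdir()
  write_canonical(rs, dir)
  expect_equal(length(readLines(file.path(dir, "reports.csv"))), 1)
  back <- read_canonical(dir)
  expect_equal(n_reports(back), 0)
})

test_that("schema version mismatch is fatal and names both versions", {
  rs <- toy_report_set()
  dir <- withr::local_tempdir()
  write_canonical(rs, dir)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  meta$schema_version <- "0.9"
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(read_canonical(dir), "0\\.9.*1\\.0")
})

test_that("deduplication keeps the greatest primary_id per case", {
  reports <- tibble::tibble(
    primary_id = c("101", "205", "7"),
    case_id = c("C1", "C1", "C2")
  )
  rs <- deduplicate(new_report_set(reports))
  expect_setequal(rs$reports$primary_id, c("205", "7"))
  expect_equal(rs$provenance$dedup_removed, 1)

  # numeric comparator: 205 > 101 even though "101" < "205" either way;
  # the distinguishing case is "9" vs "10"
  rs2 <- deduplicate(new_report_set(tibble::tibble(
    primary_id = c("9", "10"), case_id = "C1")))
  expect_equal(rs2$reports$primary_id, "10")
  rs3 <- deduplicate(new_report_set(tibble::tibble(
    primary_id = c("9", "10"), case_id = "C1")), comparator = "lexicographic")
  expect_equal(rs3$reports$primary_id, "9")
})

test_that("deduplication is idempotent and preserves input order", {
  cf <- scenario_preset("null", n_reports = 300, seed = 2)
  cf$duplicate_rate <- 0.2
  sim <- generate_reports(cf)
  once <- deduplicate(sim$report_set)
  twice <- deduplicate(once)
  expect_equal(n_reports(once),
               dplyr::n_distinct(sim$report_set$reports$case_id))
  expect_equal(twice$reports, once$reports)
  expect_equal(twice$provenance$dedup_removed, 0)
  # survivors appear in their original relative order (generator ids are
  # ascending in input order, duplicates appended last)
  expect_false(is.unsorted(as.numeric(once$reports$primary_id)))

  plain <- deduplicate(toy_report_set())
  expect_equal(n_reports(plain), 10)
  expect_equal(plain$provenance$dedup_removed, 0)
})

test_that("completeness filter drops reports missing required fields", {
  rs <- toy_report_set()  # 8 misses sex, 9 misses year, 10 misses age
  out <- filter_complete(rs, c("report_year", "age_years", "sex"))
  expect_equal(n_reports(out), 7)
  expect_equal(out$provenance$filter_dropped, 3)
  expect_equal(out$provenance$filter_dropped_sex, 1)

  only_sex <- filter_complete(rs, "sex")
  expect_equal(n_reports(only_sex), 9)

  ident <- filter_complete(rs, character(0))
  expect_equal(ident$reports, rs$reports)

  expect_error(filter_complete(rs, "weight"), "unknown required field")
})

test_that("filtering on a field union equals sequential filtering", {
  cf <- scenario_preset("paper_like", n_reports = 2000, seed = 5)
  rs <- generate_reports(cf)$report_set
  joint <- filter_complete(rs, c("report_year", "age_years", "sex"))
  seq2 <- filter_complete(filter_complete(rs, c("report_year")),
                          c("age_years", "sex"))
  expect_equal(joint$reports, seq2$reports)
})

test_that("survivor count under known missingness matches binomial expectation", {
  cf <- scenario_preset("null", n_reports = 10000, seed = 9)
  cf$missingness["age"] <- 0.2
  rs <- generate_reports(cf)$report_set
  out <- filter_complete(rs, "age_years")
  se <- sqrt(10000 * 0.2 * 0.8)
  expect_lt(abs(n_reports(out) - 8000), 4 * se)
})
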