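#' Individual case safety report sets
#'
#' A `report_set` is the package's canonical container for spontaneous
#' reports. It is a list of three tibbles sharing the `primary_id` key plus a
#' provenance log:
#'
#' * `reports`: one row per report *version* — `primary_id` (unique),
#'   `case_id` (shared across versions of one case), `report_year`,
#'   `age_years`, `sex` (`"M"`/`"F"`/`NA`), `source_tag`.
#' * `drugs`: one row per drug exposure — `drug_code`, `role` (one of
#'   [drug_roles()]), `start_date` (ISO prefix, see [date_completeness()]).
#' * `reactions`: one row per reported reaction — `pt_code` (MedDRA preferred
#'   term, opaque string), `onset_date` (ISO prefix).
#' * `provenance`: a named list of ingestion/filter counters; every filter
#'   appends its own counts so `read = kept + dropped` is checkable.
#'
#' @param reports,drugs,reactions data frames as described above.
#' @param provenance named list of counters and notes.
#' @return a `report_set` object.
#' @export
new_report_set <- function(reports, drugs = NULL, reactions = NULL,
                           provenance = list()) {
  reports <- tibble::as_tibble(reports)
  need <- c("primary_id", "case_id", "report_year", "age_years", "sex",
            "source_tag")
  for (col in setdiff(need, names(reports))) {
    reports[[col]] <- if (col == "report_year") NA_integer_
      else if (col == "age_years") NA_real_ else NA_character_
  }
  reports <- reports[, need]
  reports$primary_id <- as.character(reports$primary_id)
  reports$case_id <- as.character(reports$case_id)
  if (anyDuplicated(reports$primary_id)) {
    stop("primary_id must be unique within a report_set", call. = FALSE)
  }
  if (any(reports$age_years < 0, na.rm = TRUE)) {
    stop("age_years must be non-negative when present", call. = FALSE)
  }

  empty_drugs <- tibble::tibble(
    primary_id = character(), drug_code = character(),
    role = character(), start_date = character()
  )
  empty_reac <- tibble::tibble(
    primary_id = character(), pt_code = character(), onset_date = character()
  )
  drugs <- if (is.null(drugs)) empty_drugs else tibble::as_tibble(drugs)
  reactions <- if (is.null(reactions)) empty_reac else tibble::as_tibble(reactions)
  for (col in names(empty_drugs)) {
    if (!col %in% names(drugs)) drugs[[col]] <- NA_character_
  }
  for (col in names(empty_reac)) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_character_
  }
  drugs <- drugs[, names(empty_drugs)]
  reactions <- reactions[, names(empty_reac)]
  drugs$primary_id <- as.character(drugs$primary_id)
  reactions$primary_id <- as.character(reactions$primary_id)
  stopifnot(
    all(drugs$primary_id %in% reports$primary_id),
    all(reactions$primary_id %in% reports$primary_id)
  )
  bad_role <- !is.na(drugs$role) & !drugs$role %in% drug_roles()
  if (any(bad_role)) drugs$role[bad_role] <- "unknown"
  drugs$role[is.na(drugs$role)] <- "unknown"

  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         provenance = provenance),
    class = "report_set"
  )
}

#' Recognised drug exposure roles
#'
#' @return character vector of the role vocabulary. FAERS role codes map as
#'   PS = `suspect_primary`, SS = `suspect_secondary`, C = `concomitant`,
#'   I = `interacting`; anything else is `unknown`.
#' @export
drug_roles <- function() {
  c("suspect_primary", "suspect_secondary", "concomitant", "interacting",
    "unknown")
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$reports), " reports (",
      dplyr::n_distinct(x$reports$case_id), " cases), ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions), " reaction rows\n",
      sep = "")
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `report_set`.
#' @export
n_reports <- function(x) nrow(x$reports)

# restrict child tables to surviving report versions
subset_report_set <- function(rs, keep_ids, provenance) {
  new_report_set(
    rs$reports[match(keep_ids, rs$reports$primary_id), , drop = FALSE],
    rs$drugs[rs$drugs$primary_id %in% keep_ids, , drop = FALSE],
    rs$reactions[rs$reactions$primary_id %in% keep_ids, , drop = FALSE],
    provenance
  )
}

#' Drop duplicate case versions, keeping the most recent
#'
#' Regulators recommend keeping only the most recent version of each case
#' when the same patient is reported from several sources. "Most recent" is
#' operationalised as the greatest `primary_id` per `case_id` (report
#' identifiers in FAERS increase over time). Survivors keep their input
#' order. Reports with a missing `case_id` are treated as singleton cases.
#'
#' @param rs a `report_set`.
#' @param comparator `"auto"` compares `primary_id` numerically when every id
#'   is all-digits, lexicographically otherwise; `"numeric"` and
#'   `"lexicographic"` force one ordering.
#' @return a deduplicated `report_set`; `provenance$dedup_removed` holds the
#'   number of versions removed.
#' @export
deduplicate <- function(rs, comparator = c("auto", "numeric", "lexicographic")) {
  comparator <- match.arg(comparator)
  rep_tbl <- rs$reports
  pid <- rep_tbl$primary_id
  case <- rep_tbl$case_id
  case[is.na(case)] <- paste0(".singleton.", pid[is.na(case)])

  numeric_ok <- all(grepl("^\\d+$", pid))
  use_numeric <- switch(comparator,
    auto = numeric_ok,
    numeric = {
      if (!numeric_ok) stop("non-numeric primary_id under numeric comparator",
                            call. = FALSE)
      TRUE
    },
    lexicographic = FALSE
  )
  key <- if (use_numeric) as.numeric(pid) else pid

  keep <- rep(FALSE, length(pid))
  best <- tapply(seq_along(pid), case, function(idx) {
    top <- idx[key[idx] == max(key[idx])]
    if (length(top) > 1) {
      # identical primary_id cannot arise through new_report_set, but the
      # tie rule (keep first encountered) is part of the contract
      warning("tied primary_id within case; keeping first encountered")
    }
    top[1]
  })
  keep[unlist(best)] <- TRUE
  keep_ids <- pid[keep]  # preserves input order

  prov <- rs$provenance
  prov$dedup_removed <- sum(!keep)
  subset_report_set(rs, keep_ids, prov)
}

#' Drop reports with missing demographic fields
#'
#' Mirrors the completeness filter applied before regression: reports lacking
#' any of the required demographic fields are excluded.
#'
#' @param rs a `report_set`.
#' @param required_fields subset of `c("report_year", "age_years", "sex")`;
#'   an empty vector is the identity filter.
#' @return filtered `report_set`; `provenance$filter_dropped_<field>` counts
#'   how many *dropped* reports were missing each field, and
#'   `provenance$filter_dropped` the total dropped.
#' @export
filter_complete <- function(rs,
                            required_fields = c("report_year", "age_years",
                                                "sex")) {
  allowed <- c("report_year", "age_years", "sex")
  bad <- setdiff(required_fields, allowed)
  if (length(bad)) {
    stop("unknown required field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rep_tbl <- rs$reports
  missing_any <- rep(FALSE, nrow(rep_tbl))
  per_field <- integer(0)
  for (f in required_fields) missing_any <- missing_any | is.na(rep_tbl[[f]])
  prov <- rs$provenance
  for (f in required_fields) {
    prov[[paste0("filter_dropped_", f)]] <-
      sum(is.na(rep_tbl[[f]]) & missing_any)
  }
  prov$filter_dropped <- sum(missing_any)
  subset_report_set(rs, rep_tbl$primary_id[!missing_any], prov)
}
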