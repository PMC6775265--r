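CANONICAL_SCHEMA_VERSION <- "1.0"

#' Canonical on-disk format for report sets
#'
#' A report set is stored as a directory of three UTF-8 CSVs sharing the
#' `primary_id` key — `reports.csv`, `drugs.csv`, `reactions.csv` — plus a
#' `metadata.json` sidecar holding the schema version and row counts. Dates
#' are ISO-8601 prefixes so partial-date completeness survives the
#' round-trip; sex is `M`/`F` or empty.
#'
#' @param rs a `report_set`.
#' @param dir directory to write to (created if absent) / read from.
#' @return `write_canonical()` returns `dir` invisibly; `read_canonical()`
#'   returns a `report_set`.
#' @export
write_canonical <- function(rs, dir) {
  stopifnot(inherits(rs, "report_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(rs$reports, file.path(dir, "reports.csv"), na = "")
  readr::write_csv(rs$drugs, file.path(dir, "drugs.csv"), na = "")
  readr::write_csv(rs$reactions, file.path(dir, "reactions.csv"), na = "")
  meta <- list(
    schema_version = CANONICAL_SCHEMA_VERSION,
    n_reports = nrow(rs$reports),
    n_drug_rows = nrow(rs$drugs),
    n_reaction_rows = nrow(rs$reactions),
    provenance = rs$provenance
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_canonical
#' @export
read_canonical <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("not a canonical report-set directory (no metadata.json): ", dir,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, CANONICAL_SCHEMA_VERSION)) {
    stop("canonical schema version mismatch: file has ",
         meta$schema_version %||% "<none>", ", this package reads ",
         CANONICAL_SCHEMA_VERSION, call. = FALSE)
  }
  col <- function(...) readr::cols(...)
  reports <- readr::read_csv(
    file.path(dir, "reports.csv"),
    col_types = col(
      primary_id = readr::col_character(), case_id = readr::col_character(),
      report_year = readr::col_integer(), age_years = readr::col_double(),
      sex = readr::col_character(), source_tag = readr::col_character()
    ),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  drugs <- readr::read_csv(
    file.path(dir, "drugs.csv"),
    col_types = col(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  reactions <- readr::read_csv(
    file.path(dir, "reactions.csv"),
    col_types = col(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  prov <- meta$provenance
  if (is.null(prov) || (is.list(prov) && !length(prov))) prov <- list()
  new_report_set(reports, drugs, reactions, as.list(prov))
}
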