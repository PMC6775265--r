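#' Load a preferred-term set from a term table
#'
#' Term tables are plain CSVs with columns `set_name` and `pt_code`, one row
#' per preferred term. MedDRA itself is licensed, so the term lists (an SMQ
#' export, an SOC listing) are supplied by the user in this format.
#'
#' @param path CSV path.
#' @param set_name optionally keep only rows of one named set; default loads
#'   whatever single set the file holds (error if several).
#' @return a `term_set`: list with `name` and the unique `pt_codes`.
#' @export
load_term_table <- function(path, set_name = NULL) {
  if (!file.exists(path)) stop("missing term table: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("set_name", "pt_code") %in% names(tbl))) {
    stop("term table must have columns set_name, pt_code: ", path,
         call. = FALSE)
  }
  if (!is.null(set_name)) tbl <- tbl[tbl$set_name == set_name, , drop = FALSE]
  if (!nrow(tbl)) stop("term table is empty", if (!is.null(set_name))
    paste0(" for set '", set_name, "'"), ": ", path, call. = FALSE)
  nm <- unique(tbl$set_name)
  if (length(nm) > 1) {
    stop("term table holds several sets (", paste(nm, collapse = ", "),
         "); pass set_name", call. = FALSE)
  }
  dup <- sum(duplicated(tbl$pt_code))
  if (dup) message(dup, " duplicate pt_code row(s) collapsed in set '", nm, "'")
  term_set(nm, unique(tbl$pt_code))
}

#' Construct a term set in memory
#' @param name set label.
#' @param pt_codes character vector of preferred-term codes.
#' @return a `term_set`.
#' @export
term_set <- function(name, pt_codes) {
  structure(list(name = name, pt_codes = unique(as.character(pt_codes))),
            class = "term_set")
}

#' Define an adverse event as the intersection of an SMQ and an SOC term set
#'
#' An event is operationalised as the preferred terms that belong to both a
#' standardized MedDRA query (the clinical concept, e.g. hemorrhage,
#' SMQ 20000039) and a system organ class (the anatomical restriction, e.g.
#' gastrointestinal disorders): only reports carrying a term in the
#' intersection qualify.
#'
#' @param smq,soc `term_set` objects.
#' @param name label for the combined definition.
#' @return an `event_definition` with `effective_terms = smq` \eqn{\cap}
#'   `soc`.
#' @export
define_event <- function(smq, soc, name = paste(smq$name, soc$name, sep = "&")) {
  stopifnot(inherits(smq, "term_set"), inherits(soc, "term_set"))
  eff <- intersect(smq$pt_codes, soc$pt_codes)
  if (!length(eff)) {
    warning("event definition '", name, "' has an empty term intersection")
  }
  structure(list(name = name, smq = smq, soc = soc, effective_terms = eff),
            class = "event_definition")
}

#' @export
print.event_definition <- function(x, ...) {
  cat("<event_definition> ", x$name, ": ", length(x$effective_terms),
      " effective terms (SMQ ", length(x$smq$pt_codes), " ∩ SOC ",
      length(x$soc$pt_codes), ")\n", sep = "")
  invisible(x)
}

#' Flag case status per report
#'
#' A report is a *case* if any of its reactions carries a preferred term in
#' the event definition's effective set; reports with no reactions are
#' non-cases. The indicator is aligned with `rs$reports` row order.
#'
#' @param rs a `report_set`.
#' @param event_def an `event_definition` (or a `term_set` / character vector
#'   of codes, taken as the effective set directly).
#' @return logical vector, one element per report.
#' @export
flag_cases <- function(rs, event_def) {
  eff <- if (inherits(event_def, "event_definition")) event_def$effective_terms
         else if (inherits(event_def, "term_set")) event_def$pt_codes
         else as.character(event_def)
  hit_ids <- unique(rs$reactions$primary_id[rs$reactions$pt_code %in% eff])
  rs$reports$primary_id %in% hit_ids
}
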