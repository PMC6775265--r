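#' Default column mapping for FAERS-style quarterly ASCII tables
#'
#' Keys are canonical field names, values are the source column names as they
#' appear in each file's header. Adjust the values to match the snapshot in
#' hand; `drug_seq` entries are optional and, when present in both the DRUG
#' and THER maps, therapy start dates are joined per drug rather than per
#' report.
#'
#' @return nested named list with elements `demo`, `drug`, `reac`, `ther`.
#' @export
faers_column_map <- function() {
  list(
    demo = c(primary_id = "primaryid", case_id = "caseid",
             report_year = "event_yr", age = "age", age_unit = "age_cod",
             sex = "sex"),
    drug = c(primary_id = "primaryid", drug_seq = "drug_seq",
             drug_code = "drugname", role = "role_cod"),
    reac = c(primary_id = "primaryid", pt_code = "pt"),
    ther = c(primary_id = "primaryid", drug_seq = "dsg_drug_seq",
             start_date = "start_dt")
  )
}

#' Age-unit codes to years multipliers
#'
#' @return named numeric vector; e.g. a reported age of 18 with unit `MON`
#'   becomes 1.5 years.
#' @export
faers_age_units <- function() {
  c(YR = 1, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25, HR = 1 / 8766,
    DEC = 10)
}

#' FAERS role codes to the canonical role vocabulary
#' @return named character vector.
#' @export
faers_role_map <- function() {
  c(PS = "suspect_primary", SS = "suspect_secondary", C = "concomitant",
    I = "interacting")
}

read_delim_table <- function(path, sep, encoding, what) {
  if (!file.exists(path)) {
    stop("missing ", what, " file: ", path, call. = FALSE)
  }
  readr::read_delim(
    path, delim = sep, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = encoding), na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
}

pick_cols <- function(tbl, map, required, what, path) {
  present <- map[map %in% names(tbl)]
  miss <- setdiff(required, names(present))
  if (length(miss)) {
    stop("header of ", path, " lacks mapped column(s) for ", what, ": ",
         paste(map[miss], collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(tbl[, unname(present), drop = FALSE])
  names(out) <- names(present)
  out
}

#' Read FAERS-style "$"-delimited quarterly ASCII tables
#'
#' Joins one demographics row per report to its drug, reaction and (optional)
#' therapy rows by the report's primary id. Field values that cannot be
#' parsed are set to missing and counted in the provenance log; rows are
#' never dropped at ingestion.
#'
#' @param demo_path,drug_path,reac_path paths to the DEMO, DRUG and REAC
#'   tables.
#' @param ther_path optional path to the THER table carrying therapy start
#'   dates.
#' @param column_map see [faers_column_map()].
#' @param sep field delimiter (FAERS uses `"$"`).
#' @param encoding file encoding; malformed bytes are replaced.
#' @param age_unit_map named multipliers converting (age value, unit code) to
#'   years; unknown codes yield missing age.
#' @param role_map named map from source role codes to [drug_roles()].
#' @param max_age ages above this bound (in years) are implausible and set
#'   missing.
#' @param source_tag label stored on every report.
#' @return a [new_report_set()] object.
#' @export
read_faers_ascii <- function(demo_path, drug_path, reac_path,
                             ther_path = NULL,
                             column_map = faers_column_map(),
                             sep = "$", encoding = "UTF-8",
                             age_unit_map = faers_age_units(),
                             role_map = faers_role_map(),
                             max_age = 120,
                             source_tag = "faers") {
  demo <- read_delim_table(demo_path, sep, encoding, "DEMO")
  drug <- read_delim_table(drug_path, sep, encoding, "DRUG")
  reac <- read_delim_table(reac_path, sep, encoding, "REAC")

  d <- pick_cols(demo, column_map$demo,
                 c("primary_id", "case_id"), "DEMO", demo_path)
  dr <- pick_cols(drug, column_map$drug,
                  c("primary_id", "drug_code"), "DRUG", drug_path)
  re <- pick_cols(reac, column_map$reac,
                  c("primary_id", "pt_code"), "REAC", reac_path)

  prov <- list(
    files = c(demo = demo_path, drug = drug_path, reac = reac_path,
              ther = ther_path %||% NA_character_),
    demo_rows = nrow(demo), drug_rows = nrow(drug), reac_rows = nrow(reac),
    rows_dropped = 0L
  )

  # --- demographics -------------------------------------------------------
  year_raw <- if ("report_year" %in% names(d)) d$report_year else NA_character_
  year <- suppressWarnings(as.integer(year_raw))
  prov$year_unparseable <- sum(!is.na(year_raw) & is.na(year))

  age_raw <- if ("age" %in% names(d)) d$age else NA_character_
  age_val <- suppressWarnings(as.numeric(age_raw))
  prov$age_unparseable <- sum(!is.na(age_raw) & is.na(age_val))
  unit <- if ("age_unit" %in% names(d)) toupper(trimws(d$age_unit))
          else rep(NA_character_, nrow(d))
  mult <- unname(age_unit_map[unit])
  mult[is.na(unit)] <- 1  # unitless ages are taken as years
  prov$age_unit_unknown <- sum(!is.na(unit) & is.na(age_unit_map[unit]) &
                                 !is.na(age_val))
  age_years <- age_val * mult
  implaus <- !is.na(age_years) & age_years > max_age
  prov$age_implausible <- sum(implaus)
  age_years[implaus] <- NA_real_

  sex_raw <- if ("sex" %in% names(d)) toupper(trimws(d$sex))
             else rep(NA_character_, nrow(d))
  sex <- ifelse(sex_raw %in% c("M", "F"), sex_raw, NA_character_)

  reports <- tibble::tibble(
    primary_id = d$primary_id, case_id = d$case_id,
    report_year = year, age_years = age_years, sex = sex,
    source_tag = source_tag
  )

  # --- drug exposures -----------------------------------------------------
  role_src <- if ("role" %in% names(dr)) toupper(trimws(dr$role))
              else rep(NA_character_, nrow(dr))
  role <- unname(role_map[role_src])
  role[is.na(role)] <- "unknown"
  drugs <- tibble::tibble(
    primary_id = dr$primary_id,
    drug_code = normalize_drug_code(dr$drug_code),
    role = role,
    start_date = NA_character_
  )
  if ("drug_seq" %in% names(dr)) drugs$drug_seq <- dr$drug_seq

  # --- therapy start dates ------------------------------------------------
  if (!is.null(ther_path)) {
    ther <- read_delim_table(ther_path, sep, encoding, "THER")
    th <- pick_cols(ther, column_map$ther,
                    c("primary_id", "start_date"), "THER", ther_path)
    th$start_date <- faers_date_to_iso(th$start_date)
    prov$ther_rows <- nrow(ther)
    if ("drug_seq" %in% names(th) && "drug_seq" %in% names(drugs)) {
      key_th <- paste(th$primary_id, th$drug_seq, sep = "\r")
      key_dr <- paste(drugs$primary_id, drugs$drug_seq, sep = "\r")
      # earliest start per drug exposure (ISO prefixes sort chronologically)
      first <- tapply(th$start_date, key_th,
                      function(v) sort(v, na.last = TRUE)[1])
      drugs$start_date <- as.character(first[key_dr])
    } else {
      first <- tapply(th$start_date, th$primary_id,
                      function(v) sort(v, na.last = TRUE)[1])
      drugs$start_date <- as.character(first[drugs$primary_id])
    }
  }
  drugs$drug_seq <- NULL

  # --- reactions ----------------------------------------------------------
  reactions <- tibble::tibble(
    primary_id = re$primary_id, pt_code = trimws(re$pt_code),
    onset_date = NA_character_
  )
  if ("onset_date" %in% names(re)) {
    reactions$onset_date <- faers_date_to_iso(re$onset_date)
  }

  # child rows without a demographics row cannot be joined; drop and count
  orphan_drug <- !drugs$primary_id %in% reports$primary_id
  orphan_reac <- !reactions$primary_id %in% reports$primary_id
  prov$orphan_drug_rows <- sum(orphan_drug)
  prov$orphan_reac_rows <- sum(orphan_reac)

  new_report_set(reports, drugs[!orphan_drug, ], reactions[!orphan_reac, ],
                 prov)
}

#' Normalise a drug name
#'
#' Case-folds, trims, and optionally applies an exact-match synonym map
#' (e.g. trade name to active substance).
#'
#' @param x character vector of raw drug names.
#' @param synonyms named character vector: `names()` are source spellings
#'   (matched after case-folding/trimming), values the normalised codes.
#' @return normalised character vector.
#' @export
normalize_drug_code <- function(x, synonyms = NULL) {
  out <- tolower(trimws(as.character(x)))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(trimws(names(synonyms)))
    hit <- out %in% names(synonyms)
    out[hit] <- unname(synonyms[out[hit]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
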