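#' Build the drug-by-event 2x2 contingency table
#'
#' Report counts are cross-classified as: `a` = exposed cases, `b` = exposed
#' non-cases, `c` = unexposed cases, `d` = unexposed non-cases, so
#' `a + b + c + d` equals the number of reports analysed. A report is
#' exposed if it has at least one exposure to `drug_code` with a role in
#' `role_filter`.
#'
#' @param rs a `report_set`.
#' @param drug_code normalised drug code to test.
#' @param case_indicator logical vector from [flag_cases()], aligned with
#'   `rs$reports`.
#' @param role_filter which exposure roles count as "taking the drug";
#'   default suspect drugs only.
#' @return a `contingency_table` (list with `a`, `b`, `c`, `d`,
#'   `drug_code`).
#' @export
build_contingency <- function(rs, drug_code, case_indicator,
                              role_filter = c("suspect_primary",
                                              "suspect_secondary")) {
  stopifnot(length(case_indicator) == nrow(rs$reports))
  bad <- setdiff(role_filter, drug_roles())
  if (length(bad)) {
    stop("unknown role(s) in role_filter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sel <- rs$drugs$drug_code == drug_code & rs$drugs$role %in% role_filter
  if (!any(rs$drugs$drug_code == drug_code)) {
    warning("drug_code '", drug_code, "' not present in report set")
  }
  exposed <- rs$reports$primary_id %in% unique(rs$drugs$primary_id[sel])
  case <- as.logical(case_indicator)
  structure(
    list(
      a = sum(exposed & case, na.rm = TRUE),
      b = sum(exposed & !case, na.rm = TRUE),
      c = sum(!exposed & case, na.rm = TRUE),
      d = sum(!exposed & !case, na.rm = TRUE),
      drug_code = drug_code
    ),
    class = "contingency_table"
  )
}

#' Reporting odds ratio with Wald confidence interval
#'
#' The ROR is the cross-product ratio `(a*d)/(b*c)` of the 2x2 table, i.e.
#' the odds of the event among reports mentioning the drug against the odds
#' among all other reports. The CI is Wald on the log scale:
#' `exp(log ROR +- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero,
#' 0.5 is added to all four cells (Haldane-Anscombe) and the result flagged
#' `corrected`; an all-zero table yields an undefined (NA) result.
#'
#' @param tab a `contingency_table` or a length-4 vector `c(a, b, c, d)`.
#' @param z normal quantile for the interval; 1.96 gives the conventional
#'   95% CI.
#' @return a `ror_result`: `ror`, `ci_low`, `ci_high`, `n_cases_with_drug`
#'   (the uncorrected `a`), `corrected`, `signal` (see
#'   [apply_signal_criterion()]).
#' @export
compute_ror <- function(tab, z = 1.96) {
  if (!inherits(tab, "contingency_table")) {
    stopifnot(is.numeric(tab), length(tab) == 4)
    tab <- structure(list(a = tab[1], b = tab[2], c = tab[3], d = tab[4],
                          drug_code = NA_character_),
                     class = "contingency_table")
  }
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  stopifnot(all(cells >= 0))
  a0 <- tab$a
  corrected <- FALSE
  if (all(cells == 0)) {
    res <- list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_cases_with_drug = a0, corrected = FALSE, signal = FALSE,
                undefined = TRUE, drug_code = tab$drug_code)
    return(structure(res, class = "ror_result"))
  }
  if (any(cells == 0)) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  res <- list(
    ror = ror,
    ci_low = exp(log(ror) - z * se),
    ci_high = exp(log(ror) + z * se),
    n_cases_with_drug = a0,
    corrected = corrected,
    signal = FALSE,
    undefined = FALSE,
    drug_code = tab$drug_code
  )
  res$signal <- apply_signal_criterion(structure(res, class = "ror_result"))
  structure(res, class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<ror_result> undefined (all-zero table)\n")
  } else {
    cat(sprintf("<ror_result> ROR %.2f (95%% CI %.2f-%.2f), a = %d%s%s\n",
                x$ror, x$ci_low, x$ci_high, as.integer(x$n_cases_with_drug),
                if (x$corrected) ", corrected" else "",
                if (x$signal) ", SIGNAL" else ""))
  }
  invisible(x)
}

#' Disproportionality signal criterion
#'
#' A drug-event pair is flagged as a signal when the lower limit of the 95%
#' CI of the ROR exceeds 1 and the number of exposed case reports is at
#' least 2. An undefined CI never signals.
#'
#' @param ror_result a `ror_result`.
#' @return logical scalar.
#' @export
apply_signal_criterion <- function(ror_result) {
  isTRUE(ror_result$ci_low > 1) && isTRUE(ror_result$n_cases_with_drug >= 2)
}

#' Default age strata
#'
#' Reports are split at 60 years: the younger group (the reference in the
#' adjusted model) covers ages in `[0, 60)` and the elderly group `[60, Inf)`.
#'
#' @return named list of `c(lo, hi)` half-open intervals.
#' @export
default_age_strata <- function() {
  list("0-59" = c(0, 60), "60+" = c(60, Inf))
}

validate_strata <- function(strata) {
  stopifnot(is.list(strata), length(strata) >= 1)
  if (is.null(names(strata)) || anyDuplicated(names(strata))) {
    stop("strata must have unique labels", call. = FALSE)
  }
  iv <- do.call(rbind, strata)
  stopifnot(ncol(iv) == 2, all(iv[, 1] < iv[, 2]))
  ord <- order(iv[, 1])
  if (any(iv[ord, 2][-nrow(iv)] > iv[ord, 1][-1])) {
    stop("strata intervals overlap", call. = FALSE)
  }
  invisible(strata)
}

#' Age-stratified reporting odds ratios
#'
#' Computes one ROR per age stratum; reports with missing age are excluded
#' from every stratum. Intervals are half-open `[lo, hi)`.
#'
#' @inheritParams build_contingency
#' @param strata named list of intervals, see [default_age_strata()].
#' @param z normal quantile for the CI.
#' @return tibble with one row per stratum: label, the four cells, ROR, CI,
#'   `corrected`, `signal`, `n_stratum`.
#' @export
stratified_ror <- function(rs, drug_code, case_indicator,
                           strata = default_age_strata(),
                           role_filter = c("suspect_primary",
                                           "suspect_secondary"),
                           z = 1.96) {
  validate_strata(strata)
  age <- rs$reports$age_years
  purrr::map_dfr(names(strata), function(lab) {
    iv <- strata[[lab]]
    in_str <- !is.na(age) & age >= iv[1] & age < iv[2]
    if (!any(in_str)) {
      warning("age stratum '", lab, "' is empty")
      return(tibble::tibble(
        stratum = lab, a = 0L, b = 0L, c = 0L, d = 0L,
        ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        corrected = FALSE, signal = FALSE, n_stratum = 0L
      ))
    }
    sub <- subset_report_set(rs, rs$reports$primary_id[in_str],
                             rs$provenance)
    tab <- build_contingency(sub, drug_code, case_indicator[in_str],
                             role_filter)
    rr <- compute_ror(tab, z)
    tibble::tibble(
      stratum = lab, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      ror = rr$ror, ci_low = rr$ci_low, ci_high = rr$ci_high,
      corrected = rr$corrected, signal = rr$signal,
      n_stratum = sum(in_str)
    )
  })
}

#' Tidy crude + stratified ROR table for a set of drugs
#'
#' One row per (drug, stratum), with the crude (all-ages) analysis labelled
#' `"all"`. This is the layout written by the pipeline's disproportionality
#' stage.
#'
#' @inheritParams stratified_ror
#' @param drug_codes character vector of drugs to test.
#' @param event_name label stored in the output.
#' @return tibble.
#' @export
ror_table <- function(rs, drug_codes, case_indicator,
                      strata = default_age_strata(),
                      role_filter = c("suspect_primary", "suspect_secondary"),
                      event_name = "event", z = 1.96) {
  purrr::map_dfr(drug_codes, function(dc) {
    tab <- build_contingency(rs, dc, case_indicator, role_filter)
    rr <- compute_ror(tab, z)
    crude <- tibble::tibble(
      stratum = "all", a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      ror = rr$ror, ci_low = rr$ci_low, ci_high = rr$ci_high,
      corrected = rr$corrected, signal = rr$signal,
      n_stratum = nrow(rs$reports)
    )
    out <- dplyr::bind_rows(
      crude,
      stratified_ror(rs, dc, case_indicator, strata, role_filter, z)
    )
    out$event <- event_name
    out$drug <- dc
    dplyr::relocate(out, "event", "drug")
  })
}
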