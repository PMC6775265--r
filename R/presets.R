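#' Named scenario presets for the synthetic generator
#'
#' Three study conditions ship with the package:
#'
#' * `"null"` — four drugs, every log-odds 0 (baseline event rate only):
#'   crude and adjusted RORs should hover around 1 and stepwise inclusion of
#'   any drug should occur at roughly the significance level.
#' * `"paper_like"` — four anticoagulants with distinct strong main effects
#'   (odds-ratio targets between about 7 and 20), an elderly and a female
#'   main effect, a small age-by-sex interaction and female-by-drug
#'   interactions with ratio-of-odds-ratios 1.5, demographic missingness and
#'   duplicate case versions; per-drug Weibull onset profiles with medians
#'   between roughly 12 and 45 days.
#' * `"tto_profiles"` — three drugs with mutually exclusive exposure and
#'   Weibull onset shapes spanning a decreasing (0.7), constant (1.0) and
#'   increasing (1.5) hazard, with no date missingness, for clean
#'   time-to-onset recovery.
#'
#' @param name preset name; `scenario_presets()` lists all presets,
#'   `scenario_preset(name)` builds one config.
#' @param n_reports override the preset's default number of reports.
#' @param seed seed stored in the config.
#' @return `scenario_presets()`: named list of `generator_config` objects
#'   (at their default sizes); `scenario_preset()`: one `generator_config`.
#' @export
scenario_preset <- function(name, n_reports = NULL, seed = 1L) {
  builders <- list(
    null = function(n) {
      drugs <- tibble::tibble(
        drug_code = c("drug1", "drug2", "drug3", "drug4"),
        exposure_prob = 0.03
      )
      generator_config(
        n_reports = n %||% 20000L,
        drugs = drugs,
        event_model = list(
          intercept = stats::qlogis(0.05), year_slope = 0, age60 = 0,
          female = 0,
          drug = stats::setNames(rep(0, 4), drugs$drug_code),
          interactions = numeric(0)
        ),
        onset_model = stats::setNames(
          rep(list(c(50, 1)), 4), drugs$drug_code),
        seed = seed
      )
    },
    paper_like = function(n) {
      codes <- c("apixaban", "rivaroxaban", "edoxaban", "dabigatran")
      drugs <- tibble::tibble(
        drug_code = codes,
        exposure_prob = c(0.040, 0.050, 0.025, 0.040)
      )
      generator_config(
        n_reports = n %||% 200000L,
        drugs = drugs,
        event_model = list(
          intercept = stats::qlogis(0.02),
          year_slope = 0.04,
          age60 = log(1.6),
          female = log(1.2),
          drug = stats::setNames(log(c(6.8, 19.6, 10.2, 14.5)), codes),
          interactions = c(
            "age60:female" = log(1.15),
            stats::setNames(rep(log(1.5), 4),
                            paste0("female:drug_", codes))
          )
        ),
        onset_model = list(
          apixaban = c(40, 0.75), rivaroxaban = c(65, 0.90),
          edoxaban = c(20, 0.70), dabigatran = c(45, 0.85)
        ),
        missingness = c(year = 0.02, age = 0.10, sex = 0.05,
                        start_date = 0.25, onset_date = 0.25),
        duplicate_rate = 0.10,
        seed = seed
      )
    },
    tto_profiles = function(n) {
      codes <- c("drug_dec", "drug_const", "drug_inc")
      drugs <- tibble::tibble(drug_code = codes, exposure_prob = 0.12)
      generator_config(
        n_reports = n %||% 30000L,
        drugs = drugs,
        exposure_mode = "exclusive",
        event_model = list(
          intercept = stats::qlogis(0.05), year_slope = 0, age60 = 0,
          female = 0,
          drug = stats::setNames(rep(log(8), 3), codes),
          interactions = numeric(0)
        ),
        onset_model = list(
          drug_dec = c(60, 0.7), drug_const = c(50, 1.0),
          drug_inc = c(50, 1.5)
        ),
        seed = seed
      )
    }
  )
  if (!name %in% names(builders)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(builders), collapse = ", "), call. = FALSE)
  }
  builders[[name]](n_reports)
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() {
  nm <- c("null", "paper_like", "tto_profiles")
  stats::setNames(lapply(nm, scenario_preset), nm)
}
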