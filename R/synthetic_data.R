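#' Configure the synthetic spontaneous-report generator
#'
#' The generator emulates the *structure* of a spontaneous reporting system
#' snapshot, not the marginal distributions of any real database: per-report
#' demographics (year, age, sex) with configurable missingness, multiple
#' drugs per report with role codes, multiple reactions per report, duplicate
#' case versions, event probabilities following a logistic model in
#' year/age/sex/drug with interactions, and drug-event onset latencies
#' following Weibull distributions. Every draw is recorded pre-missingness in
#' a ground-truth ledger so each downstream stage can be checked against
#' known effects.
#'
#' @param n_reports number of base reports (before duplicate versions).
#' @param year_range inclusive integer range of reporting years.
#' @param p_female probability a report concerns a female patient.
#' @param age_mixture two-component truncated-normal mixture:
#'   `list(weights, means, sds, range)`.
#' @param drugs tibble/data.frame with `drug_code`, `exposure_prob` and
#'   optionally `p_primary`, `p_secondary`, `p_concomitant` (role mix; must
#'   sum to 1). By default study drugs are always suspect drugs so the
#'   exposure entering the event model is the exposure the analysis counts.
#' @param exposure_mode `"independent"` (each drug an independent Bernoulli)
#'   or `"exclusive"` (at most one study drug per report).
#' @param event_model named list of true log-odds: `intercept`, `year_slope`
#'   (per year, centred at the middle of `year_range`), `age60`, `female`,
#'   `drug` (named vector, one per drug code), `interactions` (named vector
#'   with names like `"female:drug_<code>"`, `"age60:drug_<code>"`,
#'   `"age60:female"`).
#' @param onset_model named list: per drug code a `c(alpha, beta)` Weibull
#'   (scale in days, shape) for the latency of the event after that drug.
#' @param missingness named rates in `[0,1]` for `year`, `age`, `sex`,
#'   `start_date`, `onset_date`. Date missingness degrades half the affected
#'   values to year-month completeness and removes the other half.
#' @param duplicate_rate fraction of reports that receive one extra case
#'   version (a near-copy with a higher primary id and one perturbed
#'   non-analysis field).
#' @param term_pools sizes of the preferred-term pools:
#'   `n_event` codes in the SMQ-SOC intersection, `n_smq_extra` in the SMQ
#'   only, `n_soc_extra` in the SOC only, `n_decoy` in neither.
#' @param reaction_rates `list(extra_event, decoy)` Poisson means for the
#'   number of additional event terms on a case and of decoy terms on any
#'   report.
#' @param seed default seed used by [generate_reports()].
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_reports,
                             year_range = c(2004, 2016),
                             p_female = 0.5,
                             age_mixture = list(weights = c(0.45, 0.55),
                                                means = c(45, 72),
                                                sds = c(14, 10),
                                                range = c(0, 100)),
                             drugs,
                             exposure_mode = c("independent", "exclusive"),
                             event_model,
                             onset_model,
                             missingness = c(year = 0, age = 0, sex = 0,
                                             start_date = 0, onset_date = 0),
                             duplicate_rate = 0,
                             term_pools = list(n_event = 152, n_smq_extra = 60,
                                               n_soc_extra = 80, n_decoy = 150),
                             reaction_rates = list(extra_event = 0.5,
                                                   decoy = 1.2),
                             seed = 1L) {
  exposure_mode <- match.arg(exposure_mode)
  drugs <- tibble::as_tibble(drugs)
  stopifnot(
    n_reports >= 1,
    length(year_range) == 2, year_range[1] <= year_range[2],
    p_female >= 0, p_female <= 1,
    all(c("drug_code", "exposure_prob") %in% names(drugs)),
    all(drugs$exposure_prob >= 0), all(drugs$exposure_prob <= 1),
    duplicate_rate >= 0, duplicate_rate <= 1
  )
  if (!"p_primary" %in% names(drugs)) drugs$p_primary <- 0.8
  if (!"p_secondary" %in% names(drugs)) drugs$p_secondary <- 0.2
  if (!"p_concomitant" %in% names(drugs)) drugs$p_concomitant <- 0
  stopifnot(abs(drugs$p_primary + drugs$p_secondary + drugs$p_concomitant - 1)
            < 1e-8)
  if (exposure_mode == "exclusive" && sum(drugs$exposure_prob) > 1) {
    stop("exclusive exposure probabilities sum above 1", call. = FALSE)
  }
  miss_fields <- c("year", "age", "sex", "start_date", "onset_date")
  m <- stats::setNames(rep(0, length(miss_fields)), miss_fields)
  m[names(missingness)] <- missingness
  stopifnot(all(m >= 0), all(m <= 1))

  em <- event_model
  em$drug <- em$drug[drugs$drug_code]
  names(em$drug) <- drugs$drug_code
  em$drug[is.na(em$drug)] <- 0
  if (is.null(em$interactions)) em$interactions <- numeric(0)
  flat <- c(em$intercept, em$year_slope, em$age60, em$female, em$drug,
            em$interactions)
  if (any(!is.finite(flat))) {
    bad <- c("intercept", "year_slope", "age60", "female", names(em$drug),
             names(em$interactions))[!is.finite(flat)]
    stop("infeasible event model: non-finite log-odds for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (dc in drugs$drug_code) {
    ab <- onset_model[[dc]]
    if (is.null(ab) || length(ab) != 2 || any(ab <= 0)) {
      stop("onset_model must give positive c(alpha, beta) for drug '", dc,
           "'", call. = FALSE)
    }
  }
  structure(
    list(n_reports = as.integer(n_reports), year_range = as.integer(year_range),
         p_female = p_female, age_mixture = age_mixture, drugs = drugs,
         exposure_mode = exposure_mode, event_model = em,
         onset_model = onset_model, missingness = m,
         duplicate_rate = duplicate_rate, term_pools = term_pools,
         reaction_rates = reaction_rates, seed = as.integer(seed)),
    class = "generator_config"
  )
}

rtruncnorm_mix <- function(n, mix) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  x <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  # resample out-of-range draws; clamp the stragglers
  for (i in 1:20) {
    bad <- x < mix$range[1] | x > mix$range[2]
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mix$means[comp[bad]], mix$sds[comp[bad]])
  }
  pmin(pmax(x, mix$range[1]), mix$range[2])
}

make_term_pools <- function(tp) {
  idx <- cumsum(c(0, tp$n_event, tp$n_smq_extra, tp$n_soc_extra, tp$n_decoy))
  code <- function(a, b) sprintf("PT%05d", (a + 1):b)
  list(
    event = code(idx[1], idx[2]),
    smq_extra = if (tp$n_smq_extra) code(idx[2], idx[3]) else character(0),
    soc_extra = if (tp$n_soc_extra) code(idx[3], idx[4]) else character(0),
    decoy = if (tp$n_decoy) code(idx[4], idx[5]) else character(0)
  )
}

#' Generate a synthetic report set with its ground-truth ledger
#'
#' Covariates are drawn per the config; case status is Bernoulli with a
#' logistic linear predictor in the pre-missingness covariates; cases receive
#' at least one preferred term from the event pool while non-cases receive
#' only non-event terms; exposed cases get a start date uniform within their
#' reporting year and an onset equal to the causal drug's start plus a
#' Weibull latency (rounded up to whole days, so the inclusive day count
#' equals the rounded draw); missingness is applied after the truth is
#' recorded; duplicate case versions are appended with higher primary ids.
#' Identical config and seed give byte-identical canonical output.
#'
#' @param config a [generator_config()].
#' @param seed overrides `config$seed`.
#' @return list with `report_set`, and `ledger` (a `list`: `truth` tibble,
#'   `effects`, `onset_params`, `duplicate_map`, `event_definition`,
#'   `term_tables`, `config`).
#' @export
generate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cf) {
  n <- cf$n_reports
  drugs <- cf$drugs
  nd <- nrow(drugs)
  year <- sample(seq(cf$year_range[1], cf$year_range[2]), n, replace = TRUE)
  female <- stats::rbinom(n, 1, cf$p_female)
  age <- rtruncnorm_mix(n, cf$age_mixture)

  # exposures
  expo <- matrix(0L, n, nd, dimnames = list(NULL, drugs$drug_code))
  if (cf$exposure_mode == "independent") {
    for (j in seq_len(nd)) {
      expo[, j] <- stats::rbinom(n, 1, drugs$exposure_prob[j])
    }
  } else {
    u <- stats::runif(n)
    edges <- cumsum(drugs$exposure_prob)
    pick <- findInterval(u, c(0, edges), left.open = TRUE)
    hit <- pick >= 1 & pick <= nd
    expo[cbind(which(hit), pick[hit])] <- 1L
  }

  # event model on pre-missingness covariates
  em <- cf$event_model
  age60 <- as.numeric(age >= 60)
  lp <- em$intercept +
    em$year_slope * (year - mean(cf$year_range)) +
    em$age60 * age60 + em$female * female +
    as.numeric(expo %*% em$drug)
  covar <- function(tok) {
    if (tok == "age60") age60
    else if (tok == "female") female
    else if (startsWith(tok, "drug_")) expo[, sub("^drug_", "", tok)]
    else stop("unknown interaction token '", tok, "'", call. = FALSE)
  }
  for (nm in names(em$interactions)) {
    tk <- strsplit(nm, ":", fixed = TRUE)[[1]]
    stopifnot(length(tk) == 2)
    lp <- lp + em$interactions[[nm]] * covar(tk[1]) * covar(tk[2])
  }
  event <- stats::rbinom(n, 1, stats::plogis(lp))

  pid <- as.character(seq_len(n))
  cid <- sprintf("C%07d", seq_len(n))

  # start dates: every exposed study-drug row, uniform within report year
  exp_idx <- which(expo == 1L, arr.ind = TRUE)
  exp_idx <- exp_idx[order(exp_idx[, 1], exp_idx[, 2]), , drop = FALSE]
  row_i <- exp_idx[, 1]
  drug_j <- exp_idx[, 2]
  start <- as.Date(sprintf("%d-01-01", year[row_i])) +
    sample.int(365, length(row_i), replace = TRUE) - 1L
  role <- character(length(row_i))
  for (j in seq_len(nd)) {
    sel <- drug_j == j
    if (!any(sel)) next
    role[sel] <- sample(
      c("suspect_primary", "suspect_secondary", "concomitant"),
      sum(sel), replace = TRUE,
      prob = c(drugs$p_primary[j], drugs$p_secondary[j],
               drugs$p_concomitant[j])
    )
  }

  # causal drug = first exposed study drug (config order); Weibull latency
  causal <- rep(NA_integer_, n)
  causal[row_i[!duplicated(row_i)]] <- drug_j[!duplicated(row_i)]
  onset <- rep(as.Date(NA), n)
  true_dur <- rep(NA_real_, n)
  first_start <- rep(as.Date(NA), n)
  first_start[row_i[!duplicated(row_i)]] <- start[!duplicated(row_i)]
  for (j in seq_len(nd)) {
    sel <- which(causal == j & event == 1)
    if (!length(sel)) next
    ab <- cf$onset_model[[drugs$drug_code[j]]]
    w <- stats::rweibull(length(sel), shape = ab[2], scale = ab[1])
    d <- ceiling(w)
    true_dur[sel] <- d
    onset[sel] <- first_start[sel] + (d - 1)
  }

  # reactions: cases get >= 1 event term, everyone gets Poisson decoys
  pools <- make_term_pools(cf$term_pools)
  non_event_pool <- c(pools$smq_extra, pools$soc_extra, pools$decoy)
  n_event_pt <- ifelse(event == 1,
                       1L + stats::rpois(n, cf$reaction_rates$extra_event),
                       0L)
  n_decoy_pt <- stats::rpois(n, cf$reaction_rates$decoy)
  ev_rows <- rep(seq_len(n), n_event_pt)
  dc_rows <- rep(seq_len(n), n_decoy_pt)
  reactions <- tibble::tibble(
    primary_id = c(pid[ev_rows], pid[dc_rows]),
    pt_code = c(sample(pools$event, length(ev_rows), replace = TRUE),
                sample(non_event_pool, length(dc_rows), replace = TRUE)),
    onset_date = c(format(onset[ev_rows], "%Y-%m-%d"),
                   rep(NA_character_, length(dc_rows))),
    .row = c(ev_rows, dc_rows)
  )
  reactions <- reactions[order(reactions$.row), ]
  reactions$.row <- NULL

  drugs_tbl <- tibble::tibble(
    primary_id = pid[row_i],
    drug_code = drugs$drug_code[drug_j],
    role = role,
    start_date = format(start, "%Y-%m-%d")
  )

  # record the truth before missingness
  truth <- tibble::tibble(
    primary_id = pid, case_id = cid,
    event = event == 1,
    report_year = year, age_years = age,
    sex = ifelse(female == 1, "F", "M"),
    age60 = age60 == 1, female = female == 1
  )
  for (j in seq_len(nd)) {
    truth[[paste0("exp_", drugs$drug_code[j])]] <- expo[, j] == 1L
  }
  truth$causal_drug <- ifelse(is.na(causal), NA_character_,
                              drugs$drug_code[causal])
  truth$true_duration <- true_dur

  # missingness, after the truth is on file
  m <- cf$missingness
  drop <- function(k, rate) stats::runif(k) < rate
  year_out <- ifelse(drop(n, m["year"]), NA_integer_, year)
  age_out <- ifelse(drop(n, m["age"]), NA_real_, age)
  sex_out <- ifelse(drop(n, m["sex"]), NA_character_, truth$sex)
  degrade <- function(dates, rate) {
    hit <- drop(length(dates), rate) & !is.na(dates)
    to_ym <- hit & stats::runif(length(dates)) < 0.5
    dates[to_ym] <- substr(dates[to_ym], 1, 7)
    dates[hit & !to_ym] <- NA_character_
    dates
  }
  drugs_tbl$start_date <- degrade(drugs_tbl$start_date, m["start_date"])
  reactions$onset_date <- degrade(reactions$onset_date, m["onset_date"])

  reports <- tibble::tibble(
    primary_id = pid, case_id = cid,
    report_year = as.integer(year_out), age_years = age_out, sex = sex_out,
    source_tag = "synthetic"
  )

  # duplicate case versions: near-copies with a higher primary id and one
  # perturbed non-analysis field (the source tag), appended after the base
  n_dup <- round(cf$duplicate_rate * n)
  duplicate_map <- tibble::tibble(case_id = character(),
                                  original_primary_id = character(),
                                  duplicate_primary_id = character())
  if (n_dup > 0) {
    dup_of <- sort(sample.int(n, n_dup))
    dup_pid <- as.character(n + seq_len(n_dup))
    dup_reports <- reports[dup_of, ]
    dup_reports$primary_id <- dup_pid
    dup_reports$source_tag <- "synthetic-v2"
    remap <- stats::setNames(dup_pid, pid[dup_of])
    dup_drugs <- drugs_tbl[drugs_tbl$primary_id %in% pid[dup_of], ]
    dup_drugs$primary_id <- unname(remap[dup_drugs$primary_id])
    dup_reac <- reactions[reactions$primary_id %in% pid[dup_of], ]
    dup_reac$primary_id <- unname(remap[dup_reac$primary_id])
    reports <- dplyr::bind_rows(reports, dup_reports)
    drugs_tbl <- dplyr::bind_rows(drugs_tbl, dup_drugs)
    reactions <- dplyr::bind_rows(reactions, dup_reac)
    duplicate_map <- tibble::tibble(
      case_id = cid[dup_of],
      original_primary_id = pid[dup_of],
      duplicate_primary_id = dup_pid
    )
  }

  smq <- term_set("smq_hemorrhage", c(pools$event, pools$smq_extra))
  soc <- term_set("soc_target", c(pools$event, pools$soc_extra))
  event_def <- define_event(smq, soc, name = "synthetic_hemorrhage")
  term_tables <- tibble::tibble(
    set_name = c(rep(smq$name, length(smq$pt_codes)),
                 rep(soc$name, length(soc$pt_codes))),
    pt_code = c(smq$pt_codes, soc$pt_codes)
  )

  rs <- new_report_set(
    reports, drugs_tbl, reactions,
    provenance = list(generator = "pvror synthetic", n_generated = n,
                      n_duplicates = n_dup)
  )
  list(
    report_set = rs,
    ledger = list(
      truth = truth,
      effects = cf$event_model,
      onset_params = cf$onset_model,
      duplicate_map = duplicate_map,
      event_definition = event_def,
      term_tables = term_tables,
      config = cf
    )
  )
}
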