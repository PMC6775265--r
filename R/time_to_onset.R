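#' Time-to-onset durations for a drug-event pair
#'
#' For every report that is a case and is exposed to `drug_code` (suspect
#' roles by default), the latency is counted from the earliest *complete*
#' (year-month-day) start date among that drug's exposures to the earliest
#' complete onset date among the reactions matching the event definition,
#' inclusive of both endpoints: `duration = onset - start + 1` days, so a
#' same-day onset counts as 1 day. Reports are excluded (and counted) when
#' either date is incomplete or missing, when onset precedes start, or when
#' the duration exceeds the analysis window.
#'
#' @param rs a `report_set`.
#' @param drug_code drug to analyse.
#' @param event_def an `event_definition` (or term set / character codes)
#'   naming the qualifying reaction terms.
#' @param window_days analysis window after the start of administration
#'   (365 by default).
#' @param role_filter exposure roles counting as drug intake.
#' @param include_same_day if `FALSE`, same-day onsets are excluded instead
#'   of counted as 1 day.
#' @return a `duration_sample`: `durations` (days, in `(0, window_days]`),
#'   exclusion counters, `window_days`, `drug_code`, `n`.
#' @export
compute_durations <- function(rs, drug_code, event_def, window_days = 365,
                              role_filter = c("suspect_primary",
                                              "suspect_secondary"),
                              include_same_day = TRUE) {
  eff <- if (inherits(event_def, "event_definition")) event_def$effective_terms
         else if (inherits(event_def, "term_set")) event_def$pt_codes
         else as.character(event_def)

  case_ids <- unique(rs$reactions$primary_id[rs$reactions$pt_code %in% eff])
  dsel <- rs$drugs$drug_code == drug_code & rs$drugs$role %in% role_filter &
    rs$drugs$primary_id %in% case_ids
  dtb <- rs$drugs[dsel, c("primary_id", "start_date")]
  qualifying <- unique(dtb$primary_id)

  # earliest complete start per qualifying report
  dtb$start <- partial_date_to_date(parse_partial_date(dtb$start_date))
  start <- dplyr::summarise(
    dplyr::group_by(dtb, .data$primary_id),
    start = if (all(is.na(.data$start))) as.Date(NA) else
      min(.data$start, na.rm = TRUE),
    .groups = "drop"
  )

  rtb <- rs$reactions[rs$reactions$primary_id %in% qualifying &
                        rs$reactions$pt_code %in% eff,
                      c("primary_id", "onset_date")]
  rtb$onset <- partial_date_to_date(parse_partial_date(rtb$onset_date))
  onset <- dplyr::summarise(
    dplyr::group_by(rtb, .data$primary_id),
    onset = if (all(is.na(.data$onset))) as.Date(NA) else
      min(.data$onset, na.rm = TRUE),
    .groups = "drop"
  )

  both <- dplyr::inner_join(start, onset, by = "primary_id")
  incomplete <- is.na(both$start) | is.na(both$onset)
  n_incomplete <- sum(incomplete) + (length(qualifying) - nrow(both))
  both <- both[!incomplete, ]
  diff_days <- as.integer(both$onset - both$start)

  negative <- diff_days < 0
  n_same_day <- 0L
  if (include_same_day) {
    dur <- diff_days[!negative] + 1L
  } else {
    n_same_day <- sum(diff_days == 0)
    dur <- diff_days[!negative & diff_days > 0]
  }
  beyond <- dur > window_days
  structure(
    list(
      durations = as.numeric(dur[!beyond]),
      n = sum(!beyond),
      n_excluded_incomplete = n_incomplete,
      n_excluded_negative = sum(negative),
      n_excluded_same_day = n_same_day,
      n_excluded_beyond_window = sum(beyond),
      window_days = window_days,
      drug_code = drug_code
    ),
    class = "duration_sample"
  )
}

#' @export
print.duration_sample <- function(x, ...) {
  cat("<duration_sample> ", x$n, " durations in (0, ", x$window_days,
      "] for '", x$drug_code, "' (excluded: ", x$n_excluded_incomplete,
      " incomplete, ", x$n_excluded_negative, " negative, ",
      x$n_excluded_beyond_window, " beyond window)\n", sep = "")
  invisible(x)
}

as_durations <- function(x) {
  if (inherits(x, "duration_sample")) x$durations else as.numeric(x)
}

# profile log-likelihood machinery: for fixed shape b, the scale has the
# closed form alpha = (mean t^b)^(1/b); the profile score in b is
# n/b + sum(log t) - n * S1(b)/S0(b) with S_k = sum t^b (log t)^k,
# strictly decreasing in b, so Newton from a moment start is safe.
weibull_profile_root <- function(t, tol = 1e-10, maxit = 200) {
  w <- log(t)
  n <- length(t)
  sw <- sum(w)
  score <- function(b) {
    z <- exp(b * w - max(b * w))  # rescaled t^b, ratios unaffected
    s0 <- sum(z); s1 <- sum(z * w); s2 <- sum(z * w * w)
    list(g = n / b + sw - n * s1 / s0,
         gprime = -n / b^2 - n * (s2 * s0 - s1^2) / s0^2)
  }
  sdw <- stats::sd(w)
  b <- if (is.finite(sdw) && sdw > 0) 1.2825 / sdw else 1
  for (i in seq_len(maxit)) {
    s <- score(b)
    step <- s$g / s$gprime
    b_new <- b - step
    while (b_new <= 0) {  # stay in the parameter space
      step <- step / 2
      b_new <- b - step
    }
    if (abs(b_new - b) < tol * max(1, b)) return(b_new)
    b <- b_new
  }
  b
}

weibull_loglik <- function(t, alpha, beta) {
  n <- length(t)
  n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(log(t)) -
    sum((t / alpha)^beta)
}

#' Weibull maximum-likelihood fit of onset latencies
#'
#' Fits the two-parameter Weibull by maximum likelihood: the shape is the
#' root of the profile score equation (Newton iteration), the scale then
#' follows in closed form. 95% CIs are Wald intervals on the log-parameter
#' scale from the inverse observed information. The hazard profile is
#' classified from the shape CI: `increasing` when the lower limit exceeds
#' 1, `decreasing` when the upper limit is below 1, `constant` otherwise
#' (shape 1 is the exponential, memoryless case).
#'
#' @param x a `duration_sample` or a numeric vector of positive durations.
#' @param floor_n minimum sample size accepted.
#' @param z normal quantile for the CIs.
#' @param tol,maxit Newton tolerance and iteration cap for the shape root.
#' @return a `weibull_fit`: `scale_alpha`, `shape_beta`, their CIs,
#'   `loglik`, `hazard_class`, `n`, `median_fit` (the fitted median
#'   `alpha * log(2)^(1/beta)`).
#' @export
weibull_mle <- function(x, floor_n = 10, z = 1.96, tol = 1e-10, maxit = 200) {
  t <- as_durations(x)
  n <- length(t)
  if (n < floor_n) {
    stop("need at least ", floor_n, " durations, got ", n, call. = FALSE)
  }
  stopifnot(all(t > 0))
  if (length(unique(t)) < 2) {
    stop("all durations identical; the shape estimate diverges",
         call. = FALSE)
  }
  gm <- exp(mean(log(t)))  # work on t/gm for numerical stability
  u <- t / gm
  beta <- weibull_profile_root(u, tol = tol, maxit = maxit)
  alpha_u <- mean(u^beta)^(1 / beta)
  alpha <- gm * alpha_u

  # observed information in (log alpha, log beta)
  nll <- function(par) -weibull_loglik(u, exp(par[1]), exp(par[2]))
  H <- stats::optimHess(c(log(alpha_u), log(beta)), nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se_la <- sqrt(V[1, 1])
  se_lb <- sqrt(V[2, 2])
  alpha_ci <- gm * exp(log(alpha_u) + c(-1, 1) * z * se_la)
  beta_ci <- exp(log(beta) + c(-1, 1) * z * se_lb)

  structure(
    list(
      scale_alpha = alpha,
      shape_beta = beta,
      alpha_ci_low = alpha_ci[1], alpha_ci_high = alpha_ci[2],
      beta_ci_low = beta_ci[1], beta_ci_high = beta_ci[2],
      loglik = weibull_loglik(t, alpha, beta),
      hazard_class = classify_hazard(beta_ci[1], beta_ci[2]),
      median_fit = alpha * log(2)^(1 / beta),
      n = n
    ),
    class = "weibull_fit"
  )
}

#' Hazard-profile class from the shape CI
#'
#' @param beta_ci_low,beta_ci_high 95% CI limits of the Weibull shape.
#' @return `"increasing"` if the lower limit exceeds 1, `"decreasing"` if
#'   the upper limit is below 1, otherwise `"constant"`.
#' @export
classify_hazard <- function(beta_ci_low, beta_ci_high) {
  if (is.na(beta_ci_low) || is.na(beta_ci_high)) return(NA_character_)
  if (beta_ci_low > 1) "increasing"
  else if (beta_ci_high < 1) "decreasing"
  else "constant"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> alpha %.2f (%.2f-%.2f), beta %.3f (%.3f-%.3f), hazard %s, n = %d\n",
    x$scale_alpha, x$alpha_ci_low, x$alpha_ci_high,
    x$shape_beta, x$beta_ci_low, x$beta_ci_high, x$hazard_class, x$n))
  invisible(x)
}

#' Empirical summary of onset latencies
#'
#' Median and quartiles use linear interpolation between order statistics;
#' `frac_within` is the share of durations at most `within_days` days; the
#' histogram covers `(0, window]` in `bin_width`-day bins (the last bin is
#' shortened to end exactly at the window).
#'
#' @param x a `duration_sample` or numeric vector of durations.
#' @param within_days threshold for the early-onset fraction (30 by
#'   convention).
#' @param bin_width histogram bin width in days.
#' @return an `onset_summary` list: `n`, `median`, `q1`, `q3`,
#'   `frac_within`, `within_days`, `breaks`, `counts`.
#' @export
summarize_onset <- function(x, within_days = 30, bin_width = 30) {
  t <- as_durations(x)
  if (!length(t)) stop("empty duration sample", call. = FALSE)
  window <- if (inherits(x, "duration_sample")) x$window_days else max(t)
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  breaks <- unique(c(seq(0, window, by = bin_width), window))
  counts <- graphics::hist(t, breaks = breaks, plot = FALSE, right = TRUE)$counts
  structure(
    list(n = length(t), median = q[2], q1 = q[1], q3 = q[3],
         frac_within = mean(t <= within_days), within_days = within_days,
         breaks = breaks, counts = counts),
    class = "onset_summary"
  )
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf(
    "<onset_summary> n = %d, median %.1f (IQR %.1f-%.1f) days, %.1f%% within %d days\n",
    x$n, x$median, x$q1, x$q3, 100 * x$frac_within, x$within_days))
  invisible(x)
}

#' Time-to-onset summary table for a set of drugs
#'
#' One row per drug: sample size, exclusion counts, empirical median and
#' quartiles, early-onset fraction, Weibull scale/shape with CIs, hazard
#' class, and the Weibull-fitted median. Drugs with fewer than `floor_n`
#' usable durations get `NA` fit columns.
#'
#' @inheritParams compute_durations
#' @param drug_codes drugs to analyse.
#' @param event_name label stored in the output.
#' @param floor_n minimum durations required for the Weibull fit.
#' @return tibble.
#' @export
tto_table <- function(rs, drug_codes, event_def, window_days = 365,
                      role_filter = c("suspect_primary", "suspect_secondary"),
                      event_name = "event", floor_n = 10) {
  purrr::map_dfr(drug_codes, function(dc) {
    ds <- compute_durations(rs, dc, event_def, window_days, role_filter)
    row <- tibble::tibble(
      event = event_name, drug = dc, n = ds$n,
      n_excluded_incomplete = ds$n_excluded_incomplete,
      n_excluded_negative = ds$n_excluded_negative,
      n_excluded_beyond_window = ds$n_excluded_beyond_window,
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      frac_within_30 = NA_real_,
      alpha = NA_real_, alpha_ci_low = NA_real_, alpha_ci_high = NA_real_,
      beta = NA_real_, beta_ci_low = NA_real_, beta_ci_high = NA_real_,
      hazard_class = NA_character_, median_fit = NA_real_
    )
    if (ds$n >= 1) {
      s <- summarize_onset(ds)
      row$median <- s$median; row$q1 <- s$q1; row$q3 <- s$q3
      row$frac_within_30 <- s$frac_within
    }
    if (ds$n >= floor_n && length(unique(ds$durations)) >= 2) {
      fit <- weibull_mle(ds, floor_n = floor_n)
      row$alpha <- fit$scale_alpha
      row$alpha_ci_low <- fit$alpha_ci_low
      row$alpha_ci_high <- fit$alpha_ci_high
      row$beta <- fit$shape_beta
      row$beta_ci_low <- fit$beta_ci_low
      row$beta_ci_high <- fit$beta_ci_high
      row$hazard_class <- fit$hazard_class
      row$median_fit <- fit$median_fit
    }
    row
  })
}
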