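test_that("durations count inclusively from first complete start to onset", {
  rs <- toy_report_set()
  ds <- compute_durations(rs, "doacx", toy_event_terms())
  # report 1: 2010-03-01 -> 2010-03-31 is 31 days inclusive
  # report 2: 2011-05-10 -> 2011-06-01 is 23 days inclusive
  # report 3: start has only year-month -> excluded as incomplete
  expect_setequal(ds$durations, c(31, 23))
  expect_equal(ds$n_excluded_incomplete, 1)
  expect_equal(ds$n_excluded_negative, 0)
})

mini_tto_set <- function(start, onset) {
  n <- length(start)
  new_report_set(
    tibble::tibble(primary_id = as.character(seq_len(n)),
                   case_id = sprintf("C%d", seq_len(n))),
    tibble::tibble(primary_id = as.character(seq_len(n)), drug_code = "dx",
                   role = "suspect_primary", start_date = start),
    tibble::tibble(primary_id = as.character(seq_len(n)), pt_code = "EV",
                   onset_date = onset)
  )
}

test_that("same-day onset counts as one day; the convention is switchable", {
  rs <- mini_tto_set("2014-03-01", "2014-03-01")
  ds <- compute_durations(rs, "dx", "EV")
  expect_equal(ds$durations, 1)
  ds2 <- compute_durations(rs, "dx", "EV", include_same_day = FALSE)
  expect_length(ds2$durations, 0)
  expect_equal(ds2$n_excluded_same_day, 1)
})

test_that("negative and beyond-window latencies are excluded and counted", {
  rs <- mini_tto_set(c("2014-06-01", "2014-01-01", "2014-01-01"),
                     c("2014-05-01", "2015-06-01", "2014-02-01"))
  ds <- compute_durations(rs, "dx", "EV")
  expect_equal(ds$durations, 32)  # only the third report survives
  expect_equal(ds$n_excluded_negative, 1)
  expect_equal(ds$n_excluded_beyond_window, 1)
})

test_that("earliest complete dates are used when several exist", {
  rs <- new_report_set(
    tibble::tibble(primary_id = "1", case_id = "C1"),
    tibble::tibble(primary_id = "1", drug_code = "dx",
                   role = c("suspect_primary", "suspect_secondary"),
                   start_date = c("2014-02-10", "2014-02-01")),
    tibble::tibble(primary_id = "1", pt_code = c("EV", "EV"),
                   onset_date = c("2014-03-05", "2014-03-01"))
  )
  ds <- compute_durations(rs, "dx", "EV")
  expect_equal(ds$durations, 29)  # 2014-02-01 -> 2014-03-01 inclusive
})

# dense 2-D grid maximisation of the Weibull log-likelihood, used as an
# independent oracle for the Newton profile solver
grid_weibull <- function(t, alpha_grid, beta_grid) {
  ll <- outer(alpha_grid, beta_grid, Vectorize(function(a, b) {
    sum(stats::dweibull(t, shape = b, scale = a, log = TRUE))
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  c(alpha = alpha_grid[best[1]], beta = beta_grid[best[2]])
}

test_that("the Weibull MLE matches a dense grid-search oracle", {
  withr::local_seed(501)
  for (i in 1:3) {
    t <- rweibull(40, shape = runif(1, 0.6, 2), scale = runif(1, 20, 80))
    fit <- weibull_mle(t)
    g1 <- grid_weibull(t, seq(1, 200, by = 0.5), seq(0.2, 4, by = 0.01))
    g2 <- grid_weibull(t, seq(g1["alpha"] - 1, g1["alpha"] + 1, by = 1e-3),
                       seq(g1["beta"] - 0.02, g1["beta"] + 0.02, by = 1e-4))
    expect_equal(fit$scale_alpha, unname(g2["alpha"]), tolerance = 1e-3)
    expect_equal(fit$shape_beta, unname(g2["beta"]), tolerance = 1e-3)
  }
})

test_that("two repeated distinct values still converge to the grid optimum", {
  t <- rep(c(5, 20), each = 10)
  fit <- weibull_mle(t)
  g1 <- grid_weibull(t, seq(5, 40, by = 0.1), seq(0.5, 5, by = 0.01))
  g2 <- grid_weibull(t, seq(g1["alpha"] - 0.2, g1["alpha"] + 0.2, by = 1e-4),
                     seq(g1["beta"] - 0.02, g1["beta"] + 0.02, by = 1e-4))
  expect_equal(fit$scale_alpha, unname(g2["alpha"]), tolerance = 1e-3)
  expect_equal(fit$shape_beta, unname(g2["beta"]), tolerance = 1e-3)
})

test_that("the MLE agrees with an independent survival-regression fit", {
  withr::local_seed(502)
  t <- rweibull(400, shape = 1.4, scale = 55)
  fit <- weibull_mle(t)
  sr <- survival::survreg(survival::Surv(t) ~ 1, dist = "weibull")
  expect_equal(fit$shape_beta, 1 / sr$scale, tolerance = 1e-5)
  expect_equal(fit$scale_alpha, unname(exp(coef(sr))), tolerance = 1e-5)
})

test_that("scale equivariance: t -> k t scales alpha and fixes beta", {
  withr::local_seed(503)
  t <- rweibull(300, shape = 1.2, scale = 40)
  f1 <- weibull_mle(t)
  f2 <- weibull_mle(7.5 * t)
  expect_equal(f2$shape_beta, f1$shape_beta, tolerance = 1e-8)
  expect_equal(f2$scale_alpha, 7.5 * f1$scale_alpha, tolerance = 1e-8)
})

test_that("degenerate samples are refused with informative errors", {
  expect_error(weibull_mle(c(1, 2, 3)), "at least 10")
  expect_error(weibull_mle(rep(5, 20)), "identical")
})

test_that("hazard class is a pure function of the shape CI", {
  expect_equal(classify_hazard(1.1, 1.8), "increasing")
  expect_equal(classify_hazard(0.6, 0.9), "decreasing")
  expect_equal(classify_hazard(0.8, 1.3), "constant")
  expect_equal(classify_hazard(1.0, 1.5), "constant")  # boundary touches 1
  expect_true(is.na(classify_hazard(NA, 1.5)))
})

test_that("onset summaries use interpolated quartiles and the 30-day fraction", {
  s <- summarize_onset(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  expect_equal(s$frac_within, 0.30)

  one <- summarize_onset(7)
  expect_equal(c(one$q1, one$median, one$q3), c(7, 7, 7))

  expect_error(summarize_onset(numeric(0)), "empty")
})

test_that("histogram bins cover the window and count every duration", {
  cf <- scenario_preset("tto_profiles", n_reports = 8000, seed = 6)
  sim <- generate_reports(cf)
  ds <- compute_durations(sim$report_set, "drug_inc",
                          sim$ledger$event_definition)
  s <- summarize_onset(ds)
  expect_equal(sum(s$counts), s$n)
  expect_equal(s$breaks[1], 0)
  expect_equal(s$breaks[length(s$breaks)], 365)
})

test_that("the per-drug summary table recovers the generator onset profiles", {
  cf <- scenario_preset("tto_profiles", seed = 19)
  sim <- generate_reports(cf)
  tt <- tto_table(sim$report_set, cf$drugs$drug_code,
                  sim$ledger$event_definition)
  expect_equal(tt$hazard_class[tt$drug == "drug_dec"], "decreasing")
  expect_equal(tt$hazard_class[tt$drug == "drug_const"], "constant")
  expect_equal(tt$hazard_class[tt$drug == "drug_inc"], "increasing")
  # whole-day rounding inflates the shape of sub-exponential profiles
  # (short latencies pile up at 1 day), so CI coverage of the continuous
  # truth is only expected for shapes at or above 1
  for (dc in c("drug_const", "drug_inc")) {
    truth <- cf$onset_model[[dc]]
    row <- tt[tt$drug == dc, ]
    expect_true(row$beta_ci_low <= truth[2] && truth[2] <= row$beta_ci_high,
                info = dc)
  }
  dec <- tt[tt$drug == "drug_dec", ]
  expect_lt(dec$beta_ci_high, 1)
  expect_gt(dec$beta, cf$onset_model[["drug_dec"]][2])  # rounding bias is up
})
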