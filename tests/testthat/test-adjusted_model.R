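test_that("design coding: elderly/female/drug indicators and their products", {
  reports <- tibble::tibble(
    primary_id = c("1", "2"), case_id = c("C1", "C2"),
    report_year = c(2012L, 2010L), age_years = c(70, 59), sex = c("F", "M"),
    source_tag = "t"
  )
  drugs <- tibble::tibble(primary_id = "1", drug_code = "rivaroxaban",
                          role = "suspect_primary", start_date = NA_character_)
  rs <- new_report_set(reports, drugs)
  spec <- model_spec("rivaroxaban")
  des <- build_design(rs, spec, c(TRUE, FALSE))
  x1 <- des$X[1, ]
  expect_equal(unname(x1[c("age60", "female", "drug_rivaroxaban",
                           "female:drug_rivaroxaban")]), c(1, 1, 1, 1))
  expect_equal(unname(des$X[2, "age60"]), 0)  # age 59 is below the cut
  expect_equal(unname(des$X[, "year_c"]), c(1, -1))

  # a drug nobody took yields a zero-variance column, which is dropped
  # along with any interaction built on it
  spec2 <- model_spec(c("rivaroxaban", "edoxaban"))
  expect_warning(des2 <- build_design(rs, spec2, c(TRUE, FALSE)),
                 "drug_edoxaban")
  expect_false("drug_edoxaban" %in% colnames(des2$X))
  expect_false("female:drug_edoxaban" %in% des2$terms$term)
})

test_that("design reproduces the generator covariates exactly", {
  cf <- scenario_preset("paper_like", n_reports = 1500, seed = 31)
  cf$missingness[] <- 0
  sim <- generate_reports(cf)
  rs <- deduplicate(sim$report_set)
  truth <- sim$ledger$truth[match(rs$reports$case_id,
                                  sim$ledger$truth$case_id), ]
  des <- build_design(rs, model_spec(cf$drugs$drug_code),
                      flag_cases(rs, sim$ledger$event_definition))
  expect_equal(unname(des$X[, "age60"]), as.numeric(truth$age60))
  expect_equal(unname(des$X[, "female"]), as.numeric(truth$female))
  for (dc in cf$drugs$drug_code) {
    expect_equal(unname(des$X[, paste0("drug_", dc)]),
                 as.numeric(truth[[paste0("exp_", dc)]]))
  }
  expect_equal(des$y, as.numeric(truth$event))
})

test_that("design demands complete demographics", {
  rs <- toy_report_set()
  expect_error(build_design(rs, model_spec("doacx"), rep(TRUE, 10)),
               "filter_complete")
})

test_that("a saturated one-indicator logistic fit equals the crude ROR", {
  # the (10, 90, 100, 9900) table expanded to unit records
  y <- c(rep(1, 10), rep(0, 90), rep(1, 100), rep(0, 9900))
  x <- c(rep(1, 100), rep(0, 10000))
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "drug")), y)
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$coefficients["drug"])), 11.0,
               tolerance = 1e-8)
  # and the intercept recovers the unexposed odds
  expect_equal(exp(unname(fit$coefficients["(Intercept)"])), 100 / 9900,
               tolerance = 1e-8)
})

test_that("exp(coefficient) equals compute_ror on random 2x2 tables", {
  withr::local_seed(42)
  for (i in 1:25) {
    cells <- sample(2:50, 4, replace = TRUE)
    x <- rep(c(1, 1, 0, 0), cells)
    y <- rep(c(1, 0, 1, 0), cells)
    fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "d")), y)
    expect_equal(exp(unname(fit$coefficients["d"])),
                 compute_ror(cells)$ror, tolerance = 1e-6)
  }
})

test_that("degenerate responses are flagged as separated, not reported", {
  y <- rep(0, 60)
  x <- matrix(rbinom(60, 1, 0.5), ncol = 1, dimnames = list(NULL, "d"))
  fit <- fit_logistic(x, y)
  expect_true(fit$separated)
  expect_false(fit$converged)
  expect_error(adjusted_rors(fit), "converged")
})

test_that("likelihood-ratio tests behave on nested fits", {
  withr::local_seed(7)
  n <- 500
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + X[, "a"]))
  full <- fit_logistic(X, y)
  red <- fit_logistic(X[, "a", drop = FALSE], y)

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$statistic, red$minus2_loglik - full$minus2_loglik)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_error(likelihood_ratio_test(red, full), "negative|nested")
})

test_that("the LRT statistic is invariant to affine rescaling of year", {
  cf <- scenario_preset("paper_like", n_reports = 4000, seed = 8)
  sim <- generate_reports(cf)
  rs <- filter_complete(deduplicate(sim$report_set))
  cases <- flag_cases(rs, sim$ledger$event_definition)
  spec <- model_spec(cf$drugs$drug_code)
  des <- build_design(rs, spec, cases)
  full <- fit_logistic(des$X, des$y)
  red <- fit_logistic(des$X[, setdiff(colnames(des$X), "year_c")], des$y)
  stat1 <- likelihood_ratio_test(full, red)$statistic

  des$X[, "year_c"] <- 10 * des$X[, "year_c"] + 3
  full2 <- fit_logistic(des$X, des$y)
  stat2 <- likelihood_ratio_test(full2, red)$statistic
  expect_equal(stat1, stat2, tolerance = 1e-6)
})

test_that("stepwise limits: alpha 1 keeps the full model, alpha ~0 none", {
  cf <- scenario_preset("paper_like", n_reports = 5000, seed = 12)
  sim <- generate_reports(cf)
  rs <- filter_complete(deduplicate(sim$report_set))
  cases <- flag_cases(rs, sim$ledger$event_definition)

  spec_all <- model_spec(cf$drugs$drug_code, alpha_enter = 1,
                         alpha_remove = 1)
  sel_all <- stepwise_select(rs, spec_all, cases)
  expect_setequal(sel_all$selected, sel_all$design$terms$term)

  spec_none <- model_spec(cf$drugs$drug_code, alpha_enter = 1e-300,
                          alpha_remove = 1e-300)
  sel_none <- stepwise_select(rs, spec_none, cases)
  expect_length(sel_none$selected, 0)
  expect_length(sel_none$fit$terms, 0)
})

test_that("hierarchy admits interactions only after both parents", {
  cf <- scenario_preset("paper_like", n_reports = 20000, seed = 3)
  sim <- generate_reports(cf)
  rs <- filter_complete(deduplicate(sim$report_set))
  cases <- flag_cases(rs, sim$ledger$event_definition)
  sel <- stepwise_select(rs, model_spec(cf$drugs$drug_code), cases)
  trace <- sel$trace
  des_terms <- sel$design$terms
  for (i in seq_len(nrow(trace))) {
    if (trace$action[i] != "add") next
    tm <- trace$term[i]
    meta <- des_terms[des_terms$term == tm, ]
    if (meta$type != "interaction") next
    in_before <- trace$term[seq_len(i - 1)][trace$action[seq_len(i - 1)] == "add"]
    expect_true(all(c(meta$parent1, meta$parent2) %in% in_before))
  }
  # every selected interaction's parents are still in the final model
  final <- sel$selected
  for (tm in final) {
    meta <- des_terms[des_terms$term == tm, ]
    if (meta$type == "interaction") {
      expect_true(all(c(meta$parent1, meta$parent2) %in% final))
    }
  }
})

test_that("adjusted RORs exponentiate Wald intervals and omit the intercept", {
  withr::local_seed(99)
  n <- 2000
  X <- cbind(d = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-2 + 0.8 * X[, "d"]))
  fit <- fit_logistic(X, y)
  adj <- adjusted_rors(fit)
  expect_equal(adj$term, "d")
  est <- unname(fit$coefficients["d"])
  se <- sqrt(fit$covariance["d", "d"])
  expect_equal(adj$adjusted_ror, exp(est))
  expect_equal(adj$ci_low, exp(est - 1.96 * se))
  expect_equal(adj$ci_high, exp(est + 1.96 * se))
  expect_false("(Intercept)" %in% adj$term)
})
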