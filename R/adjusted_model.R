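#' Specify the covariate-adjusted logistic model
#'
#' The adjusted analysis models case status on reporting year (continuous,
#' mean-centred), the elderly age-group indicator (age >= 60, with 0-59 as
#' the reference), sex (female = 1), one indicator per study drug, and
#' pairwise interactions of the age and sex indicators with each other and
#' with the drugs. Terms are screened by stepwise likelihood-ratio selection
#' at the stated significance levels.
#'
#' @param drugs character vector of drug codes entered as indicators.
#' @param include_year,include_age,include_sex include the corresponding main
#'   effect among the candidates.
#' @param interactions which interaction candidates to offer: `"age_sex"`
#'   offers age:sex plus age:drug and sex:drug products; `"none"` offers no
#'   interactions.
#' @param alpha_enter,alpha_remove entry/removal significance levels for the
#'   stepwise search (both 0.05 by convention).
#' @param age_cut age (years) at which the elderly indicator switches on.
#' @param hierarchy if `TRUE` (weak heredity), an interaction is eligible
#'   only while both its parents are in the model, and a parent cannot leave
#'   while its interaction stays.
#' @return a `model_spec` list.
#' @export
model_spec <- function(drugs,
                       include_year = TRUE, include_age = TRUE,
                       include_sex = TRUE,
                       interactions = c("age_sex", "none"),
                       alpha_enter = 0.05, alpha_remove = 0.05,
                       age_cut = 60, hierarchy = TRUE) {
  interactions <- match.arg(interactions)
  stopifnot(length(drugs) >= 1, alpha_enter > 0, alpha_enter <= 1,
            alpha_remove > 0, alpha_remove <= 1, age_cut > 0)
  structure(
    list(drugs = as.character(drugs), include_year = include_year,
         include_age = include_age, include_sex = include_sex,
         interactions = interactions, alpha_enter = alpha_enter,
         alpha_remove = alpha_remove, age_cut = age_cut,
         hierarchy = hierarchy),
    class = "model_spec"
  )
}

drug_term <- function(code) paste0("drug_", code)

#' Build the design matrix for the adjusted model
#'
#' Requires complete demographics (apply [filter_complete()] first). Columns:
#' `year_c` (reporting year minus its sample mean), `age60`, `female`, one
#' 0/1 column per drug (suspect roles by default), and the requested
#' interaction products. Zero-variance columns are dropped with a warning.
#'
#' @param rs a `report_set` with no missing year/age/sex.
#' @param spec a [model_spec()].
#' @param case_indicator logical case status aligned with `rs$reports`.
#' @param role_filter exposure roles counting as drug intake.
#' @return list with `X` (numeric matrix, no intercept column), `y` (0/1
#'   response), and `terms` (tibble: term, type, parent1, parent2).
#' @export
build_design <- function(rs, spec, case_indicator,
                         role_filter = c("suspect_primary",
                                         "suspect_secondary")) {
  rep_tbl <- rs$reports
  need <- c("report_year", "age_years", "sex")
  if (any(vapply(need, function(f) anyNA(rep_tbl[[f]]), logical(1)))) {
    stop("design requires complete report_year, age_years and sex; ",
         "run filter_complete() first", call. = FALSE)
  }
  stopifnot(length(case_indicator) == nrow(rep_tbl))
  y <- as.numeric(case_indicator)

  cols <- list()
  terms <- list()
  add_term <- function(name, x, type, p1 = NA, p2 = NA) {
    cols[[name]] <<- x
    terms[[name]] <<- tibble::tibble(term = name, type = type,
                                     parent1 = p1, parent2 = p2)
  }
  if (spec$include_year) {
    add_term("year_c", rep_tbl$report_year - mean(rep_tbl$report_year),
             "main")
  }
  if (spec$include_age) {
    add_term("age60", as.numeric(rep_tbl$age_years >= spec$age_cut), "main")
  }
  if (spec$include_sex) {
    add_term("female", as.numeric(rep_tbl$sex == "F"), "main")
  }
  sel <- rs$drugs$role %in% role_filter
  for (dc in spec$drugs) {
    ids <- unique(rs$drugs$primary_id[sel & rs$drugs$drug_code == dc])
    add_term(drug_term(dc), as.numeric(rep_tbl$primary_id %in% ids), "main")
  }

  if (spec$interactions == "age_sex") {
    pair <- function(p1, p2) {
      if (p1 %in% names(cols) && p2 %in% names(cols)) {
        add_term(paste0(p1, ":", p2), cols[[p1]] * cols[[p2]],
                 "interaction", p1, p2)
      }
    }
    pair("age60", "female")
    for (dc in spec$drugs) {
      pair("age60", drug_term(dc))
      pair("female", drug_term(dc))
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X, 2, function(v) length(unique(v)) < 2)
  if (any(const)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  term_tbl <- dplyr::bind_rows(terms)
  term_tbl <- term_tbl[term_tbl$term %in% colnames(X), ]
  # an interaction whose parent column vanished is no longer well-formed
  keep_int <- is.na(term_tbl$parent1) |
    (term_tbl$parent1 %in% colnames(X) & term_tbl$parent2 %in% colnames(X))
  term_tbl <- term_tbl[keep_int, ]
  X <- X[, term_tbl$term, drop = FALSE]
  list(X = X, y = y, terms = term_tbl)
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm.fit`) with an intercept always included. The covariance is
#' the inverse observed information at the optimum. Fits whose largest
#' absolute coefficient exceeds `sep_bound` are flagged as (quasi-)separated
#' and marked non-converged.
#'
#' @param X numeric design matrix (no intercept column).
#' @param y 0/1 response.
#' @param sep_bound separation guard on |coefficient|.
#' @param epsilon,maxit IRLS convergence tolerance (relative deviance
#'   change) and iteration cap.
#' @return a `logistic_fit`: `coefficients` (named, incl. `(Intercept)`),
#'   `covariance`, `minus2_loglik`, `converged`, `separated`, `n_obs`,
#'   `terms`, plus the data for downstream likelihood-ratio refits.
#' @export
fit_logistic <- function(X, y, sep_bound = 15, epsilon = 1e-12, maxit = 100) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n || ncol(X) == 0, all(y %in% c(0, 1)))
  Xi <- cbind(`(Intercept)` = rep(1, n), X)
  if (n <= ncol(Xi)) stop("more columns than observations", call. = FALSE)
  fit <- suppressWarnings(stats::glm.fit(
    Xi, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  p <- ncol(Xi)
  if (fit$rank < p) {
    aliased <- colnames(Xi)[is.na(fit$coefficients)]
    stop("singular information matrix; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- fit$coefficients
  # unscaled covariance from the weighted QR, as summary.glm does
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  dimnames(covmat) <- list(names(coefs), names(coefs))
  separated <- any(abs(coefs) > sep_bound)
  structure(
    list(
      coefficients = coefs,
      covariance = covmat,
      minus2_loglik = fit$deviance,  # saturated loglik is 0 for 0/1 response
      converged = fit$converged && !separated,
      separated = separated,
      n_obs = n,
      terms = colnames(X) %||% character(0),
      X = X, y = y,
      sep_bound = sep_bound, epsilon = epsilon, maxit = maxit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> ", length(x$terms), " term(s) + intercept, n = ",
      x$n_obs, ", -2logLik = ", format(x$minus2_loglik, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

refit_terms <- function(fit, terms) {
  fit_logistic(fit$X[, terms, drop = FALSE], fit$y,
               sep_bound = fit$sep_bound, epsilon = fit$epsilon,
               maxit = fit$maxit)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' The difference of the two models' `-2 log L` is referred to a chi-square
#' distribution with degrees of freedom equal to the difference in term
#' counts (one d.f. per single term).
#'
#' @param fit_full,fit_reduced `logistic_fit` objects on the same
#'   observations, with the reduced model's terms a subset of the full
#'   model's.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "logistic_fit"),
            inherits(fit_reduced, "logistic_fit"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("models fitted on different numbers of observations", call. = FALSE)
  }
  if (!all(fit_reduced$terms %in% fit_full$terms)) {
    stop("models are not nested", call. = FALSE)
  }
  stat <- fit_reduced$minus2_loglik - fit_full$minus2_loglik
  if (stat < -1e-6) {
    stop("negative likelihood-ratio statistic (", format(stat),
         "): models non-nested or not converged", call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- length(fit_full$terms) - length(fit_reduced$terms)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Stepwise term selection by likelihood-ratio tests
#'
#' Alternates forward and backward moves: a forward step adds the candidate
#' with the smallest likelihood-ratio p-value if it is at most
#' `alpha_enter`; a backward step removes the included term with the largest
#' p-value if it exceeds `alpha_remove`; the search stops when neither move
#' fires. Under `hierarchy`, an interaction becomes eligible only when both
#' parents are included, and a parent is not removable while one of its
#' interactions remains.
#'
#' @param rs a `report_set` with complete demographics.
#' @param spec a [model_spec()].
#' @param case_indicator logical case status aligned with `rs$reports`.
#' @param design optionally a precomputed [build_design()] result (then `rs`
#'   and `case_indicator` may be `NULL`).
#' @inheritParams build_design
#' @return list with `fit` (the final `logistic_fit`), `trace` (tibble:
#'   step, action, term, p_value), `selected` (term names) and `design`.
#' @export
stepwise_select <- function(rs, spec, case_indicator,
                            role_filter = c("suspect_primary",
                                            "suspect_secondary"),
                            design = NULL) {
  if (is.null(design)) design <- build_design(rs, spec, case_indicator,
                                              role_filter)
  X <- design$X
  y <- design$y
  terms <- design$terms
  candidates <- terms$term
  parents_of <- stats::setNames(
    lapply(seq_len(nrow(terms)), function(i)
      stats::na.omit(c(terms$parent1[i], terms$parent2[i]))),
    terms$term
  )

  cache <- new.env(parent = emptyenv())
  fit_set <- function(included) {
    key <- paste0("k:", paste(sort(included), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fit_logistic(X[, included, drop = FALSE], y)
    cache[[key]] <- f
    f
  }

  included <- character(0)
  trace <- list()
  step_no <- 0L
  max_steps <- 2L * length(candidates) + 2L
  repeat {
    changed <- FALSE
    cur <- fit_set(included)

    # forward
    eligible <- setdiff(candidates, included)
    if (spec$hierarchy) {
      eligible <- eligible[vapply(eligible, function(tm)
        all(parents_of[[tm]] %in% included), logical(1))]
    }
    if (length(eligible)) {
      ps <- vapply(eligible, function(tm) {
        likelihood_ratio_test(fit_set(c(included, tm)), cur)$p_value
      }, numeric(1))
      best <- which.min(ps)
      if (ps[best] <= spec$alpha_enter) {
        included <- c(included, eligible[best])
        step_no <- step_no + 1L
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step_no, action = "add", term = eligible[best],
          p_value = ps[best])
        changed <- TRUE
        cur <- fit_set(included)
      }
    }

    # backward
    removable <- included
    if (spec$hierarchy && length(removable)) {
      locked <- unique(unlist(parents_of[included]))
      removable <- setdiff(removable, locked)
    }
    if (length(removable)) {
      ps <- vapply(removable, function(tm) {
        likelihood_ratio_test(cur, fit_set(setdiff(included, tm)))$p_value
      }, numeric(1))
      worst <- which.max(ps)
      if (ps[worst] > spec$alpha_remove) {
        included <- setdiff(included, removable[worst])
        step_no <- step_no + 1L
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step_no, action = "remove", term = removable[worst],
          p_value = ps[worst])
        changed <- TRUE
      }
    }

    if (!changed) break
    if (step_no > max_steps) {
      stop("stepwise selection oscillated beyond ", max_steps,
           " steps; trace:\n",
           paste(utils::capture.output(print(dplyr::bind_rows(trace))),
                 collapse = "\n"), call. = FALSE)
    }
  }
  # keep the design's column order in the final model
  included <- candidates[candidates %in% included]
  list(
    fit = fit_set(included),
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), action = character(),
                     term = character(), p_value = numeric()),
    selected = included,
    design = design
  )
}

#' Adjusted reporting odds ratios from a logistic fit
#'
#' Each non-intercept coefficient is exponentiated to an adjusted ROR with a
#' Wald 95% CI (`exp(coef +- z * se)`); the per-term p-value is the
#' likelihood-ratio test of dropping that term alone.
#'
#' @param fit a converged `logistic_fit`.
#' @param z normal quantile for the CI.
#' @return tibble: term, estimate (log-odds), se, adjusted_ror, ci_low,
#'   ci_high, p_lrt.
#' @export
adjusted_rors <- function(fit, z = 1.96) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    stop("adjusted RORs require a converged fit", call. = FALSE)
  }
  terms <- fit$terms
  if (!length(terms)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          se = numeric(), adjusted_ror = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p_lrt = numeric()))
  }
  est <- fit$coefficients[terms]
  se <- sqrt(diag(fit$covariance)[terms])
  p <- vapply(terms, function(tm) {
    likelihood_ratio_test(fit, refit_terms(fit, setdiff(terms, tm)))$p_value
  }, numeric(1))
  tibble::tibble(
    term = terms,
    estimate = unname(est),
    se = unname(se),
    adjusted_ror = exp(unname(est)),
    ci_low = exp(unname(est) - z * se),
    ci_high = exp(unname(est) + z * se),
    p_lrt = unname(p)
  )
}
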