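# MAGGIC-EHR-style Cox benchmark: covariate extraction from raw records,
# chained-equation multiple imputation with a Nelson-Aalen auxiliary,
# per-imputation Cox fits (survival::coxph), Rubin's-rules pooling of
# coefficients and cloglog pooling of predictions.

MAGGIC_CONTINUOUS <- c("age", "SBP", "creatinine", "BMI")
MAGGIC_IMPUTE_STD <- c("SBP", "smoking", "BMI", "creatinine", "NYHA")
MAGGIC_IMPUTE_EXT <- c(MAGGIC_IMPUTE_STD, "sodium")

#' Default code groups for comorbidity and prescription flags
#'
#' Maps flag covariates to code prefixes (diagnosis ICD-10 categories, BNF
#' sections, procedure codes). User-supplied phenotyping dictionaries replace
#' this in real-data use.
#'
#' @return Named list of character prefix vectors.
#' @export
default_code_groups <- function() {
  list(diabetes = c("E10", "E11"), COPD = "J44", AF = "I48",
       stroke = c("I63", "I64"), MI = c("I21", "I22"),
       beta_blocker = "0204", acei_arb = "0205",
       PCI = "K49", CABG = "K40")
}

#' Extract benchmark covariates at baseline
#'
#' One row per patient: continuous variables are the mean of records in the
#' 36 months up to and including baseline; smoking and NYHA are the last
#' known status in that window; disease, prescription and procedure flags are
#' any matching record ever before (or on) baseline; `hf_ge_18_months`
#' indicates an incident HF diagnosis at least 18 months before baseline.
#' Absent values become `NA` (a missing marker, not an error).
#'
#' @param cohort A `trisk_cohort`.
#' @param index_dates Named `Date` vector (patient id -> baseline); defaults
#'   to the ground-truth index dates.
#' @param variant `"standard"` (MAGGIC-EHR) or `"extended"` (MAGGIC-EHR+,
#'   adding sodium, AF, stroke, MI, PCI, CABG).
#' @param code_groups Named list of code prefixes defining each flag; see
#'   [default_code_groups()].
#' @param window_months Averaging window for measurements (default 36).
#' @return Data frame of covariates, one row per patient with an index date.
#' @export
extract_covariates <- function(cohort, index_dates = NULL,
                               variant = c("standard", "extended"),
                               code_groups = default_code_groups(),
                               window_months = 36) {
  variant <- match.arg(variant)
  if (is.null(index_dates)) {
    gt <- cohort$ground_truth
    index_dates <- stats::setNames(gt$index_date, gt$patient_id)
  }
  pats <- cohort$patients[cohort$patients$patient_id %in% names(index_dates), ]
  enc <- cohort$encounters
  mea <- cohort$measurements
  win_days <- window_months * DAYS_PER_MONTH

  flag_names <- c("diabetes", "COPD", "beta_blocker", "acei_arb")
  if (variant == "extended") flag_names <- c(flag_names, "AF", "stroke", "MI",
                                             "PCI", "CABG")
  # MI enters the standard variant only through MAGGIC-EHR+; the standard set
  # keeps the core MAGGIC covariates.
  rows <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    bl <- as.Date(index_dates[[p$patient_id]])
    e <- enc[enc$patient_id == p$patient_id & enc$date <= bl, , drop = FALSE]
    m <- mea[mea$patient_id == p$patient_id & mea$date <= bl, , drop = FALSE]
    m_win <- m[as.numeric(bl - m$date) < win_days, , drop = FALSE]
    cont <- function(v) {
      x <- suppressWarnings(as.numeric(m_win$value[m_win$variable == v]))
      if (length(x) == 0) NA_real_ else mean(x)
    }
    last_cat <- function(v) {
      sel <- m_win[m_win$variable == v, , drop = FALSE]
      if (nrow(sel) == 0) NA_character_ else sel$value[which.max(sel$date)]
    }
    flag <- function(prefixes) {
      as.integer(any(vapply(prefixes, function(px) {
        any(startsWith(e$code, px))
      }, logical(1))))
    }
    row <- list(
      patient_id = p$patient_id,
      sex = p$sex,
      age = age_at(p$birth_year, bl),
      smoking = last_cat("smoking"),
      diabetes = flag(code_groups$diabetes),
      SBP = cont("SBP"),
      creatinine = cont("creatinine"),
      BMI = cont("BMI"),
      NYHA = last_cat("NYHA"),
      COPD = flag(code_groups$COPD),
      beta_blocker = flag(code_groups$beta_blocker),
      acei_arb = flag(code_groups$acei_arb),
      hf_ge_18_months = as.integer(months_between(p$first_hf_date, bl) >= 18),
      hf_subtype = p$hf_subtype
    )
    if (variant == "extended") {
      row$sodium <- cont("sodium")
      row$AF <- flag(code_groups$AF)
      row$stroke <- flag(code_groups$stroke)
      row$MI <- flag(code_groups$MI)
      row$PCI <- flag(code_groups$PCI)
      row$CABG <- flag(code_groups$CABG)
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out$smoking <- factor(out$smoking, levels = c("no", "ex", "yes"))
  out$NYHA <- factor(out$NYHA, levels = c("I", "II", "III", "IV"))
  out$hf_subtype <- factor(out$hf_subtype,
                           levels = c("unknown", "reduced", "preserved"))
  out
}

# ---- chained-equation imputation -------------------------------------------

# Bayesian-draw predictive mean matching with `donors` nearest candidates.
pmm_impute <- function(y, X, miss, donors = 5L) {
  obs <- !miss
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  qr_ <- qr(Xo)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(yo) - length(beta), 1)
  sigma2_hat <- sum(res^2) / df
  sigma2_star <- sigma2_hat * df / stats::rchisq(1, df)
  XtXi <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- beta + drop(crossprod(chol(XtXi), stats::rnorm(length(beta)))) *
    sqrt(sigma2_star)
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    cand <- order(d)[seq_len(min(donors, length(d)))]
    yo[sample(cand, 1)]
  }, 0)
}

# Multinomial imputation with a bootstrap of the observed rows for
# between-imputation variability.
polyreg_impute <- function(y, X, miss) {
  obs <- which(!miss)
  if (nlevels(droplevels(factor(y[obs]))) < 2) {
    # a single observed class: nothing to model
    return(rep(as.character(y[obs][1]), sum(miss)))
  }
  boot <- sample(obs, length(obs), replace = TRUE)
  if (nlevels(droplevels(factor(y[boot]))) < 2) boot <- obs
  df_fit <- data.frame(y = droplevels(factor(y[boot])), X[boot, , drop = FALSE])
  capture.output(
    fit <- nnet::multinom(y ~ ., data = df_fit, trace = FALSE, maxit = 200)
  )
  probs <- stats::predict(fit, newdata = data.frame(X[miss, , drop = FALSE]),
                          type = "probs")
  lv <- fit$lev
  if (is.null(dim(probs))) {
    probs <- if (length(lv) == 2) cbind(1 - probs, probs) else
      matrix(probs, nrow = sum(miss), ncol = length(lv), byrow = TRUE)
  }
  apply(probs, 1, function(p) sample(lv, 1, prob = pmax(p, 1e-12)))
}

#' Multiple imputation by chained equations
#'
#' Imputes SBP, smoking, BMI, creatinine and NYHA (plus sodium for the
#' extended variant) using all model variables together with the event
#' indicator and the Nelson-Aalen cumulative-hazard estimate at each
#' patient's follow-up time as predictors. Continuous variables use
#' predictive mean matching with 5 donors and a Bayesian parameter draw;
#' categorical variables use multinomial regression on a bootstrap of the
#' observed rows. `m` independent chains, 10 sweeps each.
#'
#' @param rows Covariate data frame from [extract_covariates()].
#' @param labels Data frame with `time` and `event` aligned to `rows`.
#' @param m Number of imputations (default 5).
#' @param variant `"standard"` or `"extended"`.
#' @param sweeps Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed.
#' @param donors PMM donor count.
#' @return List of `m` completed data frames.
#' @export
impute_chained <- function(rows, labels, m = 5L,
                           variant = c("standard", "extended"),
                           sweeps = 10L, seed = 1L, donors = 5L) {
  variant <- match.arg(variant)
  targets <- if (variant == "extended") MAGGIC_IMPUTE_EXT else MAGGIC_IMPUTE_STD
  targets <- intersect(targets, names(rows))
  miss_any <- vapply(targets, function(v) anyNA(rows[[v]]), TRUE)
  for (v in targets) {
    if (all(is.na(rows[[v]]))) {
      stop_config("variable '%s' is 100%% missing; exclude it before imputation", v)
    }
  }
  if (!any(miss_any)) return(replicate(m, rows, simplify = FALSE))

  na_fn <- nelson_aalen(labels$time, labels$event)
  aux <- data.frame(event = labels$event, cumhaz = na_fn(labels$time))
  cat_targets <- intersect(c("smoking", "NYHA"), targets)

  predictor_matrix <- function(d, exclude) {
    vars <- setdiff(names(d), c("patient_id", exclude))
    mm <- stats::model.matrix(~ ., data = cbind(d[vars], aux))
    mm
  }

  with_local_seed(derive_seed(seed, "mice"), {
    lapply(seq_len(m), function(im) {
      d <- rows
      # initial fill: random draws from the observed values
      for (v in targets) {
        mi <- is.na(d[[v]])
        if (any(mi)) {
          pool <- d[[v]][!mi]
          d[[v]][mi] <- sample(pool, sum(mi), replace = TRUE)
        }
      }
      for (sw in seq_len(sweeps)) {
        for (v in targets[miss_any]) {
          mi <- is.na(rows[[v]])
          X <- predictor_matrix(d, exclude = v)
          if (v %in% cat_targets) {
            d[[v]][mi] <- factor(polyreg_impute(rows[[v]], X, mi),
                                 levels = levels(rows[[v]]))
          } else {
            d[[v]][mi] <- pmm_impute(ifelse(mi, NA, rows[[v]]), X, mi, donors)
          }
        }
      }
      d
    })
  })
}

# ---- Cox fits and pooling ---------------------------------------------------

maggic_formula <- function(variant) {
  base <- paste("survival::Surv(time, event) ~ sex + age + smoking + diabetes",
                "+ SBP + creatinine + BMI + NYHA + COPD + beta_blocker",
                "+ acei_arb + hf_ge_18_months + hf_subtype",
                "+ age:hf_subtype + SBP:hf_subtype")
  if (variant == "extended") {
    base <- paste(base, "+ sodium + AF + stroke + MI + PCI + CABG")
  }
  stats::as.formula(base)
}

#' Fit the benchmark Cox model on one completed dataset
#'
#' Partial-likelihood Cox fit of the MAGGIC-EHR (or MAGGIC-EHR+) covariates
#' with age-by-subtype and SBP-by-subtype interactions, Breslow ties and
#' Breslow baseline cumulative hazard.
#'
#' @param dataset Completed covariate data frame with `time` and `event`
#'   columns (no missing values).
#' @param variant `"standard"` or `"extended"`.
#' @param formula Optional formula overriding the variant's default.
#' @return A `cox_fit`: coefficients, covariance, baseline cumulative hazard
#'   step function, and the fitted `coxph` object.
#' @export
fit_cox <- function(dataset, variant = c("standard", "extended"),
                    formula = NULL) {
  variant <- match.arg(variant)
  if (anyNA(dataset[setdiff(names(dataset), "patient_id")])) {
    stop_config("fit_cox requires a completed dataset (no missing values)")
  }
  if (sum(dataset$event) < 1) stop_config("at least one event required")
  f <- formula %||% maggic_formula(variant)
  # levels unobserved in the data would alias their dummies; imputation draws
  # only from the observed support, so dropping them is consistent across
  # imputed datasets
  fac <- vapply(dataset, is.factor, TRUE)
  dataset[fac] <- lapply(dataset[fac], droplevels)
  # a factor observed in a single class carries no contrast; drop its terms
  # (consistent across imputations, which share the observed support)
  single <- names(dataset)[fac][vapply(dataset[fac][names(dataset)[fac]],
                                       nlevels, 0L) < 2]
  if (length(single) > 0) {
    labs <- attr(stats::terms(f, data = dataset), "term.labels")
    keep <- !vapply(labs, function(lb) {
      any(vapply(single, function(v) grepl(v, lb, fixed = TRUE), TRUE))
    }, TRUE)
    f <- stats::as.formula(paste(deparse(f[[2]]), "~",
                                 paste(labs[keep], collapse = " + ")))
  }
  fit <- survival::coxph(f, data = dataset, ties = "breslow", x = FALSE,
                         model = TRUE)
  if (anyNA(stats::coef(fit))) {
    stop_config("Cox fit failed (aliased or separated terms): %s",
                paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                      collapse = ", "))
  }
  # centered = FALSE evaluates at x = 0, so the column-means caveat
  # survfit.coxph warns about does not apply
  bh <- suppressWarnings(survival::basehaz(fit, centered = FALSE))
  structure(list(coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit),
                 basehaz = bh,
                 variant = variant,
                 fit = fit),
            class = "cox_fit")
}

#' Pool Cox fits across imputations by Rubin's rules
#'
#' Pooled coefficient = mean of estimates; within-imputation variance `W` =
#' mean of the per-fit variances; between-imputation variance `B` = sample
#' variance of the estimates; total variance `W + (1 + 1/m) B`, all
#' componentwise.
#'
#' @param fits List of `cox_fit` objects with identical term order.
#' @return A `pooled_cox`: `m`, pooled coefficients, `W`, `B`, total
#'   variance, and the per-imputation fits.
#' @export
pool_rubin <- function(fits) {
  if (length(fits) < 2) stop_config("need at least 2 fits to pool")
  terms0 <- names(fits[[1]]$coefficients)
  for (f in fits) {
    if (!identical(names(f$coefficients), terms0)) {
      stop_config("mismatched model terms across imputations")
    }
  }
  m <- length(fits)
  est <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  W <- colMeans(do.call(rbind, lapply(fits, function(f) diag(f$vcov))))
  pooled <- colMeans(est)
  B <- apply(est, 2, stats::var)
  structure(list(m = m, coefficients = pooled, W = W, B = B,
                 total_variance = W + (1 + 1 / m) * B,
                 fits = fits),
            class = "pooled_cox")
}

#' @export
print.pooled_cox <- function(x, ...) {
  cat(sprintf("pooled_cox: %d imputations, %d terms\n", x$m,
              length(x$coefficients)))
  print(data.frame(estimate = x$coefficients,
                   se = sqrt(x$total_variance)))
  invisible(x)
}

#' Pool survival predictions across imputations (cloglog)
#'
#' `pooled S = exp(-exp(mean_m log(-log S_m)))` per patient. Values of exactly
#' 0 or 1 are undefined under the transform; callers clip to
#' `(eps, 1 - eps)` explicitly.
#'
#' @param S_matrix Numeric matrix, patients x imputations, entries in (0, 1).
#' @return Numeric vector of pooled survival probabilities.
#' @export
pool_predictions <- function(S_matrix) {
  S_matrix <- as.matrix(S_matrix)
  if (any(S_matrix <= 0 | S_matrix >= 1)) {
    stop_config("survival probabilities must lie strictly in (0, 1); clip first")
  }
  exp(-exp(rowMeans(log(-log(S_matrix)))))
}

# Survival probability at tau for new covariates under a cox_fit.
cox_survival_at <- function(cfit, newdata, tau) {
  tt <- stats::delete.response(stats::terms(cfit$fit))
  # factor levels unseen at fit time cannot be scored; map them to the
  # reference level
  for (v in names(cfit$fit$xlevels)) {
    x <- as.character(newdata[[v]])
    bad <- !x %in% cfit$fit$xlevels[[v]]
    if (any(bad)) {
      warning(sprintf("'%s': %d value(s) at level(s) unseen in derivation mapped to the reference level",
                      v, sum(bad)), call. = FALSE)
      x[bad] <- cfit$fit$xlevels[[v]][1]
    }
    newdata[[v]] <- factor(x, levels = cfit$fit$xlevels[[v]])
  }
  mf <- stats::model.frame(tt, data = newdata, xlev = cfit$fit$xlevels)
  X <- stats::model.matrix(tt, mf)[, -1, drop = FALSE]
  lp <- drop(X %*% cfit$coefficients)
  bh <- cfit$basehaz
  H0 <- stats::approx(c(0, bh$time), c(0, bh$hazard), xout = tau,
                      method = "constant", rule = 2)$y
  exp(-H0 * exp(lp))
}

#' Fit and apply the full multiple-imputation benchmark
#'
#' `fit_benchmark()` extracts covariates on the derivation cohort, imputes
#' `m` completed datasets, fits the Cox model on each, and pools by Rubin's
#' rules. `predict_benchmark()` imputes the validation covariates separately
#' (as in derivation), predicts survival at `tau` under each per-imputation
#' fit, and pools the predictions on the cloglog scale.
#'
#' @param cohort Derivation `trisk_cohort`.
#' @param labels Data frame `patient_id`, `time`, `event` (defaults to
#'   ground truth).
#' @param variant `"standard"` or `"extended"`.
#' @param m Number of imputations.
#' @param seed Integer seed.
#' @return `fit_benchmark`: a `benchmark_model` (pooled fits + metadata).
#' @export
fit_benchmark <- function(cohort, labels = NULL,
                          variant = c("standard", "extended"),
                          m = 5L, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(labels)) {
    gt <- cohort$ground_truth
    labels <- data.frame(patient_id = gt$patient_id, time = gt$observed_time,
                         event = gt$event)
  }
  cov <- extract_covariates(cohort, variant = variant)
  cov <- cov[match(labels$patient_id, cov$patient_id), ]
  # a variable with no observed value at all cannot be imputed or modelled;
  # exclude it (as fully-absent measures are excluded from EHR risk scores)
  targets <- if (variant == "extended") MAGGIC_IMPUTE_EXT else MAGGIC_IMPUTE_STD
  dropped <- targets[vapply(targets, function(v) all(is.na(cov[[v]])), TRUE)]
  if (length(dropped) > 0) {
    warning(sprintf("variable(s) fully missing, excluded from the benchmark: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    cov <- cov[setdiff(names(cov), dropped)]
  }
  f <- maggic_formula(variant)
  if (length(dropped) > 0) {
    labs <- attr(stats::terms(f), "term.labels")
    keep <- !vapply(labs, function(lb) {
      any(vapply(dropped, function(v) grepl(v, lb, fixed = TRUE), TRUE))
    }, TRUE)
    f <- stats::as.formula(paste(deparse(f[[2]]), "~",
                                 paste(labs[keep], collapse = " + ")))
  }
  imps <- impute_chained(cov, labels, m = m, variant = variant, seed = seed)
  fits <- lapply(imps, function(d) {
    d$time <- labels$time; d$event <- labels$event
    fit_cox(d, variant, formula = f)
  })
  pooled <- pool_rubin(fits)
  kept <- setdiff(targets, dropped)
  obs_values <- lapply(stats::setNames(kept, kept), function(v) {
    x <- cov[[v]]; x[!is.na(x)]
  })
  structure(list(pooled = pooled, variant = variant, m = m, seed = seed,
                 dropped = dropped, formula = f, obs_values = obs_values),
            class = "benchmark_model")
}

#' @rdname fit_benchmark
#' @param model A `benchmark_model`.
#' @param new_cohort Validation `trisk_cohort`.
#' @param new_labels Labels for the validation cohort (for the imputation
#'   auxiliary variables); defaults to its ground truth.
#' @param tau Horizon in months.
#' @param eps Clipping bound applied before cloglog pooling.
#' @return `predict_benchmark`: data frame `patient_id`, `risk`.
#' @export
predict_benchmark <- function(model, new_cohort, new_labels = NULL, tau = 36,
                              eps = 1e-10) {
  if (is.null(new_labels)) {
    gt <- new_cohort$ground_truth
    new_labels <- data.frame(patient_id = gt$patient_id,
                             time = gt$observed_time, event = gt$event)
  }
  cov <- extract_covariates(new_cohort, variant = model$variant)
  cov <- cov[match(new_labels$patient_id, cov$patient_id), ]
  cov <- cov[setdiff(names(cov), model$dropped)]
  # a model variable with no observed value in this cohort cannot be imputed
  # locally; draw it from the derivation cohort's observed distribution
  for (v in names(model$obs_values)) {
    if (all(is.na(cov[[v]]))) {
      warning(sprintf(
        "'%s' has no observed value in the validation cohort; drawing from the derivation distribution", v),
        call. = FALSE)
      cov[[v]] <- with_local_seed(
        derive_seed(model$seed, paste0("fill_", v)),
        sample(model$obs_values[[v]], nrow(cov), replace = TRUE))
    }
  }
  imps <- impute_chained(cov, new_labels, m = model$m, variant = model$variant,
                         seed = derive_seed(model$seed, "validation"))
  S <- vapply(seq_len(model$m), function(i) {
    pmin(pmax(cox_survival_at(model$pooled$fits[[i]], imps[[i]], tau), eps),
         1 - eps)
  }, numeric(nrow(cov)))
  data.frame(patient_id = new_labels$patient_id,
             risk = 1 - pool_predictions(S))
}
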