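#' Per-code hazard effect for the synthetic cohort generator
#'
#' Describes how one clinical code acts on the hazard of death in simulated
#' cohorts: a log hazard ratio `beta`, an optional exponential recency decay
#' (the effect halves every `half_life` months between the first recording of
#' the code and the index date), and the probability that an already-recorded
#' chronic code is re-recorded at subsequent visits.
#'
#' @param code Vocabulary string (e.g. an ICD-10 category like `"I50.0"` or a
#'   BNF section like `"0204"`).
#' @param modality One of `"diagnosis"`, `"medication"`, `"procedure"`.
#' @param beta Log hazard ratio contributed by the code (unitless).
#' @param decay `"none"` (effect constant in time) or `"exponential"`.
#' @param half_life Half-life in months of the exponential decay; required and
#'   positive when `decay == "exponential"`.
#' @param prevalence Probability that a not-yet-recorded code is recorded at a
#'   given visit.
#' @param chronic_rerecord_prob Probability that an already-recorded code is
#'   re-recorded at each subsequent visit, in `[0, 1]`.
#' @return An object of class `code_effect`.
#' @export
code_effect <- function(code, modality = c("diagnosis", "medication", "procedure"),
                        beta = 0, decay = c("none", "exponential"),
                        half_life = NULL, prevalence = 0.05,
                        chronic_rerecord_prob = 0.25) {
  modality <- match.arg(modality)
  decay <- match.arg(decay)
  if (decay == "exponential") {
    if (is.null(half_life) || !is.finite(half_life) || half_life <= 0) {
      stop_config("code_effect '%s': half_life must be > 0 when decay is exponential", code)
    }
  }
  if (chronic_rerecord_prob < 0 || chronic_rerecord_prob > 1) {
    stop_config("code_effect '%s': chronic_rerecord_prob must lie in [0, 1]", code)
  }
  if (prevalence < 0 || prevalence > 1) {
    stop_config("code_effect '%s': prevalence must lie in [0, 1]", code)
  }
  structure(
    list(code = as.character(code), modality = modality, beta = beta,
         decay = decay, half_life = half_life, prevalence = prevalence,
         chronic_rerecord_prob = chronic_rerecord_prob),
    class = "code_effect"
  )
}

#' Default code effects for the reference synthetic cohort
#'
#' Thirty codes across the three modalities. Five are causal with absolute log
#' hazard ratios between 0.5 and 1.5 (lung cancer, hepatic failure, chronic
#' kidney disease, myocardial infarction, and a protective beta-blocker
#' section); the rest are noise codes, including the comorbidity and
#' prescription codes the MAGGIC-style benchmark extracts as flags.
#'
#' @param decay_code_half_life If non-`NULL`, the lung-cancer code `C34.9` is
#'   given an exponential recency decay with this half-life (months); used by
#'   recency-structure experiments.
#' @return A list of [code_effect()] objects.
#' @export
default_code_effects <- function(decay_code_half_life = NULL) {
  dx <- function(code, beta = 0, ...) code_effect(code, "diagnosis", beta, ...)
  rx <- function(code, beta = 0, ...) code_effect(code, "medication", beta, ...)
  px <- function(code, beta = 0, ...) code_effect(code, "procedure", beta, ...)
  cancer <- if (is.null(decay_code_half_life)) {
    dx("C34.9", beta = 1.5, prevalence = 0.005)
  } else {
    dx("C34.9", beta = 1.5, prevalence = 0.005,
       decay = "exponential", half_life = decay_code_half_life)
  }
  c(
    list(
      # causal codes; per-visit first-recording probabilities chosen so
      # baseline prevalence sits in a realistic 5-35% band
      cancer,
      dx("K72.9", beta = 1.0, prevalence = 0.004),
      dx("N18.9", beta = 0.7, prevalence = 0.010),
      dx("I21.9", beta = 0.9, prevalence = 0.008),
      rx("0204", beta = -0.5, prevalence = 0.020, chronic_rerecord_prob = 0.3)
    ),
    # noise diagnoses (several map to benchmark comorbidity flags)
    lapply(c("I50.0", "E11.9", "J44.9", "I48.0", "I63.9", "I10.0", "E78.0",
             "M19.9", "K21.9", "F32.9", "J18.9", "N39.0", "H25.9", "L30.9"),
           function(cc) dx(cc, prevalence = 0.010, chronic_rerecord_prob = 0.15)),
    # noise prescriptions (BNF sections)
    lapply(c("0205", "0202", "0206", "0103", "0407", "1001", "0301"),
           function(cc) rx(cc, prevalence = 0.015, chronic_rerecord_prob = 0.3)),
    # noise procedures (OPCS-like)
    lapply(c("K49", "K40", "X29", "U05"),
           function(cc) px(cc, prevalence = 0.004, chronic_rerecord_prob = 0.02))
  )
}

#' Default measurement models
#'
#' Population mean/spread and per-patient missingness probability for the six
#' measurement variables. Missingness defaults reproduce the observed rates in
#' large UK heart-failure primary-care cohorts: BMI 26.7%, smoking 14.0%,
#' SBP 4.0%, creatinine 9.1%, NYHA 96.6%, sodium 9.7%.
#'
#' @return Named list of per-variable model descriptions.
#' @export
default_measurement_models <- function() {
  list(
    SBP = list(type = "continuous", mean = 134, sd_between = 12, sd_within = 8,
               missing_prob = 0.040),
    BMI = list(type = "continuous", mean = 27.5, sd_between = 4.5, sd_within = 1,
               missing_prob = 0.267),
    creatinine = list(type = "continuous", mean = 95, sd_between = 25, sd_within = 10,
                      missing_prob = 0.091),
    sodium = list(type = "continuous", mean = 139.5, sd_between = 2.5, sd_within = 1.5,
                  missing_prob = 0.097),
    smoking = list(type = "categorical", levels = c("no", "ex", "yes"),
                   probs = c(0.438, 0.433, 0.129), missing_prob = 0.140),
    NYHA = list(type = "categorical", levels = c("I", "II", "III", "IV"),
                probs = c(0.250, 0.471, 0.252, 0.027), missing_prob = 0.966)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defines the generative model for a longitudinal coded-EHR cohort with a
#' known hazard structure: patients enter the study at an age uniform on
#' `entry_age_range`, accrue visits as a homogeneous Poisson process at
#' `visit_rate` per patient-year, record codes per [code_effect()], and receive
#' an index date sampled uniformly over the window from first heart-failure
#' diagnosis to the end of study. From the index date, time to death is
#' exponential with rate `baseline_hazard_lambda0 * exp(eta)` per month, where
#' `eta` sums `beta * w(dt)` over the distinct codes recorded by the index
#' date (`w = 1`, or `2^(-dt / half_life)` under exponential decay, `dt` the
#' months from the code's first recording to the index date). Dropout
#' censoring is exponential with rate `dropout_rate` per month, independent of
#' `eta`; administrative censoring applies at `study_end`.
#'
#' @param n_patients Number of patients (> 0).
#' @param study_start,study_end Study period (`Date` or ISO strings).
#' @param entry_age_range Age range (years) at study entry; default 40-90.
#' @param visit_rate Expected visits per patient-year.
#' @param effects List of [code_effect()] objects.
#' @param baseline_hazard_lambda0 Baseline hazard, events per month (> 0).
#' @param dropout_rate Dropout censoring rate, per month (>= 0).
#' @param measurement_models See [default_measurement_models()].
#' @param measurement_visit_prob Probability a variable is recorded at each
#'   visit beyond the guaranteed first-visit record.
#' @param n_sites Number of synthetic practices; patients are assigned
#'   round-robin.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_patients,
                              study_start = as.Date("2010-01-01"),
                              study_end = as.Date("2020-01-01"),
                              entry_age_range = c(40, 90),
                              visit_rate = 4,
                              effects = default_code_effects(),
                              baseline_hazard_lambda0 = 0.02,
                              dropout_rate = 0.004,
                              measurement_models = default_measurement_models(),
                              measurement_visit_prob = 0.3,
                              n_sites = 20,
                              seed = 1L) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_config("n_patients must be a positive count")
  }
  if (!is.finite(baseline_hazard_lambda0) || baseline_hazard_lambda0 <= 0) {
    stop_config("baseline_hazard_lambda0 must be > 0")
  }
  if (dropout_rate < 0) stop_config("dropout_rate must be >= 0")
  if (study_start >= study_end) stop_config("study_start must precede study_end")
  if (visit_rate < 0) stop_config("visit_rate must be >= 0")
  for (e in effects) {
    if (!inherits(e, "code_effect")) stop_config("effects must be code_effect objects")
  }
  structure(
    list(n_patients = as.integer(n_patients), study_start = study_start,
         study_end = study_end, entry_age_range = entry_age_range,
         visit_rate = visit_rate, effects = effects,
         baseline_hazard_lambda0 = baseline_hazard_lambda0,
         dropout_rate = dropout_rate,
         measurement_models = measurement_models,
         measurement_visit_prob = measurement_visit_prob,
         n_sites = as.integer(n_sites), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Recency weight applied to a code's beta: dt is months from first recording
# of the code to the index date.
recency_weight <- function(effect, dt_months) {
  if (effect$decay == "none") rep(1, length(dt_months))
  else 2^(-dt_months / effect$half_life)
}

#' Simulate a longitudinal coded-EHR cohort with known hazards
#'
#' Generates patients, date-stamped coded encounters, measurement records and
#' a ground-truth table (index date, true linear predictor `eta`, true event
#' and censoring times in months from the index date). The observed follow-up
#' is the minimum of the death time, the dropout time and administrative end
#' of study; encounters after the end of follow-up are discarded.
#'
#' @param config A [simulation_config()].
#' @return A list of class `trisk_cohort` with data frames `patients`,
#'   `encounters`, `measurements`, `ground_truth` and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  effects <- config$effects
  codes <- vapply(effects, `[[`, "", "code")
  modal <- vapply(effects, `[[`, "", "modality")
  betas <- vapply(effects, `[[`, 0, "beta")
  prev <- vapply(effects, `[[`, 0, "prevalence")
  rere <- vapply(effects, `[[`, 0, "chronic_rerecord_prob")

  span_days <- as.numeric(config$study_end - config$study_start)
  span_years <- span_days / 365.25

  ids <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.46, 0.54))
  age0 <- stats::runif(n, config$entry_age_range[1], config$entry_age_range[2])
  birth_year <- as.integer(format(config$study_start, "%Y")) - as.integer(floor(age0))
  site <- sprintf("S%03d", (seq_len(n) - 1L) %% config$n_sites + 1L)
  subtype <- sample(c("unknown", "reduced", "preserved"), n, replace = TRUE,
                    prob = c(0.74, 0.215, 0.045))

  n_visits <- stats::rpois(n, config$visit_rate * span_years)

  enc_pid <- vector("list", n); enc_date <- vector("list", n)
  enc_code <- vector("list", n); enc_mod <- vector("list", n)
  visits_by_patient <- vector("list", n)
  eta <- numeric(n)
  index_date <- as.Date(rep(NA, n))
  first_hf <- as.Date(rep(NA, n))

  for (i in seq_len(n)) {
    k <- n_visits[i]
    vdays <- if (k > 0) sort(stats::runif(k, 0, span_days)) else numeric(0)
    vdates <- config$study_start + floor(vdays)
    first_hf[i] <- if (k > 0) vdates[1] else config$study_start
    # index date uniform over [first HF date, study end]
    win <- as.numeric(config$study_end - first_hf[i])
    index_date[i] <- first_hf[i] + floor(stats::runif(1, 0, win + 1))
    if (index_date[i] > config$study_end) index_date[i] <- config$study_end

    if (k > 0) {
      # occurrence matrix: visits x codes; first occurrence at rate prev,
      # re-recording afterwards at rate chronic_rerecord_prob
      u <- matrix(stats::runif(k * length(codes)), nrow = k)
      hit_first <- sweep(u, 2, prev, "<")
      seen <- apply(hit_first, 2, function(col) cummax(c(0, col[-length(col)])) > 0)
      seen <- matrix(seen, nrow = k)
      hit <- ifelse(seen, sweep(u, 2, rere, "<"), hit_first)
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        ord <- order(idx[, 1], idx[, 2])
        idx <- idx[ord, , drop = FALSE]
        enc_pid[[i]] <- rep(ids[i], nrow(idx))
        enc_date[[i]] <- vdates[idx[, 1]]
        enc_code[[i]] <- codes[idx[, 2]]
        enc_mod[[i]] <- modal[idx[, 2]]
      }
      visits_by_patient[[i]] <- vdates
      # eta from distinct codes recorded on or before the index date
      e <- 0
      if (nrow(idx) > 0) {
        pre <- idx[vdates[idx[, 1]] <= index_date[i], , drop = FALSE]
        if (nrow(pre) > 0) {
          for (j in unique(pre[, 2])) {
            first_rec <- min(vdates[pre[pre[, 2] == j, 1]])
            dt <- months_between(first_rec, index_date[i])
            e <- e + betas[j] * recency_weight(effects[[j]], dt)
          }
        }
      }
      eta[i] <- e
    } else {
      visits_by_patient[[i]] <- as.Date(character(0))
      eta[i] <- 0
    }
  }

  # survival from the index date (months)
  rate <- config$baseline_hazard_lambda0 * exp(eta)
  t_event <- stats::rexp(n, rate)
  t_drop <- if (config$dropout_rate > 0) stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  t_admin <- months_between(index_date, config$study_end)
  censor_time <- pmin(t_drop, t_admin)
  observed <- pmin(t_event, censor_time)
  event <- t_event <= censor_time

  end_fu <- index_date + round(observed * DAYS_PER_MONTH)
  death_date <- as.Date(ifelse(event, as.character(end_fu), NA))
  last_fu <- end_fu

  patients <- data.frame(
    patient_id = ids, sex = sex, birth_year = birth_year, site = site,
    registration_start = config$study_start, first_hf_date = first_hf,
    hf_subtype = subtype,
    death_date = death_date, last_followup_date = last_fu,
    stringsAsFactors = FALSE
  )

  encounters <- data.frame(
    patient_id = unlist(enc_pid) %||% character(0),
    date = as.Date(unlist(lapply(enc_date, as.character)) %||% character(0)),
    modality = unlist(enc_mod) %||% character(0),
    code = unlist(enc_code) %||% character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(encounters) > 0) {
    keep <- encounters$date <= last_fu[match(encounters$patient_id, ids)]
    encounters <- encounters[keep, , drop = FALSE]
    rownames(encounters) <- NULL
  }

  measurements <- simulate_measurements_all(ids, visits_by_patient, last_fu, config)

  ground_truth <- data.frame(
    patient_id = ids, index_date = index_date, eta = eta,
    true_event_time = t_event, censor_time = censor_time,
    observed_time = observed, event = as.integer(event),
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, encounters = encounters,
                 measurements = measurements, ground_truth = ground_truth,
                 config = config),
            class = "trisk_cohort")
}

#' @export
print.trisk_cohort <- function(x, ...) {
  cat(sprintf("trisk_cohort: %d patients, %d encounters, %d measurements, %d events\n",
              nrow(x$patients), nrow(x$encounters), nrow(x$measurements),
              sum(x$ground_truth$event)))
  invisible(x)
}

# Vectorised measurement simulation over the whole cohort.
simulate_measurements_all <- function(ids, visits_by_patient, last_fu, config) {
  mm <- config$measurement_models
  out <- list()
  for (vname in names(mm)) {
    m <- mm[[vname]]
    check_measurement_model(vname, m)
    rows_pid <- list(); rows_date <- list(); rows_val <- list()
    for (i in seq_along(ids)) {
      vd <- visits_by_patient[[i]]
      vd <- vd[vd <= last_fu[i]]
      if (length(vd) == 0) next
      if (stats::runif(1) < m$missing_prob) next  # variable withheld for patient
      take <- c(TRUE, stats::runif(length(vd) - 1) < config$measurement_visit_prob)
      vd <- vd[take]
      if (m$type == "continuous") {
        mu_i <- stats::rnorm(1, m$mean, m$sd_between)
        val <- stats::rnorm(length(vd), mu_i, m$sd_within)
        val <- formatC(val, digits = 8, format = "g")
      } else {
        lev <- sample(m$levels, 1, prob = m$probs)  # patient-level status
        val <- rep(lev, length(vd))
      }
      rows_pid[[length(rows_pid) + 1L]] <- rep(ids[i], length(vd))
      rows_date[[length(rows_date) + 1L]] <- as.character(vd)
      rows_val[[length(rows_val) + 1L]] <- val
    }
    if (length(rows_pid) > 0) {
      out[[vname]] <- data.frame(
        patient_id = unlist(rows_pid), date = as.Date(unlist(rows_date)),
        variable = vname, value = unlist(rows_val), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(0), date = as.Date(character(0)),
                      variable = character(0), value = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$date, res$variable), , drop = FALSE]
  rownames(res) <- NULL
  res
}

check_measurement_model <- function(vname, m) {
  known <- c("SBP", "BMI", "creatinine", "sodium", "smoking", "NYHA")
  if (!vname %in% known) {
    stop_config("unknown measurement variable '%s' (known: %s)", vname,
                paste(known, collapse = ", "))
  }
  if (m$missing_prob < 0 || m$missing_prob > 1) {
    stop_config("measurement '%s': missing_prob must lie in [0, 1]", vname)
  }
}

#' Simulate measurement records for one patient
#'
#' Draws measurement records at the patient's visit dates under the config's
#' measurement models: each variable is withheld entirely with its configured
#' missingness probability; otherwise it is recorded at the first visit and at
#' later visits with probability `measurement_visit_prob`, continuous values
#' around a patient-level mean.
#'
#' @param patient A list or one-row data frame with `patient_id` and
#'   `visit_dates` (a `Date` vector).
#' @param config A [simulation_config()].
#' @param seed Optional seed for this draw.
#' @return Data frame with columns `patient_id`, `date`, `variable`, `value`.
#' @export
simulate_measurements <- function(patient, config, seed = config$seed) {
  vd <- as.Date(patient$visit_dates[[1]] %||% patient$visit_dates)
  if (length(vd) == 0) stop_config("patient has no visit dates")
  pid <- as.character(patient$patient_id)
  with_local_seed(seed, simulate_measurements_all(
    pid, list(vd), max(vd), config))
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Emits `patients.csv`, `encounters.csv`, `measurements.csv`,
#' `ground_truth.csv` (all dates ISO-8601) and `sim_config.json`.
#'
#' @param cohort A `trisk_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trisk_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "encounters.csv",
                            "measurements.csv", "ground_truth.csv"))
  gt <- cohort$ground_truth
  for (cc in c("eta", "true_event_time", "censor_time", "observed_time")) {
    gt[[cc]] <- formatC(gt[[cc]], digits = 15, format = "g")
  }
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$encounters, paths[2], row.names = FALSE, na = "")
  utils::write.csv(cohort$measurements, paths[3], row.names = FALSE, na = "")
  utils::write.csv(gt, paths[4], row.names = FALSE, na = "")
  cfg <- cohort$config
  cfg_json <- list(
    n_patients = cfg$n_patients, study_start = as.character(cfg$study_start),
    study_end = as.character(cfg$study_end), entry_age_range = cfg$entry_age_range,
    visit_rate = cfg$visit_rate,
    baseline_hazard_lambda0 = cfg$baseline_hazard_lambda0,
    dropout_rate = cfg$dropout_rate, n_sites = cfg$n_sites, seed = cfg$seed,
    effects = lapply(cfg$effects, function(e) e[!vapply(e, is.null, TRUE)])
  )
  jpath <- file.path(dir, "sim_config.json")
  jsonlite::write_json(cfg_json, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jpath))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return A `trisk_cohort` (with `config = NULL` unless `sim_config.json`
#'   is present, in which case the raw parsed list is attached).
#' @export
read_cohort <- function(dir) {
  rd <- function(f, dates) {
    x <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                         colClasses = "character")
    for (cc in dates) x[[cc]] <- as.Date(ifelse(x[[cc]] == "", NA, x[[cc]]))
    x
  }
  patients <- rd("patients.csv", c("registration_start", "first_hf_date",
                                   "death_date", "last_followup_date"))
  patients$birth_year <- as.integer(patients$birth_year)
  encounters <- rd("encounters.csv", "date")
  measurements <- rd("measurements.csv", "date")
  gt <- rd("ground_truth.csv", "index_date")
  for (cc in c("eta", "true_event_time", "censor_time", "observed_time")) {
    gt[[cc]] <- as.numeric(gt[[cc]])
  }
  gt$event <- as.integer(gt$event)
  cfg <- NULL
  jpath <- file.path(dir, "sim_config.json")
  if (file.exists(jpath)) cfg <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  structure(list(patients = patients, encounters = encounters,
                 measurements = measurements, ground_truth = gt, config = cfg),
            class = "trisk_cohort")
}
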