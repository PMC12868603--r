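test_that("null-effect cohort reproduces the exponential KM median", {
  cfg <- simulation_config(n_patients = 5000, effects = list(),
                           baseline_hazard_lambda0 = 0.05, dropout_rate = 0,
                           seed = 7)
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth
  km <- survival::survfit(survival::Surv(observed_time, event) ~ 1, data = gt)
  med <- unname(summary(km)$table["median"])
  expect_lt(abs(med - log(2) / 0.05), 1.0)  # Monte-Carlo tolerance at n = 5000
  expect_true(all(gt$eta == 0))
})

test_that("zero visit rate gives empty encounter streams and eta = 0", {
  cfg <- simulation_config(n_patients = 50, visit_rate = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$encounters), 0)
  expect_true(all(co$ground_truth$eta == 0))
})

test_that("Cox fit on a single causal code covers the generating hazard ratio", {
  eff <- list(code_effect("X99.9", "diagnosis", beta = 1.0, prevalence = 0.035,
                          chronic_rerecord_prob = 0))
  cfg <- simulation_config(n_patients = 2000, effects = eff,
                           baseline_hazard_lambda0 = 0.02, dropout_rate = 0,
                           seed = 13)
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth
  idx <- stats::setNames(gt$index_date, gt$patient_id)
  enc <- co$encounters
  has <- unique(enc$patient_id[enc$date <= idx[enc$patient_id]])
  x <- as.integer(gt$patient_id %in% has)
  expect_gt(mean(x), 0.3)  # present at baseline in a sizeable fraction
  fit <- survival::coxph(survival::Surv(gt$observed_time, gt$event) ~ x)
  ci <- stats::confint(fit)
  expect_gt(1.0, ci[1]); expect_lt(1.0, ci[2])
})

test_that("the generator's eta matches recomputation from its encounters", {
  co <- simulate_cohort(simulation_config(n_patients = 120, seed = 17))
  effects <- co$config$effects
  betas <- stats::setNames(vapply(effects, `[[`, 0, "beta"),
                           vapply(effects, `[[`, "", "code"))
  gt <- co$ground_truth
  for (i in seq_len(40)) {
    pid <- gt$patient_id[i]
    e <- co$encounters[co$encounters$patient_id == pid &
                         co$encounters$date <= gt$index_date[i], ]
    eta <- sum(betas[unique(e$code)])  # default effects have no decay
    expect_equal(gt$eta[i], eta, tolerance = 1e-12)
  }
})

test_that("exponential decay downweights codes recorded longer before baseline", {
  eff <- code_effect("C34.9", "diagnosis", beta = 1.5, decay = "exponential",
                     half_life = 24)
  w <- sapply(c(0, 12, 24, 48, 120), function(dt) {
    trisk:::recency_weight(eff, dt)
  })
  expect_true(all(diff(w) < 0))
  expect_equal(w[3], 0.5)  # one half-life
  cfg <- simulation_config(
    n_patients = 150, seed = 23,
    effects = default_code_effects(decay_code_half_life = 24))
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth
  enc <- co$encounters[co$encounters$code == "C34.9", ]
  # recompute the decayed contribution for carriers
  carriers <- intersect(unique(enc$patient_id), gt$patient_id)
  betas <- stats::setNames(
    vapply(cfg$effects, `[[`, 0, "beta"),
    vapply(cfg$effects, `[[`, "", "code"))
  for (pid in utils::head(carriers, 15)) {
    i <- match(pid, gt$patient_id)
    e <- co$encounters[co$encounters$patient_id == pid &
                         co$encounters$date <= gt$index_date[i], ]
    if (!"C34.9" %in% e$code) next
    dt <- months_between(min(e$date[e$code == "C34.9"]), gt$index_date[i])
    eta <- sum(betas[setdiff(unique(e$code), "C34.9")]) +
      1.5 * 2^(-dt / 24)
    expect_equal(gt$eta[i], eta, tolerance = 1e-12)
  }
})

test_that("the generator is byte-deterministic given its config", {
  cfg <- simulation_config(n_patients = 80, seed = 31)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("measurement missingness defaults are honoured", {
  cfg <- simulation_config(n_patients = 4000, visit_rate = 3,
                           study_start = "2018-01-01", study_end = "2020-01-01",
                           seed = 37)
  co <- simulate_cohort(cfg)
  # patients with >= 1 visit: essentially all patients carrying any
  # measurement record (the chance of every variable being withheld at once
  # is ~1e-5 under the defaults)
  with_visits <- unique(co$measurements$patient_id)
  nyha <- unique(co$measurements$patient_id[co$measurements$variable == "NYHA"])
  frac_missing <- 1 - length(nyha) / length(with_visits)
  expect_lt(abs(frac_missing - 0.966), 0.02)
  smoking <- unique(co$measurements$patient_id[co$measurements$variable == "smoking"])
  expect_lt(abs(1 - length(smoking) / length(with_visits) - 0.140), 0.03)
})

test_that("per-patient measurement simulation honours missingness extremes", {
  cfg <- simulation_config(n_patients = 10, seed = 3)
  cfg$measurement_models$SBP$missing_prob <- 1.0
  pat <- list(patient_id = "P1",
              visit_dates = as.Date("2015-01-01") + c(0, 30, 60))
  m1 <- simulate_measurements(pat, cfg, seed = 11)
  expect_false("SBP" %in% m1$variable)
  cfg2 <- simulation_config(n_patients = 10, seed = 3)
  for (v in names(cfg2$measurement_models)) {
    cfg2$measurement_models[[v]]$missing_prob <- 0.0
  }
  m2 <- simulate_measurements(pat, cfg2, seed = 11)
  expect_setequal(unique(m2$variable),
                  names(cfg2$measurement_models))
})

test_that("cohorts round-trip losslessly through the CSV writer/reader", {
  co <- simulate_cohort(simulation_config(n_patients = 40, seed = 41))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$patients, co$patients)
  expect_equal(back$encounters, co$encounters)
  expect_equal(back$measurements, co$measurements)
  expect_equal(back$ground_truth[c("patient_id", "index_date", "event")],
               co$ground_truth[c("patient_id", "index_date", "event")])
  expect_equal(back$ground_truth$eta, co$ground_truth$eta, tolerance = 1e-12)
  expect_equal(back$ground_truth$observed_time, co$ground_truth$observed_time,
               tolerance = 1e-12)
  # encounter row counts survive
  expect_equal(nrow(back$encounters), nrow(co$encounters))
})

test_that("an empty cohort writes valid header-only files", {
  co <- simulate_cohort(simulation_config(n_patients = 1, visit_rate = 0,
                                          seed = 2))
  co <- subset_cohort(co, character(0))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$patients), 0)
  expect_equal(nrow(back$encounters), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(10, baseline_hazard_lambda0 = 0), "lambda0")
  expect_error(simulation_config(10, study_start = "2020-01-01",
                                 study_end = "2019-01-01"), "precede")
  expect_error(code_effect("X", "diagnosis", decay = "exponential"),
               "half_life")
  expect_error(code_effect("X", "diagnosis", chronic_rerecord_prob = 1.2),
               "chronic_rerecord_prob")
})
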