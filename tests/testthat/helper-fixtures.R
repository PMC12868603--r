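# Shared fixtures, built lazily and cached for the duration of the test run.
# Heavier objects (trained models) are reused across test files.

.fix <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Small default-condition cohort for corpus/benchmark/metrics tests.
small_cohort <- function() {
  fix("small_cohort", function() {
    simulate_cohort(simulation_config(n_patients = 300, seed = 101))
  })
}

# A tiny trained model over the small cohort; only needs to be a valid,
# finite, trained model (not a strong one).
tiny_model <- function() {
  fix("tiny_model", function() {
    co <- small_cohort()
    ds <- build_dataset(co, max_len = 32)
    cfg <- trisk_config(E = 16, n_layers = 1, n_heads = 2, max_len = 32,
                        max_epochs = 3, batch_size = 64, seed = 5,
                        head_hidden = 16)
    m <- train_trisk(ds, cfg)
    list(model = m, dataset = ds, cohort = co)
  })
}

# Hand-built three-patient cohort with exactly controlled dates, for
# covariate-extraction and labelling fixtures.
micro_cohort <- function() {
  dpm <- 30.4375
  bl <- as.Date("2015-06-01")
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    sex = c("female", "male", "female"),
    birth_year = c(1950L, 1940L, 1960L),
    site = c("S1", "S2", "S1"),
    registration_start = as.Date("2005-01-01"),
    first_hf_date = as.Date(c("2010-01-01", "2015-04-01", "2015-05-20")),
    hf_subtype = c("reduced", "unknown", "preserved"),
    death_date = as.Date(c(NA, "2016-06-01", NA)),
    last_followup_date = as.Date(c("2018-01-01", "2016-06-01", "2017-03-01")),
    stringsAsFactors = FALSE
  )
  encounters <- data.frame(
    patient_id = c("A", "A", "A", "B", "C"),
    date = c(bl - round(96 * dpm), as.Date("2015-05-01"), as.Date("2015-05-01"),
             as.Date("2015-04-01"), as.Date("2015-05-25")),
    modality = c("diagnosis", "diagnosis", "medication", "diagnosis",
                 "procedure"),
    code = c("I21.9", "E11.9", "0204", "I50.0", "K49"),
    stringsAsFactors = FALSE
  )
  measurements <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    date = c(bl - round(40 * dpm), bl - round(10 * dpm), bl - round(2 * dpm),
             as.Date("2015-04-15")),
    variable = c("SBP", "SBP", "SBP", "smoking"),
    value = c("130", "140", "150", "ex"),
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, encounters = encounters,
                 measurements = measurements, ground_truth = NULL,
                 config = NULL),
            class = "trisk_cohort")
}

# Reference study conditions: the 2000-patient default cohort (30 codes, 5
# causal), practice-split 3:1, with the reference-architecture model trained
# on the derivation side. Shared by the parameter-recovery and transfer
# checks.
accept_fixture <- function() {
  fix("accept_fixture", function() {
    co <- simulate_cohort(simulation_config(n_patients = 2000, seed = 1))
    sp <- split_by_practice(co, 0.75, seed = derive_seed(1, "split"))
    dtr <- build_dataset(sp$derivation, max_len = 64)
    dva <- build_dataset(sp$validation, vocab = dtr$vocab, max_len = 64)
    cfg <- trisk_config(E = 32, n_layers = 2, n_heads = 2, max_len = 64,
                        max_epochs = 20, seed = 1)
    model <- train_trisk(dtr, cfg)
    list(cohort = co, split = sp, train = dtr, valid = dva, config = cfg,
         model = model)
  })
}

expect_all_finite <- function(x) {
  expect_true(all(vapply(rapply(list(x), identity, how = "unlist"),
                         is.finite, TRUE)))
}
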