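test_that("ICD-10 codes truncate to level 4 with dot normalisation", {
  expect_equal(map_diagnosis_code("N29.9"), "N29.9")
  expect_equal(map_diagnosis_code("I50.19"), "I50.1")
  expect_equal(map_diagnosis_code("J12"), "J12")
  expect_equal(map_diagnosis_code("I5019"), "I50.1")  # undotted dialect
  expect_equal(map_diagnosis_code(c("E11", "E119", "E11.95")),
               c("E11", "E11.9", "E11.9"))
  expect_error(map_diagnosis_code("9X1"), "malformed.*9X1")
})

test_that("medication codes map to BNF sections, then VTM, then UNK", {
  bnf <- data.frame(source_code = c("p1", "p2"),
                    target_code = c("02050101", "04070201"))
  vtm <- data.frame(source_code = c("p3", "p1"),
                    target_code = c("VTM001", "VTM999"))
  expect_equal(map_medication_code("p1", bnf, vtm), "0205")  # BNF wins
  expect_equal(map_medication_code("p3", bnf, vtm), "VTM001")
  expect_warning(out <- map_medication_code("p9", bnf, vtm), "unmappable")
  expect_equal(out, "<UNK>")
})

test_that("vocabulary keeps exactly the codes above the prevalence threshold", {
  n <- 40
  patients <- data.frame(patient_id = sprintf("P%02d", 1:n),
                         stringsAsFactors = FALSE)
  enc <- rbind(
    data.frame(patient_id = patients$patient_id, code = "A01",
               modality = "diagnosis"),
    data.frame(patient_id = patients$patient_id, code = "B02",
               modality = "diagnosis"),
    data.frame(patient_id = patients$patient_id[1:3], code = "RARE",
               modality = "diagnosis"))
  enc$date <- as.Date("2015-01-01")
  co <- structure(list(patients = patients, encounters = enc),
                  class = "trisk_cohort")
  v <- build_vocabulary(co, min_prevalence = 0.1)  # threshold ceil(4) = 4
  expect_setequal(setdiff(v$code_levels, c("<PAD>", "<UNK>", "<PREDICT>")),
                  c("A01", "B02"))
  # boundary: exactly at threshold is kept
  v2 <- build_vocabulary(co, min_prevalence = 3 / 40)
  expect_true("RARE" %in% v2$code_levels)
  # all filtered away: specials survive
  v3 <- build_vocabulary(co, min_prevalence = 1.5)
  expect_equal(v3$code_levels, unname(trisk:::SPECIAL_TOKENS))
  expect_error(build_vocabulary(structure(list(
    patients = patients[0, , drop = FALSE], encounters = enc),
    class = "trisk_cohort")), "empty")
})

test_that("baseline selection is uniform over the eligibility window", {
  p <- list(first_hf_date = as.Date("2015-01-01"),
            death_date = as.Date(NA),
            last_followup_date = as.Date("2015-04-10"))
  set.seed(99)
  days <- replicate(10000, as.numeric(
    select_baseline(p, study_end = as.Date("2020-01-01")) -
      as.Date("2015-01-01")))
  expect_true(all(days >= 0 & days <= 99))
  cs <- suppressWarnings(stats::chisq.test(table(cut(days, breaks = 10))))
  expect_gt(cs$p.value, 0.001)
})

test_that("degenerate eligibility windows behave as specified", {
  one_day <- list(first_hf_date = as.Date("2015-01-01"),
                  death_date = as.Date(NA),
                  last_followup_date = as.Date("2015-01-01"))
  expect_equal(select_baseline(one_day, as.Date("2020-01-01"), seed = 1),
               as.Date("2015-01-01"))
  dead_same_day <- list(first_hf_date = as.Date("2015-01-01"),
                        death_date = as.Date("2015-01-01"),
                        last_followup_date = as.Date("2015-01-01"))
  expect_true(is.na(select_baseline(dead_same_day, as.Date("2020-01-01"),
                                    seed = 1)))
})

make_vocab <- function(codes) {
  n <- 12
  patients <- data.frame(patient_id = sprintf("P%02d", 1:n))
  enc <- do.call(rbind, lapply(codes, function(cc) {
    data.frame(patient_id = patients$patient_id, code = cc,
               modality = "diagnosis", date = as.Date("2015-01-01"))
  }))
  build_vocabulary(structure(list(patients = patients, encounters = enc),
                             class = "trisk_cohort"))
}

test_that("token sequences follow the visit-number and PREDICT conventions", {
  vocab <- make_vocab(c("A01", "B02", "C03"))
  patient <- data.frame(patient_id = "P1", birth_year = 1950L)
  enc <- data.frame(patient_id = "P1",
                    date = as.Date(c("2015-01-03", "2015-01-03", "2015-02-01")),
                    modality = "diagnosis",
                    code = c("A01", "B02", "C03"))
  s <- build_sequence(patient, enc, as.Date("2015-06-01"), vocab, max_len = 16)
  expect_equal(s$position_ids, c(1L, 1L, 2L, 3L))
  expect_equal(s$predict_pos, 4L)
  expect_equal(s$code_ids[4], vocab$predict_id)
  # age against July 1 of birth year: 2015-01-03 minus 1950-07-01 = 64 years
  expect_equal(s$age_ids[1], trisk:::age_to_id(vocab, 64))
  # empty history
  s0 <- build_sequence(patient, enc[0, ], as.Date("2015-06-01"), vocab, 16)
  expect_equal(s0$code_ids, vocab$predict_id)
  expect_equal(s0$predict_pos, 1L)
})

test_that("truncation keeps the most recent encounters", {
  vocab <- make_vocab("A01")
  patient <- data.frame(patient_id = "P1", birth_year = 1950L)
  enc <- data.frame(patient_id = "P1",
                    date = as.Date("2015-01-01") + (0:9) * 10,
                    modality = "diagnosis", code = "A01")
  s <- build_sequence(patient, enc, as.Date("2016-01-01"), vocab, max_len = 4)
  expect_length(s$code_ids, 4)
  expect_equal(s$dates[1:3], enc$date[8:10])
})

test_that("sequences use only pre-baseline information", {
  vocab <- make_vocab(c("A01", "B02"))
  patient <- data.frame(patient_id = "P1", birth_year = 1950L)
  enc <- data.frame(patient_id = "P1",
                    date = as.Date(c("2015-01-01", "2015-09-01")),
                    modality = "diagnosis", code = c("A01", "B02"))
  bl <- as.Date("2015-06-01")
  s1 <- build_sequence(patient, enc, bl, vocab, 16)
  enc2 <- enc; enc2$date[2] <- as.Date("2019-01-01")  # shift post-baseline
  s2 <- build_sequence(patient, enc2, bl, vocab, 16)
  expect_identical(s1[c("code_ids", "age_ids", "position_ids")],
                   s2[c("code_ids", "age_ids", "position_ids")])
  # same-date order is stable (input file order preserved)
  enc3 <- data.frame(patient_id = "P1", date = as.Date("2015-01-01"),
                     modality = "diagnosis", code = c("B02", "A01"))
  s3 <- build_sequence(patient, enc3, bl, vocab, 16)
  expect_equal(s3$codes[1:2], c("B02", "A01"))
})

test_that("survival labels resolve death, follow-up and study end correctly", {
  mk <- function(death, fu) list(death_date = as.Date(death),
                                 last_followup_date = as.Date(fu))
  bl <- as.Date("2015-01-01")
  lab <- label_example(mk("2015-11-01", "2016-01-01"), bl, as.Date("2020-01-01"))
  expect_equal(lab$event, 1L)
  expect_equal(lab$time, as.numeric(as.Date("2015-11-01") - bl) / 30.4375)
  lab2 <- label_example(mk(NA, "2017-01-01"), bl, as.Date("2017-01-01"))
  expect_equal(lab2$event, 0L)
  expect_equal(lab2$time, as.numeric(as.Date("2017-01-01") - bl) / 30.4375)
  # death after last follow-up: censored at last follow-up
  lab3 <- label_example(mk("2016-06-01", "2016-01-01"), bl, as.Date("2020-01-01"))
  expect_equal(lab3$event, 0L)
  expect_equal(lab3$time, as.numeric(as.Date("2016-01-01") - bl) / 30.4375)
  expect_error(label_example(mk(NA, "2014-01-01"), bl, as.Date("2020-01-01")),
               "non-positive")
})

test_that("practice splits are disjoint, site-coherent and deterministic", {
  co <- small_cohort()
  sp <- split_by_practice(co, 0.75, seed = 4)
  expect_length(intersect(sp$derivation$patients$patient_id,
                          sp$validation$patients$patient_id), 0)
  expect_length(intersect(unique(sp$derivation$patients$site),
                          unique(sp$validation$patients$site)), 0)
  sp2 <- split_by_practice(co, 0.75, seed = 4)
  expect_identical(sp$derivation$patients$patient_id,
                   sp2$derivation$patients$patient_id)
  # 4 sites at fraction 0.75 -> 3 derivation sites
  co4 <- co
  co4$patients$site <- rep(c("S1", "S2", "S3", "S4"),
                           length.out = nrow(co4$patients))
  sp4 <- split_by_practice(co4, 0.75, seed = 1)
  expect_length(unique(sp4$derivation$patients$site), 3)
  co1 <- co; co1$patients$site <- "S1"
  expect_error(split_by_practice(co1), "2 sites")
})
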