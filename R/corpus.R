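# Special tokens shared by all vocabularies. Ids are 1-based (R convention);
# specials occupy the first slots so code ids are dense and reproducible.
SPECIAL_TOKENS <- c(PAD = "<PAD>", UNK = "<UNK>", PREDICT = "<PREDICT>")

#' Truncate an ICD-10 diagnosis code to level 4
#'
#' Normalises dotted and undotted ICD-10 dialects and keeps the three-character
#' category plus at most one character after the decimal point (e.g.
#' `"N29.9"` stays `"N29.9"`, `"I50.19"` becomes `"I50.1"`, `"J12"` passes
#' through).
#'
#' @param raw Character vector of ICD-10 codes.
#' @return Character vector of level-4 codes, dot-normalised.
#' @export
map_diagnosis_code <- function(raw) {
  raw <- as.character(raw)
  stripped <- gsub("\\.", "", raw)
  ok <- grepl("^[A-Za-z][0-9]{2}[0-9A-Za-z]*$", stripped)
  if (any(!ok)) {
    stop_config("malformed ICD-10 code(s): %s",
                paste(unique(raw[!ok]), collapse = ", "))
  }
  base <- toupper(substr(stripped, 1, 3))
  ext <- substr(stripped, 4, 4)
  ifelse(ext == "", base, paste0(base, ".", toupper(ext)))
}

#' Map a product code to a BNF section or VTM code
#'
#' Product codes found in `bnf_map` are translated to the first four digits of
#' their BNF code (section level); codes absent from `bnf_map` but present in
#' `vtm_map` keep their virtual-therapeutic-moiety identifier unchanged;
#' anything else maps to the UNK token with a warning.
#'
#' @param raw Character vector of product codes.
#' @param bnf_map,vtm_map Data frames with columns `source_code`,
#'   `target_code` (user-supplied mapping tables).
#' @return Character vector of mapped codes.
#' @export
map_medication_code <- function(raw, bnf_map, vtm_map) {
  raw <- as.character(raw)
  out <- rep(unname(SPECIAL_TOKENS["UNK"]), length(raw))
  ib <- match(raw, bnf_map$source_code)
  hit_b <- !is.na(ib)
  out[hit_b] <- substr(bnf_map$target_code[ib[hit_b]], 1, 4)
  iv <- match(raw, vtm_map$source_code)
  hit_v <- !hit_b & !is.na(iv)
  out[hit_v] <- vtm_map$target_code[iv[hit_v]]
  unmapped <- !hit_b & !hit_v
  if (any(unmapped)) {
    warning(sprintf("%d product code(s) unmappable, assigned UNK: %s",
                    sum(unmapped),
                    paste(utils::head(unique(raw[unmapped]), 5), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Build the model vocabulary from a cohort
#'
#' Keeps exactly the codes carried by at least `ceil(min_prevalence *
#' n_patients)` distinct patients, plus the PAD/UNK/PREDICT special tokens.
#' The age channel has one id per integer year of age from `age_min` to
#' `age_max` plus UNK; the position channel covers visit numbers `1..
#' n_positions`.
#'
#' @param cohort A `trisk_cohort` (or any list with `patients` and
#'   `encounters` data frames).
#' @param min_prevalence Minimum fraction of patients carrying a code
#'   (default 0.001, i.e. 0.1%).
#' @param age_min,age_max Integer-year span of the age channel.
#' @param n_positions Number of visit-number ids.
#' @return An object of class `trisk_vocab`.
#' @export
build_vocabulary <- function(cohort, min_prevalence = 0.001,
                             age_min = 40L, age_max = 110L,
                             n_positions = 256L) {
  if (nrow(cohort$patients) == 0) stop_config("empty cohort")
  n <- nrow(cohort$patients)
  enc <- cohort$encounters
  thresh <- ceiling(min_prevalence * n)
  kept <- character(0)
  modality <- character(0)
  if (nrow(enc) > 0) {
    per_code <- unique(enc[, c("patient_id", "code", "modality")])
    counts <- table(per_code$code)
    kept <- sort(names(counts)[counts >= thresh])
    modality <- per_code$modality[match(kept, per_code$code)]
  }
  code_levels <- c(unname(SPECIAL_TOKENS), kept)
  structure(
    list(code_levels = code_levels,
         code_ids = stats::setNames(seq_along(code_levels), code_levels),
         code_modality = stats::setNames(modality, kept),
         pad_id = 1L, unk_id = 2L, predict_id = 3L,
         age_min = as.integer(age_min), age_max = as.integer(age_max),
         n_ages = as.integer(age_max - age_min + 2L),  # + UNK slot
         n_positions = as.integer(n_positions),
         min_prevalence = min_prevalence),
    class = "trisk_vocab"
  )
}

#' @export
print.trisk_vocab <- function(x, ...) {
  cat(sprintf("trisk_vocab: %d codes (+%d specials), ages %d-%d, %d positions\n",
              length(x$code_levels) - 3L, 3L, x$age_min, x$age_max, x$n_positions))
  invisible(x)
}

n_code_ids <- function(vocab) length(vocab$code_levels)

code_to_id <- function(vocab, code) {
  id <- unname(vocab$code_ids[code])
  id[is.na(id)] <- vocab$unk_id
  id
}

# Integer-year age to channel id; 1 is the UNK age slot.
age_to_id <- function(vocab, years) {
  y <- floor(years)
  ifelse(is.na(y) | y < vocab$age_min | y > vocab$age_max,
         1L, as.integer(y - vocab$age_min + 2L))
}

# Assumed birth date: July 1 of the stated birth year.
birth_date <- function(birth_year) as.Date(sprintf("%d-07-01", birth_year))

age_at <- function(birth_year, date) {
  as.numeric(as.Date(date) - birth_date(birth_year)) / 365.25
}

#' Select a baseline (index) date uniformly over the eligibility window
#'
#' The window runs from the first heart-failure diagnosis to the earliest of
#' death, loss to follow-up, and the end of study; a calendar day is sampled
#' uniformly from it. A patient who dies on the diagnosis day has no
#' post-diagnosis follow-up and is excluded (returns `NA`). The baseline is
#' always strictly before the death date so follow-up time is positive.
#'
#' @param patient One-row data frame (or list) with `first_hf_date`,
#'   `death_date`, `last_followup_date`.
#' @param study_end End of the study period.
#' @param seed Optional seed for the draw.
#' @return A `Date`, or `NA` if the patient cannot contribute an index date.
#' @export
select_baseline <- function(patient, study_end, seed = NULL) {
  first_hf <- as.Date(patient$first_hf_date)
  death <- as.Date(patient$death_date)
  last_fu <- as.Date(patient$last_followup_date)
  upper <- min(c(last_fu, as.Date(study_end), if (!is.na(death)) death - 1),
               na.rm = TRUE)
  if (is.na(first_hf) || upper < first_hf) return(as.Date(NA))
  draw <- function() first_hf + floor(stats::runif(1, 0, as.numeric(upper - first_hf) + 1))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Build the token sequence for one patient at a baseline date
#'
#' Encounters dated on or before the baseline (configurable) are sorted by
#' date (stable for ties, preserving input order), mapped to code ids, and
#' annotated with integer age at the encounter (birth assumed July 1 of the
#' birth year) and a visit-number position id (all encounters sharing a date
#' share a visit number). A terminal PREDICT token carries the age at baseline
#' and the next visit number. If the history exceeds `max_len - 1` tokens the
#' most recent are kept and visit numbers are renumbered from 1 within the
#' retained window.
#'
#' @param patient One-row data frame with `patient_id`, `birth_year`.
#' @param encounters Data frame of the patient's encounters (`date`, `code`,
#'   `modality`).
#' @param baseline Baseline `Date`.
#' @param vocab A `trisk_vocab`.
#' @param max_len Maximum sequence length including the PREDICT token.
#' @param include_baseline_day Include encounters dated exactly on the
#'   baseline day (default `TRUE`).
#' @return An object of class `trisk_sequence`: integer vectors `code_ids`,
#'   `age_ids`, `position_ids`, `attention_mask` (all length `<= max_len`),
#'   plus `codes`, `dates` and `predict_pos`.
#' @export
build_sequence <- function(patient, encounters, baseline, vocab, max_len = 256L,
                           include_baseline_day = TRUE) {
  baseline <- as.Date(baseline)
  enc <- encounters[encounters$patient_id == patient$patient_id, , drop = FALSE]
  keep <- if (include_baseline_day) enc$date <= baseline else enc$date < baseline
  enc <- enc[keep, , drop = FALSE]
  ord <- order(enc$date)  # stable: ties keep input file order
  enc <- enc[ord, , drop = FALSE]

  if (nrow(enc) > max_len - 1L) {
    enc <- enc[(nrow(enc) - (max_len - 2L)):nrow(enc), , drop = FALSE]
  }
  n_hist <- nrow(enc)
  if (n_hist > 0) {
    visit <- cumsum(!duplicated(enc$date))
    code_ids <- code_to_id(vocab, enc$code)
    age_ids <- age_to_id(vocab, age_at(patient$birth_year, enc$date))
    next_visit <- visit[n_hist] + 1L
  } else {
    visit <- integer(0); code_ids <- integer(0); age_ids <- integer(0)
    next_visit <- 1L
  }
  structure(
    list(code_ids = c(code_ids, vocab$predict_id),
         age_ids = c(age_ids, age_to_id(vocab, age_at(patient$birth_year, baseline))),
         position_ids = pmin(c(visit, next_visit), vocab$n_positions),
         attention_mask = rep(1L, n_hist + 1L),
         codes = c(enc$code, unname(SPECIAL_TOKENS["PREDICT"])),
         modalities = c(enc$modality, "special"),
         dates = c(enc$date, baseline),
         predict_pos = n_hist + 1L,
         patient_id = patient$patient_id,
         baseline = baseline),
    class = "trisk_sequence"
  )
}

#' Pad a token sequence to a fixed length
#'
#' Appends PAD tokens (attention mask 0) after the PREDICT token.
#'
#' @param seq A `trisk_sequence`.
#' @param max_len Target length.
#' @return A `trisk_sequence` of length `max_len`.
#' @export
pad_sequence <- function(seq, max_len) {
  n <- length(seq$code_ids)
  if (n > max_len) stop_config("sequence longer than max_len")
  k <- max_len - n
  seq$code_ids <- c(seq$code_ids, rep(1L, k))
  seq$age_ids <- c(seq$age_ids, rep(1L, k))
  seq$position_ids <- c(seq$position_ids, rep(1L, k))
  seq$attention_mask <- c(seq$attention_mask, rep(0L, k))
  seq
}

#' Survival label at a baseline date
#'
#' Event (death) with time in months from baseline if the death falls within
#' follow-up and before the end of study; otherwise censored at the earlier of
#' last follow-up and study end. Months are days / 30.4375.
#'
#' @param patient One-row data frame with `death_date`, `last_followup_date`.
#' @param baseline Baseline `Date`.
#' @param study_end End of study.
#' @return List with `time` (months, > 0) and `event` (0/1).
#' @export
label_example <- function(patient, baseline, study_end) {
  baseline <- as.Date(baseline)
  death <- as.Date(patient$death_date)
  censor_at <- min(as.Date(patient$last_followup_date), as.Date(study_end))
  if (!is.na(death) && death <= censor_at) {
    tt <- months_between(baseline, death); ev <- 1L
  } else {
    tt <- months_between(baseline, censor_at); ev <- 0L
  }
  if (tt <= 0) stop_config("non-positive follow-up time at baseline %s", baseline)
  list(time = tt, event = ev)
}

#' Split a cohort by practice (site)
#'
#' Randomly assigns whole sites to the derivation or validation side so no
#' patient's practice appears in both.
#'
#' @param cohort A `trisk_cohort` whose `patients` carry a `site` column.
#' @param fraction Fraction of sites assigned to derivation (default 0.75).
#' @param seed Seed for the site shuffle.
#' @return List with `derivation` and `validation` cohorts.
#' @export
split_by_practice <- function(cohort, fraction = 0.75, seed = 1L) {
  sites <- unique(cohort$patients$site)
  if (length(sites) < 2) stop_config("need at least 2 sites to split")
  n_der <- min(max(round(fraction * length(sites)), 1L), length(sites) - 1L)
  der_sites <- with_local_seed(seed, sample(sites, n_der))
  der_ids <- cohort$patients$patient_id[cohort$patients$site %in% der_sites]
  list(derivation = subset_cohort(cohort, der_ids),
       validation = subset_cohort(cohort, setdiff(cohort$patients$patient_id, der_ids)))
}

#' Subset a cohort to a set of patients
#' @param cohort A `trisk_cohort`.
#' @param patient_ids Character vector of patient ids to keep.
#' @return A `trisk_cohort` restricted to those patients.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  f <- function(df) {
    out <- df[df$patient_id %in% patient_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(list(patients = f(cohort$patients), encounters = f(cohort$encounters),
                 measurements = f(cohort$measurements),
                 ground_truth = if (!is.null(cohort$ground_truth)) f(cohort$ground_truth) else NULL,
                 config = cohort$config),
            class = "trisk_cohort")
}

#' Build a modelling dataset (sequences + labels) from a cohort
#'
#' Uses each patient's stored index date (from the generator's ground truth)
#' or freshly sampled baselines, builds token sequences against a vocabulary,
#' and computes survival labels against the end of study.
#'
#' @param cohort A `trisk_cohort`.
#' @param vocab A `trisk_vocab`, or `NULL` to build one from this cohort.
#' @param max_len Maximum sequence length.
#' @param study_end End of study; defaults to the config's `study_end`.
#' @param index_dates Optional named vector/data frame of baselines; defaults
#'   to `ground_truth$index_date`.
#' @return List of class `trisk_dataset`: `sequences` (list of
#'   `trisk_sequence`), `labels` (data frame `patient_id`, `time`, `event`),
#'   and `vocab`.
#' @export
build_dataset <- function(cohort, vocab = NULL, max_len = 64L,
                          study_end = NULL, index_dates = NULL) {
  if (is.null(study_end)) {
    study_end <- as.Date(cohort$config$study_end %||%
                           max(cohort$patients$last_followup_date))
  }
  if (is.null(vocab)) vocab <- build_vocabulary(cohort)
  if (is.null(index_dates)) {
    gt <- cohort$ground_truth
    index_dates <- stats::setNames(gt$index_date, gt$patient_id)
  }
  pats <- cohort$patients
  enc_split <- split(cohort$encounters,
                     factor(cohort$encounters$patient_id, levels = pats$patient_id))
  seqs <- vector("list", nrow(pats))
  times <- numeric(nrow(pats)); events <- integer(nrow(pats))
  keep <- logical(nrow(pats))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    bl <- as.Date(index_dates[[p$patient_id]])
    if (is.na(bl)) next
    lab <- tryCatch(label_example(p, bl, study_end), error = function(e) NULL)
    if (is.null(lab)) next
    seqs[[i]] <- build_sequence(p, enc_split[[p$patient_id]] %||% cohort$encounters[0, ],
                                bl, vocab, max_len)
    times[i] <- lab$time; events[i] <- lab$event; keep[i] <- TRUE
  }
  structure(list(sequences = seqs[keep],
                 labels = data.frame(patient_id = pats$patient_id[keep],
                                     time = times[keep], event = events[keep],
                                     stringsAsFactors = FALSE),
                 vocab = vocab),
            class = "trisk_dataset")
}

#' @export
print.trisk_dataset <- function(x, ...) {
  cat(sprintf("trisk_dataset: %d examples, %d events, vocab %d codes\n",
              nrow(x$labels), sum(x$labels$event), n_code_ids(x$vocab) - 3L))
  invisible(x)
}
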