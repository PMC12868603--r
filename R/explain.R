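# Integrated-gradients attribution of the horizon risk F(tau) = 1 - S(tau) to
# individual encounter tokens, taken at the embedding layer. The reference is
# the same-length sequence with every code-channel embedding replaced by the
# PAD embedding, ages/positions/mask preserved: the model's native "absence"
# of clinical content.

# Forward to the representation with an explicit code-channel matrix.
rep_forward_channels <- function(params, ch, predict_pos, config) {
  em <- embed_forward(params, ch, config$embedding_mode)
  en <- encoder_forward(params, em$H0, config)
  list(rep = en$H[predict_pos, ], em = em, en = en)
}

# Gradient of F(tau) w.r.t. the code-channel input embeddings (L x E) at the
# given channel values.
grad_F_wrt_code <- function(params, ch, predict_pos, config, tau) {
  fw <- rep_forward_channels(params, ch, predict_pos, config)
  g <- simpson_grid(tau, config$ode_step)
  reps <- matrix(fw$rep, length(g$s), length(fw$rep), byrow = TRUE)
  hf <- head_forward(params$head, reps, g$s, config$t_scale)
  Lam <- sum(g$w * hf$lambda)
  S <- exp(-Lam)
  hb <- head_backward(params$head, hf, g$w * S)  # dF/dlam_k = S * w_k
  d_rep <- colSums(hb$d_rep)
  L <- nrow(ch$code)
  dH <- matrix(0, L, config$E)
  dH[predict_pos, ] <- d_rep
  acc <- new_grad_acc(params)
  dH0 <- encoder_backward(params, fw$en$caches, dH, config, acc)
  eb <- embed_backward(params, fw$em, dH0, config$embedding_mode)
  list(grad = eb$d_code, F_value = 1 - S)
}

model_F <- function(model, ch, predict_pos, tau) {
  fw <- rep_forward_channels(model$params, ch, predict_pos, model$config)
  g <- simpson_grid(tau, model$config$ode_step)
  reps <- matrix(fw$rep, length(g$s), length(fw$rep), byrow = TRUE)
  hf <- head_forward(model$params$head, reps, g$s, model$config$t_scale)
  1 - exp(-sum(g$w * hf$lambda))
}

#' Integrated-gradients token attributions
#'
#' For each token, the attribution of the horizon risk `F(tau)` is
#' `(e - e') . mean_{k=1..steps} dF/de` evaluated at
#' `e' + (k/steps)(e - e')`, where `e` is the token's code-channel embedding
#' and `e'` the PAD embedding (ages, positions and mask preserved). Summing
#' token scores approximates `F(x) - F(reference)` (completeness); padded
#' positions score exactly 0.
#'
#' @param model A trained `trisk_model`.
#' @param seq A `trisk_sequence`.
#' @param tau Horizon in months.
#' @param steps Number of path steps (default 128).
#' @return List: `scores` (per token), `F_x`, `F_reference`, and
#'   `completeness_gap` = `|sum(scores) - (F_x - F_reference)|`.
#' @export
integrated_gradients <- function(model, seq, tau = model$config$horizon,
                                 steps = 128L) {
  params <- model$params
  if (any(!vapply(list(params$Ec, params$W), function(m) all(is.finite(m)), TRUE))) {
    stop_config("model parameters are not finite")
  }
  config <- model$config
  ch_x <- gather_channels(params, seq)
  e_ref <- params$Ec[rep(1L, length(seq$code_ids)), , drop = FALSE]  # PAD rows
  diff <- ch_x$code - e_ref
  gsum <- matrix(0, nrow(diff), ncol(diff))
  for (k in seq_len(steps)) {
    ch_k <- ch_x
    ch_k$code <- e_ref + (k / steps) * diff
    gsum <- gsum + grad_F_wrt_code(params, ch_k, seq$predict_pos, config, tau)$grad
  }
  scores <- rowSums(diff * gsum / steps)
  F_x <- model_F(model, ch_x, seq$predict_pos, tau)
  ch_r <- ch_x; ch_r$code <- e_ref
  F_ref <- model_F(model, ch_r, seq$predict_pos, tau)
  list(scores = scores, F_x = F_x, F_reference = F_ref,
       completeness_gap = abs(sum(scores) - (F_x - F_ref)))
}

#' Per-patient code attribution
#'
#' Collapses token scores to one score per distinct code: the maximum over the
#' code's occurrences. Special tokens (PAD/UNK/PREDICT) never appear.
#'
#' @param token_scores Numeric vector aligned to the sequence's tokens.
#' @param seq The `trisk_sequence` the scores belong to.
#' @return Named numeric vector, one entry per distinct code.
#' @export
per_patient_code_attribution <- function(token_scores, seq) {
  keep <- !(seq$codes %in% SPECIAL_TOKENS) & seq$modalities != "special"
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  tapply(token_scores[keep], seq$codes[keep], max)
}

#' Attribution records for a cohort
#'
#' Runs integrated gradients for every patient and emits one row per patient
#' and distinct code: the max-over-occurrences score, the age at the code's
#' first recording in the sequence, and months from that first recording to
#' baseline.
#'
#' @param model A trained `trisk_model`.
#' @param dataset A `trisk_dataset`.
#' @param cohort The source `trisk_cohort` (for sex).
#' @param tau Horizon in months.
#' @param steps IG path steps (population summaries tolerate coarser paths
#'   than completeness checks; default 32).
#' @return Data frame of attribution records.
#' @export
cohort_attributions <- function(model, dataset, cohort = NULL,
                                tau = model$config$horizon, steps = 32L) {
  sex_of <- NULL
  if (!is.null(cohort)) {
    sex_of <- stats::setNames(cohort$patients$sex, cohort$patients$patient_id)
  }
  out <- vector("list", length(dataset$sequences))
  for (i in seq_along(dataset$sequences)) {
    sq <- dataset$sequences[[i]]
    if (sq$predict_pos == 1L) next  # empty history: nothing to attribute
    ig <- integrated_gradients(model, sq, tau, steps)
    per_code <- per_patient_code_attribution(ig$scores, sq)
    if (length(per_code) == 0) next
    keep <- !(sq$codes %in% SPECIAL_TOKENS)
    first_ix <- vapply(names(per_code), function(cd) {
      which(keep & sq$codes == cd)[1]
    }, 0L)
    age_ids <- sq$age_ids[first_ix]
    first_age <- ifelse(age_ids == 1L, NA_real_,
                        model$vocab$age_min + age_ids - 2)
    out[[i]] <- data.frame(
      patient_id = sq$patient_id,
      code = names(per_code),
      modality = sq$modalities[first_ix],
      score = as.numeric(per_code),
      first_recording_age = first_age,
      months_before_baseline = months_between(sq$dates[first_ix], sq$baseline),
      sex = if (is.null(sex_of)) NA_character_ else
        unname(sex_of[sq$patient_id]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-level attribution summary
#'
#' Per code appearing in at least `min_prevalence` of patients: the mean of
#' per-patient scores with a normal-approximation 95% CI, ranked descending
#' by mean contribution.
#'
#' @param records Attribution records from [cohort_attributions()].
#' @param n_patients Number of patients in the attributed population (the
#'   prevalence denominator); defaults to the number of distinct patients in
#'   `records`.
#' @param min_prevalence Prevalence filter (default 0.01, i.e. 1%).
#' @return Data frame: `code`, `mean`, `ci_low`, `ci_high`, `n_patients`,
#'   `prevalence`, ranked by mean.
#' @export
population_summary <- function(records, n_patients = NULL,
                               min_prevalence = 0.01) {
  if (is.null(n_patients)) n_patients <- length(unique(records$patient_id))
  sp <- split(records$score, records$code)
  rows <- lapply(names(sp), function(cd) {
    x <- sp[[cd]]
    n <- length(x)
    prev <- n / n_patients
    if (prev < min_prevalence) return(NULL)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
    data.frame(code = cd, mean = mean(x),
               ci_low = mean(x) - 1.96 * se, ci_high = mean(x) + 1.96 * se,
               n_patients = n, prevalence = prev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop_config("no code passes the prevalence filter")
  }
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ATTRIB_TIME_BANDS <- c("<1y", "1-5y", "5-10y", ">10y")
ATTRIB_AGE_BANDS <- c("50-59", "60-69", "70-79", ">=80")

attribution_stratum <- function(records, strata) {
  switch(strata,
    sex = records$sex,
    age = {
      a <- records$first_recording_age
      cut(a, breaks = c(50, 60, 70, 80, Inf), right = FALSE,
          labels = ATTRIB_AGE_BANDS)
    },
    time = {
      m <- records$months_before_baseline
      cut(m, breaks = c(-Inf, 12, 60, 120, Inf),
          labels = ATTRIB_TIME_BANDS)
    },
    stop_config("unknown strata '%s'", strata)
  )
}

#' Stratified attribution summary
#'
#' [population_summary()] within strata defined by sex, by age at the code's
#' first recording (50-59, 60-69, 70-79, >=80 years), or by time from the
#' first recording to baseline (<1y, 1-5y, 5-10y, >10y).
#'
#' @param records Attribution records from [cohort_attributions()].
#' @param strata `"sex"`, `"age"` or `"time"`.
#' @param n_patients Prevalence denominator per stratum; defaults to distinct
#'   patients within the stratum.
#' @param min_prevalence Prevalence filter within each stratum.
#' @return Data frame of per-stratum code summaries with a `stratum` column.
#' @export
stratified_summary <- function(records, strata = c("time", "age", "sex"),
                               n_patients = NULL, min_prevalence = 0.01) {
  strata <- match.arg(strata)
  g <- attribution_stratum(records, strata)
  out <- lapply(levels(factor(g)), function(lv) {
    sel <- records[which(g == lv), , drop = FALSE]
    if (nrow(sel) == 0) {
      warning(sprintf("stratum '%s' is empty; skipped", lv), call. = FALSE)
      return(NULL)
    }
    s <- tryCatch(
      population_summary(sel, n_patients = n_patients,
                         min_prevalence = min_prevalence),
      error = function(e) NULL)
    if (is.null(s)) return(NULL)
    cbind(stratum = lv, s, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
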