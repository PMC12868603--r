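# Training engine: fused forward/backward over a minibatch through the
# embedding combiner, the attention encoder, the hazard head and the Simpson
# quadrature of the cumulative hazard, with the censored NLL + alpha * XCal
# objective.

# Forward (and optionally backward) over a set of examples. Returns the loss
# components; with want_grads, also a grads tree matching params.
batch_loss_grads <- function(params, seqs, times, events, config,
                             want_grads = TRUE) {
  n <- length(seqs)
  fws <- lapply(seqs, function(s) rep_forward(params, s, config))
  E <- config$E
  reps <- do.call(rbind, lapply(fws, `[[`, "rep"))

  grids <- lapply(times, simpson_grid, step = config$ode_step)
  counts <- vapply(grids, function(g) length(g$s), 0L)
  idx <- rep(seq_len(n), counts)
  s_rows <- unlist(lapply(grids, `[[`, "s"))
  w_rows <- unlist(lapply(grids, `[[`, "w"))
  rep_rows <- reps[idx, , drop = FALSE]

  hf <- head_forward(params$head, rep_rows, s_rows, config$t_scale)
  lam <- hf$lambda
  Lam <- as.numeric(rowsum(w_rows * lam, idx))
  ends <- cumsum(counts)
  lam_end <- lam[ends]
  S <- exp(-Lam)
  F_val <- pmin(pmax(1 - S, 0), 1)

  nll <- mean(-events * log(lam_end) + Lam)
  alpha <- config$xcal_weight
  if (alpha > 0) {
    xc <- xcal_loss(F_val, events, config$xcal_bins, config$xcal_temperature,
                    grad = want_grads)
    pen <- if (want_grads) xc$penalty else xc
  } else {
    pen <- 0
  }
  total <- nll + alpha * pen
  out <- list(total = total, nll = nll, xcal = pen, F_values = F_val,
              surv = S, lambda_end = lam_end)
  if (!want_grads) return(out)

  dLam <- rep(1 / n, n)
  if (alpha > 0) dLam <- dLam + alpha * xc$grad * S
  dlam <- w_rows * dLam[idx]
  dlam[ends] <- dlam[ends] - events / (n * lam_end)

  hb <- head_backward(params$head, hf, dlam)
  acc <- new_grad_acc(params)
  acc$head$W1 <- hb$gW1; acc$head$b1 <- hb$gb1
  acc$head$w2 <- hb$gw2; acc$head$b2 <- hb$gb2
  d_reps <- rowsum(hb$d_rep, idx)
  for (i in seq_len(n)) {
    rep_backward(params, seqs[[i]], fws[[i]], d_reps[i, ], config, acc)
  }
  out$grads <- acc_to_grads(acc, params)
  out
}

eval_loss <- function(params, seqs, times, events, config) {
  batch_loss_grads(params, seqs, times, events, config, want_grads = FALSE)$total
}

#' Train the transformer-ODE survival model
#'
#' Minimises the censored negative log-likelihood plus `xcal_weight` times the
#' XCal D-calibration penalty by minibatch Adam. A fraction `eval_fraction`
#' (default 5%) of the dataset is held out for end-of-epoch testing; the
#' returned model carries the checkpoint with the best end-of-epoch loss.
#' Fully deterministic given `config$seed`.
#'
#' @param dataset A `trisk_dataset` from [build_dataset()].
#' @param config A [trisk_config()].
#' @param init_params Optional initial parameters (used by [fine_tune()]).
#' @param verbose Print per-epoch losses.
#' @return An object of class `trisk_model`: `params`, `config`, `vocab`,
#'   and a `history` data frame (epoch, train loss, end-of-epoch loss).
#' @export
train_trisk <- function(dataset, config, init_params = NULL, verbose = FALSE) {
  seqs <- dataset$sequences
  labels <- dataset$labels
  n <- length(seqs)
  n_eval <- max(1L, round(config$eval_fraction * n))
  if (n - n_eval < 2 || n_eval < 1) stop_config("dataset too small to split")
  eval_ix <- with_local_seed(derive_seed(config$seed, "split"),
                             sample(n, n_eval))
  tr_ix <- setdiff(seq_len(n), eval_ix)

  params <- init_params %||%
    init_trisk_params(config, dataset$vocab, derive_seed(config$seed, "init"))
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     eval_loss = numeric(0))
  wait <- 0L

  if (config$max_epochs == 0) {
    return(structure(list(params = params, config = config,
                          vocab = dataset$vocab, history = hist,
                          best_epoch = 0L),
                     class = "trisk_model"))
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_local_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                           sample(tr_ix))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      res <- batch_loss_grads(params, seqs[bi], labels$time[bi],
                              labels$event[bi], config)
      if (!is.finite(res$total)) stop_config("training diverged (non-finite loss)")
      st <- adam_step(params, res$grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
      tl <- tl + res$total * length(bi)
    }
    tl <- tl / length(ord)
    el <- eval_loss(params, seqs[eval_ix], labels$time[eval_ix],
                    labels$event[eval_ix], config)
    if (!is.finite(el)) stop_config("training diverged (non-finite eval loss)")
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl, eval_loss = el))
    if (verbose) message(sprintf("epoch %d train %.4f eval %.4f", epoch, tl, el))
    if (el < best$loss) {
      best <- list(loss = el, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, vocab = dataset$vocab,
                 history = hist, best_epoch = best$epoch),
            class = "trisk_model")
}

#' @export
print.trisk_model <- function(x, ...) {
  cat(sprintf("trisk_model: E=%d, %d layers, %d heads, mode=%s, %d epochs (best %d)\n",
              x$config$E, x$config$n_layers, x$config$n_heads,
              x$config$embedding_mode, nrow(x$history), x$best_epoch))
  invisible(x)
}

# Copy embeddings of codes shared between vocabularies; initialise rows for
# new codes freshly (seeded). Encoder, projection and head transfer as-is.
transfer_params <- function(params, vocab_old, vocab_new, config, seed = 1L) {
  new_params <- params
  new_params$Ec <- with_local_seed(derive_seed(seed, "transfer"),
                                   rnorm_mat(n_code_ids(vocab_new), config$E))
  shared <- intersect(vocab_old$code_levels, vocab_new$code_levels)
  new_params$Ec[vocab_new$code_ids[shared], ] <-
    params$Ec[vocab_old$code_ids[shared], , drop = FALSE]
  if (vocab_old$n_ages != vocab_new$n_ages ||
      vocab_old$n_positions != vocab_new$n_positions) {
    stop_config("age/position channel schemes differ between vocabularies")
  }
  new_params
}

#' Fine-tune a trained model on a new cohort
#'
#' Transfers the pretrained weights: embeddings of codes shared between the
#' old and new vocabularies are copied, embeddings of new codes are freshly
#' initialised, and all weights are then updated on the new dataset with a
#' 10% end-of-epoch held-out split (configurable).
#'
#' @param pretrained A `trisk_model`.
#' @param new_dataset A `trisk_dataset` built against the new vocabulary.
#' @param config Training configuration; architecture fields must match the
#'   pretrained model. `eval_fraction` defaults to 0.10 for fine-tuning.
#' @return A `trisk_model` trained on the new cohort.
#' @export
fine_tune <- function(pretrained, new_dataset, config = NULL) {
  old_cfg <- pretrained$config
  if (is.null(config)) {
    config <- old_cfg
    config$eval_fraction <- 0.10
  }
  for (f in c("E", "n_layers", "n_heads", "embedding_mode", "head_hidden",
              "ffn_mult")) {
    if (!identical(config[[f]], old_cfg[[f]])) {
      stop_config("incompatible architecture: field '%s' differs", f)
    }
  }
  init <- transfer_params(pretrained$params, pretrained$vocab,
                          new_dataset$vocab, config,
                          seed = derive_seed(config$seed, "finetune"))
  train_trisk(new_dataset, config, init_params = init)
}

#' Predicted risk at a horizon
#'
#' `risk = 1 - S(tau)` per patient, with `S` the model's survival curve.
#'
#' @param model A `trisk_model`.
#' @param sequences List of `trisk_sequence` objects.
#' @param tau Horizon in months (default the config's `horizon`).
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(model, sequences, tau = model$config$horizon) {
  1 - predict_survival(model, sequences, rep(tau, length(sequences)))
}

#' Predicted survival probability at per-patient times
#'
#' @param model A `trisk_model`.
#' @param sequences List of `trisk_sequence` objects.
#' @param times Numeric vector of evaluation times (months), one per
#'   sequence.
#' @return Numeric vector of `S(t_i)` values.
#' @export
predict_survival <- function(model, sequences, times) {
  stopifnot(length(sequences) == length(times))
  if (length(sequences) == 0) return(numeric(0))
  config <- model$config
  reps <- do.call(rbind, lapply(sequences, function(s) {
    rep_forward(model$params, s, config)$rep
  }))
  grids <- lapply(times, simpson_grid, step = config$ode_step)
  counts <- vapply(grids, function(g) length(g$s), 0L)
  pos <- counts > 0
  Lam <- numeric(length(sequences))
  if (any(pos)) {
    idx <- rep(which(pos), counts[pos])
    s_rows <- unlist(lapply(grids[pos], `[[`, "s"))
    w_rows <- unlist(lapply(grids[pos], `[[`, "w"))
    hf <- head_forward(model$params$head, reps[idx, , drop = FALSE], s_rows,
                       config$t_scale)
    Lam[pos] <- as.numeric(rowsum(w_rows * hf$lambda, idx))
  }
  exp(-Lam)
}

#' Save / load a model checkpoint
#'
#' JSON manifest holding the config, the vocabulary (with a content hash) and
#' all parameters. Text-only and portable.
#'
#' @param model A `trisk_model`.
#' @param path Output file path (`.json`).
#' @export
save_trisk <- function(model, path) {
  flatten <- function(x) tree_map(function(a) as.numeric(a), x)
  shapes <- tree_map(function(a) dim(a) %||% length(a), model$params)
  vocab_hash <- sum(utf8ToInt(paste(model$vocab$code_levels, collapse = "|")))
  obj <- list(config = unclass(model$config),
              vocab = unclass(model$vocab),
              vocab_hash = vocab_hash,
              shapes = shapes,
              params = flatten(model$params),
              history = as.list(model$history),
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_trisk
#' @return `load_trisk` returns the restored `trisk_model`.
#' @export
load_trisk <- function(path) {
  # simplifyDataFrame would collapse the homogeneous per-layer parameter
  # lists into data frames; keep them as nested lists
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- structure(obj$config, class = "trisk_config")
  vocab <- obj$vocab
  vocab$code_ids <- stats::setNames(as.integer(vocab$code_ids), vocab$code_levels)
  class(vocab) <- "trisk_vocab"
  restore <- function(p, s) {
    if (is.list(s)) {
      out <- vector("list", length(s)); names(out) <- names(s)
      for (nm in seq_along(s)) out[[nm]] <- restore(p[[nm]], s[[nm]])
      out
    } else if (length(s) == 2) {
      matrix(unlist(p), s[1], s[2])
    } else {
      as.numeric(unlist(p))
    }
  }
  params <- restore(obj$params, obj$shapes)
  structure(list(params = params, config = cfg, vocab = vocab,
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch),
            class = "trisk_model")
}
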