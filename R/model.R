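#' Model configuration
#'
#' Architecture and training settings for the transformer-ODE survival model:
#' an embedding width `E` per channel (codes, ages, visit positions), combined
#' either by concatenation and a learned `3E -> E` projection with a tanh
#' non-linearity (`embedding_mode = "concat"`, the reference architecture) or
#' by elementwise summation (`"sum"`, the BEHRT-style ablation); a multi-head
#' self-attention encoder whose state at the terminal PREDICT token is the
#' patient representation; and a hazard network integrated by a fixed-step
#' solver to yield the survival curve. Training minimises the censored
#' negative log-likelihood plus `xcal_weight` times the differentiable
#' D-calibration (XCal) penalty.
#'
#' @param E Embedding width per channel; must be divisible by `n_heads`.
#' @param n_layers,n_heads Encoder depth and heads per layer.
#' @param max_len Maximum token-sequence length (including PREDICT).
#' @param embedding_mode `"concat"` or `"sum"`.
#' @param use_xcal Include the XCal penalty in the objective.
#' @param xcal_weight Weight `alpha >= 0` of the XCal penalty.
#' @param xcal_bins Number of probability bins `B >= 2`.
#' @param xcal_temperature Sharpness `gamma > 0` of the soft bin boundaries.
#' @param learning_rate,batch_size,max_epochs Optimiser settings (Adam).
#' @param eval_fraction Fraction held out for end-of-epoch testing
#'   (default 0.05).
#' @param patience Early-stopping patience in epochs on the end-of-epoch loss.
#' @param seed Integer seed controlling initialisation, the held-out split and
#'   batch order.
#' @param horizon Prediction horizon tau in months.
#' @param ffn_mult Feed-forward width multiplier.
#' @param head_hidden Hidden width of the hazard network.
#' @param ode_step Maximum solver step in months (default 0.5).
#' @param t_scale Internal time rescaling constant (months) for solver
#'   conditioning.
#' @return An object of class `trisk_config`.
#' @export
trisk_config <- function(E = 32L, n_layers = 2L, n_heads = 2L, max_len = 64L,
                         embedding_mode = c("concat", "sum"),
                         use_xcal = TRUE, xcal_weight = 1, xcal_bins = 20L,
                         xcal_temperature = 100,
                         learning_rate = 3e-3, batch_size = 64L,
                         max_epochs = 20L, eval_fraction = 0.05,
                         patience = 5L, seed = 1L, horizon = 36,
                         ffn_mult = 2L, head_hidden = 32L,
                         ode_step = 0.5, t_scale = 60) {
  embedding_mode <- match.arg(embedding_mode)
  if (E %% n_heads != 0) stop_config("E must be divisible by n_heads")
  if (xcal_bins < 2) stop_config("xcal_bins must be >= 2")
  if (xcal_temperature <= 0) stop_config("xcal_temperature must be > 0")
  if (eval_fraction <= 0 || eval_fraction >= 1) {
    stop_config("eval_fraction must lie in (0, 1)")
  }
  if (xcal_weight < 0) stop_config("xcal_weight must be >= 0")
  structure(list(E = as.integer(E), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), max_len = as.integer(max_len),
                 embedding_mode = embedding_mode, use_xcal = use_xcal,
                 xcal_weight = if (use_xcal) xcal_weight else 0,
                 xcal_bins = as.integer(xcal_bins),
                 xcal_temperature = xcal_temperature,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 eval_fraction = eval_fraction, patience = as.integer(patience),
                 seed = as.integer(seed), horizon = horizon,
                 ffn_mult = as.integer(ffn_mult),
                 head_hidden = as.integer(head_hidden),
                 ode_step = ode_step, t_scale = t_scale),
            class = "trisk_config")
}

#' Embed a token sequence
#'
#' Looks up the code, age and visit-position embeddings for each token and
#' combines them: in `"concat"` mode the three E-vectors are concatenated and
#' projected `3E -> E` by a learned weight and bias followed by tanh (so every
#' output lies strictly in (-1, 1)); in `"sum"` mode they are summed.
#'
#' @param seq A `trisk_sequence`.
#' @param params Model parameters (see [train_trisk()]).
#' @param mode `"concat"` or `"sum"`.
#' @return An `L x E` matrix of token latents.
#' @export
embed <- function(seq, params, mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  check_ids(seq, params)
  ch <- gather_channels(params, seq)
  embed_forward(params, ch, mode)$H0
}

check_ids <- function(seq, params) {
  if (any(seq$code_ids < 1 | seq$code_ids > nrow(params$Ec)) ||
      any(seq$age_ids < 1 | seq$age_ids > nrow(params$Ea)) ||
      any(seq$position_ids < 1 | seq$position_ids > nrow(params$Ep))) {
    stop_config("token id out of vocabulary range")
  }
}

#' Encode token latents to a patient representation
#'
#' Runs the multi-head self-attention encoder and returns the hidden state at
#' the PREDICT position. Padding tokens (attention mask 0) are stripped before
#' encoding, so they neither attend nor are attended to.
#'
#' @param latents `L x E` matrix from [embed()] (full, possibly padded
#'   length).
#' @param mask Attention mask (1 = real token, 0 = padding).
#' @param params,config Model parameters and [trisk_config()].
#' @param predict_pos Index of the PREDICT token; defaults to the last
#'   unpadded position.
#' @return Numeric vector of length `E`.
#' @export
encode <- function(latents, mask, params, config, predict_pos = NULL) {
  keep <- which(mask == 1)
  if (length(keep) == 0) stop_config("all-padding input")
  H0 <- latents[keep, , drop = FALSE]
  if (is.null(predict_pos)) predict_pos <- length(keep)
  out <- encoder_forward(params, H0, config)
  out$H[predict_pos, ]
}

# ---- ODE survival -----------------------------------------------------------

#' Integrate a hazard function to a survival curve
#'
#' Solves `dLambda/dt = lambda(t)` from 0 by fixed-step fourth-order
#' Runge-Kutta (for a hazard without state dependence this is composite
#' Simpson quadrature) and returns the curve `S = exp(-Lambda)`. A
#' step-halving check flags solver error above `tol`.
#'
#' @param lambda_fn Vectorised hazard function of time (per month).
#' @param times Increasing, non-negative evaluation times (months).
#' @param step Maximum step (months), default 0.5.
#' @param tol If non-`NULL`, maximum tolerated step-halving discrepancy in
#'   `Lambda`; exceeding it is an error.
#' @return A `survival_curve` data frame with columns `time`, `hazard`,
#'   `cumhaz`, `surv`.
#' @export
ode_survival <- function(lambda_fn, times, step = 0.5, tol = NULL) {
  if (any(times < 0) || is.unsorted(times)) {
    stop_config("times must be >= 0 and increasing")
  }
  cum <- function(stp) {
    Lam <- numeric(length(times)); acc <- 0; t_prev <- 0
    for (i in seq_along(times)) {
      dt <- times[i] - t_prev
      if (dt > 0) {
        g <- simpson_grid(dt, stp)
        acc <- acc + sum(g$w * lambda_fn(t_prev + g$s))
      }
      Lam[i] <- acc; t_prev <- times[i]
    }
    Lam
  }
  Lam <- cum(step)
  if (!is.null(tol)) {
    Lam2 <- cum(step / 2)
    if (max(abs(Lam - Lam2)) > tol) {
      stop_config("ODE solver discrepancy %.3g exceeds tolerance %.3g at step %.3g",
                  max(abs(Lam - Lam2)), tol, step)
    }
  }
  haz <- lambda_fn(times)
  if (any(!is.finite(Lam)) || any(haz < 0)) stop_config("solver produced invalid hazard")
  structure(data.frame(time = times, hazard = haz, cumhaz = Lam,
                       surv = exp(-Lam)),
            class = c("survival_curve", "data.frame"))
}

#' Survival curve for a patient representation
#'
#' Evaluates the model's hazard network at the representation and integrates
#' it over time. The head may be the trained MLP head or a frozen functional
#' head created by [constant_hazard_head()] / [fixed_hazard_head()].
#'
#' @param representation Numeric vector of length `E` (ignored for fixed
#'   heads).
#' @param times Evaluation grid (months, increasing).
#' @param params Model parameters (uses `params$head`).
#' @param config A [trisk_config()] (for `t_scale` and `ode_step`).
#' @return A `survival_curve` data frame.
#' @export
survival_curve <- function(representation, times, params, config) {
  lf <- head_lambda_fn(params$head, representation, config)
  ode_survival(lf, times, step = config$ode_step)
}

head_lambda_fn <- function(head, representation, config) {
  if (!is.null(head$lambda_fn)) return(head$lambda_fn)
  function(tt) {
    reps <- matrix(representation, nrow = length(tt), ncol = length(representation),
                   byrow = TRUE)
    head_forward(head, reps, tt, config$t_scale)$lambda
  }
}

#' Frozen hazard heads
#'
#' `constant_hazard_head(lambda)` builds an MLP head whose weights are zero
#' and whose output bias is set so the softplus output equals `lambda` exactly
#' for every representation and time. `fixed_hazard_head(fn)` wraps an
#' arbitrary hazard function of time (e.g. a Weibull hazard), bypassing the
#' network. Both plug into `params$head` for oracle checks.
#'
#' @param lambda Constant hazard per month (> 0).
#' @param E Representation width (to keep shapes consistent).
#' @param head_hidden Hidden width (to keep shapes consistent).
#' @return A head parameter list.
#' @export
constant_hazard_head <- function(lambda, E = 1L, head_hidden = 32L) {
  stopifnot(lambda > 0)
  list(W1 = matrix(0, E + 1L, head_hidden), b1 = numeric(head_hidden),
       w2 = matrix(0, head_hidden, 1), b2 = softplus_inv(lambda))
}

#' @rdname constant_hazard_head
#' @param fn Vectorised hazard function of time in months.
#' @export
fixed_hazard_head <- function(fn) {
  list(lambda_fn = fn)
}

# ---- losses -----------------------------------------------------------------

#' Censored negative log-likelihood
#'
#' Mean over examples of `-(event * log(lambda(t)) + log(S(t)))`, i.e.
#' `-event * log(lambda(t)) + Lambda(t)`: the exact right-censored
#' log-likelihood of the hazard model.
#'
#' @param curves List of `survival_curve` data frames, each covering its
#'   example's label time as the final grid point, or a data frame with
#'   columns `lambda_t` and `cumhaz_t`.
#' @param labels Data frame with columns `time` and `event`.
#' @return Scalar mean NLL.
#' @export
nll_loss <- function(curves, labels) {
  if (is.data.frame(curves)) {
    lam <- curves$lambda_t; Lam <- curves$cumhaz_t
  } else {
    lam <- vapply(seq_along(curves), function(i) {
      cv <- curves[[i]]
      stats::approx(cv$time, cv$hazard, xout = labels$time[i], rule = 2)$y
    }, 0)
    Lam <- vapply(seq_along(curves), function(i) {
      cv <- curves[[i]]
      stats::approx(cv$time, cv$cumhaz, xout = labels$time[i], rule = 2)$y
    }, 0)
  }
  if (any(lam[labels$event == 1] <= 0)) {
    stop_config("hazard must be positive at event times")
  }
  mean(ifelse(labels$event == 1, -log(lam), 0) + Lam)
}

# Soft bin membership matrix (n x B) for the XCal penalty: uncensored rows use
# temperature-gamma sigmoid edges; censored rows spread their residual mass
# (1 - F) uniformly over the probability region above F (piecewise-linear,
# differentiable a.e.).
xcal_membership <- function(F_values, events, B, gamma) {
  n <- length(F_values)
  edges_lo <- (seq_len(B) - 1) / B
  edges_hi <- seq_len(B) / B
  M <- matrix(0, n, B)
  dM <- matrix(0, n, B)  # d membership / d F
  ev <- events == 1
  if (any(ev)) {
    f <- F_values[ev]
    slo <- sigmoid(gamma * outer(f, edges_lo, "-"))
    shi <- sigmoid(gamma * outer(f, edges_hi, "-"))
    M[ev, ] <- slo - shi
    dM[ev, ] <- gamma * (slo * (1 - slo) - shi * (1 - shi))
  }
  if (any(!ev)) {
    f <- F_values[!ev]
    fm <- matrix(f, sum(!ev), B)
    lo <- matrix(edges_lo, sum(!ev), B, byrow = TRUE)
    hi <- matrix(edges_hi, sum(!ev), B, byrow = TRUE)
    den <- pmax(1 - fm, 1e-12)
    m <- pmax(hi - pmax(lo, fm), 0) / den
    M[!ev, ] <- m
    d <- matrix(0, sum(!ev), B)
    inside <- fm >= lo & fm < hi
    above <- fm < lo
    d[inside] <- (hi[inside] - 1) / den[inside]^2
    d[above] <- (hi[above] - lo[above]) / den[above]^2
    dM[!ev, ] <- d
  }
  list(M = M, dM = dM)
}

#' Differentiable D-calibration (XCal) penalty
#'
#' Soft-binned squared deviation of the empirical distribution of predicted
#' CDF values `F(t_i | x_i)` from uniformity over `B` equal-width bins:
#' uncensored examples get soft bin memberships through temperature-`gamma`
#' sigmoids at the bin edges; censored examples spread their residual
#' probability mass uniformly over the bins above `F(c_i)`. The penalty is
#' `sum_b (mass_b - 1/B)^2` and approaches 0 as the F-distribution approaches
#' uniform.
#'
#' @param F_values Predicted CDF values at the observed times, in `[0, 1]`.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param B Number of bins.
#' @param gamma Sigmoid temperature (larger = closer to hard binning).
#' @param grad If `TRUE`, also return the gradient w.r.t. `F_values`.
#' @return The penalty, or (with `grad`) a list `(penalty, grad)`.
#' @export
xcal_loss <- function(F_values, events, B = 20L, gamma = 100, grad = FALSE) {
  if (any(F_values < 0 | F_values > 1)) stop_config("F values must lie in [0, 1]")
  n <- length(F_values)
  mm <- xcal_membership(F_values, events, B, gamma)
  mass <- colSums(mm$M) / n
  dev <- mass - 1 / B
  pen <- sum(dev^2)
  if (!grad) return(pen)
  gF <- as.numeric(mm$dM %*% (2 * dev)) / n
  list(penalty = pen, grad = gF)
}

#' Hard-binned D-calibration statistic
#'
#' The omnibus calibration statistic: squared deviation of the hard-binned
#' masses of predicted CDF values from `1/B` per bin, with censored
#' observations spreading their residual mass uniformly over the bins above
#' `F(c_i)`. Zero iff the F-distribution is exactly uniform over bins.
#'
#' @inheritParams xcal_loss
#' @return Non-negative scalar.
#' @export
d_calibration <- function(F_values, events, B = 10L) {
  if (length(F_values) == 0) stop_config("empty input")
  if (any(F_values < 0 | F_values > 1)) stop_config("F values must lie in [0, 1]")
  n <- length(F_values)
  edges_lo <- (seq_len(B) - 1) / B
  edges_hi <- seq_len(B) / B
  mass <- numeric(B)
  for (i in seq_len(n)) {
    f <- F_values[i]
    if (events[i] == 1) {
      b <- min(max(1L, ceiling(f * B)), B)
      if (f == 0) b <- 1L
      mass[b] <- mass[b] + 1
    } else {
      den <- max(1 - f, 1e-12)
      mass <- mass + pmax(edges_hi - pmax(edges_lo, f), 0) / den
    }
  }
  mass <- mass / n
  sum((mass - 1 / B)^2)
}
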