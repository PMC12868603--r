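# Low-level neural network machinery: parameter initialisation, forward and
# backward passes for the embedding projection, the multi-head self-attention
# encoder, and the ODE hazard head, plus the Adam optimiser. All code operates
# on one (unpadded) sequence at a time as L x E matrices; minibatch routines
# loop and accumulate.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))
sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)
row_scale <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

rnorm_mat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, 0, sd), n, m)

# ---- parameter tree utilities -----------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}
tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

zeros_like <- function(p) tree_map(function(a) {
  if (is.matrix(a)) matrix(0, nrow(a), ncol(a)) else numeric(length(a))
}, p)

# Adam with bias correction; state carries first/second moments and step.
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# ---- initialisation ---------------------------------------------------------

init_trisk_params <- function(config, vocab, seed = config$seed) {
  E <- config$E
  with_local_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = rnorm_mat(E, E), bq = numeric(E),
           Wk = rnorm_mat(E, E), bk = numeric(E),
           Wv = rnorm_mat(E, E), bv = numeric(E),
           Wo = rnorm_mat(E, E), bo = numeric(E),
           g1 = rep(1, E), be1 = numeric(E),
           Wf1 = rnorm_mat(E, config$ffn_mult * E), bf1 = numeric(config$ffn_mult * E),
           Wf2 = rnorm_mat(config$ffn_mult * E, E), bf2 = numeric(E),
           g2 = rep(1, E), be2 = numeric(E))
    })
    list(
      Ec = rnorm_mat(n_code_ids(vocab), E),
      Ea = rnorm_mat(vocab$n_ages, E),
      Ep = rnorm_mat(vocab$n_positions + 1L, E),
      W = rnorm_mat(3 * E, E), b = numeric(E),
      layers = layers,
      head = list(W1 = rnorm_mat(E + 1L, config$head_hidden, sd = 0.1),
                  b1 = numeric(config$head_hidden),
                  w2 = matrix(stats::rnorm(config$head_hidden, 0, 0.1), ncol = 1),
                  b2 = softplus_inv(0.02))
    )
  })
}

# ---- embedding --------------------------------------------------------------

# Returns the three channel matrices (L x E each) for a sequence.
gather_channels <- function(params, seq) {
  list(code = params$Ec[seq$code_ids, , drop = FALSE],
       age = params$Ea[seq$age_ids, , drop = FALSE],
       pos = params$Ep[seq$position_ids, , drop = FALSE])
}

# Forward of the embedding combiner. mode "concat": [code||age||pos] (3E)
# projected to E then tanh; mode "sum": elementwise sum of the channels.
embed_forward <- function(params, ch, mode) {
  if (mode == "concat") {
    X0 <- cbind(ch$code, ch$age, ch$pos)
    H0 <- tanh(add_bias(X0 %*% params$W, params$b))
    list(H0 = H0, X0 = X0)
  } else {
    list(H0 = ch$code + ch$age + ch$pos, X0 = NULL)
  }
}

# Backward: returns grads for W, b and the three channel matrices.
embed_backward <- function(params, cache, dH0, mode) {
  if (mode == "concat") {
    E <- ncol(dH0)
    dA <- dH0 * (1 - cache$H0^2)
    gW <- crossprod(cache$X0, dA)
    gb <- colSums(dA)
    dX0 <- dA %*% t(params$W)
    list(gW = gW, gb = gb,
         d_code = dX0[, 1:E, drop = FALSE],
         d_age = dX0[, (E + 1):(2 * E), drop = FALSE],
         d_pos = dX0[, (2 * E + 1):(3 * E), drop = FALSE])
  } else {
    zE <- matrix(0, 1, 1)
    list(gW = NULL, gb = NULL, d_code = dH0, d_age = dH0, d_pos = dH0)
  }
}

# ---- layer norm -------------------------------------------------------------

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = add_bias(row_scale(xhat, g), b), xhat = xhat, inv = inv)
}

ln_backward <- function(cache, g, dy) {
  dxhat <- row_scale(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx, gg = colSums(dy * cache$xhat), gb = colSums(dy))
}

# ---- transformer encoder ----------------------------------------------------

encoder_forward <- function(params, H0, config) {
  E <- config$E; nh <- config$n_heads; dh <- E / nh
  H <- H0
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- params$layers[[l]]
    Hin <- H
    Q <- add_bias(Hin %*% p$Wq, p$bq)
    K <- add_bias(Hin %*% p$Wk, p$bk)
    V <- add_bias(Hin %*% p$Wv, p$bv)
    C <- matrix(0, nrow(Hin), E)
    Ps <- vector("list", nh)
    for (h in seq_len(nh)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dh)
      P <- softmax_rows(S)
      Ps[[h]] <- P
      C[, ix] <- P %*% V[, ix, drop = FALSE]
    }
    O <- add_bias(C %*% p$Wo, p$bo)
    R1 <- Hin + O
    ln1 <- ln_forward(R1, p$g1, p$be1)
    H1 <- ln1$y
    Fp <- add_bias(H1 %*% p$Wf1, p$bf1)
    Fa <- pmax(Fp, 0)
    F2 <- add_bias(Fa %*% p$Wf2, p$bf2)
    R2 <- H1 + F2
    ln2 <- ln_forward(R2, p$g2, p$be2)
    H <- ln2$y
    caches[[l]] <- list(Hin = Hin, Q = Q, K = K, V = V, Ps = Ps, C = C,
                        ln1 = ln1, H1 = H1, Fp = Fp, Fa = Fa, ln2 = ln2)
  }
  list(H = H, caches = caches)
}

# dH: gradient w.r.t. encoder output (L x E). Accumulates layer grads into
# `acc` (an environment mirroring params$layers) and returns dH0.
encoder_backward <- function(params, caches, dH, config, acc) {
  E <- config$E; nh <- config$n_heads; dh <- E / nh
  for (l in rev(seq_len(config$n_layers))) {
    p <- params$layers[[l]]
    cc <- caches[[l]]
    g <- acc$layers[[l]]
    b2 <- ln_backward(cc$ln2, p$g2, dH)
    g$g2 <- g$g2 + b2$gg; g$be2 <- g$be2 + b2$gb
    dR2 <- b2$dx
    dH1 <- dR2
    dF2 <- dR2
    g$Wf2 <- g$Wf2 + crossprod(cc$Fa, dF2); g$bf2 <- g$bf2 + colSums(dF2)
    dFa <- dF2 %*% t(p$Wf2)
    dFp <- dFa * (cc$Fp > 0)
    g$Wf1 <- g$Wf1 + crossprod(cc$H1, dFp); g$bf1 <- g$bf1 + colSums(dFp)
    dH1 <- dH1 + dFp %*% t(p$Wf1)
    b1 <- ln_backward(cc$ln1, p$g1, dH1)
    g$g1 <- g$g1 + b1$gg; g$be1 <- g$be1 + b1$gb
    dR1 <- b1$dx
    dHin <- dR1
    dO <- dR1
    g$Wo <- g$Wo + crossprod(cc$C, dO); g$bo <- g$bo + colSums(dO)
    dC <- dO %*% t(p$Wo)
    dQ <- matrix(0, nrow(dH), E); dK <- dQ; dV <- dQ
    for (h in seq_len(nh)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      P <- cc$Ps[[h]]
      dCtx <- dC[, ix, drop = FALSE]
      Vh <- cc$V[, ix, drop = FALSE]
      dP <- tcrossprod(dCtx, Vh)
      dV[, ix] <- crossprod(P, dCtx)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, ix] <- dS %*% cc$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- crossprod(dS, cc$Q[, ix, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- g$Wq + crossprod(cc$Hin, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(cc$Hin, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(cc$Hin, dV); g$bv <- g$bv + colSums(dV)
    dHin <- dHin + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    acc$layers[[l]] <- g
    dH <- dHin
  }
  dH
}

# ---- hazard head ------------------------------------------------------------

# Hazard MLP on stacked rows U = [rep | t / t_scale]; softplus output
# guarantees positivity.
head_forward <- function(head, reps, times, t_scale) {
  U <- cbind(reps, times / t_scale)
  Z1p <- add_bias(U %*% head$W1, head$b1)
  Z1 <- tanh(Z1p)
  z2 <- drop(Z1 %*% head$w2) + head$b2
  list(lambda = softplus(z2) + 1e-12, U = U, Z1 = Z1, z2 = z2)
}

# dlam: gradient w.r.t. lambda per row. Returns head grads and per-row
# gradient w.r.t. the representation columns.
head_backward <- function(head, cache, dlam) {
  dz2 <- dlam * sigmoid(cache$z2)
  gw2 <- crossprod(cache$Z1, dz2)
  gb2 <- sum(dz2)
  dZ1 <- outer(as.numeric(dz2), drop(head$w2))
  dZ1p <- dZ1 * (1 - cache$Z1^2)
  gW1 <- crossprod(cache$U, dZ1p)
  gb1 <- colSums(dZ1p)
  dU <- dZ1p %*% t(head$W1)
  E <- ncol(cache$U) - 1L
  list(gW1 = gW1, gb1 = gb1, gw2 = gw2, gb2 = gb2,
       d_rep = dU[, 1:E, drop = FALSE])
}

# Composite-Simpson grid over [0, t] with half-step <= step/2; equivalent to
# fixed-step RK4 on dLambda/dt = lambda(t). Returns nodes and weights so that
# Lambda(t) = sum(w * lambda(s)).
simpson_grid <- function(t, step = 0.5) {
  if (t <= 0) return(list(s = numeric(0), w = numeric(0)))
  m <- 2L * max(1L, ceiling(t / (2 * step)))
  h <- t / m
  s <- seq(0, t, length.out = m + 1L)
  w <- c(1, rep(c(4, 2), length.out = m - 1L), 1) * h / 3
  list(s = s, w = w)
}

# ---- full forward over one sequence ----------------------------------------

# Encode a single trisk_sequence to its patient representation (E-vector),
# returning caches for backward.
rep_forward <- function(params, seq, config) {
  ch <- gather_channels(params, seq)
  em <- embed_forward(params, ch, config$embedding_mode)
  en <- encoder_forward(params, em$H0, config)
  list(rep = en$H[seq$predict_pos, ], ch = ch, em = em, en = en)
}

# Backprop d_rep (E-vector) for one sequence; accumulates all parameter grads
# into `acc` (environment). Also returns the gradient w.r.t. the code-channel
# input embeddings (L x E), used by integrated gradients.
rep_backward <- function(params, seq, fw, d_rep, config, acc) {
  L <- length(seq$code_ids)
  dH <- matrix(0, L, config$E)
  dH[seq$predict_pos, ] <- d_rep
  dH0 <- encoder_backward(params, fw$en$caches, dH, config, acc)
  eb <- embed_backward(params, fw$em, dH0, config$embedding_mode)
  if (config$embedding_mode == "concat") {
    acc$W <- acc$W + eb$gW
    acc$b <- acc$b + eb$gb
  }
  acc$emb_rows$code[[length(acc$emb_rows$code) + 1L]] <-
    list(ids = seq$code_ids, g = eb$d_code)
  acc$emb_rows$age[[length(acc$emb_rows$age) + 1L]] <-
    list(ids = seq$age_ids, g = eb$d_age)
  acc$emb_rows$pos[[length(acc$emb_rows$pos) + 1L]] <-
    list(ids = seq$position_ids, g = eb$d_pos)
  eb$d_code
}

# Fresh gradient accumulator for a minibatch.
new_grad_acc <- function(params) {
  acc <- new.env(parent = emptyenv())
  acc$W <- params$W * 0
  acc$b <- params$b * 0
  acc$layers <- zeros_like(params$layers)
  acc$head <- zeros_like(params$head)
  acc$emb_rows <- list(code = list(), age = list(), pos = list())
  acc
}

# Collapse accumulated per-row embedding grads into dense tables and return a
# grads tree matching params.
acc_to_grads <- function(acc, params) {
  dense <- function(rows, table) {
    g <- table * 0
    if (length(rows) > 0) {
      ids <- unlist(lapply(rows, `[[`, "ids"))
      mats <- do.call(rbind, lapply(rows, `[[`, "g"))
      agg <- rowsum(mats, group = ids)
      g[as.integer(rownames(agg)), ] <- agg
    }
    g
  }
  list(Ec = dense(acc$emb_rows$code, params$Ec),
       Ea = dense(acc$emb_rows$age, params$Ea),
       Ep = dense(acc$emb_rows$pos, params$Ep),
       W = acc$W, b = acc$b,
       layers = acc$layers, head = acc$head)
}
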