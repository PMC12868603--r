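tiny_cfg <- function(...) {
  trisk_config(E = 8, n_layers = 2, n_heads = 2, max_len = 16,
               head_hidden = 8, seed = 3, ...)
}

tiny_setup <- function() {
  fix("tiny_setup", function() {
    co <- simulate_cohort(simulation_config(n_patients = 20, seed = 5))
    ds <- build_dataset(co, max_len = 16)
    cfg <- tiny_cfg()
    params <- init_trisk_params(cfg, ds$vocab, 7)
    list(co = co, ds = ds, cfg = cfg, params = params)
  })
}

test_that("concat embeddings are tanh-bounded and respect their inputs", {
  st <- tiny_setup()
  s <- st$ds$sequences[[1]]
  H <- embed(s, st$params, "concat")
  expect_true(all(H > -1 & H < 1))
  p0 <- st$params; p0$W[] <- 0; p0$b[] <- 0
  expect_true(all(embed(s, p0, "concat") == 0))
  # two tokens differing only in age id must embed differently
  s2 <- s
  s2$age_ids[1] <- if (s$age_ids[1] == 5L) 6L else 5L
  expect_false(isTRUE(all.equal(embed(s, st$params, "concat")[1, ],
                                embed(s2, st$params, "concat")[1, ])))
  # sum mode is the plain elementwise sum
  ch <- trisk:::gather_channels(st$params, s)
  expect_equal(embed(s, st$params, "sum"), ch$code + ch$age + ch$pos)
  s_bad <- s; s_bad$code_ids[1] <- 10000L
  expect_error(embed(s_bad, st$params), "out of vocabulary")
})

test_that("the encoder ignores padding and handles singleton sequences", {
  st <- tiny_setup()
  s <- st$ds$sequences[[which.max(vapply(st$ds$sequences, function(x)
    x$predict_pos, 0L))]]
  sp <- pad_sequence(s, 16)
  H <- embed(sp, st$params, "concat")
  r1 <- encode(H, sp$attention_mask, st$params, st$cfg,
               predict_pos = s$predict_pos)
  # permute the padded slots' latents: output unchanged
  pad_ix <- which(sp$attention_mask == 0)
  if (length(pad_ix) > 1) {
    H2 <- H; H2[pad_ix, ] <- H[rev(pad_ix), ]
    r2 <- encode(H2, sp$attention_mask, st$params, st$cfg,
                 predict_pos = s$predict_pos)
    expect_identical(r1, r2)
  }
  # unpadded computation agrees
  Hu <- embed(s, st$params, "concat")
  expect_equal(encode(Hu, s$attention_mask, st$params, st$cfg), r1)
  # a lone PREDICT token still encodes
  s1 <- s
  for (f in c("code_ids", "age_ids", "position_ids", "attention_mask")) {
    s1[[f]] <- s[[f]][s$predict_pos]
  }
  s1$predict_pos <- 1L
  r <- encode(embed(s1, st$params, "concat"), s1$attention_mask, st$params,
              st$cfg)
  expect_true(all(is.finite(r)))
  expect_error(encode(H, rep(0L, nrow(H)), st$params, st$cfg), "all-padding")
})

test_that("the ODE solver matches closed-form survival", {
  # constant hazard
  cv <- ode_survival(function(t) rep(0.05, length(t)), c(12, 24, 36))
  expect_equal(cv$surv, exp(-0.05 * c(12, 24, 36)), tolerance = 1e-10)
  expect_equal(cv$surv[2], exp(-1.2), tolerance = 1e-4)
  # Weibull shape 2 (linear hazard) and shape 1.5 on [0, 60] months
  for (k in c(2, 1.5)) {
    s <- 30
    tt <- seq(0, 60, by = 1)
    cv <- ode_survival(function(t) (k / s) * (t / s)^(k - 1), tt, step = 0.1)
    expect_lt(max(abs(cv$surv - exp(-(tt / s)^k))), 1e-4)
  }
  # S(0) = 1, monotone on refined grids
  fine <- ode_survival(function(t) 0.01 + 0.001 * t, seq(0, 48, by = 0.25))
  expect_equal(fine$surv[1], 1)
  expect_true(all(diff(fine$surv) <= 0))
  expect_error(ode_survival(function(t) rep(1, length(t)), c(3, 1)),
               "increasing")
  # step-halving tolerance check trips on a rough hazard at a coarse step
  expect_error(
    ode_survival(function(t) 5 * abs(sin(20 * t)), c(10), step = 2, tol = 1e-10),
    "discrepancy")
})

test_that("survival curves from a frozen constant head hit the closed form", {
  st <- tiny_setup()
  params <- st$params
  params$head <- constant_hazard_head(0.05, E = st$cfg$E)
  rep_vec <- rnorm(st$cfg$E)
  cv <- survival_curve(rep_vec, c(0, 12, 24), params, st$cfg)
  expect_equal(cv$surv[1], 1)
  expect_lt(abs(cv$surv[3] - 0.3012), 1e-4)
  # the learned-head curve is a valid survival curve too
  cv2 <- survival_curve(rep_vec, seq(0, 48, by = 2), st$params, st$cfg)
  expect_true(all(diff(cv2$surv) <= 0))
  expect_true(all(cv2$hazard > 0))
  expect_equal(cv2$surv, exp(-cv2$cumhaz), tolerance = 1e-12)
})

test_that("the censored NLL matches exponential closed forms", {
  cur <- ode_survival(function(t) rep(0.1, length(t)), c(0, 5, 10))
  expect_lt(abs(nll_loss(list(cur), data.frame(time = 10, event = 1)) -
                  (-log(0.1) + 1)), 1e-4)
  # censored with zero hazard: contribution 0
  cur0 <- ode_survival(function(t) rep(0, length(t)), c(0, 10))
  expect_equal(nll_loss(list(cur0), data.frame(time = 10, event = 0)), 0)
  expect_error(nll_loss(list(cur0), data.frame(time = 10, event = 1)),
               "positive")
  # batch NLL is the mean of per-example NLLs
  labs <- data.frame(time = c(10, 20), event = c(1, 0))
  cur2 <- ode_survival(function(t) rep(0.1, length(t)), c(0, 20))
  both <- nll_loss(list(cur, cur2), labs)
  one <- nll_loss(list(cur), labs[1, ])
  two <- nll_loss(list(cur2), labs[2, ])
  expect_equal(both, (one + two) / 2, tolerance = 1e-12)
})

test_that("the XCal penalty recognises uniform and degenerate F distributions", {
  f_unif <- seq(0.05, 0.95, by = 0.1)
  ev <- rep(1, 10)
  expect_lt(xcal_loss(f_unif, ev, B = 10, gamma = 1e4), 1e-3)
  clumped <- xcal_loss(rep(0.22, 10), ev, B = 10, gamma = 1e4)
  expect_gt(clumped, xcal_loss(f_unif, ev, B = 10, gamma = 1e4))
  # permutation invariance
  set.seed(1)
  f <- runif(30); e <- rbinom(30, 1, 0.6)
  p <- sample(30)
  expect_equal(xcal_loss(f, e, 10, 50), xcal_loss(f[p], e[p], 10, 50))
  expect_error(xcal_loss(c(0.5, 1.2), c(1, 1)), "\\[0, 1\\]")
  # analytic gradient against finite differences (events and censored)
  g <- xcal_loss(f, e, B = 5, gamma = 8, grad = TRUE)$grad
  for (i in c(1, 7, 19)) {
    fp <- f; fp[i] <- f[i] + 1e-6
    fm <- f; fm[i] <- f[i] - 1e-6
    num <- (xcal_loss(fp, e, 5, 8) - xcal_loss(fm, e, 5, 8)) / 2e-6
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("the hard D-calibration statistic matches direct evaluation", {
  f_unif <- seq(0.05, 0.95, by = 0.1)
  expect_equal(d_calibration(f_unif, rep(1, 10), B = 10), 0)
  expect_equal(d_calibration(rep(0.05, 100), rep(1, 100), B = 10),
               0.9^2 + 9 * 0.1^2)
  # invariant to within-bin perturbation
  expect_equal(d_calibration(f_unif + 0.02, rep(1, 10), B = 10), 0)
  expect_error(d_calibration(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients of the full objective match finite differences", {
  st <- tiny_setup()
  cfg <- tiny_cfg(xcal_weight = 0.5, xcal_bins = 5, xcal_temperature = 8)
  seqs <- st$ds$sequences[1:5]
  tt <- st$ds$labels$time[1:5]; ev <- st$ds$labels$event[1:5]
  res <- trisk:::batch_loss_grads(st$params, seqs, tt, ev, cfg)
  expect_equal(res$total, res$nll + 0.5 * res$xcal, tolerance = 1e-12)
  num <- function(get, set) {
    eps <- 1e-6
    p1 <- set(st$params, get(st$params) + eps)
    p2 <- set(st$params, get(st$params) - eps)
    (trisk:::batch_loss_grads(p1, seqs, tt, ev, cfg, want_grads = FALSE)$total -
       trisk:::batch_loss_grads(p2, seqs, tt, ev, cfg, want_grads = FALSE)$total) /
      (2 * eps)
  }
  checks <- list(
    list(g = res$grads$W[2, 3],
         f = num(function(p) p$W[2, 3], function(p, v) { p$W[2, 3] <- v; p })),
    list(g = res$grads$layers[[1]]$Wv[1, 2],
         f = num(function(p) p$layers[[1]]$Wv[1, 2],
                 function(p, v) { p$layers[[1]]$Wv[1, 2] <- v; p })),
    list(g = res$grads$layers[[2]]$g2[3],
         f = num(function(p) p$layers[[2]]$g2[3],
                 function(p, v) { p$layers[[2]]$g2[3] <- v; p })),
    list(g = res$grads$head$W1[1, 2],
         f = num(function(p) p$head$W1[1, 2],
                 function(p, v) { p$head$W1[1, 2] <- v; p })),
    list(g = res$grads$Ec[4, 2],
         f = num(function(p) p$Ec[4, 2], function(p, v) { p$Ec[4, 2] <- v; p }))
  )
  for (ck in checks) {
    expect_equal(ck$g, ck$f, tolerance = 1e-4)
  }
})
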