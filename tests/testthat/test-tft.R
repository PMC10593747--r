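# Model contracts: shapes, simplex weights, GRU recurrence oracle,
# unidirectionality, end-to-end causality, previous-session masking,
# determinism, and the training smoke test.

make_toy_bundle <- function(T = 4L, V = 6, n_static = 3, K = 2, seed = 1,
                            prev_avail = c(TRUE, FALSE)) {
  set.seed(seed)
  xtv <- matrix(rnorm(T * V), T, V,
                dimnames = list(NULL, paste0("ch", seq_len(V))))
  prev <- vector("list", K)
  if (K > 0 && any(prev_avail)) {
    for (k in which(prev_avail))
      prev[[k]] <- list(x = matrix(rnorm(3 * V), 3, V), T = 3L)
  }
  structure(list(
    session_id = "T1", patient_id = "P1", T = as.integer(T), xtv = xtv,
    elapsed_min = seq(0, by = 60, length.out = T),
    static = stats::setNames(rnorm(n_static), paste0("s", seq_len(n_static))),
    labels = matrix(rbinom(T * 3, 1, .5), T, 3),
    lmask = matrix(1, T, 3),
    prev = prev, prev_avail = prev_avail, n_tv = V %/% 2,
    feature_count = n_static + V
  ), class = "hd_bundle")
}

toy_model <- function(V = 6, n_static = 3, K = 2, H = 4, seed = 3,
                      variant = "tft") {
  cfg <- model_config(hidden = H, k_prev = K, max_epochs = 1, seed = seed,
                      dropout = 0, variant = variant)
  init_model(cfg, paste0("ch", seq_len(V)), paste0("s", seq_len(n_static)))
}

fw_probs <- function(model, bundle) {
  batch <- hdtft:::hd_make_batch(list(bundle), model$K,
                                 model$config$max_timesteps)
  fw <- hdtft:::hd_forward(model, batch, train = FALSE, collect = TRUE)
  list(prob = fw$prob[seq_len(bundle$T) * 1L +
                        rep(0, bundle$T), , drop = FALSE][seq_len(bundle$T), ],
       fw = fw, batch = batch)
}

test_that("forward pass emits per-timestep probability triples in (0, 1)", {
  m <- toy_model()
  b <- make_toy_bundle()
  out <- fw_probs(m, b)
  expect_identical(dim(out$prob), c(4L, 3L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  # single-timestep sessions are valid inputs
  b1 <- make_toy_bundle(T = 1, prev_avail = c(FALSE, FALSE))
  out1 <- fw_probs(m, b1)
  expect_identical(dim(out1$fw$prob), c(1L, 3L))
  expect_identical(out1$fw$attention[[1]], matrix(1, 1, 1))
})

test_that("selection weights are simplexes; V = 1 weight is exactly 1", {
  m <- toy_model()
  b <- make_toy_bundle()
  out <- fw_probs(m, b)
  expect_equal(rowSums(out$fw$tv_weights), rep(1, nrow(out$fw$tv_weights)),
               tolerance = 1e-6)
  expect_equal(rowSums(out$fw$static_weights), 1, tolerance = 1e-6)
  expect_true(all(out$fw$tv_weights >= 0))
  m1 <- toy_model(V = 1, n_static = 1, K = 0)
  b1 <- make_toy_bundle(V = 1, n_static = 1, K = 0,
                        prev_avail = logical(0))
  out1 <- fw_probs(m1, b1)
  expect_equal(as.vector(out1$fw$tv_weights), rep(1, b1$T))
  expect_equal(as.vector(out1$fw$static_weights), 1)
})

test_that("the GRU matches a hand-rolled recurrence on a 2-unit toy", {
  set.seed(21)
  H <- 2
  P <- list()
  for (g in c("z", "r", "n")) {
    P[[paste0("gru.W", g)]] <- matrix(rnorm(4, sd = .5), 2, 2)
    P[[paste0("gru.U", g)]] <- matrix(rnorm(4, sd = .5), 2, 2)
    P[[paste0("gru.b", g)]] <- matrix(rnorm(2, sd = .2), 1, 2)
  }
  x <- matrix(rnorm(6), 3, 2)      # T = 3, B = 1
  tp <- hdtft:::ad_tape()
  pid <- lapply(P, function(m) hdtft:::ad_leaf(tp, m))
  fused <- hdtft:::ad_leaf(tp, x)
  h0 <- hdtft:::ad_leaf(tp, matrix(0, 1, 2))
  out <- hdtft:::hd_gru_fw(tp, pid, fused, rep(1, 3), 1L, 3L, h0)
  got <- hdtft:::ad_value(tp, out)

  sig <- function(v) 1 / (1 + exp(-v))
  h <- matrix(0, 1, 2)
  want <- NULL
  for (t in 1:3) {
    xt <- x[t, , drop = FALSE]
    z <- sig(xt %*% P$gru.Wz + h %*% P$gru.Uz + P$gru.bz)
    r <- sig(xt %*% P$gru.Wr + h %*% P$gru.Ur + P$gru.br)
    nn <- tanh(xt %*% P$gru.Wn + (r * h) %*% P$gru.Un + P$gru.bn)
    h <- z * h + (1 - z) * nn
    want <- rbind(want, h)
  }
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("equal attention logits give uniform causal weights 1/t", {
  sc <- matrix(0.7, 5, 5)
  mask <- lower.tri(matrix(1, 5, 5), diag = TRUE) * 1
  tp <- hdtft:::ad_tape()
  w <- hdtft:::ad_softmax_masked(tp, hdtft:::ad_leaf(tp, sc), mask)
  wv <- hdtft:::ad_value(tp, w)
  for (t in 1:5) {
    expect_equal(wv[t, seq_len(t)], rep(1 / t, t), tolerance = 1e-12)
    if (t < 5) expect_identical(wv[t, (t + 1):5], rep(0, 5 - t))
  }
})

test_that("causality: perturbing future inputs leaves earlier predictions unchanged", {
  m <- toy_model(seed = 9)
  b <- make_toy_bundle(T = 6, seed = 4)
  base <- fw_probs(m, b)$fw$prob
  for (t in c(2, 4)) {
    b2 <- b
    b2$xtv[(t + 1):6, ] <- b2$xtv[(t + 1):6, ] + 1000
    pert <- fw_probs(m, b2)$fw$prob
    expect_identical(pert[seq_len(t), ], base[seq_len(t), ])
  }
  # recurrent baseline obeys the same unidirectionality
  mr <- toy_model(K = 0, variant = "rnn", seed = 9)
  br <- make_toy_bundle(T = 6, seed = 4, K = 0, prev_avail = logical(0))
  b2 <- br; b2$xtv[4:6, ] <- -999
  expect_identical(fw_probs(mr, br)$fw$prob[1:3, ],
                   fw_probs(mr, b2)$fw$prob[1:3, ])
})

test_that("unavailable previous-session slots have exactly zero influence", {
  m <- toy_model(K = 3, seed = 30)
  b <- make_toy_bundle(K = 3, prev_avail = c(TRUE, FALSE, FALSE), seed = 8)
  base <- fw_probs(m, b)$fw$prob
  # garbage of any magnitude in masked slots changes nothing, exactly
  b2 <- b
  b2$prev[[2]] <- list(x = matrix(1000, 3, 6), T = 3L)
  b2$prev[[3]] <- list(x = matrix(-1000, 4, 6), T = 4L)
  expect_identical(fw_probs(m, b2)$fw$prob, base)
  # masked static selection weight is exactly zero
  w <- fw_probs(m, b)$fw$static_weights
  expect_identical(unname(w[1, 5:6]), c(0, 0))   # slots 2 and 3
  # K = 0 degenerates to a single-session model with a valid forward pass
  m0 <- toy_model(K = 0, seed = 30)
  b0 <- make_toy_bundle(K = 0, prev_avail = logical(0), seed = 8)
  expect_identical(dim(fw_probs(m0, b0)$fw$prob), c(4L, 3L))
})

test_that("an available previous session does influence the prediction", {
  m <- toy_model(K = 2, seed = 12)
  b <- make_toy_bundle(K = 2, prev_avail = c(TRUE, FALSE), seed = 13)
  base <- fw_probs(m, b)$fw$prob
  b2 <- b
  b2$prev[[1]]$x <- b2$prev[[1]]$x + 5
  expect_false(identical(fw_probs(m, b2)$fw$prob, base))
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  ds <- small_dataset()
  cfg <- model_config(hidden = 8, k_prev = 3, max_epochs = 2,
                      batch_size = 16, seed = 2, dropout = 0)
  m1 <- small_model()
  m2 <- train_model(ds$train, ds$validation, cfg)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$log$train_loss[2], m1$log$train_loss[1])
  expect_error(train_model(list(), list(), cfg), class = "hdtft_train_error")
})

test_that("predictions are reproducible and aligned with bundle timestamps", {
  ds <- small_dataset()
  m <- small_model()
  p1 <- predict_model(m, ds$test[1:5])
  p2 <- predict_model(m, ds$test[1:5])
  expect_identical(p1, p2)
  expect_identical(nrow(p1), sum(vapply(ds$test[1:5], function(b) b$T, 0L)))
})
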