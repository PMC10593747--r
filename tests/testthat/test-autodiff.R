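# Finite-difference gradient checks for every tape operation, plus a check
# of the composed GRN block against a hand-written forward pass.

num_grad <- function(fn, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# Builds a scalar loss sum(op_output * W) so every output element gets a
# distinct non-trivial gradient.
check_op <- function(build, x, tol = 1e-6) {
  ad <- hdtft:::ad_tape
  tp <- ad()
  leaf <- hdtft:::ad_leaf(tp, x)
  out <- build(tp, leaf)
  ov <- hdtft:::ad_value(tp, out)
  Wt <- matrix(seq_len(length(ov)) / length(ov), nrow(ov), ncol(ov))
  loss <- hdtft:::ad_push(tp, matrix(sum(ov * Wt), 1, 1), out,
                          function(g) list(as.vector(g) * Wt))
  hdtft:::ad_backward(tp, loss)
  ga <- hdtft:::ad_grad(tp, leaf)
  gn <- num_grad(function(xx) {
    tp2 <- ad()
    l2 <- hdtft:::ad_leaf(tp2, xx)
    o2 <- build(tp2, l2)
    sum(hdtft:::ad_value(tp2, o2) * Wt)
  }, x)
  expect_lt(max(abs(ga - gn)), tol)
}

test_that("elementwise and matrix ops have correct gradients", {
  set.seed(42)
  x <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(20), 4, 5)
  b <- matrix(rnorm(5), 1, 5)
  y <- matrix(rnorm(12), 3, 4)

  check_op(function(tp, l) hdtft:::ad_mm(tp, l, hdtft:::ad_leaf(tp, W)), x)
  check_op(function(tp, l) hdtft:::ad_mm_t(tp, hdtft:::ad_leaf(tp, t(W)), l),
           x)
  check_op(function(tp, l) hdtft:::ad_add(tp, l, hdtft:::ad_leaf(tp, y)), x)
  check_op(function(tp, l)
    hdtft:::ad_bias(tp, hdtft:::ad_mm(tp, l, hdtft:::ad_leaf(tp, W)),
                    hdtft:::ad_leaf(tp, b)), x)
  check_op(function(tp, l) hdtft:::ad_emul(tp, l, hdtft:::ad_leaf(tp, y)), x)
  check_op(function(tp, l)
    hdtft:::ad_cmul(tp, l, hdtft:::ad_leaf(tp, matrix(c(.5, -2, 3), 3, 1))), x)
  check_op(function(tp, l) hdtft:::ad_cmul_const(tp, l, c(2, -1, .5)), x)
  check_op(function(tp, l) hdtft:::ad_scale(tp, l, -1.7), x)
  check_op(function(tp, l) hdtft:::ad_sigmoid(tp, l), x)
  check_op(function(tp, l) hdtft:::ad_tanh(tp, l), x)
  check_op(function(tp, l) hdtft:::ad_elu(tp, l), x, tol = 1e-5)
})

test_that("gradients flow through parameter rows of the embedding op", {
  set.seed(7)
  xv <- rnorm(5)
  w <- matrix(rnorm(4), 1, 4)
  tp <- hdtft:::ad_tape()
  wl <- hdtft:::ad_leaf(tp, w)
  bl <- hdtft:::ad_leaf(tp, matrix(0.3, 1, 4))
  out <- hdtft:::ad_outer(tp, xv, wl, bl)
  ov <- hdtft:::ad_value(tp, out)
  Wt <- matrix(seq_len(20) / 20, 5, 4)
  loss <- hdtft:::ad_push(tp, matrix(sum(ov * Wt), 1, 1), out,
                          function(g) list(as.vector(g) * Wt))
  hdtft:::ad_backward(tp, loss)
  gw <- hdtft:::ad_grad(tp, wl)
  gn <- num_grad(function(ww) {
    sum((outer(xv, as.vector(ww)) + matrix(0.3, 5, 4)) * Wt)
  }, w)
  expect_lt(max(abs(gw - gn)), 1e-6)
})

test_that("slicing, stacking and scatter ops have correct gradients", {
  set.seed(1)
  x <- matrix(rnorm(24), 6, 4)
  check_op(function(tp, l) hdtft:::ad_rows(tp, l, c(2, 4, 5)), x)
  check_op(function(tp, l) hdtft:::ad_rows(tp, l, c(1, 1, 3)), x)  # dup idx
  check_op(function(tp, l) hdtft:::ad_col(tp, l, 3), x)
  check_op(function(tp, l)
    hdtft:::ad_rbind(tp, list(l, hdtft:::ad_leaf(tp, x))), x)
  check_op(function(tp, l)
    hdtft:::ad_cbind(tp, list(l, hdtft:::ad_leaf(tp, x))), x)
  check_op(function(tp, l)
    hdtft:::ad_rows_into(tp, list(hdtft:::ad_rows(tp, l, 1:3)),
                         list(c(2, 5, 7)), 8), x)
})

test_that("masked softmax is a simplex with exact zeros and correct gradient", {
  set.seed(3)
  x <- matrix(rnorm(12), 3, 4)
  mask <- matrix(c(1, 1, 0, 0,
                   1, 1, 1, 0,
                   1, 1, 1, 1), 3, 4, byrow = TRUE)
  tp <- hdtft:::ad_tape()
  l <- hdtft:::ad_leaf(tp, x)
  s <- hdtft:::ad_softmax_masked(tp, l, mask)
  sv <- hdtft:::ad_value(tp, s)
  expect_equal(rowSums(sv), rep(1, 3), tolerance = 1e-12)
  expect_identical(sv[mask == 0], rep(0, sum(mask == 0)))
  check_op(function(tp, l) hdtft:::ad_softmax_masked(tp, l, mask), x,
           tol = 1e-5)
})

test_that("masked BCE matches a direct computation and its gradient", {
  set.seed(9)
  l <- matrix(rnorm(12), 4, 3)
  y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  m <- matrix(rbinom(12, 1, 0.7), 4, 3)
  tp <- hdtft:::ad_tape()
  ll <- hdtft:::ad_leaf(tp, l)
  loss <- hdtft:::ad_bce_masked(tp, ll, y, m)
  p <- 1 / (1 + exp(-l))
  direct <- -sum(m * (y * log(p) + (1 - y) * log(1 - p))) / sum(m)
  expect_equal(hdtft:::ad_value(tp, loss)[1, 1], direct, tolerance = 1e-10)
  hdtft:::ad_backward(tp, loss)
  ga <- hdtft:::ad_grad(tp, ll)
  gn <- num_grad(function(x) {
    px <- 1 / (1 + exp(-x))
    -sum(m * (y * log(px) + (1 - y) * log(1 - px))) / sum(m)
  }, l)
  expect_lt(max(abs(ga - gn)), 1e-5)
})

test_that("the GRN block matches a hand-written forward pass on a 2-unit toy", {
  # fixed tiny weights; plain-R oracle computed independently of the tape
  set.seed(11)
  H <- 2
  P <- list(W2 = matrix(c(.1, -.2, .3, .4), 2, 2), b2 = matrix(c(.05, -.05), 1),
            W1 = matrix(c(.2, .1, -.1, .3), 2, 2), b1 = matrix(c(0, .1), 1),
            W4 = matrix(c(-.3, .2, .1, .2), 2, 2), b4 = matrix(c(.2, 0), 1),
            W5 = matrix(c(.4, -.2, .3, .1), 2, 2), b5 = matrix(c(-.1, .2), 1))
  pid_names <- paste0("g.", names(P))
  x <- matrix(c(.7, -1.2, .3, .9), 2, 2)

  tp <- hdtft:::ad_tape()
  pid <- lapply(P, function(m) hdtft:::ad_leaf(tp, m))
  names(pid) <- pid_names
  xl <- hdtft:::ad_leaf(tp, x)
  out <- hdtft:::hd_grn_fw(tp, pid, "g", xl)
  got <- hdtft:::ad_value(tp, out)

  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  sig <- function(v) 1 / (1 + exp(-v))
  brow <- function(m, b) m + matrix(b, nrow(m), ncol(m), byrow = TRUE)
  a <- elu(brow(x %*% P$W2, P$b2))
  eta <- brow(a %*% P$W1, P$b1)
  want <- x + sig(brow(eta %*% P$W4, P$b4)) * brow(eta %*% P$W5, P$b5)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("forcing the GRN gate closed leaves only the residual path", {
  set.seed(12)
  H <- 3
  P <- hdtft:::hd_grn_params(H, H, H)
  P$b4 <- matrix(-1e4, 1, H)    # sigmoid(-1e4) == 0: gate closed
  tp <- hdtft:::ad_tape()
  pid <- lapply(P, function(m) hdtft:::ad_leaf(tp, m))
  names(pid) <- paste0("g.", names(P))
  x <- matrix(rnorm(6), 2, H)
  out <- hdtft:::hd_grn_fw(tp, pid, "g", hdtft:::ad_leaf(tp, x))
  expect_equal(hdtft:::ad_value(tp, out), x, tolerance = 1e-12)
})

test_that("fused channel ops match their naive per-channel equivalents", {
  set.seed(17)
  V <- 3; H <- 2; n <- 4
  x <- matrix(rnorm(n * V * H), n, V * H)
  w <- matrix(abs(rnorm(n * V)), n, V)
  w <- w / rowSums(w)
  tp <- hdtft:::ad_tape()
  xl <- hdtft:::ad_leaf(tp, x); wl <- hdtft:::ad_leaf(tp, w)
  out <- hdtft:::ad_wsum_channels(tp, xl, wl, V, H)
  want <- matrix(0, n, H)
  for (v in 1:V) want <- want + w[, v] * x[, ((v - 1) * H + 1):(v * H)]
  expect_equal(hdtft:::ad_value(tp, out), want, tolerance = 1e-12)
  check_op(function(tp, l)
    hdtft:::ad_wsum_channels(tp, l, hdtft:::ad_leaf(tp, w), V, H), x)
  check_op(function(tp, l)
    hdtft:::ad_wsum_channels(tp, hdtft:::ad_leaf(tp, x), l, V, H), w)

  # masked matmul: value as plain matmul, gradient masked
  W <- hdtft:::hd_emb_init(V, H)
  mask <- hdtft:::hd_emb_mask(V, H)
  xs <- matrix(rnorm(n * V), n, V)
  tp2 <- hdtft:::ad_tape()
  wl2 <- hdtft:::ad_leaf(tp2, W)
  out2 <- hdtft:::ad_mm_masked(tp2, hdtft:::ad_leaf(tp2, xs), wl2, mask)
  expect_equal(hdtft:::ad_value(tp2, out2), xs %*% W, tolerance = 1e-12)
  ov <- hdtft:::ad_value(tp2, out2)
  Wt <- matrix(seq_len(length(ov)) / length(ov), nrow(ov), ncol(ov))
  loss <- hdtft:::ad_push(tp2, matrix(sum(ov * Wt), 1, 1), out2,
                          function(g) list(as.vector(g) * Wt))
  hdtft:::ad_backward(tp2, loss)
  gW <- hdtft:::ad_grad(tp2, wl2)
  expect_identical(gW[mask == 0], rep(0, sum(mask == 0)))
  expect_equal(gW[mask == 1], (crossprod(xs, Wt))[mask == 1],
               tolerance = 1e-10)
})

test_that("the fused GRN bank equals per-channel dense GRNs and its gradients check", {
  set.seed(19)
  V <- 3; H <- 2; n <- 4
  set.seed(23)
  bankP <- hdtft:::hd_grn_bank_params(V, H)
  x <- matrix(rnorm(n * V * H), n, V * H)
  run_bank <- function(xx) {
    tp <- hdtft:::ad_tape()
    pid <- lapply(bankP, function(m) hdtft:::ad_leaf(tp, m))
    names(pid) <- paste0("bk.", names(bankP))
    out <- hdtft:::hd_grn_bank_fw(tp, pid, "bk", hdtft:::ad_leaf(tp, xx),
                                  V, H)
    list(tp = tp, out = out, pid = pid)
  }
  got <- hdtft:::ad_value(run_bank(x)$tp, run_bank(x)$out)
  # per-channel oracle through the dense GRN builder
  for (v in 1:V) {
    ix <- ((v - 1) * H + 1):(v * H)
    Pv <- lapply(bankP[c("W2", "W1", "W4", "W5")], function(m) m[ix, ix])
    Pv <- c(Pv, lapply(bankP[c("b2", "b1", "b4", "b5")],
                       function(m) m[, ix, drop = FALSE]))
    tp <- hdtft:::ad_tape()
    pid <- lapply(Pv, function(m) hdtft:::ad_leaf(tp, m))
    names(pid) <- paste0("g.", names(Pv))
    o <- hdtft:::hd_grn_fw(tp, pid, "g", hdtft:::ad_leaf(tp, x[, ix]))
    expect_equal(got[, ix], hdtft:::ad_value(tp, o), tolerance = 1e-12)
  }
  # finite-difference check for input and one weight bank
  check_op(function(tp, l) {
    pid <- lapply(bankP, function(m) hdtft:::ad_leaf(tp, m))
    names(pid) <- paste0("bk.", names(bankP))
    hdtft:::hd_grn_bank_fw(tp, pid, "bk", l, V, H)
  }, x, tol = 1e-5)
  rb <- run_bank(x)
  ov <- hdtft:::ad_value(rb$tp, rb$out)
  Wt <- matrix(seq_len(length(ov)) / length(ov), nrow(ov), ncol(ov))
  loss <- hdtft:::ad_push(rb$tp, matrix(sum(ov * Wt), 1, 1), rb$out,
                          function(g) list(as.vector(g) * Wt))
  hdtft:::ad_backward(rb$tp, loss)
  gW2 <- hdtft:::ad_grad(rb$tp, rb$pid[["bk.W2"]])
  gnum <- gW2 * 0
  eps <- 1e-6
  for (i in which(hdtft:::hd_block_mask(V, H) == 1)) {
    Pp <- bankP; Pp$W2[i] <- Pp$W2[i] + eps
    Pm <- bankP; Pm$W2[i] <- Pm$W2[i] - eps
    f1 <- {
      tp <- hdtft:::ad_tape()
      pid <- lapply(Pp, function(m) hdtft:::ad_leaf(tp, m))
      names(pid) <- paste0("bk.", names(Pp))
      sum(hdtft:::ad_value(tp, hdtft:::hd_grn_bank_fw(
        tp, pid, "bk", hdtft:::ad_leaf(tp, x), V, H)) * Wt)
    }
    f2 <- {
      tp <- hdtft:::ad_tape()
      pid <- lapply(Pm, function(m) hdtft:::ad_leaf(tp, m))
      names(pid) <- paste0("bk.", names(Pm))
      sum(hdtft:::ad_value(tp, hdtft:::hd_grn_bank_fw(
        tp, pid, "bk", hdtft:::ad_leaf(tp, x), V, H)) * Wt)
    }
    gnum[i] <- (f1 - f2) / (2 * eps)
  }
  expect_lt(max(abs(gW2 - gnum)), 1e-5)
})
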