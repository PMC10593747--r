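# Modified temporal-fusion-transformer classifier.
#
# Architecture (per session): each temporal channel (time-varying variables,
# their auxiliary indicators, and the two elapsed-time channels) and each
# time-invariant variable is embedded to an H-vector by a per-variable dense
# layer. Gated residual networks (GRNs: four dense layers with an ELU
# nonlinearity and a sigmoid gate plus a residual skip) transform each
# embedding; a variable-selection block produces a simplex of per-variable
# weights (softmax over a GRN of the concatenated embeddings) whose weighted
# sum fuses the variables. Up to K previous sessions are pushed through the
# same temporal stack and re-enter the current session as additional
# time-invariant variables; unavailable slots are zero inputs with their
# selection weight forced to exactly zero by masking the softmax. The fused
# static vector initializes a unidirectional GRU over the fused temporal
# sequence and conditions the temporal selection GRN. A causally masked
# single-headed scaled-dot-product attention block (with GRN input layer and
# gated residual output) captures long-range structure, and a GRN + single
# dense layer emits three per-timestep logits (IDH-1, IDH-2, IDHTN), mapped
# to probabilities by the sigmoid. The original quantile forecasting outputs
# and known-future-input channel are removed: this is a real-time
# classifier over observed timestamps only.
#
# Implementation notes: the per-variable embeddings and GRNs are realized as
# block-diagonal parameter matrices with masked gradients, so the whole
# variable bank is a handful of matrix products instead of V separate
# subgraphs; attention over a minibatch uses one softmax with a
# block-causal mask (exact zeros across samples and into the future), which
# is algebraically identical to per-sample attention.
#
# `variant = "rnn"` degenerates the model to the recurrent baseline:
# concatenated embeddings -> dense -> GRU -> dense head, with no variable
# selection, no attention, and no previous-session context.

#' Model configuration
#'
#' @param hidden hidden width H (default 64)
#' @param dropout dropout probability in `[0, 1)` (default 0.1)
#' @param k_prev maximum number of previous sessions K (default 5)
#' @param max_timesteps maximum sequence length (default 24)
#' @param learning_rate Adam learning rate (default 1e-3)
#' @param batch_size sessions per minibatch (default 32)
#' @param max_epochs maximum training epochs (default 30)
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (default 3)
#' @param grad_clip global gradient-norm clip (default 5)
#' @param variant `"tft"` (full model) or `"rnn"` (recurrent baseline)
#' @param seed integer seed controlling initialization, shuffling and dropout
#' @return list of class `hd_model_config`
#' @export
model_config <- function(hidden = 64L, dropout = 0.1, k_prev = 5L,
                         max_timesteps = 24L, learning_rate = 1e-3,
                         batch_size = 32L, max_epochs = 30L,
                         early_stopping_patience = 3L, grad_clip = 5,
                         variant = c("tft", "rnn"), seed = 1L) {
  variant <- match.arg(variant)
  if (hidden < 1L) hd_stop("hidden must be positive", "hdtft_config_error")
  if (dropout < 0 || dropout >= 1)
    hd_stop("dropout must lie in [0, 1)", "hdtft_config_error")
  if (k_prev < 0L) hd_stop("k_prev must be >= 0", "hdtft_config_error")
  if (variant == "rnn") k_prev <- 0L
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 k_prev = as.integer(k_prev),
                 max_timesteps = as.integer(max_timesteps),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 grad_clip = grad_clip, variant = variant,
                 outcome_heads = c("idh1", "idh2", "idhtn"),
                 seed = as.integer(seed)),
            class = "hd_model_config")
}

hd_glorot <- function(fi, fo) {
  s <- sqrt(6 / (fi + fo))
  matrix(stats::runif(fi * fo, -s, s), fi, fo)
}

hd_zeros_row <- function(n) matrix(0, 1L, n)

# V*H x V*H block-diagonal weight (and its 0/1 mask).
hd_block_init <- function(V, H) {
  M <- matrix(0, V * H, V * H)
  for (v in seq_len(V)) {
    ix <- ((v - 1L) * H + 1L):(v * H)
    M[ix, ix] <- hd_glorot(H, H)
  }
  M
}

hd_block_mask <- function(V, H) {
  M <- matrix(0, V * H, V * H)
  for (v in seq_len(V)) {
    ix <- ((v - 1L) * H + 1L):(v * H)
    M[ix, ix] <- 1
  }
  M
}

# V x V*H per-channel embedding weight (row v feeds block v) and mask.
hd_emb_init <- function(V, H) {
  M <- matrix(0, V, V * H)
  for (v in seq_len(V))
    M[v, ((v - 1L) * H + 1L):(v * H)] <- hd_glorot(1L, H)
  M
}

hd_emb_mask <- function(V, H) {
  M <- matrix(0, V, V * H)
  for (v in seq_len(V)) M[v, ((v - 1L) * H + 1L):(v * H)] <- 1
  M
}

# Parameters for one (dense) GRN block with input width f_in, output width
# f_out and internal width h; optionally with a context projection.
hd_grn_params <- function(f_in, f_out, h, ctx = FALSE) {
  p <- list(W2 = hd_glorot(f_in, h), b2 = hd_zeros_row(h),
            W1 = hd_glorot(h, f_out), b1 = hd_zeros_row(f_out),
            W4 = hd_glorot(f_out, f_out), b4 = hd_zeros_row(f_out),
            W5 = hd_glorot(f_out, f_out), b5 = hd_zeros_row(f_out))
  if (ctx) p$Wc <- hd_glorot(h, h)
  if (f_in != f_out) p$Ws <- hd_glorot(f_in, f_out)
  p
}

# Parameters for a bank of V parallel GRNs (H -> H each) stored block-diag.
hd_grn_bank_params <- function(V, H) {
  list(W2 = hd_block_init(V, H), b2 = hd_zeros_row(V * H),
       W1 = hd_block_init(V, H), b1 = hd_zeros_row(V * H),
       W4 = hd_block_init(V, H), b4 = hd_zeros_row(V * H),
       W5 = hd_block_init(V, H), b5 = hd_zeros_row(V * H))
}

hd_add_params <- function(params, prefix, new) {
  for (nm in names(new)) params[[paste0(prefix, ".", nm)]] <- new[[nm]]
  params
}

#' Initialize a model
#'
#' @param config an [model_config()]
#' @param tv_channels character vector of temporal channel names (time-varying
#'   variables, auxiliary indicators, elapsed-time channels)
#' @param static_names character vector of time-invariant variable names
#' @return list of class `hd_model`
#' @export
init_model <- function(config, tv_channels, static_names) {
  set.seed(config$seed)
  H <- config$hidden
  V <- length(tv_channels)
  K <- config$k_prev
  n_s <- length(static_names)
  P <- list()
  masks <- list(tv = hd_block_mask(V, H), tv_emb = hd_emb_mask(V, H))
  P$embt.W <- hd_emb_init(V, H); P$embt.b <- hd_zeros_row(V * H)
  if (config$variant == "tft") {
    P <- hd_add_params(P, "grnt", hd_grn_bank_params(V, H))
    P <- hd_add_params(P, "sel_t", hd_grn_params(V * H, V, H, ctx = TRUE))
    Vs <- n_s + K
    masks$st <- hd_block_mask(Vs, H)
    masks$st_emb <- hd_emb_mask(n_s, H)
    P$embs.W <- hd_emb_init(n_s, H); P$embs.b <- hd_zeros_row(n_s * H)
    P <- hd_add_params(P, "grns", hd_grn_bank_params(Vs, H))
    P <- hd_add_params(P, "sel_s", hd_grn_params(Vs * H, Vs, H))
    P$h0.W <- hd_glorot(H, H); P$h0.b <- hd_zeros_row(H)
  } else {
    P$cat_t.W <- hd_glorot(V * H, H); P$cat_t.b <- hd_zeros_row(H)
    P$cat_s.W <- hd_glorot(n_s, H); P$cat_s.b <- hd_zeros_row(H)
  }
  for (g in c("z", "r", "n")) {
    P[[paste0("gru.W", g)]] <- hd_glorot(H, H)
    P[[paste0("gru.U", g)]] <- hd_glorot(H, H)
    P[[paste0("gru.b", g)]] <- hd_zeros_row(H)
  }
  if (config$variant == "tft") {
    P <- hd_add_params(P, "glu_gru",
                       list(W1 = hd_glorot(H, H), b1 = hd_zeros_row(H),
                            W2 = hd_glorot(H, H), b2 = hd_zeros_row(H)))
    P <- hd_add_params(P, "grn_attn", hd_grn_params(H, H, H))
    P$att.Wq <- hd_glorot(H, H); P$att.Wk <- hd_glorot(H, H)
    P$att.Wv <- hd_glorot(H, H)
    P <- hd_add_params(P, "glu_att",
                       list(W1 = hd_glorot(H, H), b1 = hd_zeros_row(H),
                            W2 = hd_glorot(H, H), b2 = hd_zeros_row(H)))
    P <- hd_add_params(P, "grn_cls", hd_grn_params(H, H, H))
  }
  P$out.W <- hd_glorot(H, 3L); P$out.b <- hd_zeros_row(3L)
  structure(list(config = config, params = P, masks = masks,
                 tv_channels = tv_channels, static_names = static_names,
                 H = H, V = V, K = K, n_static = n_s),
            class = "hd_model")
}

## ---- graph builders ----

# Dense GRN forward on the tape; pid = named list of parameter leaf ids.
hd_grn_fw <- function(tp, pid, prefix, x, ctx = NULL) {
  gp <- function(nm) pid[[paste0(prefix, ".", nm)]]
  a <- ad_bias(tp, ad_mm(tp, x, gp("W2")), gp("b2"))
  if (!is.null(ctx)) a <- ad_add(tp, a, ad_mm(tp, ctx, gp("Wc")))
  a <- ad_elu(tp, a)
  eta <- ad_bias(tp, ad_mm(tp, a, gp("W1")), gp("b1"))
  gate <- ad_sigmoid(tp, ad_bias(tp, ad_mm(tp, eta, gp("W4")), gp("b4")))
  lin <- ad_bias(tp, ad_mm(tp, eta, gp("W5")), gp("b5"))
  glu <- ad_emul(tp, gate, lin)
  skip <- if (is.null(gp("Ws"))) x else ad_mm(tp, x, gp("Ws"))
  ad_add(tp, skip, glu)
}

# Bank of V parallel GRNs (block-diagonal weights) as a single fused op.
hd_grn_bank_fw <- function(tp, pid, prefix, x, V, H) {
  gp <- function(nm) pid[[paste0(prefix, ".", nm)]]
  ad_grn_bank(tp, x, gp("W2"), gp("b2"), gp("W1"), gp("b1"),
              gp("W4"), gp("b4"), gp("W5"), gp("b5"), V, H)
}

hd_glu_residual <- function(tp, pid, prefix, x, resid) {
  gp <- function(nm) pid[[paste0(prefix, ".", nm)]]
  gate <- ad_sigmoid(tp, ad_bias(tp, ad_mm(tp, x, gp("W1")), gp("b1")))
  lin <- ad_bias(tp, ad_mm(tp, x, gp("W2")), gp("b2"))
  ad_add(tp, resid, ad_emul(tp, gate, lin))
}

hd_dropout_mask <- function(n, p, H) {
  matrix(stats::rbinom(n * H, 1L, 1 - p) / (1 - p), n, H)
}

hd_v <- function(tp, id) ad_value(tp, id)

# GRU over a fused time-major sequence; returns the (B*Tmax) x H output.
hd_gru_fw <- function(tp, pid, fused, pad, B, Tmax, h0) {
  h <- h0
  outs <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    x_t <- ad_rows(tp, fused, rows)
    m <- pad[rows]
    z <- ad_sigmoid(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x_t, pid$gru.Wz),
                                           ad_mm(tp, h, pid$gru.Uz)),
                                pid$gru.bz))
    r <- ad_sigmoid(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x_t, pid$gru.Wr),
                                           ad_mm(tp, h, pid$gru.Ur)),
                                pid$gru.br))
    nn <- ad_tanh(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x_t, pid$gru.Wn),
                                         ad_mm(tp, ad_emul(tp, r, h),
                                               pid$gru.Un)),
                              pid$gru.bn))
    # h' = z * h + (1 - z) * n, written as z*h + n - z*n
    hn <- ad_add(tp, ad_emul(tp, z, h),
                 ad_add(tp, nn, ad_scale(tp, ad_emul(tp, z, nn), -1)))
    # padded positions carry the previous state through unchanged
    h <- ad_add(tp, ad_cmul_const(tp, hn, m), ad_cmul_const(tp, h, 1 - m))
    outs[[t]] <- h
  }
  ad_rbind(tp, outs)
}

# Block-causal attention mask over a time-major batch layout: query row
# (tq, b) may attend to key rows (tk, b) with tk <= min(tq, Tb[b]); padded
# query rows keep a self-loop so the softmax stays defined.
hd_att_mask <- function(B, Tmax, Tb) {
  N <- B * Tmax
  M <- diag(N)
  for (b in seq_len(B)) {
    idx <- b + B * (seq_len(Tb[b]) - 1L)
    for (qi in seq_len(Tb[b])) M[idx[qi], idx[seq_len(qi)]] <- 1
  }
  M
}

# Shared temporal encoder: embeddings -> per-channel GRN bank -> variable
# selection -> GRU -> gated residual -> causal single-headed attention ->
# gated residual. Returns ids for the terminal representation and the
# selection weights, plus the attention-weight node.
hd_encode_temporal <- function(tp, pid, model, X, pad, Tb, B, Tmax,
                               ctx = NULL, h0 = NULL, drop = 0) {
  H <- model$H; V <- model$V
  N <- B * Tmax
  Xid <- ad_leaf(tp, X)
  emb <- ad_bias(tp, ad_mm_masked(tp, Xid, pid$embt.W, model$masks$tv_emb),
                 pid$embt.b)
  if (model$config$variant == "rnn") {
    fused <- ad_elu(tp, ad_bias(tp, ad_mm(tp, emb, pid$cat_t.W), pid$cat_t.b))
    selw <- NULL
  } else {
    trans <- hd_grn_bank_fw(tp, pid, "grnt", emb, V, H)
    ctxN <- if (is.null(ctx)) NULL else ad_rows(tp, ctx, rep(seq_len(B), Tmax))
    logits <- hd_grn_fw(tp, pid, "sel_t", emb, ctxN)
    selw <- ad_softmax_masked(tp, logits, matrix(1, N, V))
    fused <- ad_wsum_channels(tp, trans, selw, V, H)
  }
  if (drop > 0)
    fused <- ad_emul(tp, fused, ad_leaf(tp, hd_dropout_mask(N, drop, H)))
  if (is.null(h0)) h0 <- ad_leaf(tp, matrix(0, B, H))
  seq_out <- hd_gru_fw(tp, pid, fused, pad, B, Tmax, h0)
  if (model$config$variant == "rnn")
    return(list(rep = seq_out, selw = NULL, attn = NULL))

  tempin <- hd_glu_residual(tp, pid, "glu_gru", seq_out, fused)
  ain <- hd_grn_fw(tp, pid, "grn_attn", tempin)
  Q <- ad_mm(tp, ain, pid$att.Wq)
  Kk <- ad_mm(tp, ain, pid$att.Wk)
  Vv <- ad_mm(tp, ain, pid$att.Wv)
  sc <- ad_scale(tp, ad_mm_t(tp, Q, Kk), 1 / sqrt(H))
  w <- ad_softmax_masked(tp, sc, hd_att_mask(B, Tmax, Tb))
  att <- ad_mm(tp, w, Vv)
  if (drop > 0)
    att <- ad_emul(tp, att, ad_leaf(tp, hd_dropout_mask(N, drop, H)))
  rep_out <- hd_glu_residual(tp, pid, "glu_att", att, tempin)
  list(rep = rep_out, selw = selw, attn = w)
}

# Assemble a minibatch from bundles; time-major layout (row (t-1)*B + b).
hd_make_batch <- function(bundles, K, max_timesteps) {
  B <- length(bundles)
  Tb <- pmin(vapply(bundles, function(b) b$T, 0L), max_timesteps)
  Tmax <- max(Tb)
  V <- ncol(bundles[[1L]]$xtv)
  n_s <- length(bundles[[1L]]$static)
  X <- matrix(0, B * Tmax, V)
  pad <- numeric(B * Tmax)
  labels <- matrix(0, B * Tmax, 3L)
  lmask <- matrix(0, B * Tmax, 3L)
  S <- matrix(0, B, n_s)
  for (b in seq_len(B)) {
    bd <- bundles[[b]]
    rows <- b + B * (seq_len(Tb[b]) - 1L)
    X[rows, ] <- bd$xtv[seq_len(Tb[b]), , drop = FALSE]
    pad[rows] <- 1
    labels[rows, ] <- bd$labels[seq_len(Tb[b]), , drop = FALSE]
    lmask[rows, ] <- bd$lmask[seq_len(Tb[b]), , drop = FALSE]
    S[b, ] <- bd$static
  }
  prev_avail <- matrix(0, B, max(K, 1L))
  prev <- NULL
  if (K > 0L) {
    ow <- integer(0); sl <- integer(0); xs <- list(); Ts <- integer(0)
    for (b in seq_len(B)) {
      bd <- bundles[[b]]
      kk <- min(K, length(bd$prev_avail))
      for (k in seq_len(kk)) {
        if (!isTRUE(bd$prev_avail[k]) || is.null(bd$prev[[k]])) next
        prev_avail[b, k] <- 1
        ow <- c(ow, b); sl <- c(sl, k)
        xp <- bd$prev[[k]]$x
        if (nrow(xp) > max_timesteps) xp <- xp[seq_len(max_timesteps), , drop = FALSE]
        xs[[length(xs) + 1L]] <- xp
        Ts <- c(Ts, nrow(xp))
      }
    }
    if (length(xs)) {
      B2 <- length(xs)
      T2 <- max(Ts)
      X2 <- matrix(0, B2 * T2, V)
      pad2 <- numeric(B2 * T2)
      for (i in seq_len(B2)) {
        rows <- i + B2 * (seq_len(Ts[i]) - 1L)
        X2[rows, ] <- xs[[i]]
        pad2[rows] <- 1
      }
      prev <- list(X = X2, pad = pad2, Tb = Ts, B = B2, Tmax = T2,
                   owner = ow, slot = sl)
    }
  }
  list(B = B, Tmax = Tmax, Tb = Tb, X = X, pad = pad, S = S,
       labels = labels, lmask = lmask, prev = prev, prev_avail = prev_avail)
}

# Full forward pass; returns tape plus ids and extracted values.
hd_forward <- function(model, batch, train = FALSE, collect = FALSE) {
  cfg <- model$config
  H <- model$H; K <- model$K
  B <- batch$B; Tmax <- batch$Tmax
  drop <- if (train) cfg$dropout else 0
  tp <- ad_tape()
  pid <- lapply(model$params, function(m) ad_leaf(tp, m))

  static_w <- NULL; attn_id <- NULL; selw_id <- NULL
  if (cfg$variant == "rnn") {
    sS <- ad_leaf(tp, batch$S)
    ctx <- ad_tanh(tp, ad_bias(tp, ad_mm(tp, sS, pid$cat_s.W), pid$cat_s.b))
    enc <- hd_encode_temporal(tp, pid, model, batch$X, batch$pad, batch$Tb,
                              B, Tmax, ctx = NULL, h0 = ctx, drop = drop)
    logits <- ad_bias(tp, ad_mm(tp, enc$rep, pid$out.W), pid$out.b)
  } else {
    # previous-session stacks through the shared temporal encoder
    slot_ids <- vector("list", K)
    if (K > 0L) {
      if (!is.null(batch$prev)) {
        pv <- batch$prev
        penc <- hd_encode_temporal(tp, pid, model, pv$X, pv$pad, pv$Tb,
                                   pv$B, pv$Tmax, drop = drop)
        last_idx <- vapply(seq_len(pv$B),
                           function(i) i + pv$B * (pv$Tb[i] - 1L), 0L)
        rep2 <- ad_rows(tp, penc$rep, last_idx)
        for (k in seq_len(K)) {
          sr <- which(pv$slot == k)
          slot_ids[[k]] <- if (length(sr))
            ad_rows_into(tp, list(ad_rows(tp, rep2, sr)),
                         list(pv$owner[sr]), B)
          else ad_leaf(tp, matrix(0, B, H))
        }
      } else {
        for (k in seq_len(K)) slot_ids[[k]] <- ad_leaf(tp, matrix(0, B, H))
      }
    }
    n_s <- model$n_static
    Vs <- n_s + K
    sS <- ad_leaf(tp, batch$S)
    emb_sc <- ad_bias(tp, ad_mm_masked(tp, sS, pid$embs.W,
                                       model$masks$st_emb), pid$embs.b)
    emb_s <- if (K > 0L) ad_cbind(tp, c(list(emb_sc), slot_ids)) else emb_sc
    trans_s <- hd_grn_bank_fw(tp, pid, "grns", emb_s, Vs, H)
    logit_s <- hd_grn_fw(tp, pid, "sel_s", emb_s)
    mask_s <- cbind(matrix(1, B, n_s),
                    if (K > 0L) batch$prev_avail[, seq_len(K), drop = FALSE])
    w_s <- ad_softmax_masked(tp, logit_s, mask_s)
    ctx <- ad_wsum_channels(tp, trans_s, w_s, Vs, H)
    h0 <- ad_tanh(tp, ad_bias(tp, ad_mm(tp, ctx, pid$h0.W), pid$h0.b))
    enc <- hd_encode_temporal(tp, pid, model, batch$X, batch$pad, batch$Tb,
                              B, Tmax, ctx = ctx, h0 = h0, drop = drop)
    cls <- hd_grn_fw(tp, pid, "grn_cls", enc$rep)
    logits <- ad_bias(tp, ad_mm(tp, cls, pid$out.W), pid$out.b)
    static_w <- hd_v(tp, w_s)
    selw_id <- enc$selw
    attn_id <- enc$attn
  }
  lmask_eff <- batch$lmask * batch$pad
  loss <- ad_bce_masked(tp, logits, batch$labels, lmask_eff)
  out <- list(tp = tp, pid = pid, loss = loss, logits = logits,
              prob = 1 / (1 + exp(-hd_v(tp, logits))),
              loss_value = hd_v(tp, loss)[1L, 1L],
              mask_sum = sum(lmask_eff))
  if (collect) {
    out$static_weights <- static_w
    out$tv_weights <- if (!is.null(selw_id)) hd_v(tp, selw_id) else NULL
    if (!is.null(attn_id)) {
      aw <- hd_v(tp, attn_id)
      out$attention <- lapply(seq_len(B), function(b) {
        idx <- b + B * (seq_len(batch$Tb[b]) - 1L)
        aw[idx, idx, drop = FALSE]
      })
    }
  }
  out
}

## ---- training ----

#' Train a model
#'
#' Minimizes the mean masked binary cross-entropy over the three outcome
#' heads with Adam, early-stopping on validation loss. Deterministic for a
#' fixed seed in single-threaded mode.
#'
#' @param train,validation lists of `hd_bundle`
#' @param config an [model_config()]
#' @param verbose print per-epoch losses
#' @return `hd_model` with fitted parameters and a `log` data.frame of
#'   per-epoch training and validation loss
#' @export
train_model <- function(train, validation, config = model_config(),
                        verbose = FALSE) {
  if (!length(train)) hd_stop("empty training set", "hdtft_train_error")
  b1 <- train[[1L]]
  model <- init_model(config, colnames(b1$xtv), names(b1$static))
  P <- model$params
  mstate <- lapply(P, function(m) m * 0)
  vstate <- lapply(P, function(m) m * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = P, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  n <- length(train)
  bs <- config$batch_size
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    tl_num <- 0; tl_den <- 0
    for (start in seq(1L, n, by = bs)) {
      ix <- ord[start:min(start + bs - 1L, n)]
      batch <- hd_make_batch(train[ix], model$K, config$max_timesteps)
      model$params <- P
      fw <- hd_forward(model, batch, train = TRUE)
      if (!is.finite(fw$loss_value))
        hd_stop(sprintf("non-finite loss at epoch %d", epoch),
                "hdtft_train_error")
      tl_num <- tl_num + fw$loss_value * fw$mask_sum
      tl_den <- tl_den + fw$mask_sum
      ad_backward(fw$tp, fw$loss)
      grads <- lapply(fw$pid, function(id) ad_grad(fw$tp, id))
      gn2 <- 0
      for (nm in names(P)) if (!is.null(grads[[nm]]))
        gn2 <- gn2 + sum(grads[[nm]]^2)
      scale <- if (sqrt(gn2) > config$grad_clip)
        config$grad_clip / sqrt(gn2) else 1
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(P)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        g <- g * scale
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        P[[nm]] <- P[[nm]] - config$learning_rate *
          (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + eps)
      }
    }
    model$params <- P
    vl <- if (length(validation)) hd_eval_loss(model, validation) else
      tl_num / max(tl_den, 1)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = tl_num / max(tl_den, 1),
                                 val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", epoch,
                      tl_num / max(tl_den, 1), vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = P, epoch = epoch)
    } else if (epoch - best$epoch >= config$early_stopping_patience) {
      break
    }
  }
  model$params <- best$params
  model$log <- log
  model$best_epoch <- best$epoch
  model
}

# Mask-weighted mean loss over a bundle list (no dropout).
hd_eval_loss <- function(model, bundles, batch_size = 64L) {
  num <- 0; den <- 0
  for (start in seq(1L, length(bundles), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, length(bundles))
    batch <- hd_make_batch(bundles[ix], model$K, model$config$max_timesteps)
    fw <- hd_forward(model, batch, train = FALSE)
    num <- num + fw$loss_value * fw$mask_sum
    den <- den + fw$mask_sum
  }
  num / max(den, 1)
}

#' Predict per-timestamp outcome probabilities
#'
#' @param model a trained `hd_model`
#' @param bundles list of `hd_bundle`
#' @param batch_size sessions per forward pass
#' @return data.frame with one row per recorded timestep: ids, `elapsed_min`,
#'   `prob_*`, `label_*`, and `mask_*` columns (mask 1 where the label is
#'   defined)
#' @export
predict_model <- function(model, bundles, batch_size = 64L) {
  out <- list()
  heads <- c("idh1", "idh2", "idhtn")
  for (start in seq(1L, length(bundles), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, length(bundles))
    batch <- hd_make_batch(bundles[ix], model$K, model$config$max_timesteps)
    fw <- hd_forward(model, batch, train = FALSE)
    B <- batch$B
    for (b in seq_len(B)) {
      bd <- bundles[[ix[b]]]
      Tn <- batch$Tb[b]
      rows <- b + B * (seq_len(Tn) - 1L)
      df <- data.frame(session_id = bd$session_id, patient_id = bd$patient_id,
                       elapsed_min = bd$elapsed_min[seq_len(Tn)])
      for (h in seq_along(heads)) {
        df[[paste0("prob_", heads[h])]] <- fw$prob[rows, h]
        df[[paste0("label_", heads[h])]] <- batch$labels[rows, h]
        df[[paste0("mask_", heads[h])]] <- batch$lmask[rows, h]
      }
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the model configuration and a hash of the variable
#' layout so that a checkpoint cannot silently be applied to data prepared
#' under a different schema.
#'
#' @param model an `hd_model`
#' @param path file path (RDS)
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  model$schema_hash <- hd_config_hash(list(model$tv_channels,
                                           model$static_names))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  want <- hd_config_hash(list(model$tv_channels, model$static_names))
  if (!identical(model$schema_hash, want))
    hd_stop("checkpoint schema hash mismatch", "hdtft_pipeline_error")
  model
}
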