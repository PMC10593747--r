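# Minimal reverse-mode automatic differentiation over dense matrices.
#
# No deep-learning runtime is assumed: the temporal-fusion network in this
# package is expressed as a tape of matrix operations built per forward pass,
# and gradients are obtained by walking the tape backwards. Nodes are integer
# handles; values, parent lists and backward closures live in hashed
# environments keyed by the node id (constant-time insertion, no
# copy-on-write of a growing list). Only the operations the network needs
# are implemented, and every operation is covered by a finite-difference
# gradient check in the test suite.

# Cached integer->character keys for environment indexing.
.hd_keys <- as.character(seq_len(131072L))

hd_key <- function(i) if (i <= 131072L) .hd_keys[i] else as.character(i)

ad_tape <- function(capacity = 4096L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- new.env(hash = TRUE, parent = emptyenv(), size = capacity)
  tp$parents <- new.env(hash = TRUE, parent = emptyenv(), size = capacity)
  tp$bw <- new.env(hash = TRUE, parent = emptyenv(), size = capacity)
  tp$n <- 0L
  tp
}

ad_push <- function(tp, val, parents = NULL, bw = NULL) {
  n <- tp$n + 1L
  key <- hd_key(n)
  tp$vals[[key]] <- val
  if (!is.null(parents)) {
    tp$parents[[key]] <- parents
    tp$bw[[key]] <- bw
  }
  tp$n <- n
  n
}

ad_value <- function(tp, id) tp$vals[[hd_key(id)]]

ad_leaf <- function(tp, val) ad_push(tp, val)

# Walk the tape backwards accumulating gradients into tp$grads.
ad_backward <- function(tp, loss_id) {
  gr <- new.env(hash = TRUE, parent = emptyenv(), size = tp$n)
  lv <- tp$vals[[hd_key(loss_id)]]
  gr[[hd_key(loss_id)]] <- matrix(1, nrow(lv), ncol(lv))
  for (i in seq.int(tp$n, 1L)) {
    key <- hd_key(i)
    g <- gr[[key]]
    if (is.null(g)) next
    f <- tp$bw[[key]]
    if (is.null(f)) next
    pg <- f(g)
    ps <- tp$parents[[key]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      pk <- hd_key(ps[[j]])
      old <- gr[[pk]]
      gr[[pk]] <- if (is.null(old)) gj else old + gj
    }
  }
  tp$grads <- gr
  invisible(gr)
}

ad_grad <- function(tp, id) tp$grads[[hd_key(id)]]

## ---- primitive operations ----
# Every op forces its node-id arguments before touching the tape, since a
# nested call (e.g. ad_bias(tp, ad_mm(...), b)) must push its node first.

ad_mm <- function(tp, a, b) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), crossprod(va, g)))
}

# a %*% t(b)
ad_mm_t <- function(tp, a, b) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, tcrossprod(va, vb), c(a, b),
          function(g) list(g %*% vb, crossprod(g, va)))
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, ad_value(tp, a) + ad_value(tp, b), c(a, b),
          function(g) list(g, g))
}

# Add a 1 x p bias row to every row of a.
ad_bias <- function(tp, a, b) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, va + matrix(vb, nrow(va), ncol(va), byrow = TRUE), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_emul <- function(tp, a, b) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, va * vb, c(a, b),
          function(g) list(g * vb, g * va))
}

# Elementwise product with an n x 1 column node, broadcast across columns.
ad_cmul <- function(tp, a, b) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- as.vector(ad_value(tp, b))
  ad_push(tp, va * vb, c(a, b),
          function(g) list(g * vb, matrix(rowSums(g * va), ncol = 1L)))
}

# Elementwise product with a constant column vector (no gradient for it).
ad_cmul_const <- function(tp, a, cv) {
  force(a)
  cv <- as.vector(cv)
  va <- ad_value(tp, a)
  ad_push(tp, va * cv, a, function(g) list(g * cv))
}

ad_scale <- function(tp, a, k) {
  force(a)
  ad_push(tp, ad_value(tp, a) * k, a, function(g) list(g * k))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  s <- 1 / (1 + exp(-ad_value(tp, a)))
  ad_push(tp, s, a, function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tp, a) {
  force(a)
  s <- tanh(ad_value(tp, a))
  ad_push(tp, s, a, function(g) list(g * (1 - s^2)))
}

ad_elu <- function(tp, a) {
  force(a)
  v <- ad_value(tp, a)
  neg <- v <= 0
  s <- v
  s[neg] <- expm1(v[neg])
  d <- matrix(1, nrow(v), ncol(v))
  d[neg] <- exp(v[neg])
  ad_push(tp, s, a, function(g) list(g * d))
}

# Scalar embedding of one input channel: outer(x, w) + bias, where x is a
# constant numeric vector and w, b are 1 x H parameter rows.
ad_outer <- function(tp, x, w, b) {
  force(w); force(b)
  vw <- ad_value(tp, w); vb <- ad_value(tp, b)
  val <- outer(x, as.vector(vw)) +
    matrix(vb, length(x), length(vb), byrow = TRUE)
  ad_push(tp, val, c(w, b),
          function(g) list(crossprod(matrix(x, ncol = 1L), g),
                           matrix(colSums(g), 1L)))
}

# Row slice; duplicate indices are allowed (gradients accumulate).
ad_rows <- function(tp, a, idx) {
  force(a)
  va <- ad_value(tp, a)
  nr <- nrow(va); nc <- ncol(va)
  ad_push(tp, va[idx, , drop = FALSE], a, function(g) {
    G <- matrix(0, nr, nc)
    if (anyDuplicated(idx)) {
      agg <- rowsum(g, group = idx)
      G[as.integer(rownames(agg)), ] <- agg
    } else {
      G[idx, ] <- g
    }
    list(G)
  })
}

ad_col <- function(tp, a, j) {
  force(a)
  va <- ad_value(tp, a)
  nr <- nrow(va); nc <- ncol(va)
  ad_push(tp, va[, j, drop = FALSE], a, function(g) {
    G <- matrix(0, nr, nc)
    G[, j] <- g
    list(G)
  })
}

# Scatter several row blocks into a zero matrix of n rows (disjoint indices).
ad_rows_into <- function(tp, ids, idxs, n) {
  ids <- vapply(ids, identity, 0L)
  nc <- ncol(ad_value(tp, ids[[1L]]))
  val <- matrix(0, n, nc)
  for (i in seq_along(ids)) val[idxs[[i]], ] <- ad_value(tp, ids[[i]])
  ad_push(tp, val, ids, function(g) {
    lapply(idxs, function(ix) g[ix, , drop = FALSE])
  })
}

ad_rbind <- function(tp, ids) {
  ids <- vapply(ids, identity, 0L)
  vals <- lapply(ids, function(i) ad_value(tp, i))
  nrs <- vapply(vals, nrow, 0L)
  ends <- cumsum(nrs)
  starts <- ends - nrs + 1L
  ad_push(tp, do.call(rbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cbind <- function(tp, ids) {
  ids <- vapply(ids, identity, 0L)
  vals <- lapply(ids, function(i) ad_value(tp, i))
  ncs <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  ad_push(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# Row-wise softmax restricted to positions where mask == 1; masked positions
# are exactly 0 in the output (and receive zero gradient).
ad_softmax_masked <- function(tp, a, mask) {
  force(a)
  v <- ad_value(tp, a)
  z <- v
  z[mask <= 0] <- -Inf
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e[mask <= 0] <- 0
  s <- e / rowSums(e)
  ad_push(tp, s, a, function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Masked mean binary cross-entropy from logits; y and m are constant matrices
# the same shape as the logits. Returns a 1 x 1 scalar node.
ad_bce_masked <- function(tp, logits, y, m) {
  force(logits)
  l <- ad_value(tp, logits)
  sp <- pmax(l, 0) + log1p(exp(-abs(l)))
  denom <- max(1, sum(m))
  val <- sum(m * (sp - y * l)) / denom
  ad_push(tp, matrix(val, 1L, 1L), logits, function(g) {
    list(as.vector(g) * m * (1 / (1 + exp(-l)) - y) / denom)
  })
}

# Matrix product where the right operand's gradient is elementwise-masked
# (used for block-diagonal parameter matrices: off-block entries are zero at
# initialization and their gradient is forced to zero, so they stay zero).
ad_mm_masked <- function(tp, a, b, mask) {
  force(a); force(b)
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), crossprod(va, g) * mask))
}

# Channel-weighted sum: a is [N x V*H] (channel-major blocks of width H),
# w is [N x V] simplex weights; returns [N x H] = sum_v w[, v] * a[, block v].
ad_wsum_channels <- function(tp, a, w, V, H) {
  force(a); force(w)
  va <- ad_value(tp, a); vw <- ad_value(tp, w)
  n <- nrow(va)
  wExp <- vw[, rep(seq_len(V), each = H), drop = FALSE]
  prod <- va * wExp
  dim(prod) <- c(n, H, V)
  val <- rowSums(prod, dims = 2L)
  ad_push(tp, val, c(a, w), function(g) {
    gTile <- g[, rep(seq_len(H), V), drop = FALSE]
    pw <- va * gTile
    dim(pw) <- c(n, H, V)
    gW <- rowSums(aperm(pw, c(1L, 3L, 2L)), dims = 2L)
    list(gTile * wExp, gW)
  })
}

# A bank of V parallel GRN blocks (H -> H each) as ONE tape node. Parameters
# are block-diagonal matrices (only diagonal blocks are touched); x is
# [N x V*H] in channel-major blocks. Forward and backward loop over the
# channels with plain matrix algebra, avoiding both per-channel tape nodes
# and dense V*H x V*H products.
ad_grn_bank <- function(tp, x, W2, b2, W1, b1, W4, b4, W5, b5, V, H) {
  force(x); force(W2); force(b2); force(W1); force(b1)
  force(W4); force(b4); force(W5); force(b5)
  vx <- ad_value(tp, x)
  vW2 <- ad_value(tp, W2); vb2 <- as.vector(ad_value(tp, b2))
  vW1 <- ad_value(tp, W1); vb1 <- as.vector(ad_value(tp, b1))
  vW4 <- ad_value(tp, W4); vb4 <- as.vector(ad_value(tp, b4))
  vW5 <- ad_value(tp, W5); vb5 <- as.vector(ad_value(tp, b5))
  n <- nrow(vx)
  sig <- function(v) 1 / (1 + exp(-v))
  out <- vx
  keep <- vector("list", V)
  for (v in seq_len(V)) {
    ix <- ((v - 1L) * H + 1L):(v * H)
    xv <- vx[, ix, drop = FALSE]
    pre <- xv %*% vW2[ix, ix] + rep(vb2[ix], each = n)
    neg <- pre <= 0
    av <- pre
    av[neg] <- expm1(pre[neg])
    eta <- av %*% vW1[ix, ix] + rep(vb1[ix], each = n)
    gv <- sig(eta %*% vW4[ix, ix] + rep(vb4[ix], each = n))
    lv <- eta %*% vW5[ix, ix] + rep(vb5[ix], each = n)
    out[, ix] <- xv + gv * lv
    keep[[v]] <- list(pre = pre, neg = neg, a = av, eta = eta, g = gv,
                      l = lv)
  }
  ad_push(tp, out, c(x, W2, b2, W1, b1, W4, b4, W5, b5), function(g) {
    gX <- g
    gW2 <- vW2 * 0; gW1 <- vW1 * 0; gW4 <- vW4 * 0; gW5 <- vW5 * 0
    gb2 <- vb2 * 0; gb1 <- vb1 * 0; gb4 <- vb4 * 0; gb5 <- vb5 * 0
    for (v in seq_len(V)) {
      ix <- ((v - 1L) * H + 1L):(v * H)
      k <- keep[[v]]
      go <- g[, ix, drop = FALSE]
      xv <- vx[, ix, drop = FALSE]
      gGate <- go * k$l * k$g * (1 - k$g)
      gLin <- go * k$g
      gW4[ix, ix] <- crossprod(k$eta, gGate)
      gb4[ix] <- colSums(gGate)
      gW5[ix, ix] <- crossprod(k$eta, gLin)
      gb5[ix] <- colSums(gLin)
      gEta <- tcrossprod(gGate, vW4[ix, ix]) + tcrossprod(gLin, vW5[ix, ix])
      gW1[ix, ix] <- crossprod(k$a, gEta)
      gb1[ix] <- colSums(gEta)
      gA <- tcrossprod(gEta, vW1[ix, ix])
      gPre <- gA
      gPre[k$neg] <- gA[k$neg] * exp(k$pre[k$neg])
      gW2[ix, ix] <- crossprod(xv, gPre)
      gb2[ix] <- colSums(gPre)
      gX[, ix] <- go + tcrossprod(gPre, vW2[ix, ix])
    }
    list(gX, gW2, matrix(gb2, 1L), gW1, matrix(gb1, 1L),
         gW4, matrix(gb4, 1L), gW5, matrix(gb5, 1L))
  })
}
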