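# Numeric core: dense layers, layer normalization, multihead self-attention,
# co-attention, GELU feed-forward blocks, softmax cross-entropy and Adam,
# all with hand-derived backward passes.  Layout convention: a batch of S
# subjects with T tokens each is a (S*T) x k matrix, subject-major (subject
# 1's T rows first).  Linear algebra is delegated to BLAS via %*%; the
# per-subject attention loops are the only scalar R loops.

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

init_linear <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / (d_in + d_out))), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(X, p) add_bias(X %*% p$W, p$b)
linear_bwd <- function(dY, X, p) {
  list(dX = dY %*% t(p$W), dW = crossprod(X, dY), db = colSums(dY))
}

# GELU, sigmoid approximation: x * sigmoid(1.702 x)
gelu <- function(x) x / (1 + exp(-1.702 * x))
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

softmax_rows <- function(X) {
  mx <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  E <- exp(X - mx)
  E / rowSums(E)
}
# dX for Y = softmax_rows(X): rows independent
softmax_rows_bwd <- function(dY, Y) Y * (dY - rowSums(dY * Y))

init_layernorm <- function(k) list(g = rep(1, k), b = numeric(k))

layernorm_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(Y = add_bias(xhat * rep(p$g, each = nrow(X)), p$b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, p) {
  n <- nrow(dY)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(p$g, each = n)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dg = dg, db = db)
}

init_mha <- function(k) {
  list(q = init_linear(k, k), k = init_linear(k, k),
       v = init_linear(k, k), o = init_linear(k, k))
}

# Multihead scaled-dot-product self-attention over S subject blocks of Tn
# tokens.  Returns the attention tensor (Tn x Tn x heads x S) in the cache;
# every row of every head's weight matrix is a probability vector.
mha_fwd <- function(X, p, S, Tn, h) {
  k <- ncol(X)
  dh <- k / h
  sc <- 1 / sqrt(dh)
  Q <- linear_fwd(X, p$q); K <- linear_fwd(X, p$k); V <- linear_fwd(X, p$v)
  Ctx <- matrix(0, nrow(X), k)
  A <- array(0, c(Tn, Tn, h, S))
  for (s in seq_len(S)) {
    idx <- ((s - 1L) * Tn + 1L):(s * Tn)
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dh + 1L):(j * dh)
      Aj <- softmax_rows(tcrossprod(Q[idx, cols, drop = FALSE],
                                    K[idx, cols, drop = FALSE]) * sc)
      A[, , j, s] <- Aj
      Ctx[idx, cols] <- Aj %*% V[idx, cols, drop = FALSE]
    }
  }
  Out <- linear_fwd(Ctx, p$o)
  list(Out = Out, cache = list(X = X, Q = Q, K = K, V = V, Ctx = Ctx, A = A,
                               S = S, Tn = Tn, h = h))
}

mha_bwd <- function(dOut, cache, p) {
  X <- cache$X; S <- cache$S; Tn <- cache$Tn; h <- cache$h
  k <- ncol(X); dh <- k / h; sc <- 1 / sqrt(dh)
  bo <- linear_bwd(dOut, cache$Ctx, p$o)
  dCtx <- bo$dX
  dQ <- matrix(0, nrow(X), k); dK <- dQ; dV <- dQ
  for (s in seq_len(S)) {
    idx <- ((s - 1L) * Tn + 1L):(s * Tn)
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * dh + 1L):(j * dh)
      Aj <- cache$A[, , j, s]
      dC <- dCtx[idx, cols, drop = FALSE]
      dA <- tcrossprod(dC, cache$V[idx, cols, drop = FALSE])
      dV[idx, cols] <- crossprod(Aj, dC)
      dS <- softmax_rows_bwd(dA, Aj) * sc
      dQ[idx, cols] <- dS %*% cache$K[idx, cols, drop = FALSE]
      dK[idx, cols] <- crossprod(dS, cache$Q[idx, cols, drop = FALSE])
    }
  }
  bq <- linear_bwd(dQ, X, p$q); bk <- linear_bwd(dK, X, p$k); bv <- linear_bwd(dV, X, p$v)
  list(dX = bq$dX + bk$dX + bv$dX,
       grads = list(q = list(W = bq$dW, b = bq$db), k = list(W = bk$dW, b = bk$db),
                    v = list(W = bv$dW, b = bv$db), o = list(W = bo$dW, b = bo$db)))
}

init_ff <- function(k, mult = 4L) {
  list(l1 = init_linear(k, k * mult), l2 = init_linear(k * mult, k))
}

ff_fwd <- function(X, p) {
  H <- linear_fwd(X, p$l1)
  G <- gelu(H)
  list(Y = linear_fwd(G, p$l2), H = H, G = G)
}

ff_bwd <- function(dY, cache, X, p) {
  b2 <- linear_bwd(dY, cache$G, p$l2)
  dH <- b2$dX * gelu_grad(cache$H)
  b1 <- linear_bwd(dH, X, p$l1)
  list(dX = b1$dX,
       grads = list(l1 = list(W = b1$dW, b = b1$db), l2 = list(W = b2$dW, b = b2$db)))
}

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

init_encoder_layer <- function(k, ff_mult = 4L) {
  list(ln1 = init_layernorm(k), mha = init_mha(k),
       ln2 = init_layernorm(k), ff = init_ff(k, ff_mult))
}

# Pre-LN transformer layer:
#   X' = MHA(LN(X)) + X ;  Y = FF(LN(X')) + X'
# (normalization before each sublayer, residual from the un-normalized input)
encoder_layer_fwd <- function(X, p, S, Tn, h, dropout = 0, train = FALSE) {
  l1 <- layernorm_fwd(X, p$ln1)
  at <- mha_fwd(l1$Y, p$mha, S, Tn, h)
  d1 <- dropout_fwd(at$Out, dropout, train)
  X1 <- X + d1$Y
  l2 <- layernorm_fwd(X1, p$ln2)
  ff <- ff_fwd(l2$Y, p$ff)
  d2 <- dropout_fwd(ff$Y, dropout, train)
  list(Y = X1 + d2$Y,
       cache = list(l1 = l1, at = at, d1 = d1, X1 = X1, l2 = l2, ff = ff, d2 = d2))
}

encoder_layer_bwd <- function(dY, cache, p) {
  dff <- dropout_bwd(dY, cache$d2$mask)
  bf <- ff_bwd(dff, cache$ff, cache$l2$Y, p$ff)
  bl2 <- layernorm_bwd(bf$dX, cache$l2, p$ln2)
  dX1 <- dY + bl2$dX
  dat <- dropout_bwd(dX1, cache$d1$mask)
  bm <- mha_bwd(dat, cache$at$cache, p$mha)
  bl1 <- layernorm_bwd(bm$dX, cache$l1, p$ln1)
  list(dX = dX1 + bl1$dX,
       grads = list(ln1 = list(g = bl1$dg, b = bl1$db), mha = bm$grads,
                    ln2 = list(g = bl2$dg, b = bl2$db), ff = bf$grads))
}

init_encoder <- function(k, n_layers, ff_mult = 4L) {
  lapply(seq_len(n_layers), function(i) init_encoder_layer(k, ff_mult))
}

encoder_fwd <- function(X, layers, S, Tn, h, dropout = 0, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    o <- encoder_layer_fwd(X, layers[[i]], S, Tn, h, dropout, train)
    X <- o$Y
    caches[[i]] <- o$cache
  }
  list(Y = X, caches = caches)
}

encoder_bwd <- function(dY, caches, layers) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- encoder_layer_bwd(dY, caches[[i]], layers[[i]])
    dY <- b$dX
    grads[[i]] <- b$grads
  }
  list(dX = dY, grads = grads)
}

init_coattn <- function(k, project = TRUE) {
  if (!project) return(list())
  list(q = init_linear(k, k), k = init_linear(k, k), v = init_linear(k, k))
}

# Single-head cross-modal attention: queries from the imaging or genetics
# sequence, keys/values from the clinical sequence; d_k equals the full
# embedding dimension.  Output lives in query-token space: O = softmax(QK'/sqrt(k)) V.
coattn_fwd <- function(Xq, Xc, p, S, Tq, Tc, project = TRUE) {
  k <- ncol(Xq)
  sc <- 1 / sqrt(k)
  Q <- if (project) linear_fwd(Xq, p$q) else Xq
  K <- if (project) linear_fwd(Xc, p$k) else Xc
  V <- if (project) linear_fwd(Xc, p$v) else Xc
  O <- matrix(0, nrow(Xq), k)
  A <- array(0, c(Tq, Tc, S))
  for (s in seq_len(S)) {
    iq <- ((s - 1L) * Tq + 1L):(s * Tq)
    ic <- ((s - 1L) * Tc + 1L):(s * Tc)
    As <- softmax_rows(tcrossprod(Q[iq, , drop = FALSE], K[ic, , drop = FALSE]) * sc)
    A[, , s] <- As
    O[iq, ] <- As %*% V[ic, , drop = FALSE]
  }
  list(O = O, A = A,
       cache = list(Xq = Xq, Xc = Xc, Q = Q, K = K, V = V, A = A,
                    S = S, Tq = Tq, Tc = Tc, project = project))
}

coattn_bwd <- function(dO, cache, p) {
  S <- cache$S; Tq <- cache$Tq; Tc <- cache$Tc
  k <- ncol(dO); sc <- 1 / sqrt(k)
  dQ <- matrix(0, S * Tq, k); dK <- matrix(0, S * Tc, k); dV <- dK
  for (s in seq_len(S)) {
    iq <- ((s - 1L) * Tq + 1L):(s * Tq)
    ic <- ((s - 1L) * Tc + 1L):(s * Tc)
    As <- cache$A[, , s, drop = FALSE]
    dim(As) <- c(Tq, Tc)
    dOs <- dO[iq, , drop = FALSE]
    dA <- tcrossprod(dOs, cache$V[ic, , drop = FALSE])
    dV[ic, ] <- crossprod(As, dOs)
    dS <- softmax_rows_bwd(dA, As) * sc
    dQ[iq, ] <- dS %*% cache$K[ic, , drop = FALSE]
    dK[ic, ] <- crossprod(dS, cache$Q[iq, , drop = FALSE])
  }
  if (cache$project) {
    bq <- linear_bwd(dQ, cache$Xq, p$q)
    bk <- linear_bwd(dK, cache$Xc, p$k)
    bv <- linear_bwd(dV, cache$Xc, p$v)
    list(dXq = bq$dX, dXc = bk$dX + bv$dX,
         grads = list(q = list(W = bq$dW, b = bq$db),
                      k = list(W = bk$dW, b = bk$db),
                      v = list(W = bv$dW, b = bv$db)))
  } else {
    list(dXq = dQ, dXc = dK + dV, grads = list())
  }
}

# class-token prepending over subject-major token blocks
cls_positions <- function(S, Tn) (0:(S - 1L)) * (Tn + 1L) + 1L

prepend_cls <- function(Tok, cls, S, Tn) {
  out <- matrix(0, S * (Tn + 1L), ncol(Tok))
  pos <- cls_positions(S, Tn)
  out[pos, ] <- matrix(cls, S, length(cls), byrow = TRUE)
  out[-pos, ] <- Tok
  out
}

prepend_cls_bwd <- function(dOut, S, Tn) {
  pos <- cls_positions(S, Tn)
  list(dcls = colSums(dOut[pos, , drop = FALSE]),
       dTok = dOut[-pos, , drop = FALSE])
}

# mean softmax cross-entropy; returns loss, probabilities and dlogits
ce_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  ix <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[ix], 1e-12)))
  dl <- P
  dl[ix] <- dl[ix] - 1
  list(loss = loss, P = P, dlogits = dl / n)
}

# ---- parameter trees ------------------------------------------------------

tree_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- lapply(seq_along(xs[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(xs, `[[`, i)))
    })
    names(out) <- names(xs[[1]])
    out
  } else {
    do.call(f, xs)
  }
}

tree_zeros <- function(p) tree_map(function(x) x * 0, p)
tree_add <- function(a, b) tree_map(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)

adam_init <- function(p) list(m = tree_zeros(p), v = tree_zeros(p), t = 0L)

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, st$m, g)
  st$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, st$v, g)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  p <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                p, st$m, st$v)
  list(p = p, st = st)
}

# minibatch Adam loop shared by all trainable models.
# step_fn(params, rows, train) -> list(loss, grads); eval_fn(params) -> scalar
# (higher is better) used for best-checkpoint selection when provided.
sgd_train <- function(params, step_fn, n_train, epochs, batch_size, lr,
                      eval_fn = NULL, verbose = FALSE) {
  st <- adam_init(params)
  history <- vector("list", epochs)
  best <- list(score = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n_train)
    losses <- c()
    for (start in seq(1L, n_train, by = batch_size)) {
      rows <- perm[start:min(start + batch_size - 1L, n_train)]
      out <- step_fn(params, rows, TRUE)
      up <- adam_step(params, out$grads, st, lr)
      params <- up$p
      st <- up$st
      losses <- c(losses, out$loss)
    }
    score <- if (is.null(eval_fn)) NA_real_ else eval_fn(params)
    if (!is.null(eval_fn) && score > best$score) {
      best <- list(score = score, params = params, epoch = ep)
    }
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(losses), val_score = score)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f", ep, mean(losses), score))
    }
  }
  if (is.null(eval_fn)) best <- list(score = NA_real_, params = params, epoch = epochs)
  list(params = best$params, final_params = params, best_epoch = best$epoch,
       best_score = best$score, history = bind_rows(history))
}
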