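# Independent reference implementations used as test oracles.  These are
# deliberately written with explicit loops and no shared code with the
# package's batched matrix implementations.

# scaled-dot-product attention, one head, explicit loops
oracle_attention <- function(Q, K, V, d_scale = ncol(Q)) {
  Tq <- nrow(Q); Tc <- nrow(K)
  O <- matrix(0, Tq, ncol(V))
  W <- matrix(0, Tq, Tc)
  for (i in seq_len(Tq)) {
    logits <- numeric(Tc)
    for (j in seq_len(Tc)) {
      logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_scale)
    }
    e <- exp(logits - max(logits))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in seq_len(Tc)) O[i, ] <- O[i, ] + w[j] * V[j, ]
  }
  list(O = O, W = W)
}

oracle_layernorm <- function(X, g, b, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    mu <- mean(x)
    v <- mean((x - mu)^2)
    out[i, ] <- (x - mu) / sqrt(v + eps) * g + b
  }
  out
}

oracle_gelu <- function(x) x / (1 + exp(-1.702 * x))

# one pre-LN transformer layer: X' = MHA(LN(X)) + X; Y = FF(LN(X')) + X'
# p is the package's encoder-layer parameter list (weights only are reused;
# the computation is independent)
oracle_encoder_layer <- function(X, p, n_heads) {
  k <- ncol(X)
  dh <- k / n_heads
  H <- oracle_layernorm(X, p$ln1$g, p$ln1$b)
  Q <- H %*% p$mha$q$W + matrix(p$mha$q$b, nrow(X), k, byrow = TRUE)
  K <- H %*% p$mha$k$W + matrix(p$mha$k$b, nrow(X), k, byrow = TRUE)
  V <- H %*% p$mha$v$W + matrix(p$mha$v$b, nrow(X), k, byrow = TRUE)
  Ctx <- matrix(0, nrow(X), k)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Ctx[, cols] <- oracle_attention(Q[, cols, drop = FALSE],
                                    K[, cols, drop = FALSE],
                                    V[, cols, drop = FALSE], d_scale = dh)$O
  }
  X1 <- Ctx %*% p$mha$o$W + matrix(p$mha$o$b, nrow(X), k, byrow = TRUE) + X
  H2 <- oracle_layernorm(X1, p$ln2$g, p$ln2$b)
  F1 <- oracle_gelu(H2 %*% p$ff$l1$W + matrix(p$ff$l1$b, nrow(X), ncol(p$ff$l1$W), byrow = TRUE))
  F2 <- F1 %*% p$ff$l2$W + matrix(p$ff$l2$b, nrow(X), k, byrow = TRUE)
  F2 + X1
}

# one-vs-one AUROC by exhaustive concordant / discordant / tied pair
# counting (no ranks)
oracle_auroc_ovo <- function(truth, prob) {
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  directed_auc <- function(score, pos) {
    p_idx <- which(pos); n_idx <- which(!pos)
    tot <- 0
    for (i in p_idx) for (j in n_idx) {
      tot <- tot + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
    }
    tot / (length(p_idx) * length(n_idx))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  mean(vapply(pairs, function(pr) {
    keep <- truth %in% pr
    a1 <- directed_auc(prob[keep, pr[1]], truth[keep] == pr[1])
    a2 <- directed_auc(prob[keep, pr[2]], truth[keep] == pr[2])
    (a1 + a2) / 2
  }, numeric(1)))
}

# conservative null SE of the pairwise-averaged AUROC: per-pair Hanley
# variance, pairs treated as independent
null_auroc_se <- function(truth) {
  tab <- table(truth)
  classes <- names(tab)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  v <- vapply(pairs, function(pr) {
    n1 <- tab[[pr[1]]]; n2 <- tab[[pr[2]]]
    (n1 + n2 + 1) / (12 * n1 * n2)
  }, numeric(1))
  sqrt(sum(v)) / length(v)
}

# finite-difference gradient checking over nested parameter trees
tree_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      for (i in seq_along(node)) walk(node[[i]], c(path, i))
    } else {
      out[[length(out) + 1]] <<- path
    }
  }
  walk(tree, integer(0))
  out
}

tree_get <- function(tree, path) {
  for (i in path) tree <- tree[[i]]
  tree
}

tree_set <- function(tree, path, val) {
  if (length(path) == 1) {
    tree[[path]] <- val
    return(tree)
  }
  tree[[path[1]]] <- tree_set(tree[[path[1]]], path[-1], val)
  tree
}

max_grad_error <- function(params, loss_fn, grads, n_checks = 40, eps = 1e-5) {
  paths <- tree_paths(params)
  maxerr <- 0
  for (t in seq_len(n_checks)) {
    p_i <- paths[[sample(length(paths), 1)]]
    leaf <- tree_get(params, p_i)
    ei <- sample(length(leaf), 1)
    up <- leaf; up[ei] <- up[ei] + eps
    dn <- leaf; dn[ei] <- dn[ei] - eps
    num <- (loss_fn(tree_set(params, p_i, up)) -
              loss_fn(tree_set(params, p_i, dn))) / (2 * eps)
    ana <- tree_get(grads, p_i)[ei]
    maxerr <- max(maxerr, abs(num - ana) / max(1e-6, abs(num), abs(ana)))
  }
  maxerr
}
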